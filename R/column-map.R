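# The column map is the indel-aware coordinate system of the alignment:
# every reference base owns one column, and each variant whose allele set
# contains insertions reserves a slot of extra columns — sized by its
# longest insertion allele — immediately after the last base of its
# (normalized) REF span. Non-carriers receive '-' across the slot, so every
# row keeps the same length and no realignment is ever needed.

#' Build the insertion-aware column map for a window
#'
#' @param window a [ref_window()].
#' @param variants list of `norm_variant` (disjoint, within the window),
#'   e.g. from [normalize_region()].
#' @return an object of class `column_map`: list with `base_col` (integer,
#'   alignment column of each reference base), `ins_slot` (integer, number
#'   of insertion columns after each reference base) and `total_cols`.
#' @export
build_column_map <- function(window, variants = list()) {
  n <- nchar(window$seq)
  ins <- integer(n)
  for (v in variants) {
    if (v$pos < window$start || v$pos + nchar(v$ref) - 1L > window$end)
      stop_input("variant at %d outside window %s:%d-%d",
                 v$pos, window$chrom, window$start, window$end)
    m <- max(v$ins_len)
    if (m > 0L) {
      off <- v$pos - window$start + nchar(v$ref)  # last REF base, 1-based
      ins[off] <- max(ins[off], m)
    }
  }
  base_col <- seq_len(n) + c(0L, cumsum(ins)[-n])
  structure(list(base_col = base_col, ins_slot = ins,
                 total_cols = n + sum(ins)),
            class = "column_map")
}

#' @export
print.column_map <- function(x, ...) {
  cat(sprintf("<column_map> %d reference bases -> %d columns (%d inserted)\n",
              length(x$base_col), x$total_cols, sum(x$ins_slot)))
  invisible(x)
}

#' Render the reference track as an aligned row
#'
#' Reference bases sit at their base columns; every insertion slot is
#' gap-filled, so degapping the row returns the window sequence.
#'
#' @param window a [ref_window()].
#' @param cmap a [build_column_map()] result.
#' @return a string of length `cmap$total_cols`.
#' @export
render_reference_row <- function(window, cmap) {
  row <- rep("-", cmap$total_cols)
  row[cmap$base_col] <- split_chars(window$seq)
  paste(row, collapse = "")
}
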
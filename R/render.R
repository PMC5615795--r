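# Rendering edits the reference row per haplotype, per variant:
#   SNV/MNP    — substitute at base columns;
#   deletion   — '-' at the deleted bases' columns;
#   insertion  — inserted bases left-aligned into the anchor's slot,
#                remainder '-' (non-carriers keep the whole slot gapped).
# Degapping any rendered row must reproduce the haplotype obtained by
# applying its alleles directly to the window sequence — the module's
# master invariant, exercised throughout the tests.

# Apply one allele of one normalized variant to a character-vector row.
apply_allele <- function(row, window, cmap, v, allele) {
  ref_len <- nchar(v$ref)
  off0 <- v$pos - window$start + 1L           # window offset of first base
  offs <- off0:(off0 + ref_len - 1L)
  alt <- v$alts[allele]
  alt_len <- nchar(alt)
  k <- min(ref_len, alt_len)
  achars <- split_chars(alt)
  row[cmap$base_col[offs[seq_len(k)]]] <- achars[seq_len(k)]
  if (alt_len < ref_len)
    row[cmap$base_col[offs[(k + 1L):ref_len]]] <- "-"
  if (alt_len > ref_len) {
    slot_off <- offs[ref_len]
    width <- cmap$ins_slot[slot_off]
    extra <- achars[(k + 1L):alt_len]
    cols <- cmap$base_col[slot_off] + seq_len(width)
    row[cols] <- c(extra, rep("-", width - length(extra)))
  }
  row
}

#' Render one haplotype as an aligned row
#'
#' @param window a [ref_window()].
#' @param cmap the [build_column_map()] of `variants`.
#' @param variants list of `norm_variant` (disjoint).
#' @param alleles integer vector, one allele index per variant for this
#'   haplotype (0 = reference, NA = missing).
#' @param missing_policy how to render a missing genotype: `"ref"` keeps
#'   the reference bases (default), `"N"` writes N across the REF span.
#' @return a string of length `cmap$total_cols`.
#' @export
render_haplotype <- function(window, cmap, variants, alleles,
                             missing_policy = c("ref", "N")) {
  missing_policy <- match.arg(missing_policy)
  if (length(alleles) != length(variants))
    stop_input("need one allele index per variant (%d vs %d)",
               length(alleles), length(variants))
  row <- rep("-", cmap$total_cols)
  row[cmap$base_col] <- split_chars(window$seq)
  for (i in seq_along(variants)) {
    v <- variants[[i]]
    a <- alleles[i]
    if (is.na(a)) {
      if (missing_policy == "N") {
        offs <- (v$pos - window$start + 1L):
                (v$pos - window$start + nchar(v$ref))
        row[cmap$base_col[offs]] <- "N"
      }
      next
    }
    if (a == 0L) next
    if (a < 0L || a > length(v$alts))
      stop_input("allele index %d out of range at %s:%d", a, v$chrom, v$pos)
    row <- apply_allele(row, window, cmap, v, a)
  }
  paste(row, collapse = "")
}

#' Build the full cohort alignment
#'
#' Two rows per phased sample, labeled `<sample>_hap1` / `<sample>_hap2`
#' (left genotype allele = hap1), in the given sample order.
#'
#' @param window a [ref_window()].
#' @param variants list of `norm_variant` from [normalize_region()].
#' @param samples character vector giving the row order; defaults to the
#'   sample order of the variants' genotype matrices.
#' @param missing_policy see [render_haplotype()].
#' @param reference_row if `TRUE`, prepend the reference track labeled
#'   with the chromosome name.
#' @return a [hap_alignment()].
#' @export
build_alignment <- function(window, variants, samples = NULL,
                            missing_policy = c("ref", "N"),
                            reference_row = FALSE) {
  missing_policy <- match.arg(missing_policy)
  if (is.null(samples)) {
    samples <- if (length(variants)) rownames(variants[[1]]$gt)
               else character(0)
  }
  cmap <- build_column_map(window, variants)
  labels <- character(0)
  seqs <- character(0)
  if (reference_row) {
    labels <- paste0(window$chrom, "_ref")
    seqs <- render_reference_row(window, cmap)
  }
  for (s in samples) {
    for (h in 1:2) {
      alleles <- vapply(variants, function(v) v$gt[s, h], integer(1))
      labels <- c(labels, sprintf("%s_hap%d", s, h))
      seqs <- c(seqs, render_haplotype(window, cmap, variants, alleles,
                                       missing_policy))
    }
  }
  if (!length(labels))
    stop_input("no rows to build: no samples and no reference row")
  hap_alignment(labels, seqs)
}

#' Remove gap characters from sequences
#'
#' @param x character vector of aligned sequences.
#' @return `x` with all `-` removed.
#' @export
degap <- function(x) gsub("-", "", x, fixed = TRUE)
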
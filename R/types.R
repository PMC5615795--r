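#' Reference window
#'
#' A contiguous slice of a reference chromosome: the coordinate frame every
#' other computation works in. Coordinates are 1-based inclusive.
#'
#' @param chrom chromosome name.
#' @param start 1-based reference coordinate of the first base of `seq`.
#' @param seq uppercase nucleotide string over `{A,C,G,T,N}`; no gaps.
#' @return an object of class `ref_window` with fields `chrom`, `start`,
#'   `end`, `seq`.
#' @examples
#' ref_window("chr1", 11, "ACGTACGT")
#' @export
ref_window <- function(chrom, start, seq) {
  start <- as.integer(start)
  if (is.na(start) || start < 1L) stop_input("window start must be >= 1")
  if (!nzchar(seq)) stop_input("window sequence must be non-empty")
  seq <- sanitize_bases(seq, "reference window")
  structure(
    list(chrom = chrom, start = start,
         end = start + nchar(seq) - 1L, seq = seq),
    class = "ref_window")
}

#' @export
print.ref_window <- function(x, ...) {
  cat(sprintf("<ref_window> %s:%d-%d (%d bp)\n",
              x$chrom, x$start, x$end, nchar(x$seq)))
  invisible(x)
}

#' Haplotype alignment matrix
#'
#' Labeled equal-length rows over the alphabet `{A,C,G,T,N,-}`.
#'
#' @param labels character vector of unique row labels.
#' @param seqs character vector of aligned sequences, one per label.
#' @return an object of class `hap_alignment` with fields `labels`, `seqs`,
#'   `ncols`.
#' @export
hap_alignment <- function(labels, seqs) {
  if (length(labels) != length(seqs))
    stop_input("labels and seqs must have equal length")
  if (length(seqs) == 0L) stop_input("alignment must have at least one row")
  w <- unique(nchar(seqs))
  if (length(w) != 1L)
    stop_input("alignment rows have unequal lengths: %s",
               paste(w, collapse = ", "))
  labels <- uniquify_labels(as.character(labels))
  structure(list(labels = labels, seqs = unname(seqs), ncols = w),
            class = "hap_alignment")
}

#' @export
print.hap_alignment <- function(x, ...) {
  cat(sprintf("<hap_alignment> %d rows x %d columns\n",
              length(x$labels), x$ncols))
  n <- min(6L, length(x$labels))
  for (i in seq_len(n)) {
    s <- x$seqs[i]
    if (nchar(s) > 50) s <- paste0(substr(s, 1, 50), "...")
    cat(sprintf("  %-20s %s\n", x$labels[i], s))
  }
  if (length(x$labels) > n) cat(sprintf("  ... %d more rows\n",
                                        length(x$labels) - n))
  invisible(x)
}

# rbind-like helper used by the pipeline when appending archaic/outgroup rows
append_rows <- function(aln, labels, seqs) {
  hap_alignment(c(aln$labels, labels), c(aln$seqs, seqs))
}
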
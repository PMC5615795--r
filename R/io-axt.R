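# AXT is the UCSC pairwise-alignment dialect the hg19/panTro4 and
# hg19/rheMac3 alignments ship in: per block, a 9-field coordinate header
# ("num tChrom tStart tEnd qChrom qStart qEnd strand score"), then the
# target (human) and query (outgroup) aligned lines. No installed package
# parses it, so the reader lives here.

#' Read pairwise alignment blocks from an AXT file
#'
#' @param path AXT file.
#' @return a list of pairwise blocks sorted by human start, each a list with
#'   `human_chrom`, `human_start`, `human_end`, `human_aln`, `other_aln`.
#'   Validates per block that the number of non-gap human characters equals
#'   the declared human span, and that no two blocks overlap on the human
#'   axis.
#' @export
read_axt <- function(path) {
  if (!file.exists(path)) stop_input("AXT file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  lines <- lines[cumsum(nzchar(lines)) > 0 | nzchar(lines)]  # keep structure
  blocks <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    hdr <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(hdr) < 9L)
      stop_input("AXT %s: malformed header at line %d", path, i)
    if (i + 2L > n)
      stop_input("AXT %s: truncated block at line %d", path, i)
    h_aln <- toupper(trimws(lines[i + 1L]))
    o_aln <- toupper(trimws(lines[i + 2L]))
    if (nchar(h_aln) != nchar(o_aln))
      stop_input("AXT %s: aligned lines of unequal length in block at line %d",
                 path, i)
    h_start <- as.integer(hdr[3]); h_end <- as.integer(hdr[4])
    span <- h_end - h_start + 1L
    nongap <- nchar(gsub("-", "", h_aln, fixed = TRUE))
    if (nongap != span)
      stop_input(paste0("AXT %s: block at line %d declares human span %d ",
                        "but the human line has %d non-gap characters"),
                 path, i, span, nongap)
    blocks[[length(blocks) + 1L]] <- list(
      human_chrom = hdr[2], human_start = h_start, human_end = h_end,
      human_aln = h_aln, other_aln = o_aln)
    i <- i + 3L
  }
  if (length(blocks) > 1L) {
    ord <- order(vapply(blocks, `[[`, integer(1), "human_start"))
    blocks <- blocks[ord]
    starts <- vapply(blocks, `[[`, integer(1), "human_start")
    ends <- vapply(blocks, `[[`, integer(1), "human_end")
    if (any(starts[-1L] <= ends[-length(ends)]))
      stop_input("AXT %s: blocks overlap on the human axis", path)
  }
  blocks
}

#' Write pairwise alignment blocks to an AXT file
#'
#' Inverse of [read_axt()]; used by the fixture generator.
#'
#' @param blocks list of blocks as returned by [read_axt()].
#' @param path output file.
#' @param other_chrom,score query-side chromosome name and score to stamp
#'   into each header (the projection only uses the human coordinates).
#' @return `path`, invisibly.
#' @export
write_axt <- function(blocks, path, other_chrom = "chrUn", score = 1000L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    qlen <- nchar(gsub("-", "", b$other_aln, fixed = TRUE))
    writeLines(c(
      sprintf("%d %s %d %d %s %d %d + %d", k - 1L, b$human_chrom,
              b$human_start, b$human_end, other_chrom, 1L, max(qlen, 1L),
              score),
      b$human_aln, b$other_aln, ""), con)
  }
  invisible(path)
}
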
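# Relaxed sequential Phylip: "<ntaxa> <ncols>" then one "name sequence" line
# per row. Haplotype labels like "HG00096_hap2" exceed the strict 10-column
# name field, so names are written in full (relaxed dialect), never
# truncated; duplicates are uniquified.

#' Write an alignment in relaxed sequential Phylip format
#'
#' @param aln a [hap_alignment()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(aln, path) {
  stopifnot(inherits(aln, "hap_alignment"))
  labels <- uniquify_labels(aln$labels)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(labels), aln$ncols), con)
  writeLines(paste(labels, aln$seqs), con)
  invisible(path)
}

#' Read a relaxed sequential Phylip alignment
#'
#' Inverse of [write_phylip()].
#'
#' @param path Phylip file.
#' @return a [hap_alignment()].
#' @export
read_phylip <- function(path) {
  if (!file.exists(path)) stop_input("Phylip file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop_input("Phylip %s: no sequence rows", path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 2L || anyNA(hdr))
    stop_input("Phylip %s: malformed header '%s'", path, lines[1])
  body <- lines[-1L]
  if (length(body) != hdr[1])
    stop_input("Phylip %s: header declares %d taxa, found %d rows",
               path, hdr[1], length(body))
  m <- regmatches(body, regexec("^(\\S+)\\s+(\\S+)$", body))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad))
    stop_input("Phylip %s: malformed row %d", path, which(bad)[1] + 1L)
  labels <- vapply(m, `[`, character(1), 2L)
  seqs <- toupper(vapply(m, `[`, character(1), 3L))
  if (any(nchar(seqs) != hdr[2]))
    stop_input("Phylip %s: row length disagrees with header", path)
  hap_alignment(labels, seqs)
}
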
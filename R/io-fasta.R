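#' Read a reference window from a FASTA file
#'
#' Extracts the requested region (1-based inclusive, tabix convention) from a
#' FASTA file. Soft-masked (lowercase) bases are uppercased; ambiguity codes
#' other than N are mapped to N with a warning.
#'
#' @param path FASTA file (plain or gzipped).
#' @param region region string `chrom:start-end`.
#' @return a [ref_window()].
#' @export
read_fasta_window <- function(path, region) {
  if (!file.exists(path)) stop_input("FASTA file not found: %s", path)
  reg <- parse_region(region)
  ss <- Biostrings::readDNAStringSet(path)
  # FASTA descriptions: the record id is the first whitespace token
  ids <- sub("\\s.*$", "", names(ss))
  hit <- match(reg$chrom, ids)
  if (is.na(hit))
    stop_input("sequence '%s' not found in %s (has: %s)",
               reg$chrom, path, paste(utils::head(ids, 5), collapse = ", "))
  len <- Biostrings::width(ss)[hit]
  if (reg$end > len)
    stop_input("region %s extends beyond sequence '%s' (length %d)",
               region, reg$chrom, len)
  seq <- as.character(Biostrings::subseq(ss[[hit]], reg$start, reg$end))
  ref_window(reg$chrom, reg$start, seq)
}

#' Write an alignment to FASTA
#'
#' Sequences are wrapped at 60 columns; duplicate labels are uniquified with
#' a `.k` suffix.
#'
#' @param aln a [hap_alignment()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "hap_alignment"))
  ss <- Biostrings::DNAStringSet(aln$seqs)
  names(ss) <- uniquify_labels(aln$labels)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Read an alignment from FASTA
#'
#' Inverse of [write_fasta()] on the alignment alphabet `{A,C,G,T,N,-}`.
#'
#' @param path FASTA file with equal-length records.
#' @return a [hap_alignment()].
#' @export
read_fasta_alignment <- function(path) {
  if (!file.exists(path)) stop_input("FASTA file not found: %s", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop_input("no records in %s", path)
  hap_alignment(names(ss), toupper(as.character(ss)))
}
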
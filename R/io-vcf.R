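# VCF reading sits on vcfR (plain or bgzipped input); this layer slices the
# requested region, parses genotypes into allele-index matrices, and applies
# the inclusion rule: a record belongs to the region iff its POS does.

parse_info <- function(info) {
  if (is.na(info) || info == "." || !nzchar(info)) return(character(0))
  parts <- strsplit(info, ";", fixed = TRUE)[[1]]
  kv <- regmatches(parts, regexec("^([^=]+)=?(.*)$", parts))
  vals <- vapply(kv, `[`, character(1), 3L)
  names(vals) <- vapply(kv, `[`, character(1), 2L)
  vals
}

# Parse one sample's GT string ("0|1", "0/1", ".", ".|.") into a 2-vector of
# 0-based allele indices (NA = missing) plus a phased flag.
parse_gt <- function(gt, n_alt, where) {
  g <- sub(":.*$", "", gt)
  if (is.na(g) || g == "." || g == "./." || g == ".|.")
    return(list(alleles = c(NA_integer_, NA_integer_),
                phased = !grepl("/", g, fixed = TRUE)))
  phased <- !grepl("/", g, fixed = TRUE)
  toks <- strsplit(g, "[|/]")[[1]]
  if (length(toks) != 2L)
    stop_input("mixed-ploidy or malformed genotype '%s' at %s", g, where)
  al <- suppressWarnings(as.integer(ifelse(toks == ".", NA, toks)))
  bad <- !is.na(al) & (al < 0L | al > n_alt)
  if (any(bad) || (any(is.na(al)) && any(toks != "." & is.na(al))))
    stop_input("genotype '%s' at %s has allele index outside [0, %d]",
               g, where, n_alt)
  list(alleles = al, phased = phased)
}

#' Read variant records for a region from a VCF file
#'
#' Returns the records whose POS falls inside the region, in file order.
#' Records that start before the region but whose REF span reaches into it
#' are skipped (not truncated) and counted, so no alleles outside the
#' requested window are ever fabricated.
#'
#' @param path VCF file, plain or bgzip/gzip compressed.
#' @param region region string `chrom:start-end` (1-based inclusive).
#' @return an object of class `variant_set`: a list with `samples`
#'   (character), `records` (list of raw records, each with `chrom`, `pos`,
#'   `id`, `ref`, `alts`, `info`, `gt` — an integer samples x 2 matrix of
#'   allele indices, NA = missing — and `phased`, a logical per sample),
#'   `skipped` (a data frame describing excluded left-overlapping records)
#'   and `region`.
#' @export
read_vcf_region <- function(path, region) {
  if (!file.exists(path)) stop_input("VCF file not found: %s", path)
  reg <- parse_region(region)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt_mat <- v@gt
  if (is.null(gt_mat) || ncol(gt_mat) < 2L)
    stop_input("VCF %s has no sample genotype columns", path)
  samples <- colnames(gt_mat)[-1L]

  records <- list()
  skipped <- data.frame(chrom = character(), pos = integer(),
                        id = character(), ref = character(),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(fix))) {
    chrom <- fix[i, "CHROM"]
    if (chrom != reg$chrom) next
    pos <- as.integer(fix[i, "POS"])
    ref <- toupper(fix[i, "REF"])
    if (pos > reg$end) next
    if (pos < reg$start) {
      if (pos + nchar(ref) - 1L >= reg$start)
        skipped <- rbind(skipped, data.frame(
          chrom = chrom, pos = pos, id = fix[i, "ID"], ref = ref,
          stringsAsFactors = FALSE))
      next
    }
    alt_field <- fix[i, "ALT"]
    if (is.na(alt_field) || alt_field == ".") next  # monomorphic line
    alts <- toupper(strsplit(alt_field, ",", fixed = TRUE)[[1]])
    where <- sprintf("%s record %d (%s:%d)", basename(path), i, chrom, pos)
    gts <- lapply(gt_mat[i, -1L], parse_gt, n_alt = length(alts),
                  where = where)
    gm <- t(vapply(gts, `[[`, integer(2), "alleles"))
    rownames(gm) <- samples
    records[[length(records) + 1L]] <- list(
      chrom = chrom, pos = pos,
      id = if (is.na(fix[i, "ID"])) "." else fix[i, "ID"],
      ref = ref, alts = alts,
      info = parse_info(fix[i, "INFO"]),
      gt = gm,
      phased = vapply(gts, `[[`, logical(1), "phased"),
      line = i)
  }
  structure(list(samples = samples, records = records,
                 skipped = skipped, region = reg),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("<variant_set> %s:%d-%d: %d records, %d samples, %d skipped\n",
              x$region$chrom, x$region$start, x$region$end,
              length(x$records), length(x$samples), nrow(x$skipped)))
  invisible(x)
}

#' Keep only the named samples of a variant set
#'
#' @param vset a `variant_set` from [read_vcf_region()].
#' @param samples character vector of sample IDs to keep.
#' @return the filtered `variant_set`.
#' @export
filter_samples <- function(vset, samples) {
  missing <- setdiff(samples, vset$samples)
  if (length(missing))
    stop_input("samples not present in VCF: %s",
               paste(utils::head(missing, 5), collapse = ", "))
  keep <- vset$samples %in% samples
  vset$samples <- vset$samples[keep]
  vset$records <- lapply(vset$records, function(r) {
    r$gt <- r$gt[keep, , drop = FALSE]
    r$phased <- r$phased[keep]
    r
  })
  vset
}

# The per-haplotype reconstruction is only defined for phased genotypes;
# unphased cohort calls must go through the unphased-genome pathway.
check_phased <- function(vset) {
  for (r in vset$records) {
    unph <- !r$phased & !apply(is.na(r$gt), 1L, all) &
      r$gt[, 1L] != r$gt[, 2L]
    # homozygous "0/0"-style calls are unambiguous; only het unphased fails
    if (any(unph, na.rm = TRUE))
      stop_input(paste0(
        "unphased heterozygous genotype for sample %s at %s:%d; the cohort ",
        "VCF must be phased (use the unphased-genome pathway for single ",
        "genomes)"),
        vset$samples[which(unph)[1]], r$chrom, r$pos)
  }
  invisible(vset)
}
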
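# Unphased single genomes (archaic-style) and outgroup tracks are added to
# an existing cohort alignment without ever touching the cohort rows or the
# column map: substitutions land at base columns, every cohort insertion
# slot stays gapped, and INDEL calls from unphased genomes are reported to
# a side file instead of being integrated.

#' Select the usable variants of an unphased single genome
#'
#' Because such genomes are unphased, only homozygous non-reference calls
#' are trusted as true differences from the reference: homozygous SNVs (and
#' same-length multi-base substitutions, applied per column) become
#' substitutions; heterozygous or missing sites keep the reference base.
#' INDEL-classified records are never applied — they are returned for the
#' `Indels_<name>.txt` report — and structural variants go to the SV list.
#'
#' @param vset single-sample `variant_set` from [read_vcf_region()].
#' @param window a [ref_window()] (substitutions reaching past its edge are
#'   clipped).
#' @return list with `snvs` (data frame `pos`, `ref`, `alt` of applied
#'   substitutions), `indel_report` (data frame `pos`, `ref`, `alt`, `gt`),
#'   `sv_records`, and counts `n_het_skipped`, `n_missing`.
#' @export
select_homozygous_snvs <- function(vset, window) {
  if (length(vset$samples) != 1L)
    stop_input("unphased-genome VCF must contain exactly one sample, found %d",
               length(vset$samples))
  snvs <- data.frame(pos = integer(), ref = character(), alt = character(),
                     stringsAsFactors = FALSE)
  indels <- data.frame(pos = integer(), ref = character(), alt = character(),
                       gt = character(), stringsAsFactors = FALSE)
  svs <- list()
  n_het <- 0L
  n_missing <- 0L
  for (rec in vset$records) {
    classes <- classify_record(rec)
    if (all(classes == "SV")) { svs <- c(svs, list(rec)); next }
    g <- rec$gt[1L, ]
    if (all(is.na(g))) { n_missing <- n_missing + 1L; next }
    homo <- !anyNA(g) && g[1L] == g[2L] && g[1L] > 0L
    a <- if (homo) g[1L] else NA_integer_
    # INDEL records are reported whatever the genotype; "1/2" is homozygous
    # for nothing and counts as heterozygous
    idx_indel <- which(classes %in% c("INSERTION", "DELETION"))
    for (ai in idx_indel)
      indels <- rbind(indels, data.frame(
        pos = rec$pos, ref = rec$ref, alt = rec$alts[ai],
        gt = paste(ifelse(is.na(g), ".", g), collapse = "/"),
        stringsAsFactors = FALSE))
    if (!homo) {
      if (any(classes %in% c("SNV", "MNP_SUBSTITUTION")))
        n_het <- n_het + 1L
      next
    }
    if (classes[a] %in% c("SNV", "MNP_SUBSTITUTION")) {
      snvs <- rbind(snvs, data.frame(
        pos = rec$pos, ref = rec$ref, alt = rec$alts[a],
        stringsAsFactors = FALSE))
    } else if (classes[a] == "SV") {
      svs <- c(svs, list(rec))
    }
    # homozygous INDEL: already reported above, never applied
  }
  list(snvs = snvs, indel_report = indels, sv_records = svs,
       n_het_skipped = n_het, n_missing = n_missing)
}

#' Render an unphased genome as one aligned row
#'
#' @param window a [ref_window()].
#' @param cmap the cohort's [build_column_map()] (read-only).
#' @param snvs data frame of substitutions (`pos`, `ref`, `alt`) from
#'   [select_homozygous_snvs()].
#' @return a string of length `cmap$total_cols`; all cohort insertion slots
#'   are gap-filled.
#' @export
render_unphased_row <- function(window, cmap, snvs) {
  row <- rep("-", cmap$total_cols)
  row[cmap$base_col] <- split_chars(window$seq)
  n <- nchar(window$seq)
  for (i in seq_len(nrow(snvs))) {
    off0 <- snvs$pos[i] - window$start + 1L
    chars <- split_chars(snvs$alt[i])
    for (k in seq_along(chars)) {
      off <- off0 + k - 1L
      if (off >= 1L && off <= n) row[cmap$base_col[off]] <- chars[k]
    }
  }
  paste(row, collapse = "")
}

#' Project an outgroup genome into the alignment's coordinate system
#'
#' Walks the reference-anchored pairwise alignment and keeps only the
#' columns where the human side is ungapped ("only the alignment gaps that
#' have been identified in human sequences" survive): at each human
#' reference position covered by a block, the outgroup character aligned to
#' that base is taken (a gap on the outgroup side stays a gap); columns
#' where the human side is gapped — outgroup-specific insertions — are
#' dropped; positions covered by no block receive `fill`. All cohort
#' insertion slots are gap-filled, so the row length always equals
#' `cmap$total_cols`.
#'
#' @param blocks list of pairwise blocks from [read_axt()].
#' @param window a [ref_window()].
#' @param cmap the cohort's [build_column_map()] (read-only).
#' @param fill character used for window positions covered by no block
#'   (`"-"` by default; `"N"` marks them as unknown instead).
#' @return list with `row` (the aligned string) and `n_human_gap_dropped`
#'   (count of dropped outgroup-insertion columns — the quantity that
#'   bounds how far human-specific deletions can hide divergence).
#' @export
project_outgroup <- function(blocks, window, cmap, fill = c("-", "N")) {
  fill <- match.arg(fill)
  n <- nchar(window$seq)
  vals <- rep(fill, n)
  if (length(blocks) > 1L) {
    starts <- vapply(blocks, `[[`, integer(1), "human_start")
    ends <- vapply(blocks, `[[`, integer(1), "human_end")
    ord <- order(starts)
    if (any(starts[ord][-1L] <= ends[ord][-length(ord)]))
      stop_input("pairwise blocks overlap on the human axis")
    blocks <- blocks[ord]
  }
  dropped <- 0L
  for (b in blocks) {
    h <- split_chars(b$human_aln)
    o <- split_chars(b$other_aln)
    pos <- b$human_start
    for (k in seq_along(h)) {
      if (h[k] == "-") {                      # outgroup insertion: dropped
        if (pos > window$start && pos <= window$end + 1L)
          dropped <- dropped + 1L
        next
      }
      if (pos >= window$start && pos <= window$end) {
        ch <- o[k]
        if (ch != "-" && !ch %in% c("A", "C", "G", "T", "N")) ch <- "N"
        vals[pos - window$start + 1L] <- ch
      }
      pos <- pos + 1L
    }
  }
  row <- rep("-", cmap$total_cols)
  row[cmap$base_col] <- vals
  list(row = paste(row, collapse = ""), n_human_gap_dropped = dropped)
}
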
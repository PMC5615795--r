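# Normalization of "complex variations": loci with mixed SNP/INDEL entries,
# duplicate same-position lines, and overlapping deletions are rewritten as
# one canonical multiallelic record per locus, so that downstream rendering
# only ever sees pairwise-disjoint variants. Overlapping groups that contain
# an insertion cannot be represented against the reference and abort with a
# dedicated error.

window_substr <- function(window, from, to) {
  if (from < window$start || to > window$end)
    stop_input("positions %d-%d outside window %s:%d-%d",
               from, to, window$chrom, window$start, window$end)
  substr(window$seq, from - window$start + 1L, to - window$start + 1L)
}

check_ref_consistency <- function(rec, window) {
  expect <- window_substr(window, rec$pos, rec$pos + nchar(rec$ref) - 1L)
  if (expect != rec$ref)
    stop_input(paste0("REF allele '%s' at %s:%d disagrees with the ",
                      "reference window ('%s')"),
               rec$ref, rec$chrom, rec$pos, expect)
  invisible(TRUE)
}

# Extend a record's REF (and each ALT with the same flanks) to the span
# [anchor, union_end] using reference bases.
pad_alleles <- function(rec, anchor, union_end, window) {
  check_ref_consistency(rec, window)
  left <- if (rec$pos > anchor)
    window_substr(window, anchor, rec$pos - 1L) else ""
  rend <- rec$pos + nchar(rec$ref) - 1L
  right <- if (rend < union_end)
    window_substr(window, rend + 1L, union_end) else ""
  list(ref = paste0(left, rec$ref, right),
       alts = paste0(left, rec$alts, right))
}

#' Convert a SNV record to INDEL form for merging
#'
#' At a locus carrying both a single-nucleotide variant and an INDEL
#' (VCF `VT=SNP,INDEL` loci, or the same locus reported on two lines), the
#' shorter REF is extended with reference bases to the longer REF's length
#' and each of its ALT alleles receives the same suffix, so the two records
#' become mergeable as one multiallelic line.
#'
#' @param snv_record,indel_record raw records sharing the same `pos`.
#' @param window the [ref_window()] covering both REF spans.
#' @return a list with `ref` (the extended common REF) and `alts` (a list of
#'   two character vectors: the padded ALTs of each input record, in order).
#' @export
convert_snp_to_indel_form <- function(snv_record, indel_record, window) {
  if (snv_record$pos != indel_record$pos)
    stop_input("records must share the same position (%d vs %d)",
               snv_record$pos, indel_record$pos)
  union_end <- max(snv_record$pos + nchar(snv_record$ref) - 1L,
                   indel_record$pos + nchar(indel_record$ref) - 1L)
  a <- pad_alleles(snv_record, snv_record$pos, union_end, window)
  b <- pad_alleles(indel_record, indel_record$pos, union_end, window)
  list(ref = a$ref, alts = list(a$alts, b$alts))
}

# Merge >= 1 span-intersecting records (SVs already removed) into one
# canonical multiallelic variant with remapped genotypes.
merge_records <- function(records, window, on_conflict = c("error", "first")) {
  on_conflict <- match.arg(on_conflict)
  stopifnot(length(records) >= 1L)
  pos <- vapply(records, `[[`, integer(1), "pos")
  ends <- pos + vapply(records, function(r) nchar(r$ref), integer(1)) - 1L
  anchor <- min(pos)
  union_end <- max(ends)

  if (length(unique(pos)) > 1L) {
    has_ins <- vapply(records, function(r)
      any(nchar(r$alts) > nchar(r$ref)), logical(1))
    if (any(has_ins))
      stop_overlap_insertion(paste0(
        "insertion at %s:%d overlaps another variant (span %d-%d); ",
        "overlapping INDELs involving sequence absent from the reference ",
        "cannot be aligned"),
        records[[which(has_ins)[1]]]$chrom, pos[which(has_ins)[1]],
        anchor, union_end)
  }

  merged_ref <- window_substr(window, anchor, union_end)
  samples <- rownames(records[[1]]$gt)
  nhap <- length(samples) * 2L
  merged_gt <- matrix(0L, nrow = length(samples), ncol = 2L,
                      dimnames = list(samples, NULL))
  claimed <- matrix(0L, nrow = length(samples), ncol = 2L)  # source record
  seen_na <- matrix(0L, nrow = length(samples), ncol = 2L)
  alts <- character(0)
  dropped_nonvariant <- 0L
  conflicts <- 0L

  for (ri in seq_along(records)) {
    rec <- records[[ri]]
    padded <- pad_alleles(rec, anchor, union_end, window)
    # map this record's allele indices into the merged index space
    amap <- integer(length(rec$alts))
    for (ai in seq_along(padded$alts)) {
      pa <- padded$alts[ai]
      if (pa == merged_ref) {          # non-variant after padding
        dropped_nonvariant <- dropped_nonvariant + 1L
        warning(sprintf(
          "allele %s>%s at %s:%d equals the reference after padding; dropped",
          rec$ref, rec$alts[ai], rec$chrom, rec$pos), call. = FALSE)
        amap[ai] <- 0L
        next
      }
      hit <- match(pa, alts)
      if (is.na(hit)) { alts <- c(alts, pa); hit <- length(alts) }
      amap[ai] <- hit
    }
    for (cell in seq_len(nhap)) {
      raw <- rec$gt[cell]
      if (is.na(raw)) { seen_na[cell] <- seen_na[cell] + 1L; next }
      if (raw == 0L) next
      val <- amap[raw]
      if (val == 0L) next
      cur <- merged_gt[cell]
      if (cur == 0L) {
        merged_gt[cell] <- val
        claimed[cell] <- ri
      } else if (cur != val && claimed[cell] != ri) {
        if (on_conflict == "error")
          stop_input(paste0(
            "sample %s haplotype %d carries conflicting non-reference ",
            "alleles from two records merged at %s:%d"),
            samples[(cell - 1L) %% length(samples) + 1L],
            (cell - 1L) %/% length(samples) + 1L,
            rec$chrom, anchor, class = "haplotype_conflict")
        conflicts <- conflicts + 1L     # policy "first": keep earlier allele
      } else if (cur != val) {
        # same record assigns two alleles to one haplotype: impossible by
        # construction (one call per record), kept as a guard
        stop_input("inconsistent allele assignment at %s:%d", rec$chrom,
                   anchor)
      }
    }
  }

  # a haplotype is missing only if every contributing record left it missing
  # and no record assigned it a non-reference allele
  missing <- seen_na == length(records) & merged_gt == 0L
  merged_gt[missing] <- NA_integer_

  classes <- vapply(alts, classify_allele, character(1), ref = merged_ref,
                    USE.NAMES = FALSE)
  structure(list(
    chrom = records[[1]]$chrom,
    pos = anchor, ref = merged_ref, alts = alts, classes = classes,
    ins_len = pmax(0L, nchar(alts) - nchar(merged_ref)),
    gt = merged_gt,
    source_ids = vapply(records, `[[`, character(1), "id"),
    n_missing = sum(missing), n_conflicts = conflicts,
    n_dropped_nonvariant = dropped_nonvariant),
    class = "norm_variant")
}

#' Merge records sharing one position into a multiallelic variant
#'
#' Implements the duplicate-entry rule: alleles reported for one locus on
#' several VCF lines are combined into a single multiallelic record, with
#' SNVs converted to INDEL form where REF lengths differ, duplicate alleles
#' deduplicated (first occurrence wins), and genotype indices remapped into
#' the merged allele space.
#'
#' @param records list of raw records sharing `pos` (SVs already removed).
#' @param window the [ref_window()].
#' @param on_conflict what to do when one haplotype carries non-reference
#'   alleles from two different source records: `"error"` (default) or
#'   `"first"` (keep the first record's allele and count the conflict).
#' @return a `norm_variant`.
#' @export
merge_same_locus <- function(records, window,
                             on_conflict = c("error", "first")) {
  pos <- vapply(records, `[[`, integer(1), "pos")
  if (length(unique(pos)) != 1L)
    stop_input("merge_same_locus requires records sharing one position")
  merge_records(records, window, match.arg(on_conflict))
}

#' Merge overlapping deletions into a multiallelic variant
#'
#' Repeat-length polymorphisms reported as overlapping deletion records are
#' combined over the union REF span: the anchor is the minimum position, the
#' REF is extended to the union span using the reference window, and every
#' allele is padded with the flanking reference bases it lacks. Any
#' insertion allele in an overlapping group raises the dedicated
#' overlapping-insertion error, since inserted sequence absent from the
#' reference cannot be placed against it.
#'
#' @inheritParams merge_same_locus
#' @param records list of raw records with intersecting REF spans.
#' @return a `norm_variant`.
#' @export
merge_overlapping_deletions <- function(records, window,
                                        on_conflict = c("error", "first")) {
  merge_records(records, window, match.arg(on_conflict))
}

#' @export
print.norm_variant <- function(x, ...) {
  cat(sprintf("<norm_variant> %s:%d %s > %s [%s]\n", x$chrom, x$pos, x$ref,
              paste(x$alts, collapse = ","),
              paste(x$classes, collapse = ",")))
  invisible(x)
}

# Clip a record whose REF span extends past the window's right edge: the
# trailing bases are removed from REF and from every same-length tail of the
# ALTs. Returns NULL if nothing variant remains.
clip_record <- function(rec, window) {
  rend <- rec$pos + nchar(rec$ref) - 1L
  if (rend <= window$end) return(list(rec = rec, clipped = FALSE))
  new_len <- window$end - rec$pos + 1L
  cut <- nchar(rec$ref) - new_len
  rec$ref <- substr(rec$ref, 1L, new_len)
  rec$alts <- vapply(rec$alts, function(a)
    substr(a, 1L, max(1L, nchar(a) - cut)), character(1),
    USE.NAMES = FALSE)
  keep <- rec$alts != rec$ref
  if (!any(keep)) return(list(rec = NULL, clipped = TRUE))
  rec <- drop_alts(rec, which(!keep))
  list(rec = rec, clipped = TRUE)
}

# Remove the ALT alleles at `idx` from a record, remapping genotype indices;
# calls that carried a removed allele become missing.
drop_alts <- function(rec, idx) {
  if (!length(idx)) return(rec)
  keep <- setdiff(seq_along(rec$alts), idx)
  remap <- integer(length(rec$alts))
  remap[keep] <- seq_along(keep)
  gt <- rec$gt
  vals <- gt[!is.na(gt) & gt > 0L]
  gt[!is.na(gt) & gt > 0L] <- ifelse(remap[vals] == 0L, NA_integer_,
                                     remap[vals])
  rec$alts <- rec$alts[keep]
  rec$gt <- gt
  rec
}

#' Normalize every record of a region
#'
#' The umbrella procedure over the complex-variant rules: structural
#' variants are routed to an exclusion list (they are never integrated into
#' the alignment, only logged); remaining records are grouped by
#' span-intersection and each group is merged into one canonical
#' multiallelic variant; output spans are pairwise disjoint and sorted.
#' Deletions reaching past the window's right edge are clipped and counted.
#'
#' @param records list of raw records (from [read_vcf_region()]), or a
#'   `variant_set`.
#' @param window the [ref_window()].
#' @param on_conflict see [merge_same_locus()].
#' @return a list with `variants` (list of `norm_variant`, sorted by
#'   position, pairwise disjoint), `sv_records` (raw records excluded as
#'   structural variants) and `report` (counts: `n_missing`, `n_conflicts`,
#'   `n_clipped`, `n_dropped_nonvariant`).
#' @export
normalize_region <- function(records, window,
                             on_conflict = c("error", "first")) {
  on_conflict <- match.arg(on_conflict)
  if (inherits(records, "variant_set")) records <- records$records
  sv_records <- list()
  kept <- list()
  n_clipped <- 0L

  for (rec in records) {
    classes <- classify_record(rec)
    if (all(classes == "SV")) { sv_records <- c(sv_records, list(rec)); next }
    if (any(classes == "SV")) {
      sv_records <- c(sv_records, list(rec))
      rec <- drop_alts(rec, which(classes == "SV"))
    }
    ident <- which(rec$alts == rec$ref)
    if (length(ident)) rec <- drop_alts(rec, ident)
    if (!length(rec$alts)) next
    cl <- clip_record(rec, window)
    if (cl$clipped) n_clipped <- n_clipped + 1L
    if (!is.null(cl$rec)) kept <- c(kept, list(cl$rec))
  }

  variants <- list()
  if (length(kept)) {
    pos <- vapply(kept, `[[`, integer(1), "pos")
    ord <- order(pos)
    kept <- kept[ord]
    pos <- pos[ord]
    ends <- pos + vapply(kept, function(r) nchar(r$ref), integer(1)) - 1L
    # chain records whose REF spans intersect into groups
    grp <- integer(length(kept))
    g <- 0L; reach <- -1L
    for (i in seq_along(kept)) {
      if (pos[i] > reach) { g <- g + 1L; reach <- ends[i] }
      else reach <- max(reach, ends[i])
      grp[i] <- g
    }
    variants <- lapply(split(kept, grp), merge_records, window = window,
                       on_conflict = on_conflict)
    names(variants) <- NULL
    vpos <- vapply(variants, `[[`, integer(1), "pos")
    variants <- variants[order(vpos)]
    vend <- vapply(variants, function(v)
      v$pos + nchar(v$ref) - 1L, integer(1))
    vpos <- sort(vpos)
    stopifnot(all(vpos[-1L] > vend[-length(vend)]))  # disjoint by design
  }

  report <- list(
    n_missing = sum(vapply(variants, `[[`, integer(1), "n_missing")),
    n_conflicts = sum(vapply(variants, `[[`, integer(1), "n_conflicts")),
    n_clipped = n_clipped,
    n_dropped_nonvariant = sum(vapply(variants, `[[`, integer(1),
                                      "n_dropped_nonvariant")))
  list(variants = variants, sv_records = sv_records, report = report)
}
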
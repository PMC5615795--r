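#' Write the plain-text side reports of a pipeline run
#'
#' Three kinds of report accompany every alignment: `log.txt` lists the
#' structural variants found in the region (excluded from the alignment, one
#' per line: chrom, pos, REF length, ALT summary, SVTYPE/VT annotation);
#' `Indels_<name>.txt` lists, per unphased genome, the INDEL records that
#' were reported rather than integrated (pos, ref, alt, genotype); and
#' `skipped.txt` lists records excluded because they start upstream of the
#' region. All files are created even when empty.
#'
#' @param sv_records list of raw SV-classified records.
#' @param archaic_indels_by_genome named list; each element a data frame
#'   with columns `pos`, `ref`, `alt`, `gt`.
#' @param skipped data frame of skipped records (`chrom`, `pos`, `id`,
#'   `ref`) as produced by [read_vcf_region()].
#' @param outdir output directory (created if absent).
#' @return character vector of the paths written, invisibly.
#' @export
write_side_reports <- function(sv_records = list(),
                               archaic_indels_by_genome = list(),
                               skipped = NULL, outdir = ".") {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop_input("cannot create output directory %s", outdir)
  paths <- character(0)

  log_path <- file.path(outdir, "log.txt")
  sv_lines <- vapply(sv_records, function(r) {
    ann <- r$info[intersect(c("SVTYPE", "VT"), names(r$info))]
    ann <- if (length(ann)) paste(names(ann), ann, sep = "=", collapse = ";")
           else "."
    sprintf("%s\t%d\t%d\t%s\t%s", r$chrom, r$pos, nchar(r$ref),
            paste(r$alts, collapse = ","), ann)
  }, character(1))
  writeLines(sv_lines, log_path)
  paths <- c(paths, log_path)

  for (name in names(archaic_indels_by_genome)) {
    df <- archaic_indels_by_genome[[name]]
    p <- file.path(outdir, sprintf("Indels_%s.txt", name))
    lines <- if (is.null(df) || nrow(df) == 0L) character(0)
             else sprintf("%d\t%s\t%s\t%s", df$pos, df$ref, df$alt, df$gt)
    writeLines(lines, p)
    paths <- c(paths, p)
  }

  skip_path <- file.path(outdir, "skipped.txt")
  skip_lines <- if (is.null(skipped) || nrow(skipped) == 0L) character(0)
                else sprintf("%s\t%d\t%s\t%s", skipped$chrom, skipped$pos,
                             skipped$id, skipped$ref)
  writeLines(skip_lines, skip_path)
  paths <- c(paths, skip_path)

  invisible(paths)
}
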
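#' Configuration for a pipeline run
#'
#' @param region region string `chrom:start-end` (1-based inclusive).
#' @param reference path to the reference FASTA.
#' @param vcf path to the phased cohort VCF (plain or bgzipped).
#' @param samples optional path to a sample-list file (one ID per line) or a
#'   character vector of sample IDs; restricts the cohort.
#' @param archaic named character vector of unphased single-genome VCF
#'   paths, e.g. `c(Altai = "altai.vcf")`.
#' @param outgroup named character vector of AXT paths, e.g.
#'   `c(panTro = "chimp.axt")`.
#' @param tree tree engine: `"nj"` (bundled), `"fasttree"`, `"raxml"`, or
#'   `"none"` (alignment only).
#' @param on_conflict,missing_policy see [merge_same_locus()] and
#'   [render_haplotype()].
#' @param fill fill character for outgroup positions covered by no block.
#' @param outdir output directory.
#' @param reference_row include an explicit reference track row.
#' @param seed seed passed to external engines that accept one.
#' @return a list of class `run_config`.
#' @export
run_config <- function(region, reference, vcf, samples = NULL,
                       archaic = character(0), outgroup = character(0),
                       tree = c("nj", "fasttree", "raxml", "none"),
                       on_conflict = c("error", "first"),
                       missing_policy = c("ref", "N"),
                       fill = c("-", "N"), outdir = ".",
                       reference_row = FALSE, seed = 1L) {
  for (p in c(reference, vcf, unname(archaic), unname(outgroup)))
    if (grepl("^[a-z]+://", p))
      stop_input(paste0("remote URL '%s' not supported: download the file ",
                        "and pass a local path"), p)
  if (length(archaic) && is.null(names(archaic)))
    stop_input("archaic paths must be named (name = path)")
  if (length(outgroup) && is.null(names(outgroup)))
    stop_input("outgroup paths must be named (name = path)")
  parse_region(region)  # fail early
  structure(list(
    region = region, reference = reference, vcf = vcf, samples = samples,
    archaic = archaic, outgroup = outgroup, tree = match.arg(tree),
    on_conflict = match.arg(on_conflict),
    missing_policy = match.arg(missing_policy), fill = match.arg(fill),
    outdir = outdir, reference_row = reference_row,
    seed = as.integer(seed)),
    class = "run_config")
}

#' Run the full alignment-and-phylogeny pipeline
#'
#' Reads the reference window and cohort VCF for the region, normalizes
#' complex variants, renders every phased haplotype as an aligned row,
#' integrates unphased genomes (homozygous SNVs only) and outgroups
#' (projected through AXT blocks), writes `<region>.fasta`,
#' `<region>.phy`, the side reports (`log.txt`, `Indels_<name>.txt`,
#' `skipped.txt`) and — unless `tree = "none"` — `<region>.newick`.
#' An overlapping-insertion group aborts the run before any alignment
#' output is written.
#'
#' @param config a [run_config()].
#' @return an object of class `run_report`: counts (haplotypes, rows,
#'   variants by class, SVs logged, skipped/clipped records, columns,
#'   per-outgroup dropped human-gap columns) and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  window <- read_fasta_window(config$reference, config$region)
  vset <- read_vcf_region(config$vcf, config$region)
  if (!is.null(config$samples)) {
    ids <- if (length(config$samples) == 1L && file.exists(config$samples))
      readLines(config$samples) else config$samples
    ids <- trimws(ids[nzchar(trimws(ids))])
    vset <- filter_samples(vset, ids)
  }
  check_phased(vset)

  norm <- normalize_region(vset, window, on_conflict = config$on_conflict)
  cmap <- build_column_map(window, norm$variants)
  aln <- build_alignment(window, norm$variants, samples = vset$samples,
                         missing_policy = config$missing_policy,
                         reference_row = config$reference_row)
  n_cohort_rows <- length(vset$samples) * 2L

  sv_records <- norm$sv_records
  indel_reports <- list()
  archaic_stats <- list()
  for (name in names(config$archaic)) {
    avset <- read_vcf_region(config$archaic[[name]], config$region)
    sel <- select_homozygous_snvs(avset, window)
    indel_reports[[name]] <- sel$indel_report
    sv_records <- c(sv_records, sel$sv_records)
    aln <- append_rows(aln, name, render_unphased_row(window, cmap, sel$snvs))
    archaic_stats[[name]] <- list(n_applied = nrow(sel$snvs),
                                  n_het_skipped = sel$n_het_skipped,
                                  n_indels = nrow(sel$indel_report))
  }

  outgroup_stats <- list()
  for (name in names(config$outgroup)) {
    blocks <- read_axt(config$outgroup[[name]])
    proj <- project_outgroup(blocks, window, cmap, fill = config$fill)
    aln <- append_rows(aln, name, proj$row)
    outgroup_stats[[name]] <- list(
      n_human_gap_dropped = proj$n_human_gap_dropped)
  }

  if (!dir.exists(config$outdir))
    dir.create(config$outdir, recursive = TRUE)
  tag <- region_tag(config$region)
  fasta_path <- file.path(config$outdir, paste0(tag, ".fasta"))
  phy_path <- file.path(config$outdir, paste0(tag, ".phy"))
  write_fasta(aln, fasta_path)
  write_phylip(aln, phy_path)
  write_side_reports(sv_records, indel_reports, vset$skipped, config$outdir)

  tree_path <- NULL
  if (config$tree != "none") {
    tree_path <- file.path(config$outdir, paste0(tag, ".newick"))
    if (config$tree == "nj") {
      d <- p_distance(aln)
      ape::write.tree(neighbor_joining(d), tree_path)
    } else {
      tmp <- run_external_tree(aln, engine = config$tree,
                               workdir = file.path(config$outdir,
                                                   paste0(config$tree, "_work")),
                               seed = config$seed)
      file.copy(tmp, tree_path, overwrite = TRUE)
    }
  }

  class_counts <- table(unlist(lapply(norm$variants, `[[`, "classes")))
  structure(list(
    region = config$region,
    n_samples = length(vset$samples),
    n_haplotypes = n_cohort_rows,
    n_rows = length(aln$labels),
    n_cols = aln$ncols,
    n_variants = length(norm$variants),
    variant_classes = class_counts,
    n_sv_logged = length(sv_records),
    n_skipped = nrow(vset$skipped),
    n_clipped = norm$report$n_clipped,
    n_missing_calls = norm$report$n_missing,
    n_conflicts = norm$report$n_conflicts,
    archaic = archaic_stats,
    outgroup = outgroup_stats,
    alignment = aln,
    paths = list(fasta = fasta_path, phylip = phy_path, newick = tree_path,
                 outdir = config$outdir)),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %s\n", x$region))
  cat(sprintf("  cohort: %d samples -> %d haplotype rows (%d total rows, %d columns)\n",
              x$n_samples, x$n_haplotypes, x$n_rows, x$n_cols))
  cat(sprintf("  variants: %d normalized [%s]; %d SV logged; %d skipped; %d clipped\n",
              x$n_variants,
              paste(names(x$variant_classes), x$variant_classes,
                    sep = "=", collapse = ", "),
              x$n_sv_logged, x$n_skipped, x$n_clipped))
  for (nm in names(x$archaic))
    cat(sprintf("  archaic %s: %d SNVs applied, %d het skipped, %d INDELs reported\n",
                nm, x$archaic[[nm]]$n_applied, x$archaic[[nm]]$n_het_skipped,
                x$archaic[[nm]]$n_indels))
  for (nm in names(x$outgroup))
    cat(sprintf("  outgroup %s: %d human-gap columns dropped\n",
                nm, x$outgroup[[nm]]$n_human_gap_dropped))
  cat(sprintf("  outputs: %s%s\n", x$paths$fasta,
              if (is.null(x$paths$newick)) " (alignment only)"
              else paste0(", ", x$paths$newick)))
  invisible(x)
}

#' Generate a complete set of synthetic inputs on disk
#'
#' Convenience wrapper over the fixture generators: writes the reference
#' FASTA, cohort VCF, one archaic VCF and one outgroup AXT into a
#' directory, and returns the paths plus all truth records.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory.
#' @return list with `region`, `reference`, `vcf`, `archaic`, `axt`,
#'   `window`, and the generators' truth records (`cohort`, `archaic_truth`,
#'   `axt_truth`).
#' @export
simulate_inputs <- function(spec = fixture_spec(), dir = tempfile("fix")) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  window <- simulate_reference(spec)
  ref_path <- file.path(dir, "reference.fa")
  Biostrings::writeXStringSet(
    stats::setNames(Biostrings::DNAStringSet(window$seq), window$chrom),
    ref_path, width = 60L)
  # the FASTA holds only the window itself, so re-anchor at coordinate 1
  window <- ref_window(window$chrom, 1L, window$seq)
  region <- sprintf("%s:%d-%d", window$chrom, window$start, window$end)
  cohort <- simulate_cohort_vcf(spec, window, file.path(dir, "cohort.vcf"))
  arch <- simulate_archaic_vcf(spec, window, file.path(dir, "altai.vcf"))
  axt <- simulate_axt(spec, window, file.path(dir, "chimp.axt"))
  list(region = region, reference = ref_path, vcf = cohort$vcf,
       archaic = stats::setNames(arch$vcf, arch$name),
       axt = stats::setNames(axt$axt, axt$name),
       window = window, cohort = cohort, archaic_truth = arch,
       axt_truth = axt)
}
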
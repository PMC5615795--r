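# Deterministic synthetic inputs: a reference window, a phased cohort VCF
# exercising every variant class the normalizer handles (including the
# pathological duplicate-entry, overlapping-deletion and
# overlapping-insertion shapes), an unphased archaic-style VCF, and AXT
# outgroup blocks. Every generator also emits an independent truth record —
# for the cohort, each haplotype's intended edited sequence, computed by
# direct string surgery on the window, which serves as the degap-equivalence
# oracle for the whole pipeline.

#' Specification for the synthetic fixture generator
#'
#' Counts are per event class within the window; the defaults emulate the
#' variant density of a typical ~1 kb human locus (one SNV every ~80 bp,
#' a handful of short INDELs, occasional multiallelic and duplicate-entry
#' loci, one structural variant) with archaic-style and outgroup inputs
#' matching their real counterparts (archaic genomes almost entirely
#' homozygous; outgroup divergence ~1.3%, the human-chimpanzee genome-wide
#' value).
#'
#' @param seed integer; fully determines all generated output.
#' @param window_len reference window length (bp).
#' @param n_samples number of diploid cohort samples.
#' @param n_snv,n_mnp,n_ins,n_del,n_multiallelic,n_sv counts of simple
#'   event classes.
#' @param n_duplicate_loci loci reported on two VCF lines sharing POS
#'   (one SNV line, one deletion line).
#' @param n_overlap_del clusters of two deletion records with intersecting
#'   REF spans.
#' @param n_overlap_ins_trap clusters where an insertion overlaps a
#'   deletion span — the shape that must abort the pipeline (default 0;
#'   only error-path fixtures set it).
#' @param n_group_snv SNVs carried by every haplotype of one sample
#'   subgroup and no other (creates two deeply divergent haplogroups,
#'   the balancing-selection phenotype).
#' @param group_fraction fraction of samples in the divergent subgroup.
#' @param max_indel_len longest INDEL allele length difference (bp).
#' @param arch_hom_snv,arch_het_snv,arch_hom_indel archaic-genome event
#'   counts (INDELs are emitted homozygous: these genomes are extremely
#'   homozygous, and unphased het calls are never integrated anyway).
#' @param out_divergence per-site substitution probability of the outgroup.
#' @param out_coverage fraction of each alignment chunk covered by a block.
#' @param out_n_blocks number of AXT blocks tiling the window.
#' @param out_n_ins outgroup-specific insertion events per block (columns
#'   gapped on the human side).
#' @param out_del_rate per-site probability of an outgroup-side gap.
#' @return a list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, window_len = 1000L, n_samples = 10L,
                         n_snv = 12L, n_mnp = 1L, n_ins = 3L, n_del = 3L,
                         n_multiallelic = 2L, n_sv = 1L,
                         n_duplicate_loci = 2L, n_overlap_del = 1L,
                         n_overlap_ins_trap = 0L,
                         n_group_snv = 0L, group_fraction = 0.5,
                         max_indel_len = 6L,
                         arch_hom_snv = 4L, arch_het_snv = 3L,
                         arch_hom_indel = 2L,
                         out_divergence = 0.013, out_coverage = 1.0,
                         out_n_blocks = 2L, out_n_ins = 1L,
                         out_del_rate = 0.005) {
  spec <- as.list(environment())
  bad <- vapply(spec, function(x) is.numeric(x) && any(x < 0), logical(1))
  if (any(bad)) stop_input("fixture_spec rates/counts must be >= 0: %s",
                           paste(names(spec)[bad], collapse = ", "))
  structure(spec, class = "fixture_spec")
}

#' Simulate a reference window
#'
#' @param spec a [fixture_spec()].
#' @param chrom,start chromosome name and 1-based start coordinate.
#' @return a [ref_window()] of uniform-random ACGT bases; byte-identical
#'   for equal seeds.
#' @export
simulate_reference <- function(spec, chrom = "chr1", start = 1001L) {
  if (spec$window_len < 1L) stop_input("window_len must be >= 1")
  seq <- withr::with_seed(spec$seed, paste(
    sample(c("A", "C", "G", "T"), spec$window_len, replace = TRUE),
    collapse = ""))
  ref_window(chrom, start, seq)
}

rand_base <- function(n = 1L) sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE)
other_base <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)

# Assign each haplotype at most one (line, allele) choice within an event
# group, so intended edits never conflict on a haplotype.
assign_carriers <- function(n_hap, choices, p_any) {
  pick <- ifelse(stats::runif(n_hap) < p_any,
                 sample.int(choices, n_hap, replace = TRUE), 0L)
  pick
}

#' Simulate a phased cohort VCF with a truth table
#'
#' Emits a position-sorted VCF v4.2 (minimal INFO: VT, SVTYPE following
#' 1000 Genomes nomenclature) containing every requested event class, and
#' computes each haplotype's intended edited sequence by direct substring
#' surgery on the window — the independent oracle used to check that
#' degapping the pipeline's rendered rows reproduces the truth byte-exactly.
#'
#' @param spec a [fixture_spec()].
#' @param window a [ref_window()] (typically [simulate_reference()]).
#' @param path output VCF path.
#' @return list with `vcf` (the path), `samples`, `truth` (named character
#'   vector of edited sequences, one per `<sample>_hap<k>`), and `lines`
#'   (the event bookkeeping: per VCF line, its class tags).
#' @export
simulate_cohort_vcf <- function(spec, window, path = tempfile(fileext = ".vcf")) {
  withr::with_seed(spec$seed + 1L, {
    n_hap <- spec$n_samples * 2L
    samples <- sprintf("S%04d", seq_len(spec$n_samples))
    hap_names <- as.vector(t(outer(samples, 1:2,
                                   function(s, h) sprintf("%s_hap%d", s, h))))
    grp_a_haps <- integer(0)
    if (spec$n_group_snv > 0L) {
      k <- max(1L, floor(spec$n_samples * spec$group_fraction))
      grp_a_haps <- sort(c(2L * seq_len(k) - 1L, 2L * seq_len(k)))
    }

    reserve <- spec$max_indel_len + 8L
    n_events <- spec$n_snv + spec$n_mnp + spec$n_ins + spec$n_del +
      spec$n_multiallelic + spec$n_sv + spec$n_duplicate_loci +
      spec$n_overlap_del + spec$n_overlap_ins_trap + spec$n_group_snv
    anchors <- seq(window$start + 1L, window$end - reserve, by = reserve)
    if (length(anchors) < n_events)
      stop_input("window too short: %d event anchors available, %d needed",
                 length(anchors), n_events)
    anchors <- sort(sample(anchors, n_events))
    kinds <- sample(rep(c("snv", "mnp", "ins", "del", "multi", "sv", "dup",
                          "odel", "otrap", "gsnv"),
                        c(spec$n_snv, spec$n_mnp, spec$n_ins, spec$n_del,
                          spec$n_multiallelic, spec$n_sv,
                          spec$n_duplicate_loci, spec$n_overlap_del,
                          spec$n_overlap_ins_trap, spec$n_group_snv)))

    at <- function(pos, len = 1L)
      substr(window$seq, pos - window$start + 1L,
             pos - window$start + len)
    lines <- list()
    vid <- 0L
    add_line <- function(pos, ref, alts, info, gt_idx, kind, applied = TRUE) {
      vid <<- vid + 1L
      lines[[length(lines) + 1L]] <<- list(
        pos = pos, id = sprintf("var%03d", vid), ref = ref, alts = alts,
        info = info, gt = gt_idx, kind = kind, applied = applied)
    }

    for (e in seq_len(n_events)) {
      p <- anchors[e]
      kind <- kinds[e]
      p_any <- stats::runif(1L, 0.1, 0.5)
      if (kind == "snv") {
        ref <- at(p); alt <- other_base(ref)
        add_line(p, ref, alt, "VT=SNP",
                 assign_carriers(n_hap, 1L, p_any), kind)
      } else if (kind == "gsnv") {
        ref <- at(p); alt <- other_base(ref)
        gt <- integer(n_hap); gt[grp_a_haps] <- 1L
        add_line(p, ref, alt, "VT=SNP", gt, kind)
      } else if (kind == "mnp") {
        ref <- at(p, 2L)
        alt <- paste0(other_base(substr(ref, 1, 1)),
                      other_base(substr(ref, 2, 2)))
        add_line(p, ref, alt, ".", assign_carriers(n_hap, 1L, p_any), kind)
      } else if (kind == "ins") {
        ref <- at(p)
        k <- sample.int(spec$max_indel_len, 1L)
        alt <- paste0(ref, paste(rand_base(k), collapse = ""))
        add_line(p, ref, alt, "VT=INDEL",
                 assign_carriers(n_hap, 1L, p_any), kind)
      } else if (kind == "del") {
        k <- sample.int(spec$max_indel_len, 1L)
        ref <- at(p, k + 1L)
        add_line(p, ref, substr(ref, 1, 1), "VT=INDEL",
                 assign_carriers(n_hap, 1L, p_any), kind)
      } else if (kind == "multi") {
        # mixed SNP/INDEL locus in one line (VT=SNP,INDEL)
        ref <- at(p)
        alts <- c(other_base(ref),
                  paste0(ref, paste(rand_base(2L), collapse = "")))
        add_line(p, ref, alts, "VT=SNP,INDEL",
                 assign_carriers(n_hap, 2L, p_any), kind)
      } else if (kind == "sv") {
        ref <- at(p)
        add_line(p, ref, "<DEL>",
                 sprintf("SVTYPE=DEL;END=%d", p + 120L),
                 assign_carriers(n_hap, 1L, p_any), kind, applied = FALSE)
      } else if (kind == "dup") {
        # same locus on two lines: a SNV line and a deletion line,
        # carriers disjoint by a single assignment over both choices
        ref1 <- at(p); ref2 <- at(p, 2L)
        pick <- assign_carriers(n_hap, 2L, p_any)
        add_line(p, ref1, other_base(ref1), "VT=SNP",
                 ifelse(pick == 1L, 1L, 0L), kind)
        add_line(p, ref2, substr(ref2, 1, 1), "VT=INDEL",
                 ifelse(pick == 2L, 1L, 0L), kind)
      } else if (kind == "odel") {
        # two deletions with intersecting REF spans
        ref1 <- at(p, 4L); ref2 <- at(p + 2L, 2L)
        pick <- assign_carriers(n_hap, 2L, p_any)
        add_line(p, ref1, substr(ref1, 1, 1), "VT=INDEL",
                 ifelse(pick == 1L, 1L, 0L), kind)
        add_line(p + 2L, ref2, substr(ref2, 1, 1), "VT=INDEL",
                 ifelse(pick == 2L, 1L, 0L), kind)
      } else if (kind == "otrap") {
        # an insertion inside a deletion span: must abort the pipeline
        ref1 <- at(p, 3L); ref2 <- at(p + 1L)
        pick <- assign_carriers(n_hap, 2L, p_any)
        add_line(p, ref1, substr(ref1, 1, 1), "VT=INDEL",
                 ifelse(pick == 1L, 1L, 0L), kind)
        add_line(p + 1L, ref2,
                 paste0(ref2, paste(rand_base(2L), collapse = "")),
                 "VT=INDEL", ifelse(pick == 2L, 1L, 0L), kind,
                 applied = FALSE)
      }
    }

    ord <- order(vapply(lines, `[[`, integer(1), "pos"))
    lines <- lines[ord]

    # truth: apply each haplotype's carried edits directly to the window,
    # right-to-left so earlier coordinates stay valid
    truth <- stats::setNames(rep(window$seq, n_hap), hap_names)
    for (h in seq_len(n_hap)) {
      edits <- list()
      for (ln in lines) {
        a <- ln$gt[h]
        if (ln$applied && a > 0L)
          edits[[length(edits) + 1L]] <- list(pos = ln$pos, ref = ln$ref,
                                              alt = ln$alts[a])
      }
      if (!length(edits)) next
      edits <- edits[order(vapply(edits, `[[`, integer(1), "pos"),
                           decreasing = TRUE)]
      s <- window$seq
      for (ed in edits) {
        off <- ed$pos - window$start + 1L
        s <- paste0(substr(s, 1L, off - 1L), ed$alt,
                    substr(s, off + nchar(ed$ref), nchar(s)))
      }
      truth[h] <- s
    }

    # serialize
    gt_field <- function(gt) {
      m <- matrix(gt, nrow = 2L)
      paste0(m[1L, ], "|", m[2L, ])
    }
    header <- c(
      "##fileformat=VCFv4.2",
      "##INFO=<ID=VT,Number=.,Type=String,Description=\"Variant type\">",
      "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
      "##INFO=<ID=END,Number=1,Type=Integer,Description=\"SV end\">",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", samples), collapse = "\t"))
    body <- vapply(lines, function(ln)
      paste(c(window$chrom, ln$pos, ln$id, ln$ref,
              paste(ln$alts, collapse = ","), ".", "PASS", ln$info, "GT",
              gt_field(ln$gt)), collapse = "\t"), character(1))
    writeLines(c(header, body), path)

    list(vcf = path, samples = samples, truth = truth, lines = lines)
  })
}

#' Simulate an unphased archaic-style VCF with truth
#'
#' One-sample VCF with homozygous and heterozygous SNVs plus homozygous
#' INDELs. Truth records which substitutions a correct integration applies
#' (the homozygous SNVs only) and how many INDEL report lines to expect.
#'
#' @param spec a [fixture_spec()].
#' @param window a [ref_window()].
#' @param path output VCF path.
#' @param name genome name (sample column and `Indels_<name>.txt` stem).
#' @return list with `vcf`, `name`, `applied` (data frame `pos`, `alt`),
#'   `n_indels`, `n_het`.
#' @export
simulate_archaic_vcf <- function(spec, window,
                                 path = tempfile(fileext = ".vcf"),
                                 name = "Altai") {
  withr::with_seed(spec$seed + 2L, {
    n_events <- spec$arch_hom_snv + spec$arch_het_snv + spec$arch_hom_indel
    reserve <- spec$max_indel_len + 4L
    anchors <- seq(window$start + 1L, window$end - reserve, by = reserve)
    if (length(anchors) < n_events)
      stop_input("window too short for %d archaic events", n_events)
    anchors <- sort(sample(anchors, n_events))
    kinds <- sample(rep(c("hom_snv", "het_snv", "hom_indel"),
                        c(spec$arch_hom_snv, spec$arch_het_snv,
                          spec$arch_hom_indel)))
    at <- function(pos, len = 1L)
      substr(window$seq, pos - window$start + 1L, pos - window$start + len)
    rows <- character(0)
    applied <- data.frame(pos = integer(), alt = character(),
                          stringsAsFactors = FALSE)
    n_indels <- 0L
    for (e in seq_len(n_events)) {
      p <- anchors[e]
      if (kinds[e] == "hom_snv") {
        ref <- at(p); alt <- other_base(ref)
        gt <- "1/1"
        applied <- rbind(applied, data.frame(pos = p, alt = alt,
                                             stringsAsFactors = FALSE))
      } else if (kinds[e] == "het_snv") {
        ref <- at(p); alt <- other_base(ref)
        gt <- "0/1"
      } else {
        if (stats::runif(1L) < 0.5) {
          ref <- at(p); alt <- paste0(ref, paste(rand_base(2L), collapse = ""))
        } else {
          ref <- at(p, 3L); alt <- substr(ref, 1, 1)
        }
        gt <- "1/1"
        n_indels <- n_indels + 1L
      }
      rows <- c(rows, paste(c(window$chrom, p, ".", ref, alt, ".", "PASS",
                              ".", "GT", gt), collapse = "\t"))
    }
    header <- c(
      "##fileformat=VCFv4.2",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", name), collapse = "\t"))
    writeLines(c(header, rows), path)
    list(vcf = path, name = name, applied = applied, n_indels = n_indels,
         n_het = spec$arch_het_snv)
  })
}

#' Simulate an AXT outgroup alignment with truth
#'
#' Tiles the window with blocks (each chunk covered over its central
#' `out_coverage` fraction), substitutes outgroup bases at the divergence
#' rate, gaps the outgroup side at `out_del_rate`, and interleaves
#' outgroup-specific insertion columns (gapped on the human side). Truth is
#' the expected projected character at every window position.
#'
#' @param spec a [fixture_spec()].
#' @param window a [ref_window()].
#' @param path output AXT path.
#' @param name outgroup name.
#' @return list with `axt`, `name`, `truth` (character vector, one entry
#'   per window position: the projected character, `-` where uncovered or
#'   outgroup-gapped), `n_outgroup_ins` (human-gap columns written).
#' @export
simulate_axt <- function(spec, window, path = tempfile(fileext = ".axt"),
                         name = "panTro") {
  withr::with_seed(spec$seed + 3L, {
    n <- nchar(window$seq)
    nb <- max(1L, spec$out_n_blocks)
    truth <- rep("-", n)
    blocks <- list()
    n_ins <- 0L
    bounds <- floor(seq(0L, n, length.out = nb + 1L))
    for (b in seq_len(nb)) {
      lo <- bounds[b] + 1L; hi <- bounds[b + 1L]
      clen <- hi - lo + 1L
      cov <- max(0L, min(clen, round(clen * spec$out_coverage)))
      if (cov < 1L) next
      pad <- (clen - cov) %/% 2L
      a <- lo + pad; z <- a + cov - 1L
      h_chars <- character(0); o_chars <- character(0)
      ins_at <- if (spec$out_n_ins > 0L && cov > 2L)
        sample(seq.int(a + 1L, z - 1L), min(spec$out_n_ins, cov - 2L))
        else integer(0)
      for (i in a:z) {
        if (i %in% ins_at) {        # outgroup-specific insertion column(s)
          k <- sample.int(3L, 1L)
          h_chars <- c(h_chars, rep("-", k))
          o_chars <- c(o_chars, rand_base(k))
          n_ins <- n_ins + k
        }
        hb <- substr(window$seq, i, i)
        ob <- if (stats::runif(1L) < spec$out_del_rate) "-"
              else if (stats::runif(1L) < spec$out_divergence) other_base(hb)
              else hb
        h_chars <- c(h_chars, hb)
        o_chars <- c(o_chars, ob)
        truth[i] <- ob
      }
      blocks[[length(blocks) + 1L]] <- list(
        human_chrom = window$chrom,
        human_start = window$start + a - 1L,
        human_end = window$start + z - 1L,
        human_aln = paste(h_chars, collapse = ""),
        other_aln = paste(o_chars, collapse = ""))
    }
    write_axt(blocks, path, other_chrom = name)
    list(axt = path, name = name, truth = truth, n_outgroup_ins = n_ins)
  })
}

#' Simulate sequences along a known tree (Jukes-Cantor)
#'
#' Fixture for topology-recovery checks: evolves `sites` independent sites
#' along `tree` under the Jukes-Cantor model and returns the leaf sequences
#' as an alignment.
#'
#' @param tree a `phylo` with branch lengths in expected substitutions per
#'   site.
#' @param sites number of sites.
#' @param seed integer seed.
#' @return a [hap_alignment()] with one row per leaf.
#' @export
simulate_jc_alignment <- function(tree, sites = 2000L, seed = 1L) {
  withr::with_seed(seed, {
    dat <- phangorn::simSeq(tree, l = sites, type = "DNA")
    m <- as.character(dat)
    hap_alignment(rownames(m), toupper(apply(m, 1L, paste, collapse = "")))
  })
}
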
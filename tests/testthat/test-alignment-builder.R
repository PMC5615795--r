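test_that("column map reserves slots sized by the longest insertion", {
  w <- ref_window("chr1", 1, "ACGT")
  ins <- list(structure(list(chrom = "chr1", pos = 2L, ref = "C",
                             alts = "CTT", classes = "INSERTION",
                             ins_len = 2L), class = "norm_variant"))
  cm <- build_column_map(w, ins)
  expect_equal(cm$total_cols, 6L)
  expect_equal(cm$ins_slot, c(0L, 2L, 0L, 0L))
  expect_equal(cm$base_col, c(1L, 2L, 5L, 6L))

  multi <- list(structure(list(chrom = "chr1", pos = 2L, ref = "C",
                               alts = c("CT", "CTTT"),
                               classes = c("INSERTION", "INSERTION"),
                               ins_len = c(1L, 3L)),
                          class = "norm_variant"))
  expect_equal(build_column_map(w, multi)$ins_slot[2], 3L)

  # no insertions: identity map
  cm0 <- build_column_map(w, list())
  expect_equal(cm0$total_cols, 4L)
  expect_equal(cm0$base_col, 1:4)
})

test_that("variants outside the window are a bounds error", {
  w <- ref_window("chr1", 10, "ACGT")
  v <- structure(list(chrom = "chr1", pos = 20L, ref = "A", alts = "T",
                      classes = "SNV", ins_len = 0L),
                 class = "norm_variant")
  expect_error(build_column_map(w, list(v)), "outside window")
})

test_that("reference row gaps every insertion slot and degaps to the window", {
  w <- ref_window("chr1", 1, "ACGT")
  ins <- list(structure(list(chrom = "chr1", pos = 2L, ref = "C",
                             alts = "CTT", classes = "INSERTION",
                             ins_len = 2L), class = "norm_variant"))
  cm <- build_column_map(w, ins)
  expect_equal(render_reference_row(w, cm), "AC--GT")
  expect_equal(degap(render_reference_row(w, cm)), w$seq)
  expect_equal(render_reference_row(w, build_column_map(w, list())), "ACGT")
})

test_that("the worked multiallelic genotype example renders correctly", {
  # reference allele with alts C and T; genotype 0|2: haplotype 1 keeps the
  # reference base, haplotype 2 carries T
  w <- ref_window("chr1", 1, "GGAGG")
  rec <- make_record(3, "A", c("C", "T"), rbind(c(0, 2)))
  out <- normalize_region(list(rec), w)
  cm <- build_column_map(w, out$variants)
  hap1 <- render_haplotype(w, cm, out$variants, 0L)
  hap2 <- render_haplotype(w, cm, out$variants, 2L)
  expect_equal(hap1, "GGAGG")
  expect_equal(hap2, "GGTGG")
})

test_that("insertion carriers fill the slot, non-carriers get gaps", {
  w <- ref_window("chr1", 1, "ACGT")
  rec <- make_record(2, "C", "CTT", rbind(c(0, 1)))
  out <- normalize_region(list(rec), w)
  cm <- build_column_map(w, out$variants)
  expect_equal(render_haplotype(w, cm, out$variants, 1L), "ACTTGT")
  expect_equal(render_haplotype(w, cm, out$variants, 0L), "AC--GT")
  # degap oracle
  expect_equal(degap("ACTTGT"),
               apply_edits(w, list(list(pos = 2, ref = "C", alt = "CTT"))))
})

test_that("deletion carriers receive gaps at the deleted columns", {
  w <- ref_window("chr1", 1, "ACGT")
  rec <- make_record(2, "CG", "C", rbind(c(0, 1)))
  out <- normalize_region(list(rec), w)
  cm <- build_column_map(w, out$variants)
  expect_equal(render_haplotype(w, cm, out$variants, 1L), "AC-T")
  expect_equal(degap(render_haplotype(w, cm, out$variants, 1L)), "ACT")
})

test_that("rendering with all-reference assignments is the reference row", {
  fix <- simulate_inputs(fixture_spec(seed = 4, n_samples = 3),
                         dir = tempfile())
  vs <- read_vcf_region(fix$vcf, fix$region)
  out <- normalize_region(vs, fix$window)
  cm <- build_column_map(fix$window, out$variants)
  allref <- rep(0L, length(out$variants))
  expect_equal(render_haplotype(fix$window, cm, out$variants, allref),
               render_reference_row(fix$window, cm))
})

test_that("adding a non-carried allele never changes base columns", {
  w <- ref_window("chr1", 1, strrep("ACGT", 5))
  r1 <- make_record(3, "G", "C", rbind(c(0, 1)))
  out1 <- normalize_region(list(r1), w)
  cm1 <- build_column_map(w, out1$variants)
  row1 <- render_haplotype(w, cm1, out1$variants, 1L)
  # add an insertion nobody carries
  r2 <- make_record(10, "C", "CAA", rbind(c(0, 0)))
  out2 <- normalize_region(list(r1, r2), w)
  cm2 <- build_column_map(w, out2$variants)
  row2 <- render_haplotype(w, cm2, out2$variants, c(1L, 0L))
  expect_equal(cm2$total_cols, cm1$total_cols + 2L)
  ch1 <- strsplit(row1, "")[[1]]
  ch2 <- strsplit(row2, "")[[1]]
  expect_equal(ch2[cm2$base_col], ch1[cm1$base_col])
})

test_that("build_alignment emits two labeled rows per sample in order", {
  w <- ref_window("chr1", 1, "ACGTACGT")
  rec <- make_record(3, "G", "T", rbind(c(0, 1), c(1, 1)),
                     samples = c("sB", "sA"))
  out <- normalize_region(list(rec), w)
  aln <- build_alignment(w, out$variants, samples = c("sB", "sA"))
  expect_equal(aln$labels, c("sB_hap1", "sB_hap2", "sA_hap1", "sA_hap2"))
  # reordering samples reorders rows, a pure function of sample_order
  aln2 <- build_alignment(w, out$variants, samples = c("sA", "sB"))
  expect_equal(aln2$labels, c("sA_hap1", "sA_hap2", "sB_hap1", "sB_hap2"))
  expect_equal(aln2$seqs[3:4], aln$seqs[1:2])
  # one sample, no variants: both rows equal the window
  aln3 <- build_alignment(w, list(), samples = "sA")
  expect_equal(aln3$seqs, c(w$seq, w$seq))
})

test_that("missing genotypes render as reference or N by policy", {
  w <- ref_window("chr1", 1, "ACGTACGT")
  rec <- make_record(3, "GT", "G", rbind(c(NA, NA)))
  out <- normalize_region(list(rec), w)
  cm <- build_column_map(w, out$variants)
  expect_equal(render_haplotype(w, cm, out$variants, NA_integer_,
                                missing_policy = "ref"), w$seq)
  expect_equal(render_haplotype(w, cm, out$variants, NA_integer_,
                                missing_policy = "N"), "ACNNACGT")
})

test_that("every rendered row degaps to the truth sequence", {
  # the module's master oracle on randomized fixtures
  for (s in c(21, 22, 23)) {
    fix <- simulate_inputs(fixture_spec(seed = s, n_samples = 5),
                           dir = tempfile())
    vs <- read_vcf_region(fix$vcf, fix$region)
    out <- normalize_region(vs, fix$window)
    aln <- build_alignment(fix$window, out$variants, samples = vs$samples)
    idx <- match(names(fix$cohort$truth), aln$labels)
    expect_false(anyNA(idx))
    expect_equal(degap(aln$seqs[idx]), unname(fix$cohort$truth))
    expect_equal(unique(nchar(aln$seqs)), aln$ncols)
  }
})

test_that("deletions reaching past the window edge are clipped", {
  w <- ref_window("chr1", 1, "ACGTAC")
  rec <- make_record(5, "ACGT", "A", rbind(c(0, 1)))  # span 5-8, window ends 6
  out <- normalize_region(list(rec), w)
  expect_equal(out$report$n_clipped, 1L)
  v <- out$variants[[1]]
  expect_equal(v$ref, "AC")
  cm <- build_column_map(w, out$variants)
  expect_equal(render_haplotype(w, cm, out$variants, 1L), "ACGTA-")
})
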
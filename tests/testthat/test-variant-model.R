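test_that("classify_allele follows the 50 bp INDEL/SV boundary", {
  expect_equal(classify_allele("A", "T"), "SNV")
  expect_equal(classify_allele("AG", "CT"), "MNP_SUBSTITUTION")
  expect_equal(classify_allele("AT", "A"), "DELETION")
  expect_equal(classify_allele("A", "AT"), "INSERTION")
  # 49 bp difference is an INDEL, 50 bp is an SV
  ins49 <- paste0("A", strrep("C", 49))
  ins50 <- paste0("A", strrep("C", 50))
  expect_equal(classify_allele("A", ins49), "INSERTION")
  expect_equal(classify_allele("A", ins50), "SV")
  expect_equal(classify_allele(ins49, "A"), "DELETION")
  expect_equal(classify_allele(ins50, "A"), "SV")
})

test_that("classify_allele honors symbolic alleles and annotations", {
  expect_equal(classify_allele("A", "<INS:ME:ALU>"), "SV")
  expect_equal(classify_allele("A", "<DEL>"), "SV")
  expect_equal(classify_allele("A", "G", info = c(SVTYPE = "DEL")), "SV")
  expect_equal(classify_allele("A", "G", info = c(VT = "SV")), "SV")
  # an explicit INDEL annotation overrides the length heuristic
  big <- paste0("A", strrep("C", 60))
  expect_equal(classify_allele("A", big, info = c(VT = "INDEL")),
               "INSERTION")
  expect_equal(classify_allele("A", "A"), "REF_IDENTICAL")
  expect_error(classify_allele("A", "Z"), "non-ACGTN")
})

test_that("classification is stable under appending a common suffix", {
  set.seed(11)
  bases <- c("A", "C", "G", "T")
  for (i in 1:40) {
    rl <- sample(1:4, 1); al <- sample(1:4, 1)
    ref <- paste(sample(bases, rl, TRUE), collapse = "")
    alt <- paste(sample(bases, al, TRUE), collapse = "")
    if (alt == ref) next
    suf <- paste(sample(bases, sample(1:3, 1), TRUE), collapse = "")
    c1 <- classify_allele(ref, alt)
    c2 <- classify_allele(paste0(ref, suf), paste0(alt, suf))
    if (c1 %in% c("SNV", "MNP_SUBSTITUTION"))
      expect_true(c2 %in% c("SNV", "MNP_SUBSTITUTION"))
    else expect_equal(c2, c1)
  }
})

test_that("convert_snp_to_indel_form pads the shorter record", {
  # window carries "AT" at position 10
  w <- ref_window("chr1", 8, "GGATCC")
  snv <- make_record(10, "A", "G", rbind(c(0, 1)))
  indel <- make_record(10, "AT", "A", rbind(c(0, 0)))
  out <- convert_snp_to_indel_form(snv, indel, w)
  expect_equal(out$ref, "AT")
  expect_equal(out$alts[[1]], "GT")
  expect_equal(out$alts[[2]], "A")
  # oracle: each padded allele applied to the window reproduces the edit
  # made by its source record
  expect_equal(apply_edits(w, list(list(pos = 10, ref = "AT", alt = "GT"))),
               apply_edits(w, list(list(pos = 10, ref = "A", alt = "G"))))
})

test_that("padding against a mismatching window is a consistency error", {
  w <- ref_window("chr1", 8, "GGACCC")  # "AC" at 10, not "AT"
  snv <- make_record(10, "A", "G", rbind(c(0, 1)))
  indel <- make_record(10, "AT", "A", rbind(c(0, 0)))
  expect_error(convert_snp_to_indel_form(snv, indel, w), "disagrees")
})

test_that("merge_same_locus combines duplicate-entry lines", {
  w <- ref_window("chr1", 1, strrep("A", 20))
  r1 <- make_record(10, "A", "C", rbind(c(0, 1), c(0, 0)))
  r2 <- make_record(10, "A", "T", rbind(c(0, 0), c(0, 1)))
  m <- merge_same_locus(list(r1, r2), w)
  expect_equal(m$alts, c("C", "T"))
  expect_equal(m$gt["s1", ], c(0L, 1L))  # C
  expect_equal(m$gt["s2", ], c(0L, 2L))  # T remapped to merged index 2
  # single record is returned unchanged
  single <- merge_same_locus(list(r1), w)
  expect_equal(single$alts, "C")
  expect_equal(unname(single$gt["s1", 2]), 1L)
})

test_that("duplicate alleles are deduplicated, first occurrence wins", {
  w <- ref_window("chr1", 1, strrep("A", 20))
  r1 <- make_record(10, "A", "C", rbind(c(0, 1)))
  r2 <- make_record(10, "A", "C", rbind(c(1, 0)))
  m <- merge_same_locus(list(r1, r2), w)
  expect_equal(m$alts, "C")
  expect_equal(m$gt["s1", ], c(1L, 1L))
})

test_that("a haplotype with alleles from two records triggers the policy", {
  w <- ref_window("chr1", 1, strrep("A", 20))
  r1 <- make_record(10, "A", "C", rbind(c(0, 1)))
  r2 <- make_record(10, "A", "T", rbind(c(0, 1)))
  expect_error(merge_same_locus(list(r1, r2), w, on_conflict = "error"),
               "conflicting")
  expect_error(merge_same_locus(list(r1, r2), w, on_conflict = "error"),
               class = "haplotype_conflict")
  m <- merge_same_locus(list(r1, r2), w, on_conflict = "first")
  expect_equal(unname(m$gt["s1", 2]), 1L)  # first record's C retained
  expect_equal(m$n_conflicts, 1L)
})

test_that("merge_overlapping_deletions pads to the union span", {
  # window "ATTTG" at position 10
  w <- ref_window("chr1", 10, "ATTTG")
  r1 <- make_record(10, "ATTT", "A", rbind(c(0, 1), c(0, 0)))
  r2 <- make_record(12, "TT", "T", rbind(c(0, 0), c(1, 0)))
  m <- merge_overlapping_deletions(list(r1, r2), w)
  expect_equal(m$pos, 10L)
  expect_equal(m$ref, "ATTT")
  expect_equal(m$alts, c("A", "ATT"))
  # oracle: the padded allele applied at the anchor equals the original
  # record's independent edit
  expect_equal(apply_edits(w, list(list(pos = 10, ref = "ATTT", alt = "ATT"))),
               apply_edits(w, list(list(pos = 12, ref = "TT", alt = "T"))))
  expect_equal(m$gt["s2", ], c(2L, 0L))
})

test_that("an insertion inside an overlapping group is a hard error", {
  w <- ref_window("chr1", 10, "ATTTG")
  del <- make_record(10, "ATT", "A", rbind(c(0, 1)))
  ins <- make_record(11, "T", "TGG", rbind(c(1, 0)))
  expect_error(merge_overlapping_deletions(list(del, ins), w),
               class = "overlapping_insertion_error")
  expect_error(normalize_region(list(del, ins), w),
               class = "overlapping_insertion_error")
})

test_that("normalize_region routes SVs, groups loci, sorts output", {
  w <- ref_window("chr1", 1, strrep("ACGT", 10))
  snv <- make_record(5, "A", "T", rbind(c(0, 1)))
  sv <- make_record(9, "A", "<DEL>", rbind(c(0, 1)),
                    info = c(SVTYPE = "DEL"))
  out <- normalize_region(list(sv, snv), w)
  expect_length(out$variants, 1L)
  expect_length(out$sv_records, 1L)
  expect_equal(out$variants[[1]]$pos, 5L)

  # the duplicate-entry shape becomes one multiallelic record
  r1 <- make_record(5, "A", "T", rbind(c(0, 1)))
  r2 <- make_record(5, "AC", "A", rbind(c(1, 0)))
  out2 <- normalize_region(list(r1, r2), w)
  expect_length(out2$variants, 1L)
  expect_equal(out2$variants[[1]]$alts, c("TC", "A"))

  # empty input
  out3 <- normalize_region(list(), w)
  expect_length(out3$variants, 0L)
  expect_length(out3$sv_records, 0L)
})

test_that("non-overlapping records are not merged", {
  w <- ref_window("chr1", 1, strrep("ACGT", 10))
  r1 <- make_record(5, "AC", "A", rbind(c(0, 1)))
  r2 <- make_record(9, "AC", "A", rbind(c(1, 0)))
  out <- normalize_region(list(r1, r2), w)
  expect_length(out$variants, 2L)
})

test_that("normalized spans are pairwise disjoint and sorted", {
  for (s in 1:10) {
    fix <- simulate_inputs(fixture_spec(seed = s, n_samples = 4),
                           dir = tempfile())
    vs <- read_vcf_region(fix$vcf, fix$region)
    out <- normalize_region(vs, fix$window)
    pos <- vapply(out$variants, `[[`, integer(1), "pos")
    ends <- pos + vapply(out$variants, function(v) nchar(v$ref),
                         integer(1)) - 1L
    expect_true(all(diff(pos) > 0))
    if (length(pos) > 1)
      expect_true(all(pos[-1] > ends[-length(ends)]))
  }
})

test_that("allele remapping is a bijection on used indices", {
  w <- ref_window("chr1", 1, strrep("ACGT", 10))
  r1 <- make_record(5, "A", c("T", "AGG"), rbind(c(1, 2), c(0, 0)))
  r2 <- make_record(5, "AC", "A", rbind(c(0, 0), c(0, 1)))
  m <- merge_same_locus(list(r1, r2), w)
  # three distinct source alleles -> three distinct merged indices
  expect_length(unique(m$alts), 3L)
  used <- sort(unique(m$gt[m$gt > 0]))
  expect_equal(used, seq_along(used))
})

test_that("a record mixing SV and INDEL alleles keeps the INDEL part", {
  w <- ref_window("chr1", 1, strrep("ACGT", 30))
  big <- paste0("A", strrep("C", 55))
  rec <- make_record(5, "A", c(big, "T"), rbind(c(1, 2), c(0, 2)))
  out <- normalize_region(list(rec), w)
  expect_length(out$sv_records, 1L)
  expect_length(out$variants, 1L)
  v <- out$variants[[1]]
  expect_equal(v$alts, "T")
  # the call that carried the SV allele became missing
  expect_true(is.na(v$gt["s1", 1]))
  expect_equal(v$gt["s2", ], c(0L, 1L))
})
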
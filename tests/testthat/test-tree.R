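test_that("p-distance uses pairwise deletion of gap and N columns", {
  aln <- hap_alignment(c("a", "b"), c("ACGT", "ACGT"))
  expect_equal(p_distance(aln)["a", "b"], 0)
  aln2 <- hap_alignment(c("a", "b"), c("ACGT", "ACGA"))
  expect_equal(p_distance(aln2)["a", "b"], 0.25)
  aln3 <- hap_alignment(c("a", "b"), c("AC-T", "ACGT"))
  expect_equal(p_distance(aln3)["a", "b"], 0)
  aln4 <- hap_alignment(c("a", "b"), c("ACNT", "ACGA"))
  expect_equal(p_distance(aln4)["a", "b"], 1 / 3)
  # no comparable columns: undefined, and NJ refuses it
  aln5 <- hap_alignment(c("a", "b", "c"), c("A--", "-C-", "AAA"))
  d <- p_distance(aln5)
  expect_true(is.na(d["a", "b"]))
  expect_error(neighbor_joining(d), "undefined")
})

test_that("p-distance matrix is symmetric with zero diagonal", {
  fix <- simulate_inputs(fixture_spec(seed = 9, n_samples = 4),
                         dir = tempfile())
  rep <- run_pipeline(run_config(fix$region, fix$reference, fix$vcf,
                                 tree = "none", outdir = tempfile()))
  d <- p_distance(rep$alignment)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, nrow(d)))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("two taxa give the trivial midpoint tree", {
  d <- matrix(c(0, 0.4, 0.4, 0), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  tr <- neighbor_joining(d)
  expect_equal(sort(tr$tip.label), c("a", "b"))
  expect_equal(sort(tr$edge.length), c(0.2, 0.2))
})

test_that("NJ reproduces additive distances exactly", {
  set.seed(5)
  for (i in 1:5) {
    gen <- ape::rtree(7)
    gen$edge.length <- stats::runif(nrow(gen$edge), 0.05, 0.3)
    d <- ape::cophenetic.phylo(gen)
    tr <- neighbor_joining(d)
    back <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
    expect_lt(max(abs(back - d)), 1e-9)
    expect_equal(sort(tr$tip.label), sort(rownames(d)))
  }
})

test_that("NJ matches the brute-force quartet oracle on additive input", {
  set.seed(17)
  labels <- c("w", "x", "y", "z")
  for (i in 1:20) {
    gen <- ape::rtree(4)
    gen$tip.label <- sample(labels)
    gen$edge.length <- stats::runif(nrow(gen$edge), 0.05, 0.4)
    d <- ape::cophenetic.phylo(gen)[labels, labels]
    oracle <- best_quartet_split(d)
    tr <- neighbor_joining(d)
    expect_equal(quartet_split_of_tree(tr, labels), oracle)
  }
})

test_that("NJ agrees with an independent implementation on topology", {
  set.seed(23)
  for (i in 1:10) {
    gen <- ape::rtree(8)
    gen$edge.length <- stats::runif(nrow(gen$edge), 0.05, 0.3)
    d <- ape::cophenetic.phylo(gen)
    t1 <- neighbor_joining(d)
    t2 <- ape::nj(stats::as.dist(d))
    expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("ties resolve deterministically to the lowest index pair", {
  lb <- c("a", "b", "c", "d")
  d <- matrix(0.5, 4, 4, dimnames = list(lb, lb))
  diag(d) <- 0
  t1 <- ape::write.tree(neighbor_joining(d))
  t2 <- ape::write.tree(neighbor_joining(d))
  expect_identical(t1, t2)
  # the first join is the smallest index pair (a, b)
  expect_match(t1, "\\(a:[0-9.]+,b:[0-9.]+\\)")
})

test_that("negative branch lengths are clamped with deficit to the sibling", {
  # a non-additive matrix known to push one NJ branch negative
  lb <- c("a", "b", "c", "d")
  d <- matrix(c(0, 0.1, 0.6, 0.6,
                0.1, 0, 0.65, 0.65,
                0.6, 0.65, 0, 0.1,
                0.6, 0.65, 0.1, 0), 4, 4, dimnames = list(lb, lb))
  tr <- neighbor_joining(d)
  expect_true(all(tr$edge.length >= 0))
})

test_that("midpoint rooting splits the longest leaf-to-leaf path", {
  tr <- ape::read.tree(text = "((a:1,b:1):0,c:4);")
  rooted <- midpoint_root(tr)
  dm <- ape::dist.nodes(rooted)
  root <- length(rooted$tip.label) + 1L
  tip_depths <- dm[root, seq_along(rooted$tip.label)]
  names(tip_depths) <- rooted$tip.label
  # diameter a-c is 5; the root sits 2.5 from each end
  expect_equal(unname(tip_depths["a"]), 2.5)
  expect_equal(unname(tip_depths["c"]), 2.5)
  # idempotence
  again <- midpoint_root(rooted)
  expect_equal(ape::dist.nodes(again)[root, seq_along(again$tip.label)],
               dm[root, seq_along(rooted$tip.label)])
})

test_that("symmetric two-leaf trees midpoint-root at the center", {
  tr <- ape::read.tree(text = "(a:1,b:1);")
  rooted <- midpoint_root(tr)
  dm <- ape::dist.nodes(rooted)
  root <- length(rooted$tip.label) + 1L
  expect_equal(unname(dm[root, 1:2]), c(1, 1))
})

test_that("zero-diameter trees warn and return unchanged", {
  tr <- ape::read.tree(text = "((a:0,b:0):0,c:0);")
  expect_warning(out <- midpoint_root(tr), "zero-diameter")
  expect_equal(sort(out$tip.label), c("a", "b", "c"))
})

test_that("sequences simulated along a tree recover its topology", {
  gen <- fixed_8taxon_tree()
  aln <- simulate_jc_alignment(gen, sites = 2000, seed = 99)
  tr <- neighbor_joining(p_distance(aln))
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(gen)), 0,
               ignore_attr = TRUE)
})

test_that("an absent engine raises engine_not_found", {
  withr::local_envvar(PATH = tempdir())
  expect_error(run_external_tree(hap_alignment(c("a", "b", "c"),
                                               c("ACGT", "ACGA", "ACTA")),
                                 engine = "fasttree"),
               class = "engine_not_found")
})

test_that("the FastTree wrapper returns a newick with all leaves", {
  fix <- simulate_inputs(fixture_spec(seed = 12, n_samples = 3),
                         dir = tempfile())
  rep <- run_pipeline(run_config(fix$region, fix$reference, fix$vcf,
                                 tree = "none", outdir = tempfile()))
  out <- run_external_tree(rep$alignment, engine = "fasttree",
                           workdir = tempfile())
  tr <- ape::read.tree(out)
  expect_equal(ape::Ntip(tr), length(rep$alignment$labels))
  expect_setequal(tr$tip.label, rep$alignment$labels)
})
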
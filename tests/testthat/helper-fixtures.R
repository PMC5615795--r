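# Shared helpers: in-code fixture builders and independent oracles.

# Build a raw variant record the way read_vcf_region() would return it.
make_record <- function(pos, ref, alts, gt, info = character(0),
                        id = ".", chrom = "chr1",
                        samples = paste0("s", seq_len(nrow(gt)))) {
  gt <- matrix(as.integer(gt), ncol = 2L,
               dimnames = list(samples, NULL))
  list(chrom = chrom, pos = as.integer(pos), id = id, ref = ref,
       alts = alts, info = info, gt = gt,
       phased = rep(TRUE, nrow(gt)), line = NA_integer_)
}

# Independent application oracle: apply raw (pos, ref, alt) edits directly
# to a window sequence, right-to-left. This is plain string surgery, with
# no knowledge of column maps or rendering.
apply_edits <- function(window, edits) {
  s <- window$seq
  if (!length(edits)) return(s)
  ord <- order(vapply(edits, function(e) as.numeric(e[["pos"]]),
                      numeric(1)), decreasing = TRUE)
  for (ed in edits[ord]) {
    off <- ed$pos - window$start + 1L
    s <- paste0(substr(s, 1L, off - 1L), ed$alt,
                substr(s, off + nchar(ed$ref), nchar(s)))
  }
  s
}

# Brute-force 4-taxon topology oracle: enumerate the three unrooted
# topologies, fit branch lengths by unconstrained least squares on the
# path-length design matrix, and return the topology with the smallest
# residual sum of squares (as a canonical split of taxon indices).
best_quartet_split <- function(d) {
  stopifnot(nrow(d) == 4L)
  splits <- list(c(1, 2), c(1, 3), c(1, 4))  # pair grouped with taxon 1
  pairs <- t(utils::combn(4, 2))
  y <- d[pairs]
  best <- NULL
  best_ss <- Inf
  for (sp in splits) {
    grp <- c(sp, setdiff(1:4, sp))
    # edges: 4 pendant + 1 internal; path uses internal edge iff the two
    # taxa sit on opposite sides of the split
    X <- matrix(0, nrow = 6, ncol = 5)
    for (r in seq_len(6)) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      X[r, i] <- 1; X[r, j] <- 1
      same <- (i %in% sp) == (j %in% sp)
      if (!same) X[r, 5] <- 1
    }
    fit <- stats::lm.fit(X, y)
    ss <- sum(fit$residuals^2)
    if (ss < best_ss) { best_ss <- ss; best <- sp }
  }
  sort(best)
}

# The split sister to taxon 1 in a 4-taxon tree, via the four-point
# condition on its path-length matrix: the true split {1,x}|{y,z} is the
# pairing whose cross sums are the two larger ones, i.e. d(1,x)+d(y,z) is
# the strict minimum of the three pairings.
quartet_split_of_tree <- function(tree, labels) {
  dm <- ape::cophenetic.phylo(tree)[labels, labels]
  sums <- vapply(2:4, function(x) {
    yz <- setdiff(2:4, x)
    dm[1, x] + dm[yz[1], yz[2]]
  }, numeric(1))
  sort(c(1L, (2:4)[which.min(sums)]))
}

fixed_8taxon_tree <- function() {
  ape::read.tree(text = paste0(
    "(((t1:0.05,t2:0.05):0.05,(t3:0.05,t4:0.05):0.05):0.05,",
    "((t5:0.05,t6:0.05):0.05,(t7:0.05,t8:0.05):0.05):0.05);"))
}

# Write a minimal phased VCF from a list of line specs
# (pos, ref, alt-string, info, gts character vector like "0|1").
write_test_vcf <- function(lines, samples, path, chrom = "chr1") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=VT,Number=.,Type=String,Description=\"Variant type\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- vapply(lines, function(ln)
    paste(c(chrom, ln$pos, if (is.null(ln$id)) "." else ln$id, ln$ref,
            ln$alt, ".", "PASS",
            if (is.null(ln$info)) "." else ln$info, "GT", ln$gts),
          collapse = "\t"), character(1))
  writeLines(c(header, body), path)
  path
}

write_test_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) writeLines(c(paste0(">", nm), seqs[[nm]]), con)
  path
}
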
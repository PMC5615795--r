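# Distance-based tree construction bundled with the package: p-distances
# under pairwise deletion, Saitou-Nei neighbor joining with deterministic
# tie-breaking, midpoint rooting, and thin wrappers for external
# maximum-likelihood engines (RAxML / FastTree under GTR+GAMMA defaults).
# Trees are ape "phylo" objects throughout; newick via ape.

#' Pairwise p-distances of an alignment
#'
#' For each pair of rows, distance = mismatches / comparable columns, where
#' a column is comparable only if neither row carries `-` or `N` there
#' (pairwise deletion: with thousands of rows and INDEL slots, complete
#' deletion could erase most columns). A pair with no comparable column is
#' undefined (`NA`).
#'
#' @param aln a [hap_alignment()] with at least 2 rows.
#' @return a symmetric numeric matrix with the row labels as dimnames,
#'   zero diagonal, values in `[0, 1]` or `NA`.
#' @export
p_distance <- function(aln) {
  stopifnot(inherits(aln, "hap_alignment"))
  n <- length(aln$labels)
  if (n < 2L) stop_input("p_distance needs at least 2 rows")
  m <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
  valid <- m == "A" | m == "C" | m == "G" | m == "T"
  d <- matrix(0, n, n, dimnames = list(aln$labels, aln$labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- valid[i, ] & valid[j, ]
      comp <- sum(ok)
      d[i, j] <- d[j, i] <-
        if (comp == 0L) NA_real_ else sum(m[i, ok] != m[j, ok]) / comp
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration with two determinism guarantees: ties
#' in the Q-criterion are broken by the lowest (row, column) index pair, and
#' a negative branch length is clamped to zero with the deficit moved to its
#' sibling edge. On an additive matrix the tree's path lengths reproduce the
#' input distances exactly (up to floating point).
#'
#' @param d symmetric numeric distance matrix with labeled dimnames and no
#'   `NA` (undefined) entries.
#' @return an unrooted tree of class `phylo` (2 taxa give the trivial
#'   `(a:d/2,b:d/2)` tree).
#' @export
neighbor_joining <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop_input("distance matrix must be square")
  if (anyNA(d))
    stop_input("distance matrix has undefined entries (no comparable columns)")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <-
      paste0("t", seq_len(nrow(d)))
  labels <- rownames(d)
  n <- nrow(d)
  if (n < 2L) stop_input("need at least 2 taxa")
  fmt <- function(x) sprintf("%.12g", max(x, 0))
  if (n == 2L) {
    nwk <- sprintf("(%s:%s,%s:%s);", labels[1], fmt(d[1, 2] / 2),
                   labels[2], fmt(d[1, 2] / 2))
    return(ape::read.tree(text = nwk))
  }
  node <- labels            # newick fragment per active node
  D <- d
  while (length(node) > 3L) {
    m <- length(node)
    r <- rowSums(D)
    # Q-criterion; scan in fixed order so ties go to the lowest index pair
    best <- c(NA_integer_, NA_integer_); bq <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        q <- (m - 2) * D[i, j] - r[i] - r[j]
        if (q < bq - 1e-12) { bq <- q; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- max(li + lj, 0); lj <- 0 }
    merged <- sprintf("(%s:%s,%s:%s)", node[i], fmt(li), node[j], fmt(lj))
    dn <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dn[keep]),
                c(dn[keep], 0))
    node <- c(node[keep], merged)
    D <- D2
  }
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", node[1], fmt(la),
                 node[2], fmt(lb), node[3], fmt(lc))
  ape::read.tree(text = nwk)
}

#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path — the
#' rooting used for visualizing cohort phylogenies when no outgroup is
#' designated. Idempotent. A zero-diameter tree cannot be midpoint-rooted;
#' it is returned with an arbitrary root and a warning.
#'
#' @param tree a `phylo` with branch lengths.
#' @return a rooted `phylo`.
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop_input("midpoint rooting needs branch lengths")
  dm <- ape::cophenetic.phylo(tree)
  if (max(dm) <= 0) {
    warning("zero-diameter tree: midpoint undefined, returning as-is",
            call. = FALSE)
    return(tree)
  }
  phangorn::midpoint(tree)
}

engine_binary <- function(engine) {
  cands <- switch(engine,
    fasttree = c("fasttree", "FastTree", "fasttreeMP"),
    raxml = c("raxmlHPC", "raxmlHPC-PTHREADS-SSE3", "raxmlHPC-SSE3",
              "raxml"),
    stop_input("unknown tree engine '%s'", engine))
  for (b in cands) {
    p <- Sys.which(b)
    if (nzchar(p)) return(p)
  }
  stop_engine_not_found(engine)
}

#' Run an external maximum-likelihood tree engine
#'
#' Thin wrappers around RAxML and FastTree, both invoked with GTR+GAMMA
#' defaults on a FASTA/Phylip export of the alignment. If the engine binary
#' is not on the PATH the call fails with an `engine_not_found` condition so
#' callers can fall back to the bundled neighbor-joining builder.
#'
#' @param aln a [hap_alignment()].
#' @param engine `"fasttree"` or `"raxml"`.
#' @param workdir directory for intermediate and output files.
#' @param seed integer random seed passed through to engines that accept
#'   one (RAxML's parsimony seed); FastTree's search is deterministic.
#' @param threads thread count for engines that support it.
#' @return path to the newick file written.
#' @export
run_external_tree <- function(aln, engine = c("fasttree", "raxml"),
                              workdir = tempdir(), seed = 1L,
                              threads = 2L) {
  engine <- match.arg(engine)
  bin <- engine_binary(engine)
  if (!dir.exists(workdir)) dir.create(workdir, recursive = TRUE)
  out <- file.path(workdir, "tree.newick")
  if (engine == "fasttree") {
    fa <- file.path(workdir, "aln.fasta")
    write_fasta(aln, fa)
    err <- file.path(workdir, "fasttree.err")
    status <- system2(bin, c("-nt", "-gtr", "-gamma", "-quiet", shQuote(fa)),
                      stdout = out, stderr = err)
    if (status != 0L)
      stop_input("FastTree failed (exit %d): %s", status,
                 paste(readLines(err, warn = FALSE), collapse = " "))
  } else {
    phy <- file.path(workdir, "aln.phy")
    write_phylip(aln, phy)
    err <- file.path(workdir, "raxml.err")
    status <- system2(bin, c("-s", shQuote(phy), "-m", "GTRGAMMA",
                             "-p", as.integer(seed), "-T",
                             as.integer(threads), "-n", "run",
                             "-w", shQuote(normalizePath(workdir))),
                      stdout = file.path(workdir, "raxml.out"), stderr = err)
    if (status != 0L)
      stop_input("RAxML failed (exit %d): %s", status,
                 paste(readLines(err, warn = FALSE), collapse = " "))
    best <- file.path(workdir, "RAxML_bestTree.run")
    if (!file.exists(best)) stop_input("RAxML produced no bestTree file")
    file.copy(best, out, overwrite = TRUE)
  }
  out
}
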
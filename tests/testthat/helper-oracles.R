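# Independent brute-force oracles. These deliberately re-derive every
# quantity by a different route than the implementation under test.

# Shortest interval holding >= ceil(mass*n) values: exhaustive window scan.
hdi_brute <- function(values, mass) {
  x <- sort(values)
  n <- length(x)
  k <- ceiling(mass * n)
  best <- NULL
  for (i in seq_len(n - k + 1L)) {
    lo <- x[i]; hi <- x[i + k - 1L]
    if (is.null(best) || (hi - lo) < (best[2] - best[1]) - 1e-12)
      best <- c(lo, hi)
  }
  best
}

# Cophenetic distance by explicit root-path walking (no ape call).
coph_brute <- function(tree) {
  ntip <- length(tree$tip.label)
  parent <- integer(ntip + tree$Nnode)
  plen <- numeric(ntip + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    parent[tree$edge[e, 2L]] <- tree$edge[e, 1L]
    plen[tree$edge[e, 2L]] <- tree$edge.length[e]
  }
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  path_to_root <- function(v) {
    nodes <- v
    while (v != root) { v <- parent[v]; nodes <- c(nodes, v) }
    nodes
  }
  depth <- function(v) { s <- 0; while (v != root) { s <- s + plen[v]; v <- parent[v] }; s }
  d <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip - 1L)) for (j in seq.int(i + 1L, ntip)) {
    anc_i <- path_to_root(i)
    lca <- anc_i[match(TRUE, anc_i %in% path_to_root(j))]
    d[i, j] <- d[j, i] <- depth(i) + depth(j) - 2 * depth(lca)
  }
  d
}

mpd_brute <- function(d, group) {
  s <- 0; np <- 0L
  for (i in seq_along(group)) for (j in seq_along(group)) if (i < j) {
    s <- s + d[group[i], group[j]]; np <- np + 1L
  }
  s / np
}

mntd_brute <- function(d, group) {
  mean(vapply(group, function(g) min(d[g, setdiff(group, g)]), numeric(1)))
}

# Benjamini-Hochberg step-up by the definition.
bh_brute <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  thresh <- which(p[o] <= seq_len(m) / m * alpha)
  rej <- logical(m)
  if (length(thresh)) rej[o[seq_len(max(thresh))]] <- TRUE
  rej
}

# Random tree with positive branch lengths.
rand_tree <- function(ntip, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(ntip)
  tr$edge.length <- runif(nrow(tr$edge), 0.1, 2)
  tr
}

# Nucleotide alignment whose mismatch counts realize a given tree's
# path lengths exactly: each edge mutates its own private block of
# `per_edge` sites (no homoplasy), so pairwise mismatch count equals the
# number of sites on the tip-to-tip path.
additive_alignment <- function(tree, per_edge = 1L) {
  ntip <- length(tree$tip.label)
  nedge <- nrow(tree$edge)
  nsite <- nedge * per_edge
  bases <- c("A", "C", "G", "T")
  seqs <- matrix("A", ntip + tree$Nnode, nsite)
  tr <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nedge)) {
    par <- tr$edge[e, 1L]; chi <- tr$edge[e, 2L]
    seqs[chi, ] <- seqs[par, ]
    idx <- ((e - 1L) * per_edge + 1L):(e * per_edge)
    seqs[chi, idx] <- vapply(seqs[chi, idx],
                             function(b) sample(setdiff(bases, b), 1L), "")
  }
  m <- seqs[seq_len(ntip), , drop = FALSE]
  dimnames(m) <- list(tr$tip.label, sprintf("s%d", seq_len(nsite)))
  m
}

# Random masked ordinal matrix for filtering tests.
rand_mask_matrix <- function(nr, nc, p_known, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(sample(1:5, nr * nc, replace = TRUE), nr,
              dimnames = list(sprintf("c%02d", 1:nr), sprintf("g%02d", 1:nc)))
  m[matrix(runif(nr * nc) > p_known, nr)] <- NA
  m
}
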
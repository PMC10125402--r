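# Synthetic tree-structured single-cell datasets: a multi-sample design
# (tumor clades plus circulating groups, one polyphyletic), ordinal
# expression and nucleotide SNVs evolving on the same tree, uneven
# per-cell dropout, and read-level base counts. The generator states the
# world the pipeline assumes; it does not imitate transcript-level count
# noise.

#' Simulation configuration
#'
#' Defaults mirror a five-sample design with three tumor samples and two
#' circulating-cell samples, sized like the reduced real-data set
#' (20/6/20/6/6 cells), with the second circulating group polyphyletic
#' (its cells seeded early along the backbone). The default per-cell
#' Beta keep-rate spans data densities from roughly 0.1% to 30%.
#'
#' @param samples named integer vector: sample label -> cell count.
#' @param monophyletic named logical vector; FALSE = cells grafted as
#'   singleton lineages at uniform backbone points.
#' @param n_genes,n_sites numbers of ordinal genes / SNV sites.
#' @param ordinal_rate expected ordinal jumps per unit branch length.
#' @param nucleotide_rate expected substitutions per unit branch length.
#' @param backbone_depth,sample_depth root-to-sample-split and
#'   within-sample tree depths; their ratio sets how much closer cells of
#'   one sample are to each other than to other samples.
#' @param dropout per-cell keep-rate model: a single rate in [0, 1]
#'   applied to every cell, or `list(shape1=, shape2=)` for Beta-drawn
#'   per-cell rates.
#' @param depth_mean mean reads per covered site (zero-truncated Poisson).
#' @param error_rate per-base sequencing error.
#' @param expression_noise_sd Gaussian sd added to the true category when
#'   emitting continuous expression values.
#' @param seed master seed; all generators derive their streams from it.
#' @return a `SimulationConfig` list.
#' @export
sim_config <- function(samples = c(T1 = 20L, T2 = 6L, T3 = 20L,
                                   CTC1 = 6L, CTC2 = 6L),
                       monophyletic = c(T1 = TRUE, T2 = TRUE, T3 = TRUE,
                                        CTC1 = TRUE, CTC2 = FALSE),
                       n_genes = 500L, n_sites = 200L,
                       ordinal_rate = 1, nucleotide_rate = 0.5,
                       backbone_depth = 1, sample_depth = 0.1,
                       dropout = list(shape1 = 0.5, shape2 = 4),
                       depth_mean = 2, error_rate = 0.01,
                       expression_noise_sd = 0.15,
                       seed = 1L) {
  stopifnot(all(samples > 0), length(samples) == length(monophyletic),
            all(names(samples) %in% names(monophyletic)),
            ordinal_rate >= 0, nucleotide_rate >= 0,
            error_rate >= 0, error_rate < 1)
  structure(list(samples = samples,
                 monophyletic = monophyletic[names(samples)],
                 n_genes = n_genes, n_sites = n_sites,
                 ordinal_rate = ordinal_rate,
                 nucleotide_rate = nucleotide_rate,
                 backbone_depth = backbone_depth,
                 sample_depth = sample_depth,
                 dropout = dropout, depth_mean = depth_mean,
                 error_rate = error_rate,
                 expression_noise_sd = expression_noise_sd,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

# Add a pendant tip of length `pendant` at `position` along edge `e`
# (measured from the child end toward the parent).
bind_tip <- function(tree, e, position, label, pendant) {
  el <- tree$edge.length[e]
  stopifnot(position >= 0, position <= el)
  child <- tree$edge[e, 2L]
  ntip <- length(tree$tip.label)
  new_tip <- ntip + 1L
  # renumber: tips 1..ntip stay, internal nodes shift by 1
  edge <- tree$edge
  edge[edge > ntip] <- edge[edge > ntip] + 1L
  new_node <- ntip + 1L + tree$Nnode + 1L
  parent_row <- edge[e, 1L]
  # split edge e: parent -> new_node (upper part), new_node -> child (lower)
  upper <- el - position
  edge[e, ] <- c(parent_row, new_node)
  tree$edge.length[e] <- upper
  edge <- rbind(edge, c(new_node, if (tree$edge[e, 2L] <= ntip) child else child + 1L),
                c(new_node, new_tip))
  tree$edge.length <- c(tree$edge.length, position, pendant)
  tree$edge <- edge
  tree$tip.label <- c(tree$tip.label, label)
  tree$Nnode <- tree$Nnode + 1L
  # tip numbering changed (new tip inserted at ntip+1), but since the new
  # tip gets the next free tip index this stays consistent
  ape::reorder.phylo(tree, "cladewise")
}

#' Simulate the ground-truth tree and sample labels
#'
#' A pure-birth backbone over the monophyletic samples (scaled to
#' `backbone_depth`) carries one birth-death subtree per sample (scaled
#' to `sample_depth`), so each monophyletic sample is a clade. Cells of
#' polyphyletic samples are grafted as singleton lineages at uniformly
#' chosen points along the backbone, emulating lineages seeded before the
#' samples diverged.
#'
#' @param config a [sim_config()].
#' @return list with `tree` (`ape::phylo`, tips = cell ids) and `labels`
#'   (named character vector cell id -> sample label).
#' @export
simulate_tree <- function(config) {
  set.seed(config$seed + 1L)
  mono <- names(config$samples)[config$monophyletic]
  poly <- names(config$samples)[!config$monophyletic]
  if (length(mono) < 2L) stop("need at least 2 monophyletic samples")
  backbone <- ape::rphylo(length(mono), birth = 1, death = 0)
  backbone$tip.label <- sample(mono)
  backbone$edge.length <- backbone$edge.length /
    max(ape::node.depth.edgelength(backbone)) * config$backbone_depth
  total_depth <- config$backbone_depth + config$sample_depth

  # graft polyphyletic cells as singleton lineages on the backbone
  for (s in poly) {
    for (i in seq_len(config$samples[[s]])) {
      depths <- ape::node.depth.edgelength(backbone)  # from root
      e <- sample.int(nrow(backbone$edge), 1L,
                      prob = backbone$edge.length)
      pos <- runif(1L, 0, backbone$edge.length[e])  # from child end
      child_depth <- depths[backbone$edge[e, 2L]]
      attach_depth <- child_depth - pos
      pendant <- max(total_depth - attach_depth, 1e-8)
      backbone <- bind_tip(backbone, e, pos,
                           sprintf("%s_c%02d", s, i), pendant)
    }
  }

  # replace each monophyletic sample tip by its within-sample subtree
  nwk <- write_newick(backbone)
  for (s in mono) {
    n <- config$samples[[s]]
    sub <- ape::rphylo(n, birth = 1, death = 0)
    sub$tip.label <- sprintf("%s_c%02d", s, seq_len(n))
    sub$edge.length <- sub$edge.length /
      max(ape::node.depth.edgelength(sub)) * config$sample_depth
    sub_nwk <- sub(";$", "", write_newick(sub))
    nwk <- sub(paste0(s, ":"), paste0(sub_nwk, ":"), nwk, fixed = TRUE)
  }
  tree <- parse_newick(nwk)
  labels <- setNames(sub("_c\\d+$", "", tree$tip.label), tree$tip.label)
  list(tree = tree, labels = labels)
}

#' Evolve ordinal expression characters on a tree
#'
#' Each gene starts at category 3 at the root and evolves independently
#' along branches by a Markov jump process: jumps arrive as a Poisson
#' process with intensity `rate` per unit branch length, each jump moves
#' one category up or down with equal probability, reflecting at the
#' bounds (from 1 only up, from 5 only down). This is the simplest
#' genuinely ordinal process and matches the ordinal-model assumption
#' made downstream.
#'
#' @param tree `ape::phylo` with branch lengths.
#' @param n_genes number of independent genes.
#' @param rate expected jumps per unit branch length.
#' @param seed integer seed.
#' @return complete (no-unknown) [ordinal_matrix()].
#' @export
evolve_ordinal <- function(tree, n_genes, rate, seed = 1L) {
  set.seed(seed)
  states <- evolve_states(tree, n_genes, function(parent_states, len) {
    s <- parent_states
    k <- rpois(length(s), rate * len)
    while (any(k > 0L)) {
      act <- which(k > 0L)
      up <- runif(length(act)) < 0.5
      step <- ifelse(s[act] == 1L, 1L, ifelse(s[act] == 5L, -1L,
                     ifelse(up, 1L, -1L)))
      s[act] <- s[act] + step
      k[act] <- k[act] - 1L
    }
    s
  }, root = rep.int(3L, n_genes))
  m <- states
  colnames(m) <- sprintf("g%04d", seq_len(n_genes))
  ordinal_matrix(m, "unknown")
}

#' Evolve nucleotide SNV characters on a tree (Jukes-Cantor)
#'
#' Root states are uniform over A/C/G/T; along a branch of length L each
#' site changes with probability (3/4)(1 - exp(-4 rate L / 3)) to a
#' uniformly chosen other base — the exact Jukes-Cantor transition, so
#' the expected mismatch fraction between two tips at path distance d is
#' (3/4)(1 - exp(-4 d rate / 3)).
#'
#' @inheritParams evolve_ordinal
#' @param n_sites number of independent sites.
#' @return complete [snv_matrix()].
#' @export
evolve_snv <- function(tree, n_sites, rate, seed = 1L) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  states <- evolve_states(tree, n_sites, function(parent_states, len) {
    p_change <- 0.75 * (1 - exp(-4 * rate * len / 3))
    s <- parent_states
    hit <- runif(length(s)) < p_change
    if (any(hit))
      s[hit] <- ((s[hit] - 1L + sample.int(3L, sum(hit), replace = TRUE)) %% 4L) + 1L
    s
  }, root = sample.int(4L, n_sites, replace = TRUE))
  m <- matrix(bases[states], nrow = nrow(states),
              dimnames = list(rownames(states),
                              sprintf("chr1:%d_A>C", seq_len(n_sites) * 100L)))
  snv_matrix(m)
}

# Preorder propagation of integer state vectors along the tree.
evolve_states <- function(tree, n_char, transition, root) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  states <- matrix(NA_integer_, nnode, n_char)
  root_node <- ntip + 1L
  states[root_node, ] <- root
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1L]
    chi <- tree$edge[e, 2L]
    states[chi, ] <- transition(states[par, ], tree$edge.length[e])
  }
  out <- states[seq_len(ntip), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

#' Apply per-cell dropout
#'
#' Draws a keep rate per cell from the configured model (fixed rate or
#' Beta) and independently retains each entry with that rate, setting the
#' rest to unknown.
#'
#' @param matrix matrix or `scp_matrix`.
#' @param keep_rate single rate in [0, 1], per-cell vector, or
#'   `list(shape1=, shape2=)` for a Beta draw per cell.
#' @param seed integer seed.
#' @return object of the same kind; `attr(, "realized_density")` and
#'   `attr(, "keep_rates")` report what happened.
#' @export
apply_dropout <- function(matrix, keep_rate, seed = 1L) {
  set.seed(seed)
  v <- as_values(matrix)
  n <- nrow(v)
  rates <- if (is.list(keep_rate)) {
    rbeta(n, keep_rate$shape1, keep_rate$shape2)
  } else if (length(keep_rate) == 1L) rep(keep_rate, n) else keep_rate
  stopifnot(length(rates) == n, all(rates >= 0), all(rates <= 1))
  # column-major fill: per-row rates expand as rep(rates, times = ncol)
  keep <- matrix(runif(n * ncol(v)) < rep(rates, times = ncol(v)), n)
  v[!keep] <- NA
  out <- rewrap(matrix, v)
  attr(out, "realized_density") <- mean(keep)
  attr(out, "keep_rates") <- setNames(rates, rownames(v))
  out
}

#' Generate per-cell base counts from an SNV matrix
#'
#' For every known (cell, site) entry a read depth is drawn from a
#' zero-truncated Poisson with mean `depth_mean`; each read reports the
#' true base with probability `1 - error_rate`, otherwise a uniformly
#' chosen other base. Unknown entries yield no record (depth 0).
#'
#' @param snv an [snv_matrix()] (unknowns allowed).
#' @param depth_mean mean of the (untruncated) Poisson read depth.
#' @param error_rate per-base error in [0, 1).
#' @param seed integer seed.
#' @return base-count data.frame (see [read_base_counts()]).
#' @export
generate_base_counts <- function(snv, depth_mean = 2, error_rate = 0.01,
                                 seed = 1L) {
  set.seed(seed)
  v <- as_values(snv)
  known <- which(!is.na(v), arr.ind = TRUE)
  if (!nrow(known))
    return(data.frame(cell_id = character(), site_id = character(),
                      countA = integer(), countC = integer(),
                      countG = integer(), countT = integer()))
  n <- nrow(known)
  # zero-truncated Poisson via inverse cdf conditioned on > 0
  p0 <- dpois(0L, depth_mean)
  depth <- qpois(p0 + runif(n) * (1 - p0), depth_mean)
  bases <- c("A", "C", "G", "T")
  true_b <- match(v[known], bases)
  counts <- matrix(0L, n, 4L, dimnames = list(NULL, bases))
  n_err <- rbinom(n, depth, error_rate)
  counts[cbind(seq_len(n), true_b)] <- depth - n_err
  has_err <- which(n_err > 0L)
  for (i in has_err) {
    others <- setdiff(1:4, true_b[i])
    err_b <- others[sample.int(3L, n_err[i], replace = TRUE)]
    tb <- tabulate(err_b, 4L)
    counts[i, ] <- counts[i, ] + tb
  }
  data.frame(cell_id = rownames(v)[known[, 1L]],
             site_id = colnames(v)[known[, 2L]],
             countA = counts[, "A"], countC = counts[, "C"],
             countG = counts[, "G"], countT = counts[, "T"],
             stringsAsFactors = FALSE)
}

#' Simulate a complete dataset
#'
#' Runs the whole generator: tree and labels, complete ordinal and SNV
#' matrices, dropout-thinned observed matrices, a continuous expression
#' matrix (true category plus Gaussian noise, dropped-out entries stored
#' as raw zeros so the expression pipeline sees them the way real count
#' data presents dropout) and read-level base counts from the observed
#' SNV matrix.
#'
#' @param config a [sim_config()].
#' @return list: `tree`, `labels`, `ordinal_true`, `snv_true`,
#'   `ordinal_obs`, `snv_obs`, `expression`, `base_counts`, `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  gt <- simulate_tree(config)
  seed <- config$seed
  ord <- evolve_ordinal(gt$tree, config$n_genes, config$ordinal_rate,
                        seed = seed + 2L)
  snv <- evolve_snv(gt$tree, config$n_sites, config$nucleotide_rate,
                    seed = seed + 3L)
  ord_obs <- apply_dropout(ord, config$dropout, seed = seed + 4L)
  snv_obs <- apply_dropout(snv, config$dropout, seed = seed + 5L)
  counts <- generate_base_counts(snv_obs, config$depth_mean,
                                 config$error_rate, seed = seed + 6L)
  set.seed(seed + 7L)
  ov <- as_values(ord_obs)
  expr <- ov + matrix(rnorm(length(ov), 0, config$expression_noise_sd),
                      nrow(ov))
  expr[is.na(ov)] <- 0  # dropout presents as a raw zero in count data
  expr <- expression_matrix(expr, gt$labels)
  list(tree = gt$tree, labels = gt$labels,
       ordinal_true = ord, snv_true = snv,
       ordinal_obs = ord_obs, snv_obs = snv_obs,
       expression = expr, base_counts = counts, config = config)
}

#' Write a simulated dataset in the formats the pipeline reads
#'
#' newick ground-truth tree, label TSV, expression and character matrix
#' tables, base-count TSV and a synthetic VCF site list.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_trees(sim$tree, file.path(dir, "truth.nwk"))
  data.table::fwrite(data.table::data.table(cell_id = names(sim$labels),
                                            sample = unname(sim$labels)),
                     file.path(dir, "labels.tsv"), sep = "\t")
  write_matrix_table(sim$expression, file.path(dir, "expression.tsv"))
  write_matrix_table(sim$ordinal_obs, file.path(dir, "ordinal.tsv"))
  data.table::fwrite(data.table::as.data.table(sim$base_counts),
                     file.path(dir, "base_counts.tsv"), sep = "\t")
  sites <- colnames(as_values(sim$snv_true))
  pos <- as.integer(sub("^chr1:(\\d+)_.*$", "\\1", sites))
  vcf <- c("##fileformat=VCFv4.2",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
           sprintf("chr1\t%d\t.\tA\tC\t.\tPASS\t.", pos))
  writeLines(vcf, file.path(dir, "sites.vcf"))
  invisible(dir)
}
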
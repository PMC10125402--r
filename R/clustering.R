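# Phylogenetic clustering tests: MPD/MNTD with permutation nulls, rank
# p-values, BH-FDR over a results family, and summarization over
# bootstrap/posterior tree samples.

#' Mean pairwise distance and mean nearest taxon distance of a group
#'
#' MPD is the mean cophenetic distance over all unordered pairs of group
#' members; MNTD the mean, over members, of the distance to the closest
#' other member. Low values indicate phylogenetic clustering.
#'
#' @param dist tips x tips distance matrix (see [cophenetic_distances()]).
#' @param group character vector of tip labels, length >= 2.
#' @return a single number in branch-length units.
#' @export
mpd <- function(dist, group) {
  idx <- match_group(dist, group)
  pr <- combn(idx, 2L)
  mean(dist[cbind(pr[1L, ], pr[2L, ])])
}

#' @rdname mpd
#' @export
mntd <- function(dist, group) {
  idx <- match_group(dist, group)
  sub <- dist[idx, idx, drop = FALSE]
  diag(sub) <- Inf
  mean(apply(sub, 1L, min))
}

match_group <- function(dist, group) {
  idx <- match(group, rownames(dist))
  if (anyNA(idx)) stop("group members absent from distance matrix: ",
                       paste(group[is.na(idx)], collapse = ", "))
  if (length(idx) < 2L) stop("group must contain at least 2 tips")
  idx
}

# Union groups: "T1+CTC2" means the union of labels T1 and CTC2.
group_members <- function(labels, group) {
  parts <- strsplit(group, "+", fixed = TRUE)[[1L]]
  unknown <- setdiff(parts, unique(labels))
  if (length(unknown)) stop("group label(s) not present: ",
                            paste(unknown, collapse = ", "))
  names(labels)[labels %in% parts]
}

#' Permutation test of phylogenetic clustering
#'
#' Tests whether the cells of a group sit closer together on the tree
#' than expected by chance. The null is built by uniformly permuting the
#' label vector across all tips (group sizes preserved) `n_perm` times
#' and recomputing the statistic; since only one group is scored per
#' call, this is realized by drawing the group's tip set uniformly
#' without replacement, which is the same null. The one-sided rank
#' p-value includes the observed value:
#' p = (1 + #\{null < observed\}) / (n_perm + 1), so p is never 0 and the
#' smallest attainable value is 1/(n_perm + 1) (0.001 at the default 999
#' permutations). Null values exactly equal to the observed statistic are
#' attributed to the observed arrangement (already counted by the +1), so
#' a group strictly denser than every distinct relabeling attains the
#' floor regardless of how often its own arrangement is redrawn.
#'
#' @param tree `ape::phylo` whose tips are cell ids (or NULL if `dist`
#'   is supplied directly).
#' @param labels named character vector, cell id -> sample label, covering
#'   every tip.
#' @param group a sample label, or a union such as `"T2+CTC1"`.
#' @param statistic `"MPD"` or `"MNTD"`.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed recorded in the result; the test is
#'   bit-reproducible given the seed.
#' @param dist optional precomputed cophenetic matrix (avoids recomputing
#'   it across many calls on the same tree).
#' @return a `ClusteringTestResult`: list with `group`, `n_cells`,
#'   `statistic`, `observed`, `null_values`, `p_value`, `n_perm`, `seed`.
#' @export
permutation_test <- function(tree, labels, group,
                             statistic = c("MPD", "MNTD"),
                             n_perm = 999L, seed = NULL, dist = NULL) {
  statistic <- match.arg(statistic)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (is.null(dist)) dist <- cophenetic_distances(tree)
  tips <- rownames(dist)
  if (!all(tips %in% names(labels))) stop("every tip needs a label")
  members <- intersect(group_members(labels[tips], group), tips)
  if (length(members) < 2L)
    stop("group ", group, " has fewer than 2 tips on the tree")
  g <- length(members)
  n <- length(tips)
  obs <- if (statistic == "MPD") mpd(dist, members) else mntd(dist, members)
  if (!is.null(seed)) set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) sample.int(n, g), integer(g))
  null_values <- if (statistic == "MPD") {
    pr <- combn(seq_len(g), 2L)
    a <- perm[pr[1L, ], , drop = FALSE]
    b <- perm[pr[2L, ], , drop = FALSE]
    colMeans(matrix(dist[cbind(as.vector(a), as.vector(b))], ncol = n_perm))
  } else {
    vapply(seq_len(n_perm), function(i) {
      sub <- dist[perm[, i], perm[, i], drop = FALSE]
      diag(sub) <- Inf
      mean(apply(sub, 1L, min))
    }, numeric(1L))
  }
  # strictly smaller nulls count against clustering; a null equal to the
  # observed can only arise from redrawing the observed arrangement itself,
  # which the +1 already accounts for
  p <- (1 + sum(null_values < obs)) / (n_perm + 1)
  structure(list(group = group, n_cells = g, statistic = statistic,
                 observed = obs, null_values = null_values, p_value = p,
                 n_perm = n_perm, seed = seed),
            class = "ClusteringTestResult")
}

#' @export
print.ClusteringTestResult <- function(x, ...) {
  cat(sprintf("%s %s: observed %.4f, p = %.4g (%d cells, %d permutations)\n",
              x$group, x$statistic, x$observed, x$p_value, x$n_cells, x$n_perm))
  invisible(x)
}

#' Benjamini-Hochberg FDR correction over a family of clustering tests
#'
#' Flags results significant under the BH step-up rule at level `alpha`.
#' The family is whatever is supplied: conventionally all groups x both
#' statistics x both data types of one results table.
#'
#' @param results list of `ClusteringTestResult`, or a data.frame with a
#'   `p_value` column.
#' @param alpha FDR level in (0, 1).
#' @return same structure with `fdr_significant` (and `p_adjusted`) added.
#' @export
fdr_correct <- function(results, alpha = 0.05) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (is.data.frame(results)) {
    if (!nrow(results)) return(results)
    results$p_adjusted <- p.adjust(results$p_value, method = "BH")
    results$fdr_significant <- results$p_adjusted <= alpha
    return(results)
  }
  if (!length(results)) return(results)
  padj <- p.adjust(vapply(results, `[[`, numeric(1L), "p_value"), "BH")
  for (i in seq_along(results)) {
    results[[i]]$p_adjusted <- padj[i]
    results[[i]]$fdr_significant <- padj[i] <= alpha
  }
  results
}

#' Run the full clustering battery on one tree
#'
#' Permutation tests for every group x statistic combination, collected
#' in a table mirroring the usual reporting layout (group, n cells,
#' statistic, p, FDR flag at `alpha` across the whole table).
#'
#' @inheritParams permutation_test
#' @param groups character vector of labels / `+`-unions.
#' @param statistics subset of `c("MPD", "MNTD")`.
#' @param alpha FDR level.
#' @param data_type free-text tag (e.g. "expression (ML)") carried into
#'   the table, to combine several calls into one FDR family upstream.
#' @return data.frame with one row per test; `attr(, "results")` holds
#'   the full `ClusteringTestResult` objects including null values.
#' @export
clustering_battery <- function(tree, labels, groups,
                               statistics = c("MPD", "MNTD"),
                               n_perm = 999L, seed = NULL, alpha = 0.05,
                               data_type = NA_character_, dist = NULL) {
  if (is.null(dist)) dist <- cophenetic_distances(tree)
  res <- list()
  k <- 0L
  for (gp in groups) for (st in statistics) {
    k <- k + 1L
    s <- if (is.null(seed)) NULL else (seed + k) %% .Machine$integer.max
    res[[k]] <- permutation_test(NULL, labels, gp, st, n_perm, s, dist = dist)
  }
  res <- fdr_correct(res, alpha)
  tab <- data.frame(
    group = vapply(res, `[[`, character(1L), "group"),
    n_cells = vapply(res, `[[`, integer(1L), "n_cells"),
    statistic = vapply(res, `[[`, character(1L), "statistic"),
    data_type = data_type,
    p_value = vapply(res, `[[`, numeric(1L), "p_value"),
    fdr_significant = vapply(res, `[[`, logical(1L), "fdr_significant"))
  attr(tab, "results") <- res
  tab
}

#' Summarize clustering tests over a tree sample
#'
#' Runs the full permutation test on every tree of a bootstrap or
#' posterior sample and summarizes each group x statistic as the mean
#' p-value with an empirical 95% interval (2.5% / 97.5% quantiles) across
#' trees. The same permutation stream (derived from the master seed) is
#' reused for every tree, so identical trees give identical p-values and
#' the summary isolates topological uncertainty from Monte Carlo noise.
#'
#' @param trees `multiPhylo` (identical tip sets required).
#' @inheritParams clustering_battery
#' @return data.frame: group, statistic, mean_p, ci_lower, ci_upper.
#' @export
summarize_over_trees <- function(trees, labels, groups,
                                 statistics = c("MPD", "MNTD"),
                                 n_perm = 999L, seed = 1L) {
  tipset <- sort(trees[[1L]]$tip.label)
  ps <- vector("list", length(trees))
  for (t in seq_along(trees)) {
    tr <- trees[[t]]
    if (!identical(sort(tr$tip.label), tipset))
      stop("tree ", t, " has a mismatching tip set")
    tab <- clustering_battery(tr, labels, groups, statistics, n_perm,
                              seed = seed)
    ps[[t]] <- tab$p_value
  }
  key <- clustering_battery(trees[[1L]], labels, groups, statistics,
                            n_perm = 1L, seed = seed)
  pm <- do.call(rbind, ps)
  data.frame(group = key$group, statistic = key$statistic,
             mean_p = colMeans(pm),
             ci_lower = apply(pm, 2L, quantile, 0.025),
             ci_upper = apply(pm, 2L, quantile, 0.975))
}

#' Write clustering results
#'
#' `write_results_table()` writes the battery table as TSV;
#' `write_results_json()` additionally serializes the null distributions.
#'
#' @param tab output of [clustering_battery()].
#' @param path output file.
#' @export
write_results_table <- function(tab, path) {
  data.table::fwrite(data.table::as.data.table(tab), path, sep = "\t")
  invisible(path)
}

#' @rdname write_results_table
#' @export
write_results_json <- function(tab, path) {
  res <- attr(tab, "results")
  out <- lapply(res, function(r) r[c("group", "n_cells", "statistic",
                                     "observed", "p_value", "p_adjusted",
                                     "fdr_significant", "n_perm", "seed",
                                     "null_values")])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
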
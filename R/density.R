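# Data density and the two reduction strategies: greedy stepwise
# filtering toward a target density, and per-sample quota selection.

#' Data density of a matrix with unknowns
#'
#' Density is the fraction of known (non-NA) entries: 1 means no unknown
#' values, 0 a matrix made entirely of unknowns.
#'
#' @param matrix matrix or `scp_matrix`.
#' @return a `DensityReport`: list with `density`, `n_cells`, `n_features`,
#'   `per_cell_known`, `per_feature_known`.
#' @export
data_density <- function(matrix) {
  v <- as_values(matrix)
  if (nrow(v) == 0L || ncol(v) == 0L) stop("zero-dimension matrix")
  known <- !is.na(v)
  structure(list(density = mean(known),
                 n_cells = nrow(v), n_features = ncol(v),
                 per_cell_known = rowSums(known),
                 per_feature_known = colSums(known)),
            class = "DensityReport")
}

#' @export
print.DensityReport <- function(x, ...) {
  cat(sprintf("density %.4f over %d cells x %d features\n",
              x$density, x$n_cells, x$n_features))
  invisible(x)
}

#' Greedy stepwise filtering toward a target data density
#'
#' Iteratively removes the single row or column with the lowest fraction
#' of known entries (fractions, not raw counts, so rows and columns are
#' comparable) and recomputes the overall density. A removal is accepted
#' only if it increases density; the algorithm stops when the target is
#' reached, when no single removal increases density (a local maximum),
#' or when a dimension would become empty. Ties between candidates go to
#' rows before columns, then lexicographic id.
#'
#' @param matrix matrix or `scp_matrix`.
#' @param target_density fraction in (0, 1].
#' @return list with the filtered `matrix`, retained `cell_ids` and
#'   `feature_ids`, a `trace` data.frame (step, type, id, density after
#'   the removal), `reached` flag and the final `density`.
#' @export
stepwise_filter <- function(matrix, target_density) {
  if (!(target_density > 0 && target_density <= 1))
    stop("target_density must be in (0, 1]")
  v <- as_values(matrix)
  known <- !is.na(v)
  trace <- list()
  step <- 0L
  repeat {
    dens <- mean(known)
    if (dens >= target_density) break
    if (nrow(known) <= 1L && ncol(known) <= 1L) break
    rf <- rowMeans(known)
    cf <- colMeans(known)
    # candidate = lowest known fraction; rows beat columns on ties,
    # then the lexicographically smallest id
    cand_row <- if (nrow(known) > 1L) order(rf, rownames(known))[1L] else NA
    cand_col <- if (ncol(known) > 1L) order(cf, colnames(known))[1L] else NA
    take_row <- if (is.na(cand_col)) TRUE
      else if (is.na(cand_row)) FALSE
      else rf[cand_row] <= cf[cand_col]
    frac <- if (take_row) rf[cand_row] else cf[cand_col]
    # removing a line raises density iff its known fraction < current density
    if (frac >= dens) break
    step <- step + 1L
    if (take_row) {
      id <- rownames(known)[cand_row]
      known <- known[-cand_row, , drop = FALSE]
      v <- v[-cand_row, , drop = FALSE]
      trace[[step]] <- data.frame(step = step, type = "cell", id = id,
                                  density = mean(known))
    } else {
      id <- colnames(known)[cand_col]
      known <- known[, -cand_col, drop = FALSE]
      v <- v[, -cand_col, drop = FALSE]
      trace[[step]] <- data.frame(step = step, type = "feature", id = id,
                                  density = mean(known))
    }
  }
  dens <- mean(known)
  reached <- dens >= target_density
  if (!reached)
    warning(sprintf("target density %.3f unreachable; best achieved %.3f",
                    target_density, dens))
  list(matrix = rewrap(matrix, v),
       cell_ids = rownames(v), feature_ids = colnames(v),
       trace = if (length(trace)) do.call(rbind, trace)
               else data.frame(step = integer(), type = character(),
                               id = character(), density = numeric()),
       reached = reached, density = dens)
}

#' Select the densest cells per sample
#'
#' Keeps, for every sample, the `quota` cells with the largest number of
#' known values (ties broken by lexicographic cell id), then removes
#' features left uninformative in the reduced matrix: features known in
#' fewer than two cells and — for categorical matrices — features with a
#' single known category.
#'
#' Expression and SNV matrices are normally filtered independently; to
#' force an identical cell set across the two (shared-cell mode), pass the
#' `cell_ids` retained from the first selection as `cells` when filtering
#' the second.
#'
#' @param matrix matrix or `scp_matrix`.
#' @param quotas named integer vector, sample label -> number of cells.
#' @param sample_of named character vector cell id -> sample label; taken
#'   from the object when it carries one.
#' @param cells optional explicit cell ids: skip the quota ranking and keep
#'   exactly these cells (shared-cell mode).
#' @return filtered object of the same kind; `attr(, "cell_ids")` holds the
#'   retained cells for reuse on a sibling matrix.
#' @export
select_cells <- function(matrix, quotas, sample_of = NULL, cells = NULL) {
  v <- as_values(matrix)
  if (is.null(cells)) {
    if (is.null(sample_of) && inherits(matrix, "scp_matrix"))
      sample_of <- matrix$sample_of
    if (is.null(sample_of)) stop("sample_of required")
    sample_of <- sample_of[rownames(v)]
    if (any(quotas <= 0)) stop("quotas must be positive")
    known <- rowSums(!is.na(v))
    keep <- character()
    for (s in names(quotas)) {
      ids <- rownames(v)[!is.na(sample_of) & sample_of == s]
      if (length(ids) < quotas[[s]])
        stop(sprintf("sample %s: quota %d exceeds available %d cells",
                     s, quotas[[s]], length(ids)))
      ids <- ids[order(-known[ids], ids)]
      keep <- c(keep, ids[seq_len(quotas[[s]])])
    }
  } else {
    if (!all(cells %in% rownames(v)))
      stop("cells absent from matrix: ",
           paste(setdiff(cells, rownames(v)), collapse = ", "))
    keep <- cells
  }
  v <- v[keep, , drop = FALSE]
  categorical <- inherits(matrix, c("OrdinalMatrix", "SNVCharacterMatrix"))
  fkeep <- apply(v, 2L, function(g) {
    g <- g[!is.na(g)]
    length(g) >= 2L && (!categorical || length(unique(g)) >= 2L)
  })
  out <- rewrap(matrix, v[, fkeep, drop = FALSE])
  attr(out, "cell_ids") <- keep
  out
}

#' Quality-control filter on raw counts
#'
#' Drops cells with fewer than `min_features` represented features
#' (entries with a positive count) or a total count below `min_total`;
#' intended for raw pre-discretization UMI counts.
#'
#' @param matrix numeric count matrix or `ExpressionMatrix`.
#' @param min_features minimum represented features per cell.
#' @param min_total minimum total counts (UMI) per cell.
#' @param sample_of optional labels for the per-sample pass report.
#' @return filtered object; `attr(, "pass_by_sample")` gives per-sample
#'   pass counts when labels are available. Empty results warn.
#' @export
qc_filter <- function(matrix, min_features = 250, min_total = 500,
                      sample_of = NULL) {
  v <- as_values(matrix)
  if (is.null(sample_of) && inherits(matrix, "scp_matrix"))
    sample_of <- matrix$sample_of
  pos <- !is.na(v) & v > 0
  nfeat <- rowSums(pos)
  v0 <- v
  v0[!pos] <- 0
  tot <- rowSums(v0)
  pass <- nfeat >= min_features & tot >= min_total
  if (!any(pass)) warning("no cell passes the QC thresholds")
  out <- rewrap(matrix, v[pass, , drop = FALSE])
  if (!is.null(sample_of))
    attr(out, "pass_by_sample") <- table(sample_of[rownames(v)][pass])
  out
}
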
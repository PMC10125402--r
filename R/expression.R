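# Expression pipeline: per-gene standardization, HDI-based ordinal
# discretization, uninformative-gene removal and the FASTA interface.

#' Highest density interval of a sample
#'
#' The HDI at mass `m` is the shortest interval containing at least
#' `ceiling(m * n)` of the `n` values. Among all contiguous windows of that
#' length in the sorted sample the narrowest is returned; ties are broken
#' by the lowest lower bound, so the result is deterministic.
#'
#' @param values numeric vector, no NAs (exclude unknowns before calling).
#' @param mass fraction in (0, 1].
#' @return an `HdiInterval`: list with `lower`, `upper`, `mass`.
#' @examples
#' compute_hdi(c(0, 1, 2, 3, 10), 0.6)  # [0, 2]
#' @export
compute_hdi <- function(values, mass) {
  if (length(values) == 0L) stop("compute_hdi: empty input")
  if (anyNA(values)) stop("compute_hdi: unknowns must be excluded by caller")
  if (!(mass > 0 && mass <= 1)) stop("mass must be in (0, 1]")
  x <- sort(values)
  n <- length(x)
  k <- ceiling(mass * n)
  lo <- x[seq_len(n - k + 1L)]
  hi <- x[seq.int(k, n)]
  i <- which.min(hi - lo)  # which.min takes the first minimum: lowest lower bound
  structure(list(lower = lo[i], upper = hi[i], mass = mass),
            class = "HdiInterval")
}

#' @export
print.HdiInterval <- function(x, ...) {
  cat(sprintf("HDI(%g%%): [%g, %g]\n", 100 * x$mass, x$lower, x$upper))
  invisible(x)
}

#' Center and rescale expression values per gene
#'
#' Standardizes each gene to mean 0 and sample variance 1 over its known
#' values. With `zero_mode = "unknown"` raw zeros are first converted to
#' unknown (dropout cannot be distinguished from absence of expression)
#' and never enter the mean/variance. With `zero_mode = "biological"` raw
#' zeros are kept aside as true non-expression: they are excluded from
#' standardization (their mass would otherwise dominate the distribution)
#' and tagged so that [discretize()] can assign them category 0.
#'
#' Genes with fewer than two known values or zero variance cannot be
#' scaled; they are dropped and their count reported via
#' `attr(, "n_dropped")` and a message.
#'
#' @param matrix an [expression_matrix()] (or bare numeric matrix).
#' @param zero_mode `"unknown"` (default) or `"biological"`.
#' @return standardized object of the same kind; in biological mode with a
#'   logical `attr(, "raw_zero")` matrix marking the zero entries.
#' @export
center_scale <- function(matrix, zero_mode = c("unknown", "biological")) {
  zero_mode <- match.arg(zero_mode)
  v <- as_values(matrix)
  zero <- !is.na(v) & v == 0
  v[zero] <- NA  # excluded from standardization in both modes
  n_known <- colSums(!is.na(v))
  mu <- colMeans(v, na.rm = TRUE)
  sdv <- apply(v, 2L, sd, na.rm = TRUE)
  bad <- n_known < 2L | is.na(sdv) | sdv == 0
  if (all(bad)) stop("no gene with >= 2 known values and positive variance")
  if (any(bad))
    message(sum(bad), " gene(s) dropped: <2 known values or zero variance")
  keep <- which(!bad)
  v <- sweep(sweep(v[, keep, drop = FALSE], 2L, mu[keep]), 2L, sdv[keep], "/")
  out <- rewrap(matrix, v)
  attr(out, "n_dropped") <- sum(bad)
  if (zero_mode == "biological")
    attr(out, "raw_zero") <- zero[, keep, drop = FALSE]
  out
}

#' Discretize standardized expression into a five-level ordinal scale
#'
#' Values inside the 60% HDI are "normal" (category 3); between the 60%
#' and 90% HDIs decreased/increased (2/4); outside the 90% HDI extremely
#' decreased/increased (1/5). The 60% interval is closed on both ends.
#' Unknowns propagate. In biological mode the entries tagged as raw zeros
#' by [center_scale()] become category 0, exempt from the interval map.
#'
#' By default both HDIs are pooled over all known standardized values of
#' the matrix (the values are per-gene standardized, so pooling is
#' scale-consistent); set `per_gene = TRUE` to compute them gene by gene.
#'
#' @param matrix standardized expression (output of [center_scale()]).
#' @param hdi60,hdi90 optional [compute_hdi()] intervals; computed from the
#'   pooled known values when omitted. `hdi60` must be nested in `hdi90`.
#' @param zero_mode `"unknown"` or `"biological"`; must match the mode used
#'   in [center_scale()].
#' @param per_gene compute the HDIs per gene instead of pooled.
#' @return an [ordinal_matrix()].
#' @export
discretize <- function(matrix, hdi60 = NULL, hdi90 = NULL,
                       zero_mode = c("unknown", "biological"),
                       per_gene = FALSE) {
  zero_mode <- match.arg(zero_mode)
  v <- as_values(matrix)
  raw_zero <- attr(matrix, "raw_zero")
  if (zero_mode == "biological" && is.null(raw_zero))
    stop("biological mode needs the raw-zero tags from center_scale()")
  if (per_gene && (is.null(hdi60) || is.null(hdi90))) {
    out <- v
    for (j in seq_len(ncol(v))) {
      known <- v[, j][!is.na(v[, j])]
      out[, j] <- categorize(v[, j], compute_hdi(known, 0.60),
                             compute_hdi(known, 0.90))
    }
  } else {
    pooled <- v[!is.na(v)]
    if (is.null(hdi60)) hdi60 <- compute_hdi(pooled, 0.60)
    if (is.null(hdi90)) hdi90 <- compute_hdi(pooled, 0.90)
    if (hdi60$lower < hdi90$lower || hdi60$upper > hdi90$upper)
      stop("hdi60 must be nested within hdi90")
    out <- categorize(v, hdi60, hdi90)
  }
  if (zero_mode == "biological") out[raw_zero] <- 0L
  dim(out) <- dim(v)
  dimnames(out) <- dimnames(v)
  ordinal_matrix(out, zero_mode)
}

categorize <- function(v, hdi60, hdi90) {
  out <- rep.int(NA_integer_, length(v))
  known <- !is.na(v)
  x <- v[known]
  cat <- ifelse(x < hdi90$lower, 1L,
         ifelse(x < hdi60$lower, 2L,
         ifelse(x <= hdi60$upper, 3L,
         ifelse(x <= hdi90$upper, 4L, 5L))))
  out[known] <- cat
  out
}

#' Remove phylogenetically uninformative genes
#'
#' Drops genes whose known values comprise fewer than two distinct
#' categories (constant, hence carrying no tree signal) and genes known in
#' fewer than two cells. Works on ordinal and SNV character matrices.
#'
#' @param matrix an [ordinal_matrix()] or [snv_matrix()].
#' @return matrix of the same class with `attr(, "n_dropped")` genes removed.
#' @export
remove_uninformative_genes <- function(matrix) {
  v <- as_values(matrix)
  keep <- apply(v, 2L, function(g) {
    g <- g[!is.na(g)]
    length(g) >= 2L && length(unique(g)) >= 2L
  })
  if (!any(keep)) stop("all genes uninformative: empty alignment")
  out <- rewrap(matrix, v[, keep, drop = FALSE])
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Ordinal FASTA interface
#'
#' One record per cell, id = cell id, one character per gene in fixed gene
#' order; categories written as digits ('1'-'5', plus '0' in biological
#' mode), unknowns as '-'. The reader inverts the writer exactly: cell ids
#' and values round-trip losslessly. FASTA carries no column names, so
#' gene ids are regenerated positionally unless `gene_ids` is supplied.
#'
#' @param matrix an [ordinal_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ordinal_fasta <- function(matrix, path) {
  v <- as_values(matrix)
  if (anyDuplicated(rownames(v))) stop("duplicate cell ids")
  ch <- matrix(ifelse(is.na(v), "-", as.character(v)), nrow = nrow(v))
  seqs <- apply(ch, 1L, paste0, collapse = "")
  ss <- Biostrings::BStringSet(setNames(seqs, rownames(v)))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @rdname write_ordinal_fasta
#' @param zero_mode category set expected in the file.
#' @param gene_ids optional feature names for the columns.
#' @export
read_ordinal_fasta <- function(path, zero_mode = c("unknown", "biological"),
                               gene_ids = NULL) {
  zero_mode <- match.arg(zero_mode)
  m <- read_char_fasta(path, gene_ids)
  m[m == "-"] <- NA
  storage.mode(m) <- "integer"
  ordinal_matrix(m, zero_mode)
}

# FASTA -> character matrix shared by the ordinal and SNV readers
read_char_fasta <- function(path, feature_ids = NULL) {
  ss <- Biostrings::readBStringSet(path)
  if (anyDuplicated(names(ss))) stop("duplicate cell ids in FASTA")
  wid <- unique(Biostrings::width(ss))
  if (length(wid) != 1L) stop("FASTA records have unequal lengths")
  m <- do.call(rbind, strsplit(as.character(ss), "", fixed = TRUE))
  rownames(m) <- names(ss)
  colnames(m) <- if (is.null(feature_ids)) sprintf("f%d", seq_len(wid)) else feature_ids
  m
}
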
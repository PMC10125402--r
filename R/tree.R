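# Tree plumbing: newick I/O, cophenetic distances, pairwise distances on
# character matrices with pairwise deletion, and an internal
# neighbor-joining builder so the pipeline is testable without external
# ML/Bayesian engines (which are consumed via newick import, never
# re-implemented here).

#' Parse and write newick trees
#'
#' Thin wrappers around `ape`'s newick reader/writer. `parse_newick()`
#' takes a newick string; `read_trees()` reads a file with one tree per
#' line (bootstrap or posterior samples) and always returns a
#' `multiPhylo`; `write_trees()` writes one tree per line preserving
#' order.
#'
#' @param text newick string (terminating `;` required).
#' @return `parse_newick()`: an `ape::phylo`.
#' @export
parse_newick <- function(text) {
  tr <- tryCatch(ape::read.tree(text = text), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr)) stop("malformed newick: ", substr(text, 1, 60))
  tr
}

#' @rdname parse_newick
#' @param tree an `ape::phylo`.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}

#' @rdname parse_newick
#' @param path file with one newick tree per line.
#' @export
read_trees <- function(path) {
  trs <- ape::read.tree(path)
  if (is.null(trs)) stop("no trees in ", path)
  if (inherits(trs, "phylo")) trs <- c(trs)  # promote to multiPhylo
  trs
}

#' @rdname parse_newick
#' @param trees `phylo` or `multiPhylo`.
#' @export
write_trees <- function(trees, path) {
  ape::write.tree(trees, file = path)
  invisible(path)
}

#' Cophenetic (tip-to-tip path) distances
#'
#' Entry (i, j) is the sum of branch lengths along the path between tips
#' i and j; symmetric with zero diagonal.
#'
#' @param tree `ape::phylo` with branch lengths.
#' @param unit_branch if TRUE, a tree without branch lengths is given
#'   unit lengths instead of erroring.
#' @return tips x tips numeric matrix.
#' @export
cophenetic_distances <- function(tree, unit_branch = FALSE) {
  if (is.null(tree$edge.length)) {
    if (!unit_branch) stop("tree has no branch lengths")
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) stop("missing branch length")
  ape::cophenetic.phylo(tree)
}

#' Pairwise distances between cells of a character matrix
#'
#' Pairwise deletion: each pair is compared over the sites known in both
#' cells. Ordinal distance is the mean absolute category difference
#' divided by 4 (the category range 5-1), nucleotide distance the
#' mismatch fraction; both live in [0, 1]. Pairs with no shared known
#' site get the maximal distance 1 and raise a warning.
#'
#' @param matrix [ordinal_matrix()] / [snv_matrix()] or bare matrix.
#' @param kind `"ordinal"` or `"nucleotide"`; inferred from the class
#'   when possible.
#' @return cells x cells symmetric distance matrix.
#' @export
pairwise_distances <- function(matrix, kind = c("ordinal", "nucleotide")) {
  if (inherits(matrix, "SNVCharacterMatrix")) kind <- "nucleotide"
  else if (inherits(matrix, "OrdinalMatrix")) kind <- "ordinal"
  else kind <- match.arg(kind)
  v <- as_values(matrix)
  n <- nrow(v)
  d <- matrix(0, n, n, dimnames = list(rownames(v), rownames(v)))
  if (kind == "nucleotide") {
    num <- matrix(match(v, c("A", "C", "G", "T")), n)
  } else {
    num <- v
    storage.mode(num) <- "double"
  }
  no_overlap <- FALSE
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    sh <- !is.na(num[i, ]) & !is.na(num[j, ])
    if (!any(sh)) {
      no_overlap <- TRUE
      d[i, j] <- d[j, i] <- 1
    } else if (kind == "ordinal") {
      d[i, j] <- d[j, i] <- mean(abs(num[i, sh] - num[j, sh])) / 4
    } else {
      d[i, j] <- d[j, i] <- mean(num[i, sh] != num[j, sh])
    }
  }
  if (no_overlap)
    warning("cell pair(s) with no shared known sites assigned distance 1")
  d
}

#' Neighbor-joining tree from an ordinal or nucleotide alignment
#'
#' Internal stand-in for external tree inference: builds pairwise
#' distances with [pairwise_distances()] and runs neighbor joining;
#' negative branch lengths are clamped to 0. Intended as test plumbing,
#' not a substitute for likelihood-based reconstruction.
#'
#' @inheritParams pairwise_distances
#' @return `ape::phylo`.
#' @export
nj_tree <- function(matrix, kind = c("ordinal", "nucleotide")) {
  v <- as_values(matrix)
  if (nrow(v) < 3L) stop("need at least 3 sequences")
  d <- pairwise_distances(matrix, kind)
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Write inputs and a settings manifest for external tree engines
#'
#' Writes the alignment FASTA plus a JSON manifest recording the engine
#' settings appropriate for the data kind: for the ML engine an ordinal
#' alignment uses an ordinal model with ascertainment bias correction
#' (`-m ORDINAL+ASC`, the alignment holds no invariant characters) and a
#' nucleotide alignment standard model selection (`-m TEST`), with
#' nonparametric bootstrap `-b 100`; for the Bayesian engine the manifest
#' is an XML-generation checklist: ordinal characters via a morphological
#' (Mk-family) model, nucleotides via GTR, ambiguous states not ignored,
#' and both documented tree-prior options (birth-death; coalescent with
#' exponential growth) listed without choosing.
#'
#' @param alignment [ordinal_matrix()] or [snv_matrix()].
#' @param outdir output directory (created if needed).
#' @param engine `"iqtree"` or `"beast2"`.
#' @return paths of the files written, invisibly.
#' @export
write_engine_inputs <- function(alignment, outdir,
                                engine = c("iqtree", "beast2")) {
  engine <- match.arg(engine)
  v <- as_values(alignment)
  if (nrow(v) == 0L || ncol(v) == 0L) stop("empty alignment")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ordinal <- inherits(alignment, "OrdinalMatrix")
  fasta <- file.path(outdir, "alignment.fasta")
  if (ordinal) write_ordinal_fasta(alignment, fasta)
  else write_snv_fasta(alignment, fasta)
  manifest <- if (engine == "iqtree") {
    list(engine = "iqtree",
         alignment = basename(fasta),
         data_kind = if (ordinal) "ordinal" else "nucleotide",
         model = if (ordinal) "ORDINAL+ASC" else "TEST",
         model_flag = if (ordinal) "-m ORDINAL+ASC" else "-m TEST",
         bootstrap = "-b 100")
  } else {
    list(engine = "beast2",
         alignment = basename(fasta),
         data_kind = if (ordinal) "ordinal" else "nucleotide",
         site_model = if (ordinal) "ordinal (Morph-Models / Mk family)"
                      else "GTR",
         ambiguous_states = "do not ignore",
         tree_prior_options = c("birth-death",
                                "coalescent with exponential growth"),
         posterior_sample = 1000)
  }
  mpath <- file.path(outdir, paste0(engine, "_manifest.json"))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(fasta, mpath))
}
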
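# Per-cell consensus SNV matrix from base counts at pre-called candidate
# sites; variant calling itself happens upstream and is consumed as input.

#' Consensus base from per-cell base counts
#'
#' Returns the strictly most common base among A/C/G/T counts; no coverage
#' or a tie for the maximum yields unknown (NA). Heterogeneity and copy
#' number are deliberately ignored: one base per cell per site.
#'
#' @param countA,countC,countG,countT non-negative integer vectors
#'   (recycled to a common length).
#' @return character vector in \{A,C,G,T\} with NA for unknown.
#' @export
consensus_base <- function(countA, countC, countG, countT) {
  m <- cbind(A = countA, C = countC, G = countG, T = countT)
  if (any(m < 0)) stop("negative base count")
  top <- apply(m, 1L, function(x) {
    mx <- max(x)
    if (mx == 0 || sum(x == mx) > 1L) NA_character_ else names(x)[which.max(x)]
  })
  unname(top)
}

#' Read a per-cell base-count table
#'
#' Delimited table with columns cell_id, site_id, countA, countC, countG,
#' countT (header required; extra columns ignored).
#'
#' @param path file path.
#' @return data.frame with the six canonical columns.
#' @export
read_base_counts <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  need <- c("cell_id", "site_id", "countA", "countC", "countG", "countT")
  if (!all(need %in% names(dt)))
    stop("base-count table must have columns: ", paste(need, collapse = ", "))
  as.data.frame(dt[, need, with = FALSE])
}

#' Read a VCF site list (CHROM, POS, REF, ALT only)
#'
#' Reads the candidate SNV positions from an (uncompressed) VCF produced
#' by an upstream caller; genotypes and INFO are ignored. Site ids are
#' formed as `CHROM:POS_REF>ALT`.
#'
#' @param path VCF file.
#' @return data.frame with chrom, pos (1-based), ref, alt, site_id.
#' @export
read_vcf_sites <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) stop("VCF contains no sites")
  f <- data.table::fread(text = body, header = FALSE, sep = "\t")
  out <- data.frame(chrom = as.character(f[[1]]), pos = as.integer(f[[2]]),
                    ref = as.character(f[[4]]), alt = as.character(f[[5]]),
                    stringsAsFactors = FALSE)
  out$site_id <- sprintf("%s:%d_%s>%s", out$chrom, out$pos, out$ref, out$alt)
  out
}

#' Build a per-cell SNV character matrix
#'
#' Applies [consensus_base()] to every (cell, site) record, fills the
#' cells x sites matrix (unknown where no record exists), then drops
#' sites known in fewer than `min_cells_per_site` cells. Cells without a
#' single known site are reported and optionally dropped.
#'
#' @param table base-count table (see [read_base_counts()]).
#' @param sites character vector of site ids defining column order;
#'   defaults to the sites present in the table.
#' @param min_cells_per_site drop sites represented in fewer cells.
#' @param drop_empty_cells drop cells with zero known sites.
#' @return an [snv_matrix()]; `attr(, "empty_cells")` lists cells without
#'   any positively identified SNV, `attr(, "n_sites_dropped")` the count
#'   of removed sites.
#' @export
build_snv_matrix <- function(table, sites = NULL, min_cells_per_site = 2L,
                             drop_empty_cells = FALSE) {
  if (is.null(sites)) sites <- unique(table$site_id)
  if (!length(sites)) stop("sites must be non-empty")
  cells <- unique(table$cell_id)
  if (!nrow(table)) {
    warning("empty base-count table: all sites dropped")
    m <- matrix(NA_character_, 0L, 0L, dimnames = list(NULL, NULL))
    return(structure(list(values = m), class = c("SNVCharacterMatrix", "scp_matrix")))
  }
  if (anyDuplicated(table[c("cell_id", "site_id")]))
    stop("(cell_id, site_id) pairs must be unique")
  m <- matrix(NA_character_, length(cells), length(sites),
              dimnames = list(cells, sites))
  inside <- table$site_id %in% sites
  tb <- table[inside, , drop = FALSE]
  m[cbind(match(tb$cell_id, cells), match(tb$site_id, sites))] <-
    consensus_base(tb$countA, tb$countC, tb$countG, tb$countT)
  known_per_site <- colSums(!is.na(m))
  keep <- known_per_site >= min_cells_per_site
  n_dropped <- sum(!keep)
  m <- m[, keep, drop = FALSE]
  empty <- rownames(m)[rowSums(!is.na(m)) == 0L]
  if (drop_empty_cells && length(empty))
    m <- m[setdiff(rownames(m), empty), , drop = FALSE]
  out <- snv_matrix(m)
  attr(out, "empty_cells") <- empty
  attr(out, "n_sites_dropped") <- n_dropped
  out
}

#' SNV FASTA interface
#'
#' One record per cell; bases A/C/G/T, unknown as 'N'. Lossless round
#' trip with [read_snv_fasta()] (site ids regenerate positionally unless
#' supplied).
#'
#' @param matrix an [snv_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_snv_fasta <- function(matrix, path) {
  v <- as_values(matrix)
  if (nrow(v) == 0L || ncol(v) == 0L) stop("empty SNV matrix")
  if (anyDuplicated(rownames(v))) stop("duplicate cell ids")
  ch <- v
  ch[is.na(ch)] <- "N"
  seqs <- apply(ch, 1L, paste0, collapse = "")
  ss <- Biostrings::BStringSet(setNames(seqs, rownames(v)))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @rdname write_snv_fasta
#' @param site_ids optional column names.
#' @export
read_snv_fasta <- function(path, site_ids = NULL) {
  m <- read_char_fasta(path, site_ids)
  m[m == "N"] <- NA
  snv_matrix(m)
}
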
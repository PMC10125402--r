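make_expr <- function(values, samples = NULL) {
  if (is.null(rownames(values)))
    dimnames(values) <- list(sprintf("c%d", seq_len(nrow(values))),
                             sprintf("g%d", seq_len(ncol(values))))
  if (is.null(samples))
    samples <- setNames(rep("S1", nrow(values)), rownames(values))
  expression_matrix(values, samples)
}

test_that("compute_hdi matches hand-derived and brute-force windows", {
  h <- compute_hdi(c(0, 1, 2, 3, 10), 0.6)
  expect_equal(c(h$lower, h$upper), c(0, 2))   # widths 2,2,8; tie -> lowest
  h <- compute_hdi(1:10, 0.5)
  expect_equal(c(h$lower, h$upper), c(1, 5))   # all 5-windows width 4
  h <- compute_hdi(c(4, -1, 7), 1.0)
  expect_equal(c(h$lower, h$upper), c(-1, 7))  # mass 1 -> full range
  expect_error(compute_hdi(numeric(0), 0.5), "empty")
  expect_error(compute_hdi(c(1, NA), 0.5), "unknown")

  set.seed(11)
  for (i in 1:50) {
    n <- sample(2:200, 1)
    x <- rnorm(n, sd = sample(c(0.5, 5), 1))
    mass <- runif(1, 0.05, 1)
    h <- compute_hdi(x, mass)
    expect_equal(unname(c(h$lower, h$upper)), unname(hdi_brute(x, mass)))
    expect_gte(sum(x >= h$lower & x <= h$upper), ceiling(mass * n))
  }
})

test_that("HDI approaches the central quantile interval for symmetric samples", {
  set.seed(42)
  x <- rnorm(1e5)
  h <- compute_hdi(x, 0.9)
  expect_lt(abs(h$lower - qnorm(0.05)), 0.02)
  expect_lt(abs(h$upper - qnorm(0.95)), 0.02)
})

test_that("center_scale standardizes per gene and handles the zero modes", {
  m <- make_expr(cbind(g1 = c(1, 2, 3), g2 = c(0, 2, 4), g3 = c(5, 5, 5)))
  expect_message(out <- center_scale(m, "biological"), "1 gene")
  expect_equal(attr(out, "n_dropped"), 1)
  expect_equal(colnames(out$values), c("g1", "g2"))
  expect_equal(unname(out$values[, "g1"]), c(-1, 0, 1))  # sample sd = 1

  out <- center_scale(m, "unknown")
  # zeros removed before mean/sd: g2 standardized over {2,4}
  expect_equal(unname(out$values[, "g2"]),
               c(NA, -1 / sqrt(2), 1 / sqrt(2)))
  # per-gene known values: mean 0, sample variance 1
  for (j in seq_len(ncol(out$values))) {
    v <- out$values[, j][!is.na(out$values[, j])]
    expect_lt(abs(mean(v)), 1e-9)
    expect_lt(abs(var(v) - 1), 1e-9)
  }
})

test_that("center_scale is idempotent on standardized genes", {
  set.seed(7)
  m <- make_expr(matrix(rnorm(60), 10))
  once <- center_scale(m, "unknown")
  twice <- center_scale(make_expr(once$values), "unknown")
  expect_equal(twice$values, once$values, tolerance = 1e-10)
})

test_that("biological mode tags raw zeros and excludes them from scaling", {
  m <- make_expr(cbind(g1 = c(0, 1, 2, 3)))
  out <- center_scale(m, "biological")
  expect_true(attr(out, "raw_zero")[1, "g1"])
  v <- out$values[, 1][!is.na(out$values[, 1])]
  expect_equal(mean(v), 0)         # over {1,2,3} only
  expect_true(is.na(out$values[1, 1]))
})

test_that("discretize maps the five categories and propagates unknowns", {
  h60 <- structure(list(lower = -1, upper = 1, mass = 0.6), class = "HdiInterval")
  h90 <- structure(list(lower = -2, upper = 2, mass = 0.9), class = "HdiInterval")
  v <- cbind(g1 = c(-3, -1.5, 0, 1.5, 3, NA))
  rownames(v) <- sprintf("c%d", 1:6)
  om <- discretize(v, h60, h90, zero_mode = "unknown")
  expect_equal(unname(om$values[, 1]), c(1L, 2L, 3L, 4L, 5L, NA))
  # boundary values: 60% HDI closed both ends, 90% closed outward
  vb <- cbind(g1 = c(-2, -1, 1, 2))
  rownames(vb) <- sprintf("b%d", 1:4)
  expect_equal(unname(discretize(vb, h60, h90)$values[, 1]), c(2L, 3L, 3L, 4L))
  expect_error(discretize(v, h90, h60), "nested")
})

test_that("discretize is monotone and preserves known-entry counts", {
  set.seed(5)
  m <- make_expr(matrix(rnorm(400), 20))
  m$values[sample(400, 80)] <- NA
  om <- discretize(center_scale(m, "unknown"), zero_mode = "unknown")
  cs <- center_scale(m, "unknown")
  expect_equal(sum(!is.na(om$values)), sum(!is.na(cs$values)))
  # monotone: sort known values of a gene, categories must be non-decreasing
  for (j in 1:5) {
    v <- cs$values[, j]; o <- order(v, na.last = NA)
    expect_true(all(diff(om$values[o, j]) >= 0))
  }
})

test_that("biological mode yields category 0 and enlarges the known count", {
  set.seed(8)
  raw <- matrix(rpois(300, 2), 30)
  m <- make_expr(raw)
  cs <- center_scale(m, "biological")
  om <- discretize(cs, zero_mode = "biological")
  kept <- colnames(cs$values)
  expect_equal(sum(om$values == 0, na.rm = TRUE),
               sum(raw[, match(kept, colnames(m$values))] == 0))
  known <- om$values[!is.na(om$values)]
  expect_true(all(known %in% 0:5))
  expect_true(0L %in% known)
  expect_equal(om$zero_mode, "biological")
})

test_that("remove_uninformative_genes drops constants and singletons", {
  v <- cbind(g1 = c(3L, 3L, 3L),          # constant -> dropped
             g2 = c(2L, NA, 4L),          # two known categories -> kept
             g3 = c(1L, NA, NA))          # known in one cell -> dropped
  rownames(v) <- c("a", "b", "c")
  om <- ordinal_matrix(v, "unknown")
  out <- remove_uninformative_genes(om)
  expect_equal(colnames(out$values), "g2")
  expect_equal(attr(out, "n_dropped"), 2)
  only_bad <- ordinal_matrix(v[, c("g1", "g3")], "unknown")
  expect_error(remove_uninformative_genes(only_bad), "empty alignment")
})

test_that("ordinal FASTA round-trips losslessly", {
  v <- matrix(c(3L, 3L, 3L, NA, 1L, 5L), 2, byrow = TRUE,
              dimnames = list(c("cellA", "cellB"), sprintf("g%d", 1:3)))
  om <- ordinal_matrix(v, "unknown")
  path <- withr::local_tempfile(fileext = ".fasta")
  write_ordinal_fasta(om, path)
  lines <- readLines(path)
  expect_equal(lines[2], "333")
  expect_equal(lines[4], "-15")
  back <- read_ordinal_fasta(path, "unknown", gene_ids = colnames(v))
  expect_identical(back$values, om$values)

  set.seed(9)
  v2 <- matrix(sample(c(1:5, NA), 200, replace = TRUE), 10,
               dimnames = list(sprintf("c%02d", 1:10), sprintf("g%02d", 1:20)))
  om2 <- ordinal_matrix(v2, "unknown")
  write_ordinal_fasta(om2, path)
  expect_identical(read_ordinal_fasta(path, gene_ids = colnames(v2))$values,
                   om2$values)
  # all-unknown cell serializes to dashes
  v3 <- rbind(v2, allna = rep(NA_integer_, 20))
  write_ordinal_fasta(ordinal_matrix(v3, "unknown"), path)
  expect_true(any(grepl("^-{20}$", readLines(path))))
  expect_error(write_ordinal_fasta(v2[c(1, 1), ], path), "duplicate")
})
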
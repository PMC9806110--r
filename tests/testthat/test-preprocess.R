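test_that("QC filtering applies every rule exactly, genes then cells", {
  m <- toy_qc_matrix()
  filt <- filter_cells_genes(m, min_cells_per_gene = 3L,
                             max_mito_frac = 0.20,
                             min_genes = 2L, max_genes = 5L)
  oracle <- qc_oracle(m, 3L, 0.20, 2L, 5L)
  expect_identical(dim(filt), dim(oracle))
  expect_identical(as.matrix(filt)[rownames(oracle), colnames(oracle)],
                   oracle)
  # forced removals: the 27%-mito cell and the 2-cell gene
  expect_false("c01" %in% rownames(filt))
  expect_false("G4" %in% colnames(filt))
  # boundary of the gene rule: detected in exactly 3 cells is retained
  expect_true("MT-1" %in% colnames(filt))
  expect_true("G2" %in% colnames(filt))
  report <- attr(filt, "qc_report")
  expect_equal(report$summary$genes_removed,
               ncol(m) - ncol(oracle))
  expect_equal(report$summary$cells_removed,
               nrow(qc_oracle(m, 3L, 1, 0L, 100L)) - nrow(oracle))
})

test_that("a gene detected in exactly min_cells_per_gene cells survives", {
  m <- toy_qc_matrix()
  det <- colSums(m > 0)
  filt <- filter_cells_genes(m, min_cells_per_gene = 3L,
                             min_genes = 0L, max_genes = 100L,
                             max_mito_frac = 1)
  expect_setequal(colnames(filt), names(det)[det >= 3])
  # at threshold det + 1 the same gene is gone
  g3 <- sum(m[, "G3"] > 0)
  filt2 <- filter_cells_genes(m, min_cells_per_gene = g3 + 1L,
                              min_genes = 0L, max_genes = 100L,
                              max_mito_frac = 1)
  expect_false("G3" %in% colnames(filt2))
})

test_that("ribosomal rule modes act in the stated directions", {
  m <- toy_qc_matrix()
  # c02 has the only ribosomal count
  below <- filter_cells_genes(m, min_cells_per_gene = 0L, min_genes = 0L,
                              max_genes = 100L, max_mito_frac = 1,
                              ribo_rule = "remove_below", ribo_frac = 0.01)
  expect_true("c02" %in% rownames(below))
  expect_lt(nrow(below), nrow(m))
  above <- filter_cells_genes(m, min_cells_per_gene = 0L, min_genes = 0L,
                              max_genes = 100L, max_mito_frac = 1,
                              ribo_rule = "remove_above", ribo_frac = 0.01)
  expect_false("c02" %in% rownames(above))
})

test_that("filtering is idempotent and errors on empty results", {
  sim <- simulate_single_cell(small_sim_config(seed = 26))
  strip <- function(x) {
    y <- as.matrix(x)
    attr(y, "qc_report") <- NULL
    y
  }
  f1 <- filter_cells_genes(sim$counts, min_cells_per_gene = 3L,
                           min_genes = 20L, max_genes = 5000L)
  f2 <- filter_cells_genes(f1, min_cells_per_gene = 3L,
                           min_genes = 20L, max_genes = 5000L)
  expect_identical(strip(f1), strip(f2))
  m <- toy_qc_matrix()
  expect_error(filter_cells_genes(m, min_cells_per_gene = 100L),
               "empty result")
  expect_error(filter_cells_genes(m, min_cells_per_gene = 0L,
                                  min_genes = 50L, max_genes = 60L),
               "empty result")
})

test_that("log-normalization matches its closed form", {
  m <- matrix(c(10, 90, 0, 25, 50, 25), nrow = 2, byrow = TRUE,
              dimnames = list(c("c1", "c2"), c("g1", "g2", "g3")))
  norm <- lognormalize(m, scale_factor = 1e4)
  expect_equal(norm["c1", "g1"], log1p(10 / 100 * 1e4))
  expect_equal(norm["c1", "g3"], 0)  # zero count maps to zero
  # closed-form spot value: count 10 of total 100 at scale 10000
  expect_equal(unname(norm["c1", "g1"]), log(1 + 1000), tolerance = 1e-12)
  # scale invariance: doubling all counts of a cell changes nothing
  m2 <- m
  m2["c1", ] <- m["c1", ] * 2
  expect_equal(as.matrix(lognormalize(m2))["c1", ],
               as.matrix(norm)["c1", ])
  # zero-total cell is an error naming the cell
  m3 <- rbind(m, c0 = c(0, 0, 0))
  expect_error(lognormalize(m3), "c0")
})

test_that("normalization preserves within-cell rank order", {
  sim <- simulate_single_cell(small_sim_config(seed = 2))
  norm <- lognormalize(sim$counts)
  for (i in c(1L, 50L, 200L)) {
    expect_identical(order(as.numeric(sim$counts[i, ])),
                     order(as.numeric(norm[i, ])))
  }
})

test_that("variable-gene selection matches a brute-force re-ranking", {
  sim <- simulate_single_cell(sim_config(
    n_genes = 50L, n_marker_genes_per_cluster = 5L,
    cluster_spec = c("CSC" = 60L, "OS-A2" = 60L, "OS-B2" = 60L,
                     "OS-C2" = 60L), seed = 13
  ))
  norm <- lognormalize(sim$counts)
  sel <- select_variable_genes(norm, 20L)

  # dense, loop-based re-computation of the documented statistic: loess
  # trend of log10 variance on log10 mean, z-scores clipped at sqrt(n),
  # variance of the clipped z-scores
  x <- as.matrix(norm)
  n <- nrow(x)
  mu <- colMeans(x)
  v <- apply(x, 2L, var)
  usable <- v > 0 & mu > 0
  fit <- stats::loess(log10(v[usable]) ~ log10(mu[usable]),
                      span = 0.3, degree = 2)
  sd_hat <- sqrt(v)
  pred <- 10^stats::predict(fit, newdata = log10(mu[usable]))
  ok <- is.finite(pred) & pred > 0
  sd_hat[usable][ok] <- sqrt(pred[ok])
  stat <- vapply(seq_len(ncol(x)), function(j) {
    if (sd_hat[j] <= 0 || !is.finite(sd_hat[j])) return(0)
    z <- (x[, j] - mu[j]) / sd_hat[j]
    z <- pmin(pmax(z, -sqrt(n)), sqrt(n))
    sum(z^2) / (n - 1)
  }, numeric(1))
  oracle_rank <- colnames(x)[order(-stat, colnames(x))][1:20]
  expect_identical(sel[seq_len(20L)], oracle_rank)

  # the selection is enriched for the planted markers
  markers <- unlist(sim$truth$planted_markers, use.names = FALSE)
  expect_gte(sum(sel %in% markers), 12L)

  # constant gene can never precede a non-constant gene
  x2 <- cbind(as.matrix(norm), CONST = rep(2, n))
  sel2 <- select_variable_genes(Matrix::Matrix(x2, sparse = TRUE), 50L)
  expect_false("CONST" %in% sel2[seq_len(49L)])

  # n = n_genes returns everything; n too large errors
  expect_setequal(select_variable_genes(norm, ncol(norm)), colnames(norm))
  expect_error(select_variable_genes(norm, ncol(norm) + 1L), "select")
})

test_that("variable-gene selection is permutation-equivariant", {
  sim <- simulate_single_cell(small_sim_config(seed = 4))
  norm <- lognormalize(sim$counts)
  sel <- select_variable_genes(norm, 30L)
  set.seed(1)
  perm <- sample(ncol(norm))
  sel_perm <- select_variable_genes(norm[, perm], 30L)
  expect_identical(as.character(sel), as.character(sel_perm))
})

test_that("clustering recovers separable populations and flags k = 1", {
  # two populations with disjoint expressed gene sets
  set.seed(1)
  lam1 <- rep(c(20, 1), each = 15)
  lam2 <- rep(c(1, 20), each = 15)
  x <- rbind(
    matrix(rpois(100 * 30, rep(lam1, each = 100)), 100),
    matrix(rpois(100 * 30, rep(lam2, each = 100)), 100)
  )
  rownames(x) <- sprintf("c%03d", 1:200)
  colnames(x) <- sprintf("g%02d", 1:30)
  truth <- rep(c(0, 1), each = 100)
  norm <- lognormalize(x)
  lab <- embed_and_cluster(norm, colnames(x), n_pcs = 5L, k = 2L, seed = 9)
  expect_equal(adjusted_rand_index(lab, truth), 1.0)

  one <- embed_and_cluster(norm, colnames(x), n_pcs = 5L, k = 1L, seed = 9)
  expect_true(isTRUE(attr(one, "degenerate")))
  expect_true(all(one == 0L))
  expect_error(adjusted_rand_index(one, rep(0L, 200L)), "undefined")
  expect_error(embed_and_cluster(norm, colnames(x), k = 300L), "exceeds")

  # deterministic given the seed
  lab2 <- embed_and_cluster(norm, colnames(x), n_pcs = 5L, k = 2L, seed = 9)
  expect_identical(lab, lab2)
})

test_that("the default tumor atlas is recovered at k = 10", {
  sim <- simulate_single_cell(sim_config(seed = 1))
  norm <- lognormalize(sim$counts)
  hvg <- select_variable_genes(norm, 500L)
  lab <- embed_and_cluster(norm, hvg, n_pcs = 20L, k = 10L, seed = 1)
  expect_gte(adjusted_rand_index(lab, sim$truth$cell_labels), 0.9)
})
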
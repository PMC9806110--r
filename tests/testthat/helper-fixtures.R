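# Shared fixture builders. Everything is generated in code at test time.

# A small simulation configuration: 4 clusters, few genes, quick to draw.
small_sim_config <- function(seed = 42, ...) {
  sim_config(
    n_genes = 300L,
    n_marker_genes_per_cluster = 10L,
    cluster_spec = c("CSC" = 80L, "OS-A2" = 80L, "OS-B2" = 80L,
                     "OS-C2" = 80L, "BMSC" = 40L, "Osteoblast" = 40L,
                     "Immune" = 40L),
    library_size_range = c(50, 100),  # keeps per-gene sparsity realistic
    seed = seed,
    ...
  )
}

# Deterministic toy count matrix with known QC violations, used by the
# filtering tests. Rows are cells, columns genes; MT-1 is mitochondrial.
toy_qc_matrix <- function() {
  genes <- c("MT-1", "RPS1", "G1", "G2", "G3", "G4")
  cells <- sprintf("c%02d", 1:10)
  m <- matrix(0L, nrow = 10, ncol = 6, dimnames = list(cells, genes))
  m[, "G1"] <- c(5L, 4L, 6L, 5L, 3L, 4L, 5L, 6L, 4L, 5L)
  m[, "G2"] <- c(2L, 3L, 1L, 2L, 2L, 3L, 1L, 2L, 3L, 0L)
  m[, "G3"] <- c(1L, 0L, 2L, 1L, 0L, 1L, 2L, 0L, 1L, 1L)
  # MT-1 detected in 3 cells so it survives the gene filter;
  # c01 then has 3 / 11 = 27% mitochondrial reads -> dropped at 20%
  m[, "MT-1"] <- c(3L, 0L, 1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L)
  m["c02", "RPS1"] <- 1L
  m["c03", "G4"] <- 1L     # G4 detected in 2 cells only -> dropped
  m["c04", "G4"] <- 2L
  m["c05", c("G2", "G3")] <- 0L  # only 1 non-mito detected gene
  m
}

# Brute-force QC oracle: re-applies every rule with explicit loops.
qc_oracle <- function(m, min_cells_per_gene, max_mito_frac,
                      min_genes, max_genes) {
  keep_gene <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    keep_gene[j] <- sum(m[, j] > 0) >= min_cells_per_gene
  }
  m2 <- m[, keep_gene, drop = FALSE]
  mito <- grepl("^MT-", colnames(m2), ignore.case = TRUE)
  keep_cell <- logical(nrow(m2))
  for (i in seq_len(nrow(m2))) {
    det <- sum(m2[i, ] > 0)
    tot <- sum(m2[i, ])
    mf <- if (tot > 0) sum(m2[i, mito]) / tot else 0
    keep_cell[i] <- det >= min_genes && det <= max_genes &&
      mf <= max_mito_frac
  }
  m2[keep_cell, , drop = FALSE]
}

# Exhaustive two-sided Mann-Whitney p-value by enumerating every way of
# assigning the pooled values to the first group.
exact_wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2L, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  mu <- n1 * (length(pooled) - n1) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu))
}

# Same configuration, different replicate seed.
sim_config_reseed <- function(cfg, seed) {
  cfg$seed <- as.integer(seed)
  cfg
}

# The six-marker IHC panel with its group mapping.
ihc_panel <- function() {
  marker_panel(list(A = c("ALKBH5", "TOM1L2"),
                    B = c("CDK4", "LMO7"),
                    C = c("COL6A3", "THBS2")))
}
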
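#' Quality-control filtering of a single-cell count matrix
#'
#' Applies the standard droplet QC rules in a fixed genes-then-cells order:
#' first genes detected (count > 0) in fewer than `min_cells_per_gene` cells
#' are dropped; then, on the gene-filtered matrix, cells are dropped when
#' their detected-gene count falls outside `[min_genes, max_genes]`, their
#' mitochondrial read fraction exceeds `max_mito_frac`, or they violate the
#' configurable ribosomal-fraction rule.
#'
#' The ribosomal rule has three modes because the conventional direction of
#' that filter is ambiguous in practice: `"off"` (default), `"remove_below"`
#' (drop cells with ribosomal fraction < `ribo_frac`) and `"remove_above"`
#' (drop cells with fraction > `ribo_frac`).
#'
#' @param counts cells x genes matrix of non-negative integer counts
#'   (dense or `Matrix` sparse) with unique row (cell) and column (gene)
#'   names.
#' @param min_cells_per_gene keep genes detected in at least this many
#'   cells (default 3).
#' @param max_mito_frac remove cells with mitochondrial fraction strictly
#'   above this value (default 0.20).
#' @param ribo_rule one of `"off"`, `"remove_below"`, `"remove_above"`.
#' @param ribo_frac threshold for the ribosomal rule (default 0.05).
#' @param min_genes,max_genes keep cells with detected-gene count in
#'   `[min_genes, max_genes]` (defaults 200 and 5000).
#' @param mito_genes,ribo_genes character vectors of gene ids to treat as
#'   mitochondrial / ribosomal. Default: ids matching `^MT-` and `^RP[SL]`
#'   (case-insensitive).
#' @return The filtered count matrix with a `"qc_report"` attribute: a list
#'   with per-cell QC metrics (`cell_qc` data.frame computed after the gene
#'   filter) and counts of removed genes/cells per rule.
#' @examples
#' sim <- simulate_single_cell(sim_config(seed = 1))
#' filt <- filter_cells_genes(sim$counts, min_genes = 10, max_genes = 1e6)
#' attr(filt, "qc_report")$summary
#' @export
filter_cells_genes <- function(counts,
                               min_cells_per_gene = 3L,
                               max_mito_frac = 0.20,
                               ribo_rule = c("off", "remove_below",
                                             "remove_above"),
                               ribo_frac = 0.05,
                               min_genes = 200L,
                               max_genes = 5000L,
                               mito_genes = NULL,
                               ribo_genes = NULL) {
  ribo_rule <- match.arg(ribo_rule)
  stopifnot(min_cells_per_gene >= 0, max_mito_frac >= 0, min_genes >= 0)
  if (min_genes >= max_genes) {
    stop("min_genes must be smaller than max_genes")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry cell rownames and gene colnames")
  }

  # genes first
  n_cells_detect <- Matrix::colSums(counts > 0)
  keep_gene <- n_cells_detect >= min_cells_per_gene
  n_genes_removed <- sum(!keep_gene)
  if (!any(keep_gene)) {
    stop("empty result: all ", ncol(counts), " genes removed by the ",
         "min_cells_per_gene >= ", min_cells_per_gene, " rule")
  }
  counts <- counts[, keep_gene, drop = FALSE]

  gene_ids <- colnames(counts)
  if (is.null(mito_genes)) {
    mito_genes <- gene_ids[grepl("^MT-", gene_ids, ignore.case = TRUE)]
  }
  if (is.null(ribo_genes)) {
    ribo_genes <- gene_ids[grepl("^RP[SL]", gene_ids, ignore.case = TRUE)]
  }
  is_mito <- gene_ids %in% mito_genes
  is_ribo <- gene_ids %in% ribo_genes

  totals <- Matrix::rowSums(counts)
  detected <- Matrix::rowSums(counts > 0)
  mito_frac <- ifelse(totals > 0,
                      Matrix::rowSums(counts[, is_mito, drop = FALSE]) /
                        totals, 0)
  ribo_frac_cell <- ifelse(totals > 0,
                           Matrix::rowSums(counts[, is_ribo, drop = FALSE]) /
                             totals, 0)

  pass_genes_lo <- detected >= min_genes
  pass_genes_hi <- detected <= max_genes
  pass_mito <- mito_frac <= max_mito_frac
  pass_ribo <- switch(ribo_rule,
    off = rep(TRUE, length(totals)),
    remove_below = ribo_frac_cell >= ribo_frac,
    remove_above = ribo_frac_cell <= ribo_frac
  )
  keep_cell <- pass_genes_lo & pass_genes_hi & pass_mito & pass_ribo

  cell_qc <- data.frame(
    cell_id = rownames(counts),
    total_counts = as.numeric(totals),
    n_genes_detected = as.integer(detected),
    mito_frac = as.numeric(mito_frac),
    ribo_frac = as.numeric(ribo_frac_cell),
    pass = keep_cell,
    stringsAsFactors = FALSE
  )

  if (!any(keep_cell)) {
    stop("empty result: all ", nrow(counts), " cells removed (",
         sum(!pass_genes_lo), " below min_genes, ",
         sum(!pass_genes_hi), " above max_genes, ",
         sum(!pass_mito), " above max_mito_frac, ",
         sum(!pass_ribo), " failing the ribosomal rule)")
  }
  out <- counts[keep_cell, , drop = FALSE]
  attr(out, "qc_report") <- list(
    cell_qc = cell_qc,
    summary = list(
      genes_removed = as.integer(n_genes_removed),
      cells_removed = as.integer(sum(!keep_cell)),
      removed_min_genes = as.integer(sum(!pass_genes_lo)),
      removed_max_genes = as.integer(sum(!pass_genes_hi)),
      removed_mito = as.integer(sum(!pass_mito)),
      removed_ribo = as.integer(sum(!pass_ribo))
    ),
    params = list(
      min_cells_per_gene = min_cells_per_gene,
      max_mito_frac = max_mito_frac,
      ribo_rule = ribo_rule, ribo_frac = ribo_frac,
      min_genes = min_genes, max_genes = max_genes
    )
  )
  out
}

#' Library-size log-normalization
#'
#' Scales each cell to a common library size and log-transforms:
#' `value = log1p(count / cell_total * scale_factor)`. Zero counts map to
#' zero, so sparsity is preserved.
#'
#' @param counts cells x genes count matrix (dense or sparse) with cell
#'   rownames.
#' @param scale_factor common library size to scale to (default 10000).
#' @return A sparse cells x genes matrix of normalized values with
#'   attributes `scale_factor`.
#' @examples
#' m <- matrix(c(10, 90, 5, 95), 2, 2, byrow = TRUE,
#'             dimnames = list(c("c1", "c2"), c("g1", "g2")))
#' lognormalize(m, scale_factor = 100)
#' @export
lognormalize <- function(counts, scale_factor = 1e4) {
  stopifnot(scale_factor > 0)
  totals <- Matrix::rowSums(counts)
  if (any(totals <= 0)) {
    bad <- rownames(counts)[which(totals <= 0)]
    stop("cells with zero total count cannot be normalized: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  sp <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  norm <- Matrix::Diagonal(x = scale_factor / totals) %*% sp
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)
  attr(norm, "scale_factor") <- scale_factor
  norm
}

# Per-gene mean, variance and clipped standardized variance of a sparse
# cells x genes matrix. The expected sd per gene comes from a loess trend of
# log10 variance on log10 mean across genes (the usual variance-stabilizing
# convention); z-scores are clipped at sqrt(n_cells) before re-computing the
# variance, so a handful of outlier cells cannot dominate the ranking.
standardized_variance <- function(norm) {
  n <- nrow(norm)
  mu <- Matrix::colMeans(norm)
  ex2 <- Matrix::colMeans(norm^2)
  v <- (ex2 - mu^2) * n / (n - 1)
  v[v < 0] <- 0

  usable <- v > 0 & mu > 0
  sd_hat <- sqrt(v)
  if (sum(usable) >= 10L) {
    fit <- try(stats::loess(log10(v[usable]) ~ log10(mu[usable]),
                            span = 0.3, degree = 2), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      pred <- 10^stats::predict(fit, newdata = log10(mu[usable]))
      ok <- is.finite(pred) & pred > 0
      sd_hat[usable][ok] <- sqrt(pred[ok])
    }
  }

  clip <- sqrt(n)
  stat <- numeric(ncol(norm))
  csp <- methods::as(norm, "CsparseMatrix")
  ptr <- csp@p
  xs <- csp@x
  for (j in seq_len(ncol(norm))) {
    if (sd_hat[j] <= 0 || !is.finite(sd_hat[j])) next
    xj <- xs[(ptr[j] + 1L):ptr[j + 1L]]
    if (ptr[j + 1L] == ptr[j]) xj <- numeric(0)
    z_nonzero <- pmin(pmax((xj - mu[j]) / sd_hat[j], -clip), clip)
    z_zero <- pmin(pmax((0 - mu[j]) / sd_hat[j], -clip), clip)
    n_zero <- n - length(xj)
    stat[j] <- (sum(z_nonzero^2) + n_zero * z_zero^2) / (n - 1)
  }
  # loess predictions carry ~1e-16 order-dependent jitter; round so the
  # ranking (and its gene-id tie-break) is permutation-equivariant
  stat <- signif(stat, 9)
  data.frame(gene_id = colnames(norm), mean = mu, variance = v,
             std_variance = stat, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Select highly variable genes
#'
#' Ranks genes by clipped standardized variance (variance of z-scores taken
#' against a loess mean-variance trend, clipped at `sqrt(n_cells)`) and
#' returns the top `n`. Ties are broken by lexicographic gene id, so the
#' selection is deterministic and equivariant under gene permutation.
#'
#' @param norm normalized cells x genes matrix from [lognormalize()].
#' @param n number of genes to select (default 1000).
#' @return Character vector of `n` gene ids, ordered by decreasing
#'   standardized variance. The full ranking table is attached as attribute
#'   `"hvg_stats"`.
#' @export
select_variable_genes <- function(norm, n = 1000L) {
  if (n > ncol(norm)) {
    stop("cannot select ", n, " genes from a matrix with ", ncol(norm))
  }
  stats_df <- standardized_variance(norm)
  ord <- order(-stats_df$std_variance, stats_df$gene_id)
  out <- stats_df$gene_id[ord][seq_len(n)]
  attr(out, "hvg_stats") <- stats_df[ord, ]
  out
}

#' PCA embedding and k-means clustering of cells
#'
#' Scales the selected genes, embeds cells with PCA and clusters the
#' leading principal components with k-means (multiple restarts, fixed
#' seed). This supplies the cluster labels the marker-discovery stage
#' needs; it intentionally avoids graph-based clustering so results are
#' fully deterministic given the seed.
#'
#' @param norm normalized cells x genes matrix.
#' @param genes character vector of genes to embed on (e.g. from
#'   [select_variable_genes()]).
#' @param n_pcs number of principal components (default 20, capped at the
#'   data dimensions).
#' @param k number of clusters; `k = 1` returns a single cluster with a
#'   `degenerate` attribute set.
#' @param seed integer RNG seed.
#' @param nstart k-means restarts (default 25).
#' @return Integer vector of cluster labels in `0..k-1`, named by cell id.
#' @export
embed_and_cluster <- function(norm, genes, n_pcs = 20L, k, seed = 1L,
                              nstart = 25L) {
  if (k > nrow(norm)) {
    stop("k = ", k, " exceeds the number of cells (", nrow(norm), ")")
  }
  if (k < 1L) stop("k must be >= 1")
  genes <- intersect(genes, colnames(norm))
  if (length(genes) == 0L) stop("none of the requested genes are present")
  x <- as.matrix(norm[, genes, drop = FALSE])
  sds <- apply(x, 2L, stats::sd)
  x <- x[, sds > 0, drop = FALSE]
  x <- scale(x)
  n_pcs <- min(n_pcs, nrow(x) - 1L, ncol(x))
  if (n_pcs < 1L) stop("not enough non-constant genes for PCA")

  set.seed(seed)
  pcs <- stats::prcomp(x, center = FALSE, scale. = FALSE,
                       rank. = n_pcs)$x
  if (k == 1L) {
    labels <- stats::setNames(rep(0L, nrow(norm)), rownames(norm))
    attr(labels, "degenerate") <- TRUE
    return(labels)
  }
  km <- stats::kmeans(pcs, centers = k, nstart = nstart, iter.max = 100L)
  stats::setNames(as.integer(km$cluster) - 1L, rownames(norm))
}
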
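#' Resampling consensus clustering of bulk samples
#'
#' Repeatedly subsamples the cohort without replacement, clusters each
#' subsample with k-means at every `k` in `k_range`, and tallies, for each
#' pair of samples, how often both were drawn (`indicator_counts`) and how
#' often they landed in the same cluster (`cocluster_counts`). The
#' consensus matrix at each `k` is the ratio of the two tallies; stable
#' subtype structure shows up as near-0/1 blocks. Final labels per `k` come
#' from average-linkage hierarchical clustering of `1 - consensus` cut at
#' `k`; the number of subtypes is chosen by minimum PAC
#' (see [pac_and_cdf()]).
#'
#' Expression is restricted to the panel genes (when a panel is given) and
#' each gene is z-scored across the cohort before clustering, so genes on
#' different scales contribute comparably to the Euclidean distances.
#'
#' @param expr samples x genes numeric matrix with sample rownames.
#' @param panel optional [marker_panel()]; expression is restricted to its
#'   genes (missing panel genes are dropped with a warning).
#' @param k_range integer vector of cluster numbers to evaluate
#'   (default `2:6`).
#' @param n_resamples number of subsampling iterations (default 500).
#' @param subsample_frac fraction of samples drawn per iteration
#'   (default 0.8).
#' @param seed integer RNG seed; results are deterministic given the seed.
#' @param scale_genes z-score genes across the cohort first (default TRUE).
#' @param nstart k-means restarts per inner run (default 10).
#' @return An object of class `consensus_result`: list with
#'   `consensus` (list of symmetric samples x samples matrices per k),
#'   `indicator_counts`, `cocluster_counts`, `labels_per_k`, `cdf_per_k`,
#'   `pac_per_k`, `chosen_k`, and `params`.
#' @examples
#' cohort <- simulate_bulk_cohort(sim_config(seed = 3, bulk_n_per_group = 10))
#' cc <- consensus_cluster(cohort$expr[, 1:60], k_range = 2:4,
#'                         n_resamples = 30, seed = 3)
#' cc$chosen_k
#' @export
consensus_cluster <- function(expr, panel = NULL, k_range = 2:6,
                              n_resamples = 500L, subsample_frac = 0.8,
                              seed = 1L, scale_genes = TRUE,
                              nstart = 10L) {
  if (!is.null(panel)) {
    panel <- as_marker_panel(panel)
    wanted <- unlist(panel$panels, use.names = FALSE)
    missing <- setdiff(wanted, colnames(expr))
    if (length(missing) > 0L) {
      warning("dropping ", length(missing),
              " panel gene(s) absent from the expression table: ",
              paste(utils::head(missing, 5L), collapse = ", "))
    }
    expr <- expr[, intersect(wanted, colnames(expr)), drop = FALSE]
    if (ncol(expr) == 0L) stop("no panel genes present in expression table")
  }
  n <- nrow(expr)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2L)) stop("k_range values must be >= 2")
  if (n < max(k_range) * 2L) {
    stop("need at least 2 * max(k_range) = ", max(k_range) * 2L,
         " samples, found ", n)
  }
  if (subsample_frac <= 0 || subsample_frac > 1) {
    stop("subsample_frac must be in (0, 1]")
  }
  m <- ceiling(subsample_frac * n)
  if (m < max(k_range)) {
    stop("subsample of size ", m, " cannot be split into ",
         max(k_range), " clusters")
  }

  x <- as.matrix(expr)
  if (scale_genes) x <- zscore_columns(x)
  sample_ids <- rownames(expr) %||% sprintf("S%03d", seq_len(n))

  set.seed(seed)
  resample_seeds <- sample.int(.Machine$integer.max - 1L, n_resamples)

  indicator <- matrix(0L, n, n, dimnames = list(sample_ids, sample_ids))
  cocluster <- lapply(k_range, function(k) indicator)
  names(cocluster) <- as.character(k_range)

  for (b in seq_len(n_resamples)) {
    set.seed(resample_seeds[b])
    idx <- sample.int(n, m)
    drawn <- integer(n)
    drawn[idx] <- 1L
    indicator <- indicator + tcrossprod(drawn)
    for (k in k_range) {
      km <- stats::kmeans(x[idx, , drop = FALSE], centers = k,
                          nstart = nstart, iter.max = 100L)
      memb <- matrix(0L, n, k)
      memb[cbind(idx, km$cluster)] <- 1L
      cocluster[[as.character(k)]] <-
        cocluster[[as.character(k)]] + tcrossprod(memb)
    }
  }

  never_drawn <- indicator == 0
  diag(never_drawn) <- FALSE
  if (any(never_drawn)) {
    warning(sum(never_drawn) / 2,
            " sample pair(s) never co-drawn; consensus entries set to 0")
  }

  consensus <- lapply(cocluster, function(cc) {
    cm <- ifelse(indicator > 0, cc / pmax(indicator, 1L), 0)
    dimnames(cm) <- list(sample_ids, sample_ids)
    cm
  })

  labels_per_k <- list()
  cdf_per_k <- list()
  pac_per_k <- stats::setNames(numeric(length(k_range)),
                               as.character(k_range))
  for (k in k_range) {
    ck <- as.character(k)
    hc <- stats::hclust(stats::as.dist(1 - consensus[[ck]]),
                        method = "average")
    labels_per_k[[ck]] <- stats::setNames(stats::cutree(hc, k = k),
                                          sample_ids)
    pc <- pac_and_cdf(consensus[[ck]])
    cdf_per_k[[ck]] <- pc$cdf
    pac_per_k[[ck]] <- pc$pac
  }
  chosen_k <- k_range[which.min(pac_per_k)]

  structure(list(
    consensus = consensus,
    indicator_counts = indicator,
    cocluster_counts = cocluster,
    labels_per_k = labels_per_k,
    cdf_per_k = cdf_per_k,
    pac_per_k = pac_per_k,
    chosen_k = chosen_k,
    params = list(k_range = k_range, n_resamples = n_resamples,
                  subsample_frac = subsample_frac, seed = seed,
                  scale_genes = scale_genes, nstart = nstart)
  ), class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("Consensus clustering of %d samples (%d resamples, frac %.2f)\n",
              nrow(x$indicator_counts), x$params$n_resamples,
              x$params$subsample_frac))
  cat("  PAC per k:",
      paste(sprintf("k=%s: %.3f", names(x$pac_per_k), x$pac_per_k),
            collapse = ", "), "\n")
  cat("  chosen k (min PAC):", x$chosen_k, "\n")
  invisible(x)
}

#' PAC score and consensus CDF
#'
#' Computes the empirical CDF of the off-diagonal consensus-matrix entries
#' and the proportion of ambiguous clustering,
#' `PAC = CDF(upper) - CDF(lower)`: the mass of pairs whose co-clustering
#' frequency is far from both 0 and 1. Low PAC indicates a stable `k`.
#'
#' @param consensus symmetric samples x samples matrix with entries in
#'   \[0, 1\].
#' @param lower,upper the ambiguity interval bounds (defaults 0.1 and 0.9).
#' @return List with `cdf` (an `ecdf` function over the off-diagonal
#'   entries) and `pac` (a single number in \[0, 1\]).
#' @export
pac_and_cdf <- function(consensus, lower = 0.1, upper = 0.9) {
  if (lower >= upper) stop("lower must be smaller than upper")
  if (nrow(consensus) != ncol(consensus)) {
    stop("consensus matrix must be square")
  }
  off <- consensus[upper.tri(consensus)]
  if (any(off < 0 | off > 1)) stop("consensus entries must lie in [0, 1]")
  cdf <- stats::ecdf(off)
  list(cdf = cdf, pac = unname(cdf(upper) - cdf(lower)))
}

#' Name consensus clusters as subtype groups
#'
#' Extracts the sample labels at a given `k` from a [consensus_cluster()]
#' result and names each cluster by the marker panel it over-expresses:
#' the group whose panel-mean z-scored expression is highest within the
#' cluster. A collision (two clusters mapping to the same group) is an
#' error; `k = 1` returns a single unnamed cluster flagged as degenerate.
#'
#' @param result a `consensus_result`.
#' @param k the number of clusters to use (must be in the computed range).
#' @param expr the samples x genes expression matrix used for clustering.
#' @param panel the [marker_panel()] defining the groups.
#' @return Factor of group labels named by sample id, with attribute
#'   `"cluster_to_group"` recording the mapping.
#' @export
assign_from_consensus <- function(result, k, expr, panel) {
  stopifnot(inherits(result, "consensus_result"))
  panel <- as_marker_panel(panel)
  if (identical(as.integer(k), 1L)) {
    labels <- stats::setNames(rep("cluster1", nrow(expr)), rownames(expr))
    attr(labels, "degenerate") <- TRUE
    return(labels)
  }
  ck <- as.character(as.integer(k))
  if (!ck %in% names(result$labels_per_k)) {
    stop("k = ", k, " was not part of the computed k_range")
  }
  clusters <- result$labels_per_k[[ck]]
  expr <- expr[names(clusters), , drop = FALSE]

  scores <- score_panels(expr, panel, mode = "panel_mean",
                         normalization = "zscore_cohort")
  groups <- colnames(scores)
  cluster_ids <- sort(unique(clusters))
  mapping <- vapply(cluster_ids, function(cl) {
    groups[which.max(colMeans(scores[clusters == cl, , drop = FALSE]))]
  }, character(1))
  names(mapping) <- as.character(cluster_ids)
  if (anyDuplicated(mapping)) {
    dup <- mapping[duplicated(mapping)]
    stop("cluster naming collision: group(s) ",
         paste(unique(dup), collapse = ", "),
         " claimed by more than one cluster")
  }
  out <- factor(mapping[as.character(clusters)], levels = sort(groups))
  names(out) <- names(clusters)
  attr(out, "cluster_to_group") <- mapping
  out
}
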
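#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items,
#' used to score cluster-label recovery against simulation ground truth.
#' Returns 1 for identical partitions (up to relabeling) and ~0 for
#' independent ones.
#'
#' @param a,b vectors of equal length giving the two labelings.
#' @return A single number in (-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) {
    stop("labelings must have equal length")
  }
  if (length(unique(a)) < 2L && length(unique(b)) < 2L) {
    stop("ARI is undefined when both partitions have a single class")
  }
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  expected <- sum_i * sum_j / comb2(n)
  maxidx <- (sum_i + sum_j) / 2
  if (maxidx == expected) {
    return(0)
  }
  (sum_ij - expected) / (maxidx - expected)
}

#' Cluster composition of a labeled cell population
#'
#' Tabulates cluster sizes and their percentage of all labeled cells, the
#' summary usually reported alongside a single-cell atlas (e.g. the share
#' of a stem-like cluster in the tumor-cell compartment).
#'
#' @param labels vector of cluster labels, one per cell.
#' @return data.frame with `cluster`, `n_cells` and `pct` (percentage of
#'   all cells, full precision).
#' @examples
#' cluster_fractions(c("A", "A", "B"))
#' @export
cluster_fractions <- function(labels) {
  if (length(labels) == 0L) stop("no labels given")
  tab <- table(labels)
  data.frame(
    cluster = names(tab),
    n_cells = as.integer(tab),
    pct = 100 * as.numeric(tab) / length(labels),
    stringsAsFactors = FALSE
  )
}

# Derive a per-stage RNG seed from the root seed, keeping results of one
# stage reproducible when other stages are rerun. Stays well below 2^31.
stage_seed <- function(seed, stage) {
  offsets <- c(
    genes = 7L, sc = 11L, bulk = 23L, surv = 31L, ihc = 37L,
    cluster = 43L, consensus = 53L
  )
  if (!stage %in% names(offsets)) {
    stop("unknown stage: ", stage)
  }
  (abs(as.integer(seed)) %% 1000000L) * 1000L + offsets[[stage]]
}

# z-score the columns of a samples x genes matrix; constant columns map to 0.
zscore_columns <- function(x) {
  mu <- colMeans(x)
  sds <- apply(x, 2L, stats::sd)
  sds[sds == 0 | !is.finite(sds)] <- Inf
  sweep(sweep(x, 2L, mu, "-"), 2L, sds, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
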
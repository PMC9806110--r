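#' One-vs-rest Wilcoxon marker statistics for one cluster
#'
#' For every gene, compares normalized expression in the target cluster
#' against all other cells (or against one specific cluster via `against`)
#' with a two-sided Wilcoxon rank-sum test. Small, tie-free comparisons use
#' the exact null distribution; otherwise the normal approximation with tie
#' correction and continuity correction is used. The reported effect is the
#' natural-log fold change of cluster means on the de-logged scale with a
#' pseudocount of 1:
#' `log((mean(expm1(x_in)) + 1) / (mean(expm1(x_out)) + 1))`.
#'
#' @param norm normalized cells x genes matrix ([lognormalize()] scale).
#' @param labels vector of cluster labels, one per cell (same order as the
#'   matrix rows, or named by cell id).
#' @param cluster the target cluster label.
#' @param against optional label of a single comparison cluster; default
#'   `NULL` compares against all other cells (one-vs-rest).
#' @return data.frame with one row per gene: `gene_id`, `cluster`,
#'   `effect`, `p_value`, `q_value` (Benjamini-Hochberg), `pct_in`,
#'   `pct_out`, ordered as the matrix columns.
#' @examples
#' sim <- simulate_single_cell(sim_config(seed = 1))
#' norm <- lognormalize(sim$counts)
#' res <- wilcoxon_one_vs_rest(norm, sim$truth$cell_labels, "OS-A2")
#' head(res[order(res$p_value), ])
#' @export
wilcoxon_one_vs_rest <- function(norm, labels, cluster, against = NULL) {
  if (!is.null(names(labels)) && !is.null(rownames(norm))) {
    labels <- labels[rownames(norm)]
  }
  if (length(labels) != nrow(norm)) {
    stop("labels must cover every cell in the matrix")
  }
  in_idx <- which(labels == cluster)
  out_idx <- if (is.null(against)) {
    which(labels != cluster)
  } else {
    which(labels == against)
  }
  if (length(in_idx) < 3L || length(out_idx) < 3L) {
    stop("cluster '", cluster, "' needs >= 3 cells in and out of the group ",
         "(found ", length(in_idx), " in, ", length(out_idx), " out)")
  }

  x_in <- as.matrix(norm[in_idx, , drop = FALSE])
  x_out <- as.matrix(norm[out_idx, , drop = FALSE])
  n1 <- nrow(x_in)
  n2 <- nrow(x_out)

  p <- vapply(seq_len(ncol(norm)), function(j) {
    rank_sum_p(x_in[, j], x_out[, j])
  }, numeric(1))

  mean_in <- colMeans(expm1(x_in))
  mean_out <- colMeans(expm1(x_out))
  effect <- log((mean_in + 1) / (mean_out + 1))

  data.frame(
    gene_id = colnames(norm),
    cluster = cluster,
    effect = effect,
    p_value = p,
    q_value = bh_adjust(p),
    pct_in = colMeans(x_in > 0),
    pct_out = colMeans(x_out > 0),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

# Two-sided rank-sum p for one gene. Exact Mann-Whitney null when both
# groups are small and the pooled values are tie-free; otherwise normal
# approximation with tie and continuity corrections.
rank_sum_p <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  ties <- table(r)
  has_ties <- any(ties > 1)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

  if (!has_ties && n1 < 50 && n2 < 50) {
    # mirror the smaller tail of the exact distribution
    if (u > n1 * n2 / 2) {
      p <- stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE)
    } else {
      p <- stats::pwilcox(u, n1, n2)
    }
    return(min(1, 2 * p))
  }

  mu <- n1 * n2 / 2
  n <- n1 + n2
  tie_term <- sum(ties^3 - ties)
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) {
    return(1)
  }
  z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  min(1, 2 * stats::pnorm(-z))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param method adjustment method: `"BH"` (default), `"bonferroni"` or
#'   `"none"`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p, method = c("BH", "bonferroni", "none")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = method)
}

#' Construct a marker panel
#'
#' A marker panel maps each subtype group (typically A, B, C) to an ordered
#' list of exclusive marker genes. Panels must be pairwise disjoint and
#' non-empty.
#'
#' @param panels named list of character vectors, one per group.
#' @param selection_params optional list recording how the panel was
#'   derived.
#' @return An object of class `marker_panel`.
#' @export
marker_panel <- function(panels, selection_params = list()) {
  if (is.null(names(panels)) || anyDuplicated(names(panels))) {
    stop("panels must be a uniquely named list")
  }
  if (any(lengths(panels) == 0L)) {
    stop("every panel must contain at least one gene")
  }
  all_genes <- unlist(panels, use.names = FALSE)
  if (anyDuplicated(all_genes)) {
    stop("panels must be pairwise disjoint; shared genes: ",
         paste(unique(all_genes[duplicated(all_genes)]), collapse = ", "))
  }
  structure(list(panels = lapply(panels, as.character),
                 selection_params = selection_params),
            class = "marker_panel")
}

as_marker_panel <- function(x) {
  if (inherits(x, "marker_panel")) return(x)
  if (is.list(x)) return(marker_panel(x))
  stop("cannot interpret object as a marker panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  sizes <- lengths(x$panels)
  cat(sprintf("Marker panel: %d genes (%s)\n", sum(sizes),
              paste(sprintf("%s: %d", names(sizes), sizes),
                    collapse = ", ")))
  for (g in names(x$panels)) {
    cat(sprintf("  %s: %s\n", g,
                paste(utils::head(x$panels[[g]], 8L), collapse = ", ")))
  }
  invisible(x)
}

#' Select exclusive branch-specific marker panels
#'
#' Screens per-cluster one-vs-rest marker statistics with the usual
#' thresholds (adjusted p, effect size, detection fractions), then enforces
#' cross-cluster exclusivity: any gene qualifying as a candidate for two or
#' more clusters is removed from all panels. Survivors are ranked by effect
#' size, descending. Panel sizes therefore differ between groups as the
#' data dictate.
#'
#' @param stats_by_group named list (one element per group, e.g.
#'   `list(A = ..., B = ..., C = ...)`) of marker statistics from
#'   [wilcoxon_one_vs_rest()], computed on a shared gene universe.
#' @param q_max maximum adjusted p-value (default 0.05).
#' @param min_effect minimum natural-log fold change (default `log(1.5)`).
#' @param min_pct_in minimum in-cluster detection fraction (default 0.25).
#' @param max_pct_out maximum out-of-cluster detection fraction
#'   (default 0.25).
#' @param max_per_group optional cap on panel size (top genes by effect).
#' @return A [marker_panel()] whose `selection_params` record the
#'   thresholds.
#' @export
select_specific_panel <- function(stats_by_group,
                                  q_max = 0.05,
                                  min_effect = log(1.5),
                                  min_pct_in = 0.25,
                                  max_pct_out = 0.25,
                                  max_per_group = NULL) {
  if (is.null(names(stats_by_group)) || length(stats_by_group) < 2L) {
    stop("stats_by_group must be a named list with >= 2 groups")
  }
  universe <- stats_by_group[[1]]$gene_id
  for (s in stats_by_group) {
    if (!setequal(s$gene_id, universe)) {
      stop("marker statistics must share one gene universe across groups")
    }
  }

  candidates <- lapply(stats_by_group, function(s) {
    keep <- s$q_value <= q_max & s$effect >= min_effect &
      s$pct_in >= min_pct_in & s$pct_out <= max_pct_out
    s[keep, , drop = FALSE]
  })
  if (all(vapply(candidates, nrow, integer(1)) == 0L)) {
    stop("no candidate markers passed the thresholds in any group; ",
         "consider relaxing q_max or min_effect")
  }

  cand_genes <- lapply(candidates, function(s) s$gene_id)
  tallied <- table(unlist(cand_genes, use.names = FALSE))
  shared <- names(tallied)[tallied >= 2L]

  panels <- lapply(candidates, function(s) {
    s <- s[!s$gene_id %in% shared, , drop = FALSE]
    s <- s[order(-s$effect, s$gene_id), , drop = FALSE]
    if (!is.null(max_per_group)) s <- utils::head(s, max_per_group)
    s$gene_id
  })
  empty <- names(panels)[lengths(panels) == 0L]
  if (length(empty) > 0L) {
    stop("panel(s) empty after the exclusivity rule: ",
         paste(empty, collapse = ", "),
         "; consider relaxing the selection thresholds")
  }
  marker_panel(panels, selection_params = list(
    q_max = q_max, min_effect = min_effect, min_pct_in = min_pct_in,
    max_pct_out = max_pct_out, max_per_group = max_per_group,
    excluded_shared = shared
  ))
}
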
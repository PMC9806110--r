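#' Configuration of the synthetic osteosarcoma data generator
#'
#' Collects every tunable of the synthetic single-cell, bulk-cohort and
#' IHC-panel generators, with validation. The default configuration encodes
#' the tumor structure the subtyping method assumes: a stem-like (CSC) root
#' cluster, three two-cluster differentiation branches whose terminal
#' clusters (OS-A2, OS-B2, OS-C2) carry exclusive marker genes, three
#' stromal/normal populations, bulk samples dominated by one branch with
#' stromal contamination, and exponential survival with the worst hazard in
#' the B-like subtype.
#'
#' @param n_genes total number of genes simulated.
#' @param n_marker_genes_per_cluster number of exclusive marker genes
#'   planted per cluster; marker sets are disjoint by construction.
#' @param cluster_spec named integer vector of cells per cluster. Names
#'   must be unique; defaults to 200 cells in each of CSC, OS-A1, OS-A2,
#'   OS-B1, OS-B2, OS-C1, OS-C2, BMSC, Osteoblast and Immune.
#' @param marker_log_fold_change natural-log fold change of planted marker
#'   means over baseline, within the marker's own cluster only.
#' @param nb_dispersion negative-binomial dispersion phi, so that
#'   variance = mean + phi * mean^2.
#' @param baseline_mean median baseline per-gene expected count before
#'   library-size scaling.
#' @param baseline_sdlog log-scale standard deviation of per-gene baseline
#'   means (log-normal around `baseline_mean`), giving the mean-variance
#'   continuum real transcriptomes show; 0 gives a flat baseline.
#' @param library_size_range length-2 numeric, uniform range of per-cell
#'   total counts.
#' @param bulk_n_per_group bulk samples simulated per subtype (A, B, C).
#' @param bulk_purity fraction in \[0,1\] of each bulk sample's signal coming
#'   from its dominant branch's terminal-cluster profile; the remainder is
#'   a stromal background profile.
#' @param bulk_noise_sd standard deviation of additive Gaussian noise on
#'   bulk expression (FPKM-like units; values are truncated at zero).
#' @param hazard_scale_by_group named numeric vector of exponential event
#'   rates per subtype. The default gives the B-like group twice the rate
#'   of A and C, encoding its worse prognosis.
#' @param censoring_rate target fraction of censored samples in \[0,1\].
#' @param ihc_effect additive score elevation of a sample's own-group
#'   markers in the simulated IHC table.
#' @param ihc_noise_sd standard deviation of Gaussian noise on IHC scores.
#' @param ihc_n_per_group IHC cohort samples per subtype.
#' @param seed root integer seed; per-stage streams are derived from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$cluster_spec
#' @export
sim_config <- function(n_genes = 2000L,
                       n_marker_genes_per_cluster = 20L,
                       cluster_spec = NULL,
                       marker_log_fold_change = 1.5,
                       nb_dispersion = 0.3,
                       baseline_mean = 0.2,
                       baseline_sdlog = 0.15,
                       library_size_range = c(300, 600),
                       bulk_n_per_group = 30L,
                       bulk_purity = 0.7,
                       bulk_noise_sd = 5,
                       hazard_scale_by_group = c(A = 0.1, B = 0.2, C = 0.1),
                       censoring_rate = 0.3,
                       ihc_effect = 2,
                       ihc_noise_sd = 0.5,
                       ihc_n_per_group = 46L,
                       seed = 1L) {
  if (is.null(cluster_spec)) {
    cluster_spec <- stats::setNames(
      rep(200L, 10L),
      c("CSC", "OS-A1", "OS-A2", "OS-B1", "OS-B2", "OS-C1", "OS-C2",
        "BMSC", "Osteoblast", "Immune")
    )
  }
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_marker_genes_per_cluster = as.integer(n_marker_genes_per_cluster),
    cluster_spec = cluster_spec,
    marker_log_fold_change = marker_log_fold_change,
    nb_dispersion = nb_dispersion,
    baseline_mean = baseline_mean,
    baseline_sdlog = baseline_sdlog,
    library_size_range = library_size_range,
    bulk_n_per_group = as.integer(bulk_n_per_group),
    bulk_purity = bulk_purity,
    bulk_noise_sd = bulk_noise_sd,
    hazard_scale_by_group = hazard_scale_by_group,
    censoring_rate = censoring_rate,
    ihc_effect = ihc_effect,
    ihc_noise_sd = ihc_noise_sd,
    ihc_n_per_group = as.integer(ihc_n_per_group),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_genes < 1L || cfg$n_marker_genes_per_cluster < 1L) {
    stop("configuration error: gene counts must be >= 1")
  }
  cs <- cfg$cluster_spec
  if (length(cs) == 0L) {
    stop("configuration error: empty cluster_spec")
  }
  if (is.null(names(cs)) || anyDuplicated(names(cs)) ||
      any(!nzchar(names(cs)))) {
    stop("configuration error: cluster names must be unique and non-empty")
  }
  if (any(cs < 1L)) {
    stop("configuration error: all cluster sizes must be >= 1")
  }
  if (cfg$n_marker_genes_per_cluster * length(cs) > cfg$n_genes) {
    stop("configuration error: not enough genes for disjoint marker sets")
  }
  if (cfg$marker_log_fold_change < 0) {
    stop("configuration error: marker_log_fold_change must be >= 0")
  }
  if (cfg$nb_dispersion <= 0) {
    stop("configuration error: non-positive nb_dispersion")
  }
  if (cfg$baseline_mean <= 0) {
    stop("configuration error: baseline_mean must be > 0")
  }
  if (cfg$baseline_sdlog < 0) {
    stop("configuration error: baseline_sdlog must be >= 0")
  }
  if (length(cfg$library_size_range) != 2L ||
      cfg$library_size_range[1] <= 0 ||
      cfg$library_size_range[1] > cfg$library_size_range[2]) {
    stop("configuration error: invalid library_size_range")
  }
  if (cfg$bulk_purity < 0 || cfg$bulk_purity > 1) {
    stop("configuration error: bulk_purity must be in [0, 1]")
  }
  if (cfg$censoring_rate < 0 || cfg$censoring_rate >= 1) {
    stop("configuration error: censoring_rate must be in [0, 1)")
  }
  if (cfg$bulk_noise_sd < 0 || cfg$ihc_noise_sd < 0) {
    stop("configuration error: noise standard deviations must be >= 0")
  }
  groups <- c("A", "B", "C")
  hz <- cfg$hazard_scale_by_group
  if (!all(groups %in% names(hz))) {
    stop("configuration error: hazard map missing a group: ",
         paste(setdiff(groups, names(hz)), collapse = ", "))
  }
  if (any(hz <= 0)) {
    stop("configuration error: hazard rates must be > 0")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic osteosarcoma simulation configuration\n")
  cat(sprintf("  genes: %d (%d exclusive markers per cluster, lfc = %.2f)\n",
              x$n_genes, x$n_marker_genes_per_cluster,
              x$marker_log_fold_change))
  cat(sprintf("  clusters: %s\n",
              paste(sprintf("%s(%d)", names(x$cluster_spec), x$cluster_spec),
                    collapse = " ")))
  cat(sprintf("  bulk: %d per group, purity %.2f, noise sd %.1f\n",
              x$bulk_n_per_group, x$bulk_purity, x$bulk_noise_sd))
  cat(sprintf("  hazards: %s; censoring %.2f\n",
              paste(sprintf("%s=%.2f", names(x$hazard_scale_by_group),
                            x$hazard_scale_by_group), collapse = " "),
              x$censoring_rate))
  invisible(x)
}

# Deterministic allocation of disjoint marker gene sets: the first
# n_marker * n_cluster gene ids, in cluster_spec order.
planted_marker_sets <- function(cfg) {
  gene_ids <- sim_gene_ids(cfg)
  nm <- cfg$n_marker_genes_per_cluster
  clusters <- names(cfg$cluster_spec)
  markers <- lapply(seq_along(clusters), function(i) {
    gene_ids[((i - 1L) * nm + 1L):(i * nm)]
  })
  names(markers) <- clusters
  markers
}

sim_gene_ids <- function(cfg) {
  sprintf("G%04d", seq_len(cfg$n_genes))
}

# Per-gene baseline expected counts (before library-size scaling), drawn
# log-normally around baseline_mean on a seed stream of their own so the
# gene-level landscape is shared across stages and reruns.
gene_baselines <- function(cfg) {
  set.seed(stage_seed(cfg$seed, "genes"))
  b <- cfg$baseline_mean *
    exp(stats::rnorm(cfg$n_genes, mean = 0, sd = cfg$baseline_sdlog))
  stats::setNames(b, sim_gene_ids(cfg))
}
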
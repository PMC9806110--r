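#' Simulate a clustered single-cell count matrix
#'
#' Draws negative-binomial counts for a population of cells organized into
#' the clusters of `cfg$cluster_spec`. Every cluster receives a disjoint set
#' of planted marker genes whose expected expression is elevated by
#' `exp(marker_log_fold_change)` over baseline in that cluster only; all
#' other genes share a flat baseline. Per-cell library sizes are drawn
#' uniformly from `library_size_range` and gene means are rescaled so each
#' cell's expected total equals its library size. Because every cluster
#' carries the same number of elevated markers at the same fold change, the
#' in-cluster versus out-of-cluster mean ratio of a marker equals
#' `exp(marker_log_fold_change)` exactly in expectation.
#'
#' @param cfg a [sim_config()] object.
#' @return A list with elements:
#'   \describe{
#'     \item{counts}{sparse `dgCMatrix`, cells x genes, integer counts,
#'       with cell barcodes as rownames and gene ids as colnames.}
#'     \item{truth}{list with `cell_labels` (named character vector,
#'       cell id -> cluster) and `planted_markers` (named list of disjoint
#'       gene-id vectors per cluster).}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' sim <- simulate_single_cell(sim_config(seed = 7))
#' dim(sim$counts)
#' @export
simulate_single_cell <- function(cfg) {
  validate_sim_config(cfg)
  gene_ids <- sim_gene_ids(cfg)
  markers <- planted_marker_sets(cfg)
  baselines <- gene_baselines(cfg)  # own seed stream; must precede reseeding
  set.seed(stage_seed(cfg$seed, "sc"))
  clusters <- names(cfg$cluster_spec)
  phi <- cfg$nb_dispersion
  lfc_mult <- exp(cfg$marker_log_fold_change)

  blocks <- vector("list", length(clusters))
  labels <- character(0)
  barcodes <- character(0)
  for (ci in seq_along(clusters)) {
    cl <- clusters[ci]
    n_cells <- cfg$cluster_spec[[cl]]
    profile <- baselines
    profile[markers[[cl]]] <- profile[markers[[cl]]] * lfc_mult
    rel <- profile / sum(profile)

    lib <- stats::runif(n_cells, cfg$library_size_range[1],
                        cfg$library_size_range[2])
    mu <- outer(lib, rel)  # cells x genes expected counts
    counts <- matrix(
      stats::rnbinom(length(mu), mu = as.vector(mu), size = 1 / phi),
      nrow = n_cells
    )
    bc <- sprintf("%s_%04d", gsub("[^A-Za-z0-9]", "", cl), seq_len(n_cells))
    rownames(counts) <- bc
    blocks[[ci]] <- counts
    labels <- c(labels, rep(cl, n_cells))
    barcodes <- c(barcodes, bc)
  }
  counts <- do.call(rbind, blocks)
  colnames(counts) <- gene_ids
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")

  list(
    counts = counts,
    truth = list(
      cell_labels = stats::setNames(labels, barcodes),
      planted_markers = markers
    ),
    config = cfg
  )
}

# FPKM-like mean profile of one cluster: flat baseline of 10 units with the
# cluster's planted markers elevated by the configured fold change.
bulk_profile <- function(cfg, cluster, markers, base = 10) {
  profile <- rep(base, cfg$n_genes)
  names(profile) <- sim_gene_ids(cfg)
  profile[markers[[cluster]]] <-
    profile[markers[[cluster]]] * exp(cfg$marker_log_fold_change)
  profile
}

#' Simulate a bulk expression cohort with survival follow-up
#'
#' Generates `bulk_n_per_group` samples per subtype (A, B, C). Each sample's
#' expression is a purity-weighted mixture of its branch's terminal-cluster
#' profile (OS-A2, OS-B2 or OS-C2) and a stromal background profile (the
#' average of the BMSC, Osteoblast and Immune profiles), plus additive
#' Gaussian noise truncated at zero — an FPKM-like continuous table.
#' Survival times are exponential with the sample's group-specific rate;
#' censoring is independent exponential with its rate chosen so the expected
#' censored fraction equals `censoring_rate`.
#'
#' @param cfg a [sim_config()] object.
#' @return A list with elements:
#'   \describe{
#'     \item{expr}{numeric matrix, samples x genes.}
#'     \item{survival}{data.frame with `sample_id`, `time`, `event`
#'       (1 = death observed, 0 = censored) and the true `group`.}
#'     \item{truth}{list with `bulk_group` (named vector sample -> group),
#'       `planted_markers`, and `true_survival_params`.}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' cohort <- simulate_bulk_cohort(sim_config(seed = 7))
#' table(cohort$truth$bulk_group)
#' @export
simulate_bulk_cohort <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(stage_seed(cfg$seed, "bulk"))

  markers <- planted_marker_sets(cfg)
  groups <- c("A", "B", "C")
  terminal <- c(A = "OS-A2", B = "OS-B2", C = "OS-C2")
  stromal <- intersect(c("BMSC", "Osteoblast", "Immune"),
                       names(cfg$cluster_spec))
  if (length(stromal) == 0L) {
    stop("configuration error: no stromal clusters in cluster_spec")
  }
  missing_term <- setdiff(terminal, names(cfg$cluster_spec))
  if (length(missing_term) > 0L) {
    stop("configuration error: cluster_spec lacks terminal clusters: ",
         paste(missing_term, collapse = ", "))
  }
  background <- Reduce(`+`, lapply(stromal, bulk_profile, cfg = cfg,
                                   markers = markers)) / length(stromal)

  n_per <- cfg$bulk_n_per_group
  n <- n_per * length(groups)
  expr <- matrix(0, nrow = n, ncol = cfg$n_genes,
                 dimnames = list(NULL, sim_gene_ids(cfg)))
  group <- rep(groups, each = n_per)
  sample_ids <- sprintf("S%03d", seq_len(n))
  rownames(expr) <- sample_ids

  for (g in groups) {
    sig <- bulk_profile(cfg, terminal[[g]], markers)
    idx <- which(group == g)
    mean_expr <- cfg$bulk_purity * sig + (1 - cfg$bulk_purity) * background
    noise <- matrix(stats::rnorm(length(idx) * cfg$n_genes,
                                 sd = cfg$bulk_noise_sd),
                    nrow = length(idx))
    expr[idx, ] <- pmax(0, rep(1, length(idx)) %o% mean_expr + noise)
  }

  surv <- simulate_survival(cfg, sample_ids, group)

  list(
    expr = expr,
    survival = surv,
    truth = list(
      bulk_group = stats::setNames(group, sample_ids),
      planted_markers = markers,
      true_survival_params = list(
        hazard_scale_by_group = cfg$hazard_scale_by_group,
        censoring_rate = cfg$censoring_rate
      )
    ),
    config = cfg
  )
}

# Exponential survival with group-specific event rates and independent
# exponential censoring. With event rate l and censoring rate m the
# probability of censoring is m / (l + m), so m = l * c / (1 - c) hits the
# target censored fraction c within each group. Assumes the current RNG
# stream; callers seed it.
simulate_survival <- function(cfg, sample_ids, group) {
  rates <- cfg$hazard_scale_by_group[group]
  t_event <- stats::rexp(length(group), rate = rates)
  cr <- cfg$censoring_rate
  if (cr > 0) {
    cens_rate <- rates * cr / (1 - cr)
    t_cens <- stats::rexp(length(group), rate = cens_rate)
  } else {
    t_cens <- rep(Inf, length(group))
  }
  data.frame(
    sample_id = sample_ids,
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    group = group,
    stringsAsFactors = FALSE
  )
}

#' Simulate an IHC-style marker score table
#'
#' Emulates a clinical cohort scored for a small immunohistochemistry panel:
#' per sample, the markers belonging to its true subtype receive
#' `base + ihc_effect + noise` while all other markers receive
#' `base + noise`; scores are truncated at zero. The cohort has
#' `ihc_n_per_group` samples per subtype.
#'
#' @param cfg a [sim_config()] object.
#' @param panel a marker panel as produced by [select_specific_panel()] or
#'   [marker_panel()]: each group must contribute at least one marker.
#' @param base baseline score level.
#' @return A list with `scores` (samples x markers matrix) and `truth`
#'   (named vector sample -> group).
#' @examples
#' pnl <- marker_panel(list(A = c("ALKBH5", "TOM1L2"),
#'                          B = c("CDK4", "LMO7"),
#'                          C = c("COL6A3", "THBS2")))
#' ihc <- simulate_ihc_panel(sim_config(seed = 7), pnl)
#' head(ihc$scores)
#' @export
simulate_ihc_panel <- function(cfg, panel, base = 1) {
  validate_sim_config(cfg)
  panel <- as_marker_panel(panel)
  if (any(lengths(panel$panels) < 1L)) {
    stop("configuration error: every group needs >= 1 marker in the panel")
  }
  set.seed(stage_seed(cfg$seed, "ihc"))

  groups <- names(panel$panels)
  n_per <- cfg$ihc_n_per_group
  group <- rep(groups, each = n_per)
  n <- length(group)
  sample_ids <- sprintf("IHC%03d", seq_len(n))
  all_markers <- unlist(panel$panels, use.names = FALSE)

  scores <- matrix(base, nrow = n, ncol = length(all_markers),
                   dimnames = list(sample_ids, all_markers))
  for (g in groups) {
    scores[group == g, panel$panels[[g]]] <-
      scores[group == g, panel$panels[[g]]] + cfg$ihc_effect
  }
  scores <- scores + matrix(stats::rnorm(length(scores),
                                         sd = cfg$ihc_noise_sd),
                            nrow = n)
  scores[scores < 0] <- 0

  list(scores = scores, truth = stats::setNames(group, sample_ids))
}
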
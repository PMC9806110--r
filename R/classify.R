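#' Per-group panel scores for each sample
#'
#' Scores every sample against each group's marker panel. In `panel_mean`
#' mode the score is the mean normalized expression over the group's panel
#' genes; in `single_marker` mode it is the maximum normalized value among
#' them (the strongest-marker rule used for IHC tables). Normalization is
#' applied per gene across the cohort: `zscore_cohort` (default), `rank`
#' (average ranks rescaled to \[0, 1\]) or `none`.
#'
#' @param expr samples x genes (or samples x markers) numeric matrix with
#'   sample rownames.
#' @param panel a [marker_panel()].
#' @param mode `"panel_mean"` or `"single_marker"`.
#' @param normalization `"zscore_cohort"`, `"rank"` or `"none"`.
#' @return Numeric matrix samples x groups of scores, with attribute
#'   `"missing_genes"` listing panel genes absent from `expr`.
#' @export
score_panels <- function(expr, panel,
                         mode = c("panel_mean", "single_marker"),
                         normalization = c("zscore_cohort", "rank",
                                           "none")) {
  mode <- match.arg(mode)
  normalization <- match.arg(normalization)
  panel <- as_marker_panel(panel)
  x <- as.matrix(expr)
  if (any(!is.finite(x))) stop("expression values must be finite")

  missing <- setdiff(unlist(panel$panels, use.names = FALSE), colnames(x))
  measured <- lapply(panel$panels, intersect, y = colnames(x))
  empty <- names(measured)[lengths(measured) == 0L]
  if (length(empty) > 0L) {
    stop("no measured markers for group(s): ",
         paste(empty, collapse = ", "))
  }
  if (length(missing) > 0L) {
    message("score_panels: ", length(missing),
            " panel gene(s) not measured: ",
            paste(utils::head(missing, 5L), collapse = ", "))
  }

  xn <- switch(normalization,
    zscore_cohort = zscore_columns(x),
    rank = apply(x, 2L, function(col) rank(col) / length(col)),
    none = x
  )

  scores <- vapply(measured, function(genes) {
    sub <- xn[, genes, drop = FALSE]
    if (mode == "panel_mean") rowMeans(sub) else apply(sub, 1L, max)
  }, numeric(nrow(x)))
  if (is.null(dim(scores))) {
    scores <- matrix(scores, nrow = 1L,
                     dimnames = list(rownames(x), names(measured)))
  }
  rownames(scores) <- rownames(x)
  attr(scores, "missing_genes") <- missing
  scores
}

#' Assign each sample to its argmax group
#'
#' Takes a samples x groups score matrix and assigns every sample to the
#' group with the highest score. Ties are broken deterministically in
#' alphabetical group order and flagged: `tie_flag` is set whenever the
#' margin (top score minus runner-up) does not exceed `tie_tol`
#' (default 0, i.e. exact ties only).
#'
#' @param scores samples x groups numeric matrix, e.g. from
#'   [score_panels()].
#' @param tie_tol non-negative margin below which an assignment is flagged
#'   as a tie.
#' @return data.frame with `sample_id`, `group`, one `score_<group>`
#'   column per group, `margin` and `tie_flag`.
#' @examples
#' s <- rbind(S1 = c(A = 1, B = 3, C = 2), S2 = c(A = 2, B = 2, C = 1))
#' assign_group(s)
#' @export
assign_group <- function(scores, tie_tol = 0) {
  scores <- as.matrix(scores)
  if (any(!is.finite(scores))) {
    stop("non-finite score(s); cannot assign groups")
  }
  if (is.null(colnames(scores))) stop("scores must have group colnames")
  if (ncol(scores) < 2L) stop("need scores for at least two groups")
  groups <- sort(colnames(scores))
  scores <- scores[, groups, drop = FALSE]
  sample_ids <- rownames(scores) %||% sprintf("S%03d", seq_len(nrow(scores)))

  pick <- apply(scores, 1L, which.max)  # first max = alphabetical tie-break
  sorted <- apply(scores, 1L, sort, decreasing = TRUE)
  margin <- sorted[1L, ] - sorted[2L, ]

  out <- data.frame(
    sample_id = sample_ids,
    group = groups[pick],
    stringsAsFactors = FALSE
  )
  for (g in groups) out[[paste0("score_", g)]] <- scores[, g]
  out$margin <- margin
  out$tie_flag <- margin <= tie_tol
  rownames(out) <- NULL
  out
}

#' Classify samples from an IHC marker score table
#'
#' Applies the strongest-marker rule to a quantified
#' immunohistochemistry table: each marker column is normalized across the
#' cohort, and every sample is assigned to the group of its strongest
#' normalized marker. The default marker-to-group mapping is the
#' six-marker osteosarcoma panel
#' (A: ALKBH5, TOM1L2; B: CDK4, LMO7; C: COL6A3, THBS2).
#'
#' @param table samples x markers numeric matrix or data.frame with sample
#'   rownames.
#' @param marker_to_group named character vector mapping marker column name
#'   to group label.
#' @param normalization per-marker normalization (default
#'   `"zscore_cohort"`).
#' @param tie_tol passed to [assign_group()].
#' @return The assignment data.frame from [assign_group()].
#' @export
classify_ihc_table <- function(table,
                               marker_to_group = c(
                                 ALKBH5 = "A", TOM1L2 = "A",
                                 CDK4 = "B", LMO7 = "B",
                                 COL6A3 = "C", THBS2 = "C"
                               ),
                               normalization = "zscore_cohort",
                               tie_tol = 0) {
  x <- as.matrix(table)
  missing <- setdiff(names(marker_to_group), colnames(x))
  if (length(missing) > 0L) {
    stop("missing marker column(s): ", paste(missing, collapse = ", "))
  }
  panels <- split(names(marker_to_group), unname(marker_to_group))
  panel <- marker_panel(panels,
                        selection_params = list(source = "ihc_mapping"))
  scores <- score_panels(x[, names(marker_to_group), drop = FALSE], panel,
                         mode = "single_marker",
                         normalization = normalization)
  assign_group(scores, tie_tol = tie_tol)
}
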
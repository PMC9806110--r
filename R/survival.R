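#' Kaplan-Meier product-limit estimate
#'
#' Computes the product-limit survival curve
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over the distinct event times,
#' with the standard convention for ties: subjects censored at an event
#' time are still at risk at that time (events precede censorings).
#'
#' @param table data.frame with columns `time` (non-negative follow-up)
#'   and `event` (1 = event observed, 0 = censored); an optional
#'   `sample_id` column is carried for validation only.
#' @return An object of class `km_curve`: data.frame with one row per
#'   distinct event time — `time`, `n_risk`, `n_event`, `n_censor`
#'   (censorings in `[time, next event time)`), and `survival`.
#' @examples
#' tbl <- data.frame(time = c(1, 2, 2, 3), event = c(1, 1, 0, 1))
#' km_estimate(tbl)
#' @export
km_estimate <- function(table) {
  check_survival_table(table)
  if (nrow(table) == 0L) stop("survival table is empty")
  time <- table$time
  event <- table$event

  event_times <- sort(unique(time[event == 1]))
  if (length(event_times) == 0L) {
    out <- data.frame(time = numeric(0), n_risk = integer(0),
                      n_event = integer(0), n_censor = integer(0),
                      survival = numeric(0))
    class(out) <- c("km_curve", "data.frame")
    return(out)
  }
  n_risk <- vapply(event_times, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(event_times, function(t) sum(time == t & event == 1),
                    numeric(1))
  bounds <- c(event_times[-1], Inf)
  n_censor <- vapply(seq_along(event_times), function(i) {
    sum(event == 0 & time >= event_times[i] & time < bounds[i])
  }, numeric(1))
  surv <- cumprod(1 - n_event / n_risk)

  out <- data.frame(time = event_times, n_risk = n_risk,
                    n_event = n_event, n_censor = n_censor,
                    survival = surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param curve a `km_curve` from [km_estimate()].
#' @param times numeric vector of evaluation times.
#' @return `S(times)`: 1 before the first event time, step values after.
#' @export
km_survival_at <- function(curve, times) {
  vapply(times, function(t) {
    i <- sum(curve$time <= t)
    if (i == 0L) 1 else curve$survival[i]
  }, numeric(1))
}

check_survival_table <- function(table, need_group = FALSE) {
  if (!all(c("time", "event") %in% names(table))) {
    stop("survival table needs 'time' and 'event' columns")
  }
  if (any(table$time < 0)) stop("negative follow-up time")
  if (!all(table$event %in% c(0, 1))) {
    stop("event must be 0 (censored) or 1 (event)")
  }
  if (!is.null(table$sample_id) && anyDuplicated(table$sample_id)) {
    stop("duplicate sample ids in survival table")
  }
  if (need_group && is.null(table$group)) {
    stop("survival table needs a 'group' column")
  }
  invisible(table)
}

#' Multi-group log-rank test
#'
#' Standard g-sample log-rank test: at every distinct event time, observed
#' events per group are compared with their expectation under the
#' hypergeometric model given the risk sets; the chi-square statistic is
#' formed from the summed observed-minus-expected vector and its
#' variance-covariance matrix (one group dropped, generalized inverse used
#' if the reduced covariance is singular), with `g - 1` degrees of
#' freedom.
#'
#' @param table data.frame with columns `time`, `event` and `group`
#'   (>= 2 non-empty groups).
#' @return List of class `logrank_test`: `chi_square`, `df`, `p_value`,
#'   plus per-group `observed` and `expected` event counts.
#' @examples
#' tbl <- data.frame(time = c(1, 2, 3, 4, 5, 6),
#'                   event = c(1, 1, 1, 1, 0, 1),
#'                   group = rep(c("A", "B"), each = 3))
#' logrank_test(tbl)
#' @export
logrank_test <- function(table) {
  check_survival_table(table, need_group = TRUE)
  group <- if (is.factor(table$group)) table$group else factor(table$group)
  g <- nlevels(group)
  if (g < 2L) stop("need at least 2 groups")
  sizes <- table(group)
  if (any(sizes == 0L)) {
    stop("group with zero subjects: ",
         paste(names(sizes)[sizes == 0L], collapse = ", "))
  }
  time <- table$time
  event <- table$event

  event_times <- sort(unique(time[event == 1]))
  observed <- expected <- stats::setNames(numeric(g), levels(group))
  v <- matrix(0, g, g, dimnames = list(levels(group), levels(group)))

  for (t in event_times) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    n_jt <- tapply(at_risk, group, sum)
    n_jt[is.na(n_jt)] <- 0
    d_t <- sum(time == t & event == 1)
    d_jt <- tapply(time == t & event == 1, group, sum)
    d_jt[is.na(d_jt)] <- 0

    observed <- observed + d_jt
    expected <- expected + d_t * n_jt / n_t
    if (n_t > 1) {
      # hypergeometric variance-covariance of the event-count vector
      frac <- n_jt / n_t
      vc <- d_t * (n_t - d_t) / (n_t - 1) *
        (diag(frac, nrow = g) - tcrossprod(frac))
      v <- v + vc
    }
  }

  observed <- stats::setNames(as.numeric(observed), levels(group))
  expected <- stats::setNames(as.numeric(expected), levels(group))
  o_minus_e <- (observed - expected)[-g]
  v_red <- v[-g, -g, drop = FALSE]
  if (all(abs(v_red) < .Machine$double.eps)) {
    chi <- 0
  } else {
    v_inv <- tryCatch(solve(v_red), error = function(e) MASS::ginv(v_red))
    chi <- drop(t(o_minus_e) %*% v_inv %*% o_minus_e)
    chi <- max(chi, 0)
  }
  structure(list(
    chi_square = chi,
    df = g - 1L,
    p_value = stats::pchisq(chi, df = g - 1L, lower.tail = FALSE),
    observed = observed,
    expected = expected
  ), class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.3f on %d df, p = %.4g\n",
              x$chi_square, x$df, x$p_value))
  tab <- rbind(observed = x$observed, expected = round(x$expected, 2))
  print(tab)
  invisible(x)
}

#' Dichotomize a cohort on a panel score and compare survival
#'
#' Computes the panel-mean score of one subtype's markers for every sample
#' (z-scored across the cohort), splits the cohort into high and low
#' expression at the chosen cut (median, or upper tertile versus the
#' rest), and runs a two-group log-rank test. This reproduces the common
#' "high versus low signature expression" survival comparison.
#'
#' @param expr samples x genes expression matrix with sample rownames.
#' @param panel a [marker_panel()].
#' @param group which panel group's markers to score.
#' @param survival data.frame with `sample_id`, `time`, `event` covering
#'   every expression sample to be used.
#' @param cut `"median"` (default) or `"tertile"` (upper tertile = high).
#' @param normalization passed to [score_panels()].
#' @return List with `labels` ("high"/"low" named by sample), `scores`,
#'   `cutpoint` and `logrank` (a [logrank_test()] result).
#' @export
dichotomize_and_compare <- function(expr, panel, group, survival,
                                    cut = c("median", "tertile"),
                                    normalization = "zscore_cohort") {
  cut <- match.arg(cut)
  panel <- as_marker_panel(panel)
  if (!group %in% names(panel$panels)) {
    stop("panel has no group '", group, "'")
  }
  check_survival_table(survival)
  common <- intersect(rownames(expr), survival$sample_id)
  if (length(common) == 0L) {
    stop("no overlap between expression samples and survival table")
  }
  expr <- expr[common, , drop = FALSE]
  survival <- survival[match(common, survival$sample_id), , drop = FALSE]

  sub_panel <- marker_panel(panel$panels[group])
  scores <- score_panels(expr, sub_panel, mode = "panel_mean",
                         normalization = normalization)[, group]

  cutpoint <- switch(cut,
    median = stats::median(scores),
    tertile = stats::quantile(scores, 2 / 3, names = FALSE)
  )
  high <- scores > cutpoint
  if (all(high) || !any(high)) {
    stop("the ", cut, " cut produced an empty group (all scores ",
         if (all(high)) "above" else "at or below", " the cutpoint)")
  }
  labels <- stats::setNames(ifelse(high, "high", "low"), common)

  tbl <- data.frame(sample_id = common, time = survival$time,
                    event = survival$event, group = unname(labels),
                    stringsAsFactors = FALSE)
  list(labels = labels, scores = scores, cutpoint = cutpoint,
       logrank = logrank_test(tbl))
}
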
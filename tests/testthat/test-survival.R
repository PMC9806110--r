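test_that("KM estimator handles the no-event and single-event cases", {
  no_events <- data.frame(time = c(1, 2, 3), event = c(0, 0, 0))
  km <- km_estimate(no_events)
  expect_equal(nrow(km), 0L)
  expect_equal(km_survival_at(km, c(0, 1, 10)), c(1, 1, 1))

  one <- data.frame(time = c(2, 3, 4, 5), event = c(1, 0, 0, 0))
  km1 <- km_estimate(one)
  expect_equal(km1$survival, 0.75)  # (n-1)/n with n = 4 at risk
  expect_equal(km1$n_risk, 4)
  expect_equal(km_survival_at(km1, c(1.9, 2, 100)), c(1, 0.75, 0.75))
  expect_error(km_estimate(data.frame(time = -1, event = 1)), "negative")
})

test_that("KM matches a hand-computed product over a censored toy table", {
  # 8 subjects; censored subjects at an event time stay at risk there
  tbl <- data.frame(
    sample_id = sprintf("P%d", 1:8),
    time = c(1, 2, 2, 3, 4, 4, 5, 6),
    event = c(1, 1, 0, 1, 0, 1, 0, 1)
  )
  km <- km_estimate(tbl)
  # hand tally: t=1: 8 at risk, 1 event -> 7/8
  #             t=2: 7 at risk, 1 event -> 7/8 * 6/7          = 0.75
  #             t=3: 5 at risk, 1 event -> 0.75 * 4/5         = 0.6
  #             t=4: 4 at risk, 1 event -> 0.6  * 3/4         = 0.45
  #             t=6: 1 at risk, 1 event -> 0.45 * 0           = 0
  expect_equal(km$time, c(1, 2, 3, 4, 6))
  expect_equal(km$n_risk, c(8, 7, 5, 4, 1))
  expect_equal(km$survival, c(7 / 8, 0.75, 0.6, 0.45, 0))
  # censorings per inter-event interval: t=2 (P3), then P5 and P7 in [4,6)
  expect_equal(km$n_censor, c(0, 1, 0, 2, 0))
  # independent cross-check against the survival package
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = tbl)
  expect_equal(km$survival, sf$surv[sf$n.event > 0])
})

test_that("KM equals the empirical survival function without censoring", {
  set.seed(12)
  for (r in 1:5) {
    times <- round(rexp(30, 0.2), 2)
    tbl <- data.frame(time = times, event = 1)
    km <- km_estimate(tbl)
    grid <- sort(unique(times))
    expect_equal(km_survival_at(km, grid),
                 vapply(grid, function(t) mean(times > t), numeric(1)))
  }
})

test_that("log-rank is null on exchangeable groups and exact on a toy", {
  base <- data.frame(time = c(1, 2, 3, 4, 5), event = c(1, 0, 1, 1, 0))
  same <- rbind(transform(base, group = "A", sample_id = paste0("a", 1:5)),
                transform(base, group = "B", sample_id = paste0("b", 1:5)))
  res <- logrank_test(same)
  expect_equal(res$chi_square, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)

  # hand-tallied two-group toy: O, E accumulated over event times
  tbl <- data.frame(
    time = c(1, 2, 3, 4, 5, 6),
    event = c(1, 1, 1, 1, 0, 1),
    group = c("A", "A", "A", "B", "B", "B")
  )
  res2 <- logrank_test(tbl)
  # t=1: risk 6 (3A/3B), 1 event in A -> E_A += 1/2
  # t=2: risk 5 (2A/3B), 1 event in A -> E_A += 2/5
  # t=3: risk 4 (1A/3B), 1 event in A -> E_A += 1/4
  # t=4: risk 3 (0A/3B), 1 event in B -> E_A += 0
  # t=6: risk 1 (0A/1B), 1 event in B -> E_A += 0
  expect_equal(unname(res2$observed), c(3, 2))
  expect_equal(unname(res2$expected[["A"]]), 0.5 + 0.4 + 0.25)
  # variance tally: d(N-d)/(N-1) * nA*nB/N^2 at each event time
  v <- 1 * 5 / 5 * (3 * 3) / 36 + 1 * 4 / 4 * (2 * 3) / 25 +
    1 * 3 / 3 * (1 * 3) / 16 + 0 + 0
  expect_equal(res2$chi_square, (3 - 1.15)^2 / v)
  # cross-check chi-square against the survival package
  sd2 <- survival::survdiff(survival::Surv(time, event) ~ group,
                            data = tbl)
  expect_equal(res2$chi_square, sd2$chisq)
  expect_equal(res2$df, 1L)
})

test_that("three-group log-rank agrees with the survival package", {
  set.seed(33)
  tbl <- data.frame(
    time = round(rexp(60, rep(c(0.1, 0.3, 0.1), each = 20)), 3),
    event = rbinom(60, 1, 0.8),
    group = rep(c("A", "B", "C"), each = 20)
  )
  res <- logrank_test(tbl)
  sd3 <- survival::survdiff(survival::Surv(time, event) ~ group,
                            data = tbl)
  expect_equal(res$chi_square, sd3$chisq, tolerance = 1e-10)
  expect_equal(res$df, 2L)
  expect_error(logrank_test(transform(tbl, group = "A")), "2 groups")
  empty_level <- transform(tbl, group = factor(group,
                                               levels = c("A", "B", "C",
                                                          "D")))
  expect_error(logrank_test(empty_level), "zero subjects: D")
})

test_that("log-rank is invariant to time-unit rescaling", {
  set.seed(44)
  tbl <- data.frame(time = rexp(40, 0.2), event = rbinom(40, 1, 0.7),
                    group = rep(c("A", "B"), 20))
  r1 <- logrank_test(tbl)
  r2 <- logrank_test(transform(tbl, time = time * 365.25))
  expect_equal(r1$chi_square, r2$chi_square)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("panel-score dichotomization splits and compares survival", {
  cohort <- simulate_bulk_cohort(sim_config(
    seed = 37, hazard_scale_by_group = c(A = 0.1, B = 0.3, C = 0.1)
  ))
  panel <- marker_panel(lapply(
    c(A = "OS-A2", B = "OS-B2", C = "OS-C2"),
    function(cl) cohort$truth$planted_markers[[cl]]
  ))
  res <- dichotomize_and_compare(cohort$expr, panel, "B",
                                 cohort$survival)
  # median cut on distinct scores: balanced split
  expect_equal(sum(res$labels == "high"), sum(res$labels == "low"))
  # every true-B sample scores above the median of the B-panel score
  true_b <- names(cohort$truth$bulk_group)[cohort$truth$bulk_group == "B"]
  expect_true(all(res$labels[true_b] == "high"))
  # high-score samples must die faster (direction of the effect)
  km_h <- km_estimate(data.frame(
    time = cohort$survival$time[res$labels == "high"],
    event = cohort$survival$event[res$labels == "high"]
  ))
  km_l <- km_estimate(data.frame(
    time = cohort$survival$time[res$labels == "low"],
    event = cohort$survival$event[res$labels == "low"]
  ))
  mid <- median(cohort$survival$time)
  expect_lt(km_survival_at(km_h, mid), km_survival_at(km_l, mid))

  # identical scores cannot be cut
  flat <- matrix(1, nrow(cohort$expr), 3,
                 dimnames = list(rownames(cohort$expr),
                                 panel$panels$B[1:3]))
  expect_error(
    dichotomize_and_compare(flat, marker_panel(list(B = panel$panels$B[1:3])),
                            "B", cohort$survival, normalization = "none"),
    "empty group"
  )
})

test_that("B-panel dichotomization detects a tripled hazard reliably", {
  cfg <- small_sim_config(
    seed = 61, hazard_scale_by_group = c(A = 0.1, B = 0.3, C = 0.1)
  )
  rejections <- vapply(1:200, function(r) {
    cohort <- simulate_bulk_cohort(sim_config_reseed(cfg, 5000 + r))
    panel <- marker_panel(lapply(
      c(A = "OS-A2", B = "OS-B2", C = "OS-C2"),
      function(cl) cohort$truth$planted_markers[[cl]]
    ))
    # upper-tertile cut: the high group is the B-like third of the cohort
    res <- dichotomize_and_compare(cohort$expr, panel, "B",
                                   cohort$survival, cut = "tertile")
    res$logrank$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.9)
})

test_that("median cut on 2n distinct scores gives groups of size n", {
  set.seed(50)
  n <- 12
  expr <- matrix(runif(2 * n * 4, 1, 9), 2 * n,
                 dimnames = list(sprintf("S%02d", 1:(2 * n)),
                                 c("m1", "m2", "m3", "m4")))
  surv <- data.frame(sample_id = rownames(expr),
                     time = rexp(2 * n, 0.2), event = 1)
  res <- dichotomize_and_compare(expr, marker_panel(list(B = c("m1", "m2"))),
                                 "B", surv)
  expect_equal(unname(table(res$labels)["high"]), n)
  expect_equal(unname(table(res$labels)["low"]), n)
})
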
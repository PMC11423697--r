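# Survival primitives against closed-form and brute-force oracles.

test_that("Cox coefficient equals the 1-D partial-likelihood optimum", {
  d <- sim_simple_cox(8, b = 0.5, seed = 2)
  fit <- fit_cox(d$time, d$event, d$x)
  grid_opt <- optimize(function(b) -cox_loglik_1d(b, d$time, d$event, d$x),
                       c(-5, 5), tol = 1e-10)$minimum
  expect_equal(unname(fit$coefficients), grid_opt, tolerance = 1e-6)

  # two subjects, both events, higher-covariate subject failing first: the
  # partial likelihood b - log(exp(b) + 1) is monotone, so the likelihood
  # is unbounded and the fit must be flagged, not crash
  fit2 <- fit_cox(c(1, 2), c(1, 1), c(1, 0))
  expect_true(fit2$infinite)
  expect_gt(unname(fit2$coefficients), 5)
})

test_that("degenerate Cox inputs error informatively", {
  expect_error(fit_cox(c(1, 2), c(1, 1), c(3, 3)), "variation")
  expect_error(fit_cox(c(1, 2), c(0, 0), c(1, 0)), "no events")
  expect_error(fit_cox(c(1, -1), c(1, 1), c(1, 0)), "positive")
})

test_that("sandwich variance with singleton clusters equals unclustered robust variance", {
  d <- sim_simple_cox(60, b = 0.3, seed = 5)
  ours <- fit_cox(d$time, d$event, d$x, cluster = seq_len(60))
  ref <- survival::coxph(survival::Surv(time, event) ~ x, data = d,
                         robust = TRUE, ties = "efron")
  expect_equal(unname(ours$robust_se), sqrt(ref$var[1, 1]), tolerance = 1e-10)
})

test_that("Fine-Gray reduces to Cox with no competing events", {
  d <- sim_simple_cox(80, b = 0.4, seed = 6)
  cl <- rep(1:40, each = 2)
  fg <- fit_fine_gray(d$time, d$event, d$x, cluster = cl)
  cx <- fit_cox(d$time, d$event, d$x, cluster = cl)
  expect_equal(unname(fg$coefficients), unname(cx$coefficients),
               tolerance = 1e-8)
  expect_error(fit_fine_gray(c(1, 2), c(2, 2), c(1, 0)), "cause-1")
})

test_that("Fine-Gray agrees with an independent competing-risk implementation", {
  skip_if_not_installed("cmprsk")
  cfg <- plain_config(n_pairs = 400, n_cpgs = 2, n_causal = 1,
                      causal_log_shr = log(2), seed = 13,
                      base_rate_cause1 = 0.004)
  sim <- simulate_cohort(cfg)
  x <- scale_cols(sim$methylation)[, sim$truth$cpg_id]
  oc <- sim$outcomes
  ours <- fit_fine_gray(oc$time, oc$event, x)
  ref <- cmprsk::crr(oc$time, oc$event, matrix(x), failcode = 1, cencode = 0)
  expect_equal(unname(ours$coefficients), unname(ref$coef), tolerance = 0.02)
})

test_that("subdistribution parameter is recovered from the generator", {
  cfg <- plain_config(n_pairs = 2500, n_cpgs = 2, seed = 1,
                      base_rate_cause1 = 0.004)
  set.seed(21)
  x <- rbinom(5000, 1, 0.5)
  oc <- simulate_event_times(log(2) * x, cfg, seed = 22)
  fit <- fit_fine_gray(oc$time, oc$event, x)
  ci <- unname(fit$coefficients) + c(-1.96, 1.96) * unname(fit$robust_se)
  expect_true(ci[1] < log(2) && log(2) < ci[2])
})

test_that("stratified Cox uses only within-pair information", {
  # all pairs covariate-concordant: no information
  t <- c(1, 2, 3, 4)
  e <- c(1, 0, 1, 0)
  x <- c(1, 1, 0, 0)
  expect_error(fit_stratified_cox(t, e, x, strata = c(1, 1, 2, 2)),
               "informative")

  # planted within-pair effect recovered
  set.seed(31)
  n_pairs <- 150
  u <- rnorm(n_pairs)                      # pair-level baseline shift
  x1 <- rnorm(n_pairs); x2 <- rnorm(n_pairs)
  lam1 <- 0.2 * exp(u + 0.7 * x1)
  lam2 <- 0.2 * exp(u + 0.7 * x2)
  d <- data.frame(
    time = c(rexp(n_pairs, lam1), rexp(n_pairs, lam2)),
    event = 1L, x = c(x1, x2), pair = rep(seq_len(n_pairs), 2))
  f <- fit_stratified_cox(d$time, d$event, d$x, strata = d$pair)
  ci <- unname(f$coefficients) + c(-1.96, 1.96) * unname(f$naive_se)
  expect_true(ci[1] < 0.7 && 0.7 < ci[2])
})

test_that("PH test calibrates and rejects a reversing effect", {
  d <- sim_simple_cox(300, b = 0.5, seed = 8)
  fit <- fit_cox(d$time, d$event, d$x)
  pt <- ph_test(fit)
  expect_gte(pt$table[1, "p"], 0)

  # effect that reverses mid-follow-up violates proportionality
  set.seed(9)
  n <- 1000
  x <- rnorm(n)
  t1 <- rexp(n, 0.5 * exp(1.5 * x))
  tm <- median(t1)
  t_full <- ifelse(t1 <= tm, t1, tm + rexp(n, 0.5 * exp(-1.5 * x)))
  fit2 <- fit_cox(t_full, rep(1L, n), x)
  pt2 <- ph_test(fit2)
  expect_lt(pt2$table[1, "p"], 0.01)

  one <- fit_cox(c(1, 2), c(1, 0), c(1, 0))
  expect_error(ph_test(one), "2 events")
})

test_that("cumulative incidence equals the empirical subdistribution without censoring", {
  ci <- cumulative_incidence(c(1, 2, 1.5, 3), c(1, 1, 2, 0))
  expect_equal(eval_cif(ci, 10), 0.5)            # 2 of 4 fail from cause 1
  expect_equal(eval_cif(ci, 1.2), 0.25)
  expect_equal(eval_cif(ci, 10, "cause2"), 0.25)

  none <- cumulative_incidence(c(1, 2, 3), c(0, 0, 0))
  expect_equal(eval_cif(none, 5), 0)

  set.seed(10)
  cfg <- plain_config(n_pairs = 100, n_cpgs = 2, base_rate_cause1 = 0.01)
  oc <- simulate_event_times(rnorm(200), cfg, seed = 11)
  cc <- cumulative_incidence(oc$time, oc$event)
  tot <- cc$cif[, "cause1"] + if ("cause2" %in% colnames(cc$cif))
    cc$cif[, "cause2"] else 0
  expect_true(all(diff(cc$cif[, "cause1"]) >= -1e-12))
  expect_true(all(tot <= 1 + 1e-12))
})

test_that("Harrell's C matches exhaustive pair enumeration", {
  expect_equal(harrells_c(c(1, 2, 3), c(1, 1, 1), c(3, 2, 1))$c_index, 1)
  expect_equal(harrells_c(c(1, 2, 3), c(1, 1, 1), c(1, 2, 3))$c_index, 0)

  set.seed(12)
  time <- rexp(20)
  event <- rbinom(20, 1, 0.6)
  score <- sample(1:5, 20, replace = TRUE)   # ties in score on purpose
  got <- harrells_c(time, event, score)
  want <- brute_force_c(time, event, score)
  expect_equal(got$c_index, want$c_index)
  expect_equal(got$n_concordant, want$conc)
  expect_equal(got$n_discordant, want$disc)
  expect_equal(got$n_tied, want$tied)
})

test_that("Harrell's C is invariant to monotone score transforms", {
  set.seed(13)
  time <- rexp(50)
  event <- rbinom(50, 1, 0.5)
  score <- rnorm(50)
  c1 <- harrells_c(time, event, score)$c_index
  expect_equal(harrells_c(time, event, exp(3 * score))$c_index, c1)
  expect_equal(harrells_c(time, event, rank(score))$c_index, c1)
})

test_that("time-varying AUC matches direct enumeration without censoring", {
  set.seed(14)
  n <- 120
  cfg <- plain_config(n_pairs = 60, n_cpgs = 2, base_rate_cause1 = 0.02,
                      base_rate_death = 0.05)
  x <- rnorm(n)
  oc <- simulate_event_times(1.2 * x, cfg, seed = 15)
  # remove administrative censoring from comparisons: evaluate before it
  for (h in c(3, 6, 10)) {
    got <- time_varying_auc(oc$time, oc$event, x, h)$auc
    want <- brute_force_auc(oc$time, oc$event, x, h)
    expect_equal(got, want, tolerance = 1e-12)
  }
  expect_error(time_varying_auc(oc$time, oc$event, x, 99), "follow-up")
})

test_that("time-varying AUC of a random score is near one half", {
  cfg <- plain_config(n_pairs = 1000, n_cpgs = 2, base_rate_cause1 = 0.01)
  set.seed(16)
  score <- rnorm(2000)
  oc <- simulate_event_times(rep(0, 2000), cfg, seed = 17)
  auc <- time_varying_auc(oc$time, oc$event, score, c(5, 10))
  expect_true(all(auc$auc > 0.45 & auc$auc < 0.55))
})
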
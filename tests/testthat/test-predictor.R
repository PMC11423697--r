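# LASSO-Cox path, smoothness-parameter rules, stability selection, refit
# and validation.

pred_fixture <- function(seed = 19, n_pairs = 400, shr = 3, n_cpgs = 12) {
  cfg <- plain_config(n_pairs = n_pairs, n_cpgs = n_cpgs, n_causal = 1,
                      causal_log_shr = log(shr), seed = seed,
                      base_rate_cause1 = 0.006)
  sim <- simulate_cohort(cfg)
  res <- scale_cols(sim$methylation)
  ids <- rownames(res)
  oc <- sim$outcomes[match(ids, sim$outcomes$individual_id), ]
  pair <- sim$phenotypes$pair_id[match(ids, sim$phenotypes$individual_id)]
  X <- predictor_design(res, sim$phenotypes, colnames(res))
  list(sim = sim, res = res, oc = oc, pair = pair, X = X)
}

test_that("full shrinkage zeroes the CpGs but never the forced covariates", {
  fx <- pred_fixture(n_pairs = 150)
  path <- fit_lasso_cox_path(fx$X, fx$oc$time, fx$oc$event)
  cf <- coef(path, s = max(path$lambda))
  cpg_rows <- !(rownames(cf) %in% c("sexF", "age"))
  expect_true(all(cf[cpg_rows, 1] == 0))
  expect_error(fit_lasso_cox_path(fx$X, fx$oc$time, rep(0L, nrow(fx$X))),
               "no events")
})

test_that("the unpenalized end of the path matches the ordinary Cox fit", {
  fx <- pred_fixture(n_pairs = 250, n_cpgs = 4)
  keep <- c(colnames(fx$res)[1:4], "sexF", "age")
  X <- fx$X[, keep]
  path <- fit_lasso_cox_path(X, fx$oc$time, fx$oc$event,
                             lambda = c(0.1, 0.01, 1e-4, 1e-6),
                             thresh = 1e-14)
  cf <- as.numeric(coef(path, s = 1e-6))
  ref <- survival::coxph(survival::Surv(fx$oc$time, fx$oc$event == 1) ~ X,
                         ties = "breslow")
  expect_equal(cf, unname(coef(ref)), tolerance = 1e-4)
})

test_that("lambda rules evaluate hand-set CV curves correctly", {
  lam <- c(1, 0.5, 0.25, 0.1, 0.05)
  cvm <- c(10, 7.6, 7.5, 7.8, 8.1)
  cvsd <- rep(0.4, 5)
  expect_identical(lambda_rule(lam, cvm, cvsd, "min"), 0.25)
  # min + half SE = 7.7; lambdas within it: 0.5 and 0.25; take the largest
  expect_identical(lambda_rule(lam, cvm, cvsd, "min_plus_half_se"), 0.5)
  expect_identical(lambda_rule(lam, cvm, cvsd, "literal_half_se"), 0.45)
  # more penalization than the plain minimizer, always
  set.seed(2)
  for (i in 1:20) {
    cvm_i <- sort(runif(5, 5, 9), decreasing = sample(c(TRUE, FALSE), 1))
    cvsd_i <- runif(5, 0.1, 0.5)
    expect_gte(lambda_rule(lam, cvm_i, cvsd_i, "min_plus_half_se"),
               lambda_rule(lam, cvm_i, cvsd_i, "min"))
  }
})

test_that("pair-blocked CV keeps cotwins in one fold and is seeded", {
  fx <- pred_fixture(n_pairs = 150)
  sel <- select_lambda_cv(fx$X, fx$oc$time, fx$oc$event, fx$pair, seed = 4)
  sel2 <- select_lambda_cv(fx$X, fx$oc$time, fx$oc$event, fx$pair, seed = 4)
  expect_identical(sel$lambda, sel2$lambda)
  fold <- twinsurv:::pair_folds(fx$pair, 10, seed = 4)
  expect_true(all(tapply(fold, fx$pair, function(f) length(unique(f))) == 1L))
})

test_that("stability selection finds a strong CpG, ignores noise, and is deterministic", {
  fx <- pred_fixture(seed = 23, n_pairs = 500, shr = 4)
  st <- stability_selection(fx$X, fx$oc$time, fx$oc$event, fx$pair,
                            n_replicates = 30, seed = 11)
  causal <- fx$sim$truth$cpg_id
  expect_gt(st$selection_frequency[st$cpg_id == causal], 0.8)
  expect_lt(max(st$selection_frequency[st$cpg_id != causal]), 0.5)
  expect_true(st$selected[st$cpg_id == causal])
  st2 <- stability_selection(fx$X, fx$oc$time, fx$oc$event, fx$pair,
                             n_replicates = 30, seed = 11)
  expect_identical(as.data.frame(st), as.data.frame(st2))
})

test_that("the refit predictor delegates exactly to the clustered Cox fit", {
  fx <- pred_fixture(n_pairs = 200)
  sel <- fx$sim$truth$cpg_id
  model <- build_predictor(sel, fx$res, fx$sim$outcomes, fx$sim$phenotypes)
  expect_identical(nrow(model$coefficients), length(sel) + 2L)
  direct <- fit_cox(fx$oc$time, fx$oc$event,
                    predictor_design(fx$res, fx$sim$phenotypes, sel),
                    cluster = fx$pair)
  expect_equal(model$coefficients$log_hr, unname(direct$coefficients),
               tolerance = 1e-12)
  expect_true(all(c("sexF", "age") %in% model$coefficients$term))
  expect_error(build_predictor(character(0), fx$res, fx$sim$outcomes,
                               fx$sim$phenotypes), "empty")
})

test_that("cross-validation separates signal from a permuted null", {
  fx <- pred_fixture(seed = 29, n_pairs = 400, shr = 4)
  sel <- fx$sim$truth$cpg_id
  cv <- cross_validate(sel, fx$res, fx$sim$outcomes, fx$sim$phenotypes,
                       k = 5, seed = 7)
  cv_b <- cross_validate(sel, fx$res, fx$sim$outcomes, fx$sim$phenotypes,
                         k = 5, seed = 7)
  expect_identical(cv$c_full, cv_b$c_full)     # deterministic at fixed seed
  expect_gt(cv$c_full, cv$c_basic)
  expect_gt(cv$c_full, 0.6)

  # permuting outcomes severs the link: C near one half
  perm_oc <- fx$sim$outcomes
  set.seed(31)
  perm <- sample(nrow(perm_oc))
  perm_oc$time <- perm_oc$time[perm]
  perm_oc$event <- perm_oc$event[perm]
  cv0 <- cross_validate(sel, fx$res, perm_oc, fx$sim$phenotypes,
                        k = 5, seed = 7)
  expect_gt(cv0$c_full, 0.38)
  expect_lt(cv0$c_full, 0.62)
})

test_that("external validation drops missing CpGs, logs them, and self-validates", {
  fx <- pred_fixture(seed = 37, n_pairs = 300, shr = 3, n_cpgs = 8)
  sel <- c(fx$sim$truth$cpg_id,
           setdiff(colnames(fx$res), fx$sim$truth$cpg_id)[1:3])
  model <- build_predictor(sel, fx$res, fx$sim$outcomes, fx$sim$phenotypes)

  # self-validation: the external cohort is the training cohort
  ev_self <- external_validate(model, fx$res, fx$sim$outcomes,
                               fx$sim$phenotypes)
  expect_equal(ev_self$c_combined, model$training_c, tolerance = 1e-12)

  # two model CpGs unavailable externally
  res_miss <- fx$res[, setdiff(colnames(fx$res), sel[3:4])]
  expect_message(
    ev <- external_validate(model, res_miss, fx$sim$outcomes,
                            fx$sim$phenotypes),
    "drops 2")
  expect_identical(sort(ev$dropped_cpgs), sort(sel[3:4]))
  expect_true(is.finite(ev$c_combined))
  expect_identical(nrow(ev$per_cpg), 2L)

  empty <- fx$res[, setdiff(colnames(fx$res), sel), drop = FALSE]
  expect_error(external_validate(model, empty, fx$sim$outcomes,
                                 fx$sim$phenotypes), "no predictor CpGs")
})
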
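# G-computation risk ratios, zygosity ICCs and the matched cotwin analysis.

causal_fixture <- function(seed = 5, n_pairs = 400, shr = 2) {
  cfg <- plain_config(n_pairs = n_pairs, n_cpgs = 2, seed = seed,
                      base_rate_cause1 = 0.004)
  n <- 2 * n_pairs
  set.seed(seed)
  expo <- rbinom(n, 1, 0.5)
  oc <- simulate_event_times(log(shr) * expo, cfg, seed = seed + 1)
  pair <- rep(seq_len(n_pairs), each = 2)
  list(cfg = cfg, expo = expo, oc = oc, pair = pair)
}

test_that("a forced-null exposure coefficient gives a ratio of exactly one", {
  fx <- causal_fixture()
  a <- ate_risk_ratio(fx$expo, fx$oc$time, fx$oc$event, fx$pair,
                      horizon = 5, n_boot = 0, coef_override = 0)
  expect_identical(a$ate_ratio, 1)
  expect_identical(a$risk_high, a$risk_low)
})

test_that("swapping exposure labels inverts the ratio and swaps the risks", {
  fx <- causal_fixture()
  a <- ate_risk_ratio(fx$expo, fx$oc$time, fx$oc$event, fx$pair,
                      horizon = 5, n_boot = 0)
  b <- ate_risk_ratio(1L - fx$expo, fx$oc$time, fx$oc$event, fx$pair,
                      horizon = 5, n_boot = 0)
  expect_equal(b$ate_ratio, 1 / a$ate_ratio, tolerance = 1e-6)
  expect_equal(b$risk_high, a$risk_low, tolerance = 1e-6)
  expect_equal(b$risk_low, a$risk_high, tolerance = 1e-6)
})

test_that("without competing events or censoring the estimator is plug-in Cox G-computation", {
  set.seed(6)
  n <- 150
  expo <- rbinom(n, 1, 0.5)
  time <- rexp(n, 0.3 * exp(0.6 * expo))
  event <- rep(1L, n)
  a <- ate_risk_ratio(expo, time, event, rep(1:75, each = 2),
                      horizon = 2, n_boot = 0)
  # independent plug-in route through an ordinary Cox model
  d <- data.frame(time = time, event = event, x = expo)
  cf <- survival::coxph(survival::Surv(time, event) ~ x, data = d,
                        ties = "breslow")
  bh <- survival::basehaz(cf, centered = FALSE)
  H0 <- c(0, bh$hazard)[findInterval(2, c(0, bh$time))]
  expect_equal(a$risk_high, 1 - exp(-H0 * exp(unname(coef(cf)))),
               tolerance = 1e-8)
  expect_equal(a$risk_low, 1 - exp(-H0), tolerance = 1e-8)
})

test_that("input contracts are enforced", {
  fx <- causal_fixture(n_pairs = 40)
  expect_error(ate_risk_ratio(rep(1L, 160), fx$oc$time, fx$oc$event,
                              fx$pair), "single level")
  expect_error(ate_risk_ratio(fx$expo, fx$oc$time, fx$oc$event, fx$pair,
                              horizon = 99), "horizon")
})

test_that("the pair bootstrap yields a covering interval for a planted effect", {
  fx <- causal_fixture(seed = 9, n_pairs = 1500, shr = 2)
  a <- ate_risk_ratio(fx$expo, fx$oc$time, fx$oc$event, fx$pair,
                      horizon = 5, n_boot = 60, seed = 2)
  truth <- true_cause1_cif(fx$cfg, 5, log(2)) / true_cause1_cif(fx$cfg, 5, 0)
  expect_true(a$ci_lower < truth && truth < a$ci_upper)
  expect_true(a$ci_lower < a$ate_ratio && a$ate_ratio < a$ci_upper)
})

test_that("double-entry ICC behaves at its boundaries and under reordering", {
  ph <- toy_phenotypes(12)
  ph$zygosity <- rep(c("MZ", "DZ"), each = 6)
  m <- matrix(rep(rnorm(6), each = 2), 12, 1,
              dimnames = list(ph$individual_id, "cgQ"))
  r <- icc_by_zygosity(m, ph, "cgQ")
  expect_equal(r$icc_mz, 1)
  expect_equal(r$heritability_upper_bound, r$icc_mz)

  # member order within pair is irrelevant
  set.seed(7)
  m2 <- matrix(rnorm(12), 12, 1, dimnames = dimnames(m))
  swap <- as.vector(rbind(seq(2, 12, 2), seq(1, 11, 2)))
  m2_sw <- m2[swap, , drop = FALSE]
  rownames(m2_sw) <- rownames(m2)[swap]
  r1 <- icc_by_zygosity(m2, ph, "cgQ")
  r2 <- icc_by_zygosity(m2_sw, ph, "cgQ")
  expect_equal(r1$icc_mz, r2$icc_mz, tolerance = 1e-12)
})

test_that("independent pair members give a near-zero ICC", {
  ph <- toy_phenotypes(1000)
  set.seed(8)
  m <- matrix(rnorm(1000), 1000, 1,
              dimnames = list(ph$individual_id, "cgN"))
  r <- suppressWarnings(icc_by_zygosity(m, ph, "cgN"))
  expect_lt(abs(r$icc_mz), 0.1)
})

test_that("matched analysis is unbiased under pair-level confounding where the unmatched fit is not", {
  set.seed(15)
  n_pairs <- 1500
  cfg <- plain_config(n_pairs = n_pairs, n_cpgs = 2,
                      base_rate_cause1 = 0.01, base_rate_death = 0.01)
  u <- rnorm(n_pairs)                       # shared confounder
  x <- sqrt(0.5) * rep(u, each = 2) + sqrt(0.5) * rnorm(2 * n_pairs)
  oc <- simulate_event_times(0.9 * rep(u, each = 2), cfg, seed = 16)
  pair <- rep(seq_len(n_pairs), each = 2)
  unmatched <- fit_cox(oc$time, oc$event, x, cluster = pair)
  matched <- fit_stratified_cox(oc$time, oc$event, x, strata = pair)
  expect_gt(abs(unname(unmatched$coefficients)), 0.15)   # biased away from 0
  ci <- unname(matched$coefficients) +
    c(-1.96, 1.96) * unname(matched$naive_se)
  expect_true(ci[1] < 0 && 0 < ci[2])                    # truth is null
})

test_that("per-variable matched table errors when no pair is informative", {
  ph <- toy_phenotypes(8)
  oc <- data.frame(individual_id = ph$individual_id,
                   time = rep(c(1, 2, 3, 4), each = 2),
                   event = rep(c(1L, 0L), 4))
  m <- matrix(rep(c(0.3, -1.2, 0.8, 0.1), each = 2), 8, 1,
              dimnames = list(ph$individual_id, "cgC"))   # pair-concordant
  expect_error(matched_pair_analysis(m, oc, ph), "informative")
})
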
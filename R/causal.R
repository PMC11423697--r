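# Causal and twin-design analyses: G-computation risk ratios at a fixed
# horizon on the Fine-Gray model, zygosity-specific intraclass correlations
# (the MZ ICC upper-bounds heritability under the polygenic model), and the
# matched case-cotwin stratified Cox analysis.

fg_counterfactual_risks <- function(exposure, time, event, horizon,
                                    coef_override = NULL) {
  fgd <- finegray_expand(time, event)
  d <- data.frame(fgd[c("fgstart", "fgstop", "fgstatus", "fgwt")],
                  x = exposure[fgd$orig_row])
  fit <- quiet_cox(
    survival::coxph(survival::Surv(fgstart, fgstop, fgstatus) ~ x,
                    data = d, weights = fgwt, ties = "breslow"))
  b <- if (is.null(coef_override)) unname(fit$coefficients) else coef_override
  # baseline cumulative subdistribution hazard (weighted Breslow, x = 0)
  bh <- survival::basehaz(fit, centered = FALSE)
  H0 <- c(0, bh$hazard)[findInterval(horizon, c(0, bh$time))]
  # counterfactual cause-1 risks averaged over the cohort; with an
  # exposure-only model the standardization is over a degenerate design
  risk <- function(xval) mean(1 - exp(-H0 * exp(b * xval)))
  c(risk_high = risk(1), risk_low = risk(0), coef = b)
}

#' Average causal exposure-effect risk ratio by G-computation
#'
#' Estimates the ratio of counterfactual cause-1 (malignancy) risks at a
#' fixed horizon under exposure forced high versus low, by standardization
#' on a Fine-Gray model: the model-based cumulative incidence at the
#' horizon is computed for every subject under each forced exposure level
#' (baseline subdistribution hazard by the weighted Breslow estimator) and
#' averaged over the cohort. Confidence interval and p-value come from a
#' pair-level nonparametric bootstrap (pairs resampled with replacement,
#' percentile CI, normal-approximation p on the log ratio).
#'
#' @param exposure binary 0/1 exposure per subject (high vs low methylation).
#' @param time,event competing-risk outcomes (0 censored, 1 malignancy,
#'   2 death).
#' @param cluster pair identifier per subject; the bootstrap resampling unit.
#' @param horizon evaluation horizon in years (default 5).
#' @param n_boot bootstrap replicates (default 500).
#' @param seed bootstrap seed.
#' @param coef_override optional fixed log-sHR used in place of the
#'   estimate (diagnostic; `0` yields a ratio of exactly 1).
#' @return An object of class `ate_result` with `risk_high`, `risk_low`,
#'   `ate_ratio`, percentile `ci_lower`/`ci_upper`, `p_value`, `horizon`
#'   and `n_boot`.
#' @export
ate_risk_ratio <- function(exposure, time, event, cluster, horizon = 5,
                           n_boot = 500L, seed = 1L, coef_override = NULL) {
  check_outcomes(time, event)
  if (!all(exposure %in% 0:1)) stop("exposure must be binary 0/1")
  if (length(unique(exposure)) < 2L) stop("exposure has a single level")
  if (horizon > max(time)) stop("horizon lies beyond the last observed time")
  pt <- fg_counterfactual_risks(exposure, time, event, horizon, coef_override)
  ratio <- unname(pt[["risk_high"]] / pt[["risk_low"]])

  ci <- c(NA_real_, NA_real_)
  pval <- NA_real_
  if (n_boot > 0L) {
    ucl <- unique(cluster)
    idx_by <- split(seq_along(time), match(cluster, ucl))
    log_ratios <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        ix <- unlist(idx_by[sample.int(length(ucl), replace = TRUE)],
                     use.names = FALSE)
        if (sum(event[ix] == 1L) < 1L ||
            length(unique(exposure[ix])) < 2L) return(NA_real_)
        r <- tryCatch(
          fg_counterfactual_risks(exposure[ix], time[ix], event[ix],
                                  horizon, coef_override),
          error = function(e) NULL)
        if (is.null(r)) NA_real_ else log(r[["risk_high"]] / r[["risk_low"]])
      }, numeric(1))
    })
    log_ratios <- log_ratios[is.finite(log_ratios)]
    if (length(log_ratios) >= 10L) {
      ci <- exp(stats::quantile(log_ratios, c(0.025, 0.975), names = FALSE))
      se <- stats::sd(log_ratios)
      if (se > 0) pval <- 2 * stats::pnorm(-abs(log(ratio)) / se)
    }
  }
  structure(
    list(risk_high = unname(pt[["risk_high"]]),
         risk_low = unname(pt[["risk_low"]]),
         ate_ratio = ratio, ci_lower = ci[1], ci_upper = ci[2],
         p_value = pval, horizon = horizon, n_boot = n_boot),
    class = "ate_result")
}

#' @export
print.ate_result <- function(x, ...) {
  cat(sprintf("G-computation ATE risk ratio at %g years: %.3f (95%% CI %.3f-%.3f, p = %.3g)\n",
              x$horizon, x$ate_ratio, x$ci_lower, x$ci_upper, x$p_value))
  cat(sprintf("  counterfactual risks: high %.4f, low %.4f (%d pair-bootstrap reps)\n",
              x$risk_high, x$risk_low, x$n_boot))
  invisible(x)
}

double_entry_icc <- function(m1, m2) {
  stats::cor(c(m1, m2), c(m2, m1))
}

#' Within-pair intraclass correlation by zygosity
#'
#' Double-entry Pearson correlation of standardized methylation residuals
#' within complete MZ and DZ pairs, with Fisher-z confidence intervals
#' using the number of pairs as the effective sample size. Under the
#' polygenic (ADCE) variance-components model the MZ ICC is an upper bound
#' for the heritability of the methylation level.
#'
#' @param residuals samples x CpGs standardized residual matrix with sample
#'   ids as row names.
#' @param phenotypes phenotype table with `individual_id`, `pair_id`,
#'   `zygosity`.
#' @param cpg_ids CpGs to report (default: all columns).
#' @return An object of class `icc_result`: one row per CpG with `icc_mz`,
#'   `icc_mz_lower`, `icc_mz_upper`, `icc_dz`, `icc_dz_lower`,
#'   `icc_dz_upper`, `n_pairs_mz`, `n_pairs_dz` and
#'   `heritability_upper_bound` (= `icc_mz`). Zygosities with fewer than 3
#'   complete pairs yield `NA` with a warning.
#' @export
icc_by_zygosity <- function(residuals, phenotypes, cpg_ids = colnames(residuals)) {
  ids <- rownames(residuals)
  ph <- phenotypes[match(ids, phenotypes$individual_id), ]
  pair_members <- split(seq_along(ids), ph$pair_id)
  pair_members <- pair_members[lengths(pair_members) == 2L]
  zyg <- vapply(pair_members, function(ix) ph$zygosity[ix[1]], character(1))
  fisher_ci <- function(r, n) {
    if (is.na(r) || n < 4L) return(c(NA_real_, NA_real_))
    z <- atanh(r) + c(-1, 1) * stats::qnorm(0.975) / sqrt(n - 3)
    tanh(z)
  }
  one_zyg <- function(cpg, which_zyg) {
    pm <- pair_members[zyg == which_zyg]
    n <- length(pm)
    if (n < 3L) return(c(NA_real_, NA_real_, NA_real_, n))
    m1 <- vapply(pm, function(ix) residuals[ix[1], cpg], numeric(1))
    m2 <- vapply(pm, function(ix) residuals[ix[2], cpg], numeric(1))
    r <- double_entry_icc(m1, m2)
    c(r, fisher_ci(r, n), n)
  }
  rows <- lapply(cpg_ids, function(cpg) {
    mz <- one_zyg(cpg, "MZ")
    dz <- one_zyg(cpg, "DZ")
    data.frame(cpg_id = cpg,
               icc_mz = mz[1], icc_mz_lower = mz[2], icc_mz_upper = mz[3],
               icc_dz = dz[1], icc_dz_lower = dz[2], icc_dz_upper = dz[3],
               n_pairs_mz = mz[4], n_pairs_dz = dz[4],
               heritability_upper_bound = mz[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(out$n_pairs_mz < 3L) || any(out$n_pairs_dz < 3L)) {
    warning("fewer than 3 complete pairs for a zygosity; ICC reported as NA")
  }
  structure(out, class = c("icc_result", "data.frame"))
}

#' Matched case-cotwin stratified Cox analysis
#'
#' Fits pair-stratified Cox models (twin-pair-specific baseline hazards) so
#' estimates use only within-pair contrasts, cancelling confounders shared
#' by the twins (germline genetics, shared environment). With a single
#' score column per call this yields the per-CpG matched hazard ratios;
#' with `combined = TRUE` all columns enter one model and the global
#' score-test p-value tests the predictor as a whole.
#'
#' @param scores samples x variables matrix (CpG residuals or predictor
#'   components), sample ids as row names.
#' @param outcomes outcome table (`individual_id`, `time`, `event`).
#' @param phenotypes phenotype table with `pair_id` and `zygosity`.
#' @param zygosity optional filter, e.g. `"MZ"`.
#' @param combined fit one multivariable stratified model instead of one
#'   model per column.
#' @return For `combined = TRUE` a `cox_fit` (with `score_test_p`);
#'   otherwise a data frame with one row per column (`variable`, `hr`,
#'   `se`, `p`).
#' @export
matched_pair_analysis <- function(scores, outcomes, phenotypes,
                                  zygosity = NULL, combined = FALSE) {
  scores <- as.matrix(scores)
  ids <- rownames(scores)
  oc <- outcomes[match(ids, outcomes$individual_id), ]
  ph <- phenotypes[match(ids, phenotypes$individual_id), ]
  keep <- if (is.null(zygosity)) rep(TRUE, length(ids)) else
    ph$zygosity %in% zygosity
  if (combined) {
    return(fit_stratified_cox(oc$time[keep], oc$event[keep],
                              scores[keep, , drop = FALSE],
                              strata = ph$pair_id[keep]))
  }
  rows <- lapply(seq_len(ncol(scores)), function(j) {
    f <- tryCatch(
      fit_stratified_cox(oc$time[keep], oc$event[keep],
                         scores[keep, j, drop = FALSE],
                         strata = ph$pair_id[keep]),
      error = function(e) NULL)
    if (is.null(f)) {
      data.frame(variable = colnames(scores)[j], hr = NA_real_,
                 se = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
    } else {
      data.frame(variable = colnames(scores)[j], hr = unname(f$hr[1]),
                 se = unname(f$naive_se[1]), p = unname(f$p_value[1]),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (all(is.na(out$hr))) {
    stop("no informative discordant pairs for any variable")
  }
  out
}
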
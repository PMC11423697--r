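# Estimation and metric primitives used by every analysis stage:
# pair-clustered Cox, stratified (matched) Cox, Fine-Gray subdistribution
# regression, proportional-hazards diagnostics, Aalen-Johansen cumulative
# incidence, Harrell's C and IPCW time-varying AUC.

as_cov_matrix <- function(covariates) {
  X <- as.matrix(covariates)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("covariates must be finite")
  X
}

check_outcomes <- function(time, event, n = NULL) {
  if (length(time) != length(event)) stop("time and event lengths differ")
  if (!is.null(n) && length(time) != n) {
    stop("outcome length does not match covariate rows")
  }
  if (any(time <= 0)) stop("all event times must be positive")
  if (!all(event %in% 0:2)) stop("event codes must be in {0, 1, 2}")
  invisible(TRUE)
}

new_cox_fit <- function(fit, robust, n_events, ties, class2 = NULL,
                        infinite = FALSE) {
  beta <- stats::coef(fit)
  se_naive <- sqrt(diag(if (is.null(fit$naive.var)) fit$var else fit$naive.var))
  se_rob <- sqrt(diag(fit$var))
  se <- if (robust) se_rob else se_naive
  z <- beta / se
  structure(
    list(coefficients = beta,
         hr = exp(beta),
         robust_se = if (robust) se_rob else se_naive,
         naive_se = se_naive,
         wald_z = z,
         p_value = 2 * stats::pnorm(-abs(z)),
         n_events = n_events,
         ties_method = ties,
         infinite = infinite,
         fit = fit),
    class = c(class2, "cox_fit")
  )
}

#' Pair-clustered Cox regression for one competing cause
#'
#' Fits a Cox proportional hazards model for the cause of interest, treating
#' the competing cause as censoring on the cause-specific hazard scale, with
#' Efron tie handling and a cluster-sandwich (working-independence) variance
#' that aggregates score residuals within twin pairs. This marginal model
#' with pair-robust standard errors is the default reading of a "Cox
#' frailty" analysis with robust variance; a shared gamma-frailty fit is
#' available via `frailty = TRUE`.
#'
#' @param time follow-up time in years since entry (> 0).
#' @param event event code per subject: 0 censored, 1 cause of interest,
#'   2 competing event.
#' @param covariates numeric vector, matrix or data frame of covariates.
#' @param cluster cluster (twin pair) identifier per subject; `NULL` for
#'   independent subjects.
#' @param event_of_interest event code modelled as the event (default 1).
#' @param frailty if `TRUE`, add a gamma frailty term per cluster instead of
#'   the sandwich variance.
#' @return An object of class `cox_fit` with elements `coefficients` (log
#'   HR), `hr`, `robust_se`, `naive_se`, `wald_z`, `p_value` (two-sided
#'   robust Wald), `n_events`, `ties_method`, an `infinite` flag marking
#'   monotone-likelihood fits, and the underlying [survival::coxph()] fit.
#' @examples
#' set.seed(1)
#' d <- data.frame(t = rexp(60), e = rbinom(60, 1, 0.7), x = rnorm(60))
#' fit_cox(d$t, d$e, d$x, cluster = rep(1:30, each = 2))
#' @export
fit_cox <- function(time, event, covariates, cluster = NULL,
                    event_of_interest = 1L, frailty = FALSE) {
  X <- as_cov_matrix(covariates)
  check_outcomes(time, event, nrow(X))
  status <- as.integer(event == event_of_interest)
  if (sum(status) < 1L) stop("no events of the cause of interest")
  sds <- col_sds(X)
  if (any(sds == 0)) {
    stop("covariate(s) without variation: ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  }
  d <- data.frame(.time = time, .status = status, X, check.names = FALSE)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .status) ~",
    paste(sprintf("`%s`", colnames(X)), collapse = " + "),
    if (frailty && !is.null(cluster)) "+ survival::frailty(.cluster)" else ""))
  if (!is.null(cluster)) d$.cluster <- cluster
  infinite <- FALSE
  fit <- withCallingHandlers(
    if (!is.null(cluster) && !frailty) {
      survival::coxph(fml, data = d, cluster = .cluster, ties = "efron",
                      x = FALSE, y = TRUE)
    } else {
      survival::coxph(fml, data = d, ties = "efron", x = FALSE, y = TRUE)
    },
    warning = function(w) {
      if (grepl("infinite|converge|beta", conditionMessage(w))) {
        infinite <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  new_cox_fit(fit, robust = !is.null(cluster) && !frailty,
              n_events = sum(status), ties = "efron", infinite = infinite)
}

#' Matched (pair-stratified) Cox regression
#'
#' Fits a Cox model with a separate baseline hazard per stratum (twin
#' pair), so only within-pair information contributes: pairs without an
#' event, or concordant in all covariates, drop out of the partial
#' likelihood. This is the matched case-cotwin analysis that cancels
#' confounders shared by the twins.
#'
#' @inheritParams fit_cox
#' @param strata stratum (pair) identifier per subject.
#' @return A `cox_fit`; `p_value` uses the model-based standard error, and
#'   the attribute field `score_test_p` holds the global score-test p-value.
#' @export
fit_stratified_cox <- function(time, event, covariates, strata,
                               event_of_interest = 1L) {
  X <- as_cov_matrix(covariates)
  check_outcomes(time, event, nrow(X))
  status <- as.integer(event == event_of_interest)
  if (sum(status) < 1L) stop("no events of the cause of interest")
  # informative stratum: has an event and within-stratum covariate variation
  informative <- vapply(split(seq_along(time), strata), function(ix) {
    any(status[ix] == 1L) && length(ix) > 1L &&
      any(apply(X[ix, , drop = FALSE], 2L, function(v) length(unique(v)) > 1L))
  }, logical(1))
  if (!any(informative)) {
    stop("no informative strata: every event stratum is covariate-concordant")
  }
  d <- data.frame(.time = time, .status = status, .strata = strata, X,
                  check.names = FALSE)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .status) ~",
    paste(sprintf("`%s`", colnames(X)), collapse = " + "),
    "+ strata(.strata)"))
  infinite <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = d, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge|beta", conditionMessage(w))) {
        infinite <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  out <- new_cox_fit(fit, robust = FALSE, n_events = sum(status),
                     ties = "efron", class2 = "stratified_cox_fit",
                     infinite = infinite)
  out$score_test_p <- unname(summary(fit)$sctest["pvalue"])
  out$n_informative_strata <- sum(informative)
  out
}

# Expand outcomes into the finegray counting-process data set (cause-1
# subdistribution risk set with Kaplan-Meier censoring weights). The
# expansion depends only on the outcomes, so the EWAS loop builds it once
# and re-attaches each CpG column through `orig_row`.
finegray_expand <- function(time, event) {
  check_outcomes(time, event)
  if (sum(event == 1L) < 1L) stop("no cause-1 events; Fine-Gray fit undefined")
  d <- data.frame(
    .time = time,
    .status = factor(event, levels = 0:2, labels = c("censor", "ev1", "ev2")),
    orig_row = seq_along(time))
  survival::finegray(survival::Surv(.time, .status) ~ orig_row, data = d,
                     etype = "ev1")
}

#' Fine-Gray subdistribution hazards regression with pair clustering
#'
#' Estimates log subdistribution hazard ratios for the cause of interest by
#' weighted Cox estimation on the subdistribution risk set: subjects with a
#' competing event remain at risk with inverse-probability-of-censoring
#' weights from the overall Kaplan-Meier estimator of the censoring
#' distribution (Breslow tie handling, cluster-sandwich variance by twin
#' pair). With no competing events the fit reduces to the ordinary Cox
#' model.
#'
#' @inheritParams fit_cox
#' @return An object of classes `fine_gray_fit` and `cox_fit`; `hr` holds
#'   the subdistribution hazard ratios (sHR).
#' @export
fit_fine_gray <- function(time, event, covariates, cluster = NULL) {
  X <- as_cov_matrix(covariates)
  check_outcomes(time, event, nrow(X))
  sds <- col_sds(X)
  if (any(sds == 0)) {
    stop("covariate(s) without variation: ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  }
  fgd <- finegray_expand(time, event)
  Xe <- X[fgd$orig_row, , drop = FALSE]
  d <- data.frame(fgd[c("fgstart", "fgstop", "fgstatus", "fgwt")], Xe,
                  check.names = FALSE)
  fml <- stats::as.formula(paste(
    "survival::Surv(fgstart, fgstop, fgstatus) ~",
    paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  infinite <- FALSE
  fit <- withCallingHandlers({
    if (!is.null(cluster)) {
      d$.cluster <- cluster[fgd$orig_row]
      survival::coxph(fml, data = d, weights = fgwt, cluster = .cluster,
                      ties = "breslow")
    } else {
      survival::coxph(fml, data = d, weights = fgwt, ties = "breslow")
    }
  }, warning = function(w) {
    if (grepl("infinite|converge|beta", conditionMessage(w))) {
      infinite <<- TRUE
      invokeRestart("muffleWarning")
    }
  })
  out <- new_cox_fit(fit, robust = TRUE, n_events = sum(event == 1L),
                     ties = "breslow", class2 = "fine_gray_fit",
                     infinite = infinite)
  out$censoring_weights_model <- "Kaplan-Meier (overall)"
  out$finegray_data <- d
  out
}

#' @export
print.cox_fit <- function(x, ...) {
  lab <- if (inherits(x, "fine_gray_fit")) "sHR" else "HR"
  cat(sprintf("%s (%d events, %s ties%s)\n",
              if (inherits(x, "fine_gray_fit"))
                "Fine-Gray subdistribution hazards fit"
              else if (inherits(x, "stratified_cox_fit"))
                "Pair-stratified Cox fit" else "Cox proportional hazards fit",
              x$n_events, x$ties_method,
              if (x$infinite) ", monotone likelihood flagged" else ""))
  tab <- data.frame(coef = x$coefficients, x$hr, robust_se = x$robust_se,
                    z = x$wald_z, p = signif(x$p_value, 3))
  names(tab)[2] <- lab
  print(tab, digits = 4)
  invisible(x)
}

#' @export
coef.cox_fit <- function(object, ...) object$coefficients

#' Scaled Schoenfeld residual test of proportional hazards
#'
#' Grambsch-Therneau score test of correlation between the scaled
#' Schoenfeld residuals of a fitted Cox model and transformed time.
#'
#' @param fit a `cox_fit` from [fit_cox()].
#' @param transform time transform: `"km"` (default), `"identity"` or
#'   `"rank"`.
#' @return An object of class `ph_test_result`: per-covariate chi-square
#'   statistics, degrees of freedom and p-values, plus the global test.
#' @export
ph_test <- function(fit, transform = c("km", "identity", "rank")) {
  transform <- match.arg(transform)
  stopifnot(inherits(fit, "cox_fit"))
  if (fit$n_events < 2L) stop("proportional hazards test needs at least 2 events")
  z <- survival::cox.zph(fit$fit, transform = transform, global = TRUE)
  k <- nrow(z$table) - 1L
  structure(
    list(table = z$table[seq_len(k), , drop = FALSE],
         global_p = z$table[k + 1L, "p"],
         time_transform = transform),
    class = "ph_test_result")
}

#' @export
print.ph_test_result <- function(x, ...) {
  cat(sprintf("Scaled Schoenfeld PH test (%s time transform)\n",
              x$time_transform))
  print(x$table, digits = 4)
  cat(sprintf("global p = %.4g\n", x$global_p))
  invisible(x)
}

#' Nonparametric cumulative incidence (Aalen-Johansen)
#'
#' @param time follow-up times (> 0).
#' @param event event codes 0/1/2.
#' @return An object of class `cif_curve`: step-function evaluation times
#'   and one nondecreasing cumulative incidence column per cause, starting
#'   at zero; the cause-wise sum never exceeds one.
#' @export
cumulative_incidence <- function(time, event) {
  check_outcomes(time, event)
  if (length(time) == 0L) stop("no outcomes supplied")
  if (all(event == 0L)) {
    return(structure(list(times = c(0, sort(unique(time))),
                          cif = matrix(0, length(unique(time)) + 1L, 2L,
                                       dimnames = list(NULL, c("cause1", "cause2")))),
                     class = "cif_curve"))
  }
  st <- factor(event, levels = 0:2, labels = c("censor", "cause1", "cause2"))
  f <- survival::survfit(survival::Surv(time, st) ~ 1)
  states <- f$states
  cif <- f$pstate[, states %in% c("cause1", "cause2"), drop = FALSE]
  colnames(cif) <- states[states %in% c("cause1", "cause2")]
  structure(
    list(times = c(0, f$time),
         cif = rbind(0, cif)),
    class = "cif_curve")
}

#' Evaluate a cumulative incidence curve at given times
#' @param x a `cif_curve`.
#' @param times evaluation times.
#' @param cause `"cause1"` or `"cause2"`.
#' @return Cumulative incidence values (right-continuous step function).
#' @export
eval_cif <- function(x, times, cause = "cause1") {
  stopifnot(inherits(x, "cif_curve"))
  if (!cause %in% colnames(x$cif)) return(rep(0, length(times)))
  idx <- findInterval(times, x$times)
  unname(x$cif[pmax(idx, 1L), cause])
}

#' Harrell's concordance index
#'
#' Probability that, of a comparable pair under censoring, the subject with
#' the higher risk score fails first; score ties count one half. Subjects
#' with a competing (code 2) event are treated as censored at their event
#' time.
#'
#' @param time follow-up times.
#' @param event event codes; code 1 is the event of interest.
#' @param score risk score (higher = higher predicted risk).
#' @return An object of class `concordance_result` with `c_index`,
#'   `n_concordant`, `n_discordant`, `n_tied` (score ties) and
#'   `n_comparable`.
#' @export
harrells_c <- function(time, event, score) {
  check_outcomes(time, event)
  if (length(score) != length(time)) stop("score length mismatch")
  status <- as.integer(event == 1L)
  cf <- survival::concordance(survival::Surv(time, status) ~ score,
                              reverse = TRUE, timewt = "n")
  cnt <- as.numeric(cf$count)
  names(cnt) <- names(cf$count)
  n_comp <- cnt[["concordant"]] + cnt[["discordant"]] + cnt[["tied.x"]]
  structure(
    list(c_index = unname(cf$concordance),
         n_concordant = cnt[["concordant"]],
         n_discordant = cnt[["discordant"]],
         n_tied = cnt[["tied.x"]],
         n_comparable = n_comp),
    class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Harrell's C = %.4f (%g concordant / %g discordant / %g tied of %g comparable pairs)\n",
              x$c_index, x$n_concordant, x$n_discordant, x$n_tied,
              x$n_comparable))
  invisible(x)
}

# Left-continuous Kaplan-Meier censoring survival G(t-) evaluated at t.
km_censoring <- function(time, event) {
  f <- survival::survfit(survival::Surv(time, event == 0L) ~ 1)
  function(t) {
    # G(t-): survival just before t
    idx <- findInterval(t - 1e-12, c(0, f$time))
    c(1, f$surv)[pmax(idx, 1L)]
  }
}

#' Time-varying cumulative/dynamic AUC with IPCW
#'
#' Discrimination of a risk score between subjects failing from the cause of
#' interest by time t (cumulative cases) and subjects event-free at t
#' (dynamic controls), with censoring handled by inverse-probability
#' weights from the Kaplan-Meier estimator of the censoring distribution.
#' Subjects with a competing (code 2) event by t are retained as controls
#' (cause-specific cumulative/dynamic definition).
#'
#' @param time follow-up times.
#' @param event event codes 0/1/2.
#' @param score risk score (higher = higher predicted risk).
#' @param horizons evaluation times, strictly inside the observed follow-up.
#' @param n_boot optional number of bootstrap replicates for percentile
#'   confidence intervals (0 = no CI).
#' @param cluster optional cluster (pair) ids; the bootstrap resamples
#'   clusters.
#' @param seed seed for the bootstrap.
#' @return An object of class `auc_curve`: a data frame with `horizon`,
#'   `auc`, `ci_lower`, `ci_upper` plus attributes describing the weighting.
#' @export
time_varying_auc <- function(time, event, score, horizons, n_boot = 0L,
                             cluster = NULL, seed = 1L) {
  check_outcomes(time, event)
  if (length(score) != length(time)) stop("score length mismatch")
  if (any(horizons <= 0) || any(horizons >= max(time))) {
    stop("horizons must lie strictly inside the observed follow-up")
  }
  point <- ipcw_auc(time, event, score, horizons)
  lo <- hi <- rep(NA_real_, length(horizons))
  if (n_boot > 0L) {
    cl <- if (is.null(cluster)) seq_along(time) else cluster
    ucl <- unique(cl)
    idx_by <- split(seq_along(time), match(cl, ucl))
    bootm <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        pick <- sample.int(length(ucl), replace = TRUE)
        ix <- unlist(idx_by[pick], use.names = FALSE)
        ipcw_auc(time[ix], event[ix], score[ix], horizons)
      }, numeric(length(horizons)))
    })
    bootm <- matrix(bootm, nrow = length(horizons))
    lo <- apply(bootm, 1L, stats::quantile, probs = 0.025, na.rm = TRUE)
    hi <- apply(bootm, 1L, stats::quantile, probs = 0.975, na.rm = TRUE)
  }
  structure(
    data.frame(horizon = horizons, auc = point, ci_lower = lo, ci_upper = hi),
    weighting = "IPCW (Kaplan-Meier censoring), cumulative/dynamic",
    class = c("auc_curve", "data.frame"))
}

ipcw_auc <- function(time, event, score, horizons) {
  G <- km_censoring(time, event)
  vapply(horizons, function(t) {
    case <- which(time <= t & event == 1L)
    ctrl <- c(which(time > t), which(time <= t & event == 2L))
    if (length(case) == 0L || length(ctrl) == 0L) return(NA_real_)
    wc <- 1 / G(time[case])
    wk <- ifelse(time[ctrl] > t, 1 / G(t), 1 / G(time[ctrl]))
    sc <- score[case]
    sk <- score[ctrl]
    # weighted Mann-Whitney with half credit for score ties
    num <- 0
    for (i in seq_along(sc)) {
      num <- num + wc[i] * sum(wk * ((sc[i] > sk) + 0.5 * (sc[i] == sk)))
    }
    num / (sum(wc) * sum(wk))
  }, numeric(1))
}
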
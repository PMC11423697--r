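# Stability-selected LASSO-Cox predictor with forced sex/age, validated by
# pair-blocked cross-validated Harrell's C, IPCW time-varying AUC, and an
# external-cohort protocol.

#' Assemble the predictor design matrix
#'
#' Binds the requested standardized CpG residual columns with the forced
#' covariates: `sexF` (indicator of female sex) and `age` (years at blood
#' sampling), aligned on the residual matrix's sample ids.
#'
#' @param residuals samples x CpGs standardized residual matrix.
#' @param phenotypes phenotype table.
#' @param cpg_ids CpG columns to include (may be empty for the basic model).
#' @return Numeric matrix with `length(cpg_ids) + 2` columns.
#' @export
predictor_design <- function(residuals, phenotypes, cpg_ids) {
  ids <- rownames(residuals)
  ph <- phenotypes[match(ids, phenotypes$individual_id), ]
  X <- cbind(residuals[, cpg_ids, drop = FALSE],
             sexF = as.numeric(ph$sex == "F"),
             age = ph$age_at_entry)
  X
}

#' L1-penalized Cox path with penalty-free covariates
#'
#' Fits the LASSO-Cox coefficient path over a decreasing lambda sequence,
#' with zero penalty on the forced covariates (sex and age in the default
#' pipeline) so they stay in the model at every lambda.
#'
#' @param X numeric covariate matrix (standardized CpG columns plus forced
#'   covariates).
#' @param time,event outcomes; code 1 is the modelled event, 2 is treated
#'   as censoring on this (cause-specific hazard) scale.
#' @param penalty_free column names of `X` exempt from the L1 penalty.
#' @param lambda optional lambda sequence; defaults to the glmnet path.
#' @param ... further arguments passed to [glmnet::glmnet()] (e.g. a
#'   tighter convergence threshold `thresh`).
#' @return The fitted [glmnet::glmnet()] Cox path object.
#' @export
fit_lasso_cox_path <- function(X, time, event, penalty_free = c("sexF", "age"),
                               lambda = NULL, ...) {
  X <- as_cov_matrix(X)
  check_outcomes(time, event, nrow(X))
  status <- as.integer(event == 1L)
  if (sum(status) < 1L) stop("no events: penalized Cox fit undefined")
  pf <- as.numeric(!(colnames(X) %in% penalty_free))
  y <- survival::Surv(time, status)
  if (is.null(lambda)) {
    glmnet::glmnet(X, y, family = "cox", penalty.factor = pf, ...)
  } else {
    glmnet::glmnet(X, y, family = "cox", penalty.factor = pf,
                   lambda = lambda, ...)
  }
}

#' Apply a smoothness-parameter rule to a CV deviance curve
#'
#' Given the cross-validated partial-likelihood deviance per lambda, returns
#' the lambda chosen by `rule`: `"min"` is the deviance minimizer;
#' `"min_plus_half_se"` is the largest lambda whose deviance lies within
#' half a standard error of the minimum (the within-k-SE family with
#' k = 0.5); `"literal_half_se"` adds half the standard error at the
#' minimizer to the minimizing lambda itself, a sensitivity variant.
#'
#' @param lambda decreasing lambda sequence.
#' @param cvm mean CV deviance per lambda.
#' @param cvsd standard error of `cvm` per lambda.
#' @param rule one of `"min_plus_half_se"`, `"min"`, `"literal_half_se"`.
#' @return The selected lambda.
#' @export
lambda_rule <- function(lambda, cvm, cvsd,
                        rule = c("min_plus_half_se", "min", "literal_half_se")) {
  rule <- match.arg(rule)
  i_min <- which.min(cvm)
  switch(rule,
         min = lambda[i_min],
         min_plus_half_se = max(lambda[cvm <= cvm[i_min] + 0.5 * cvsd[i_min]]),
         literal_half_se = lambda[i_min] + 0.5 * cvsd[i_min])
}

# Round-robin fold assignment by pair, after a seeded shuffle of pairs, so
# both members of a twin pair always share a fold (no cotwin leakage).
pair_folds <- function(pair, k, seed) {
  ucl <- unique(pair)
  with_seed(seed, {
    ord <- sample(ucl)
    fold_of_pair <- stats::setNames(rep_len(seq_len(k), length(ucl)),
                                    ord)
    unname(fold_of_pair[as.character(pair)])
  })
}

#' Choose the LASSO smoothness parameter by pair-blocked cross-validation
#'
#' Runs k-fold cross-validation of the penalized Cox partial-likelihood
#' deviance with folds assigned by twin pair, then applies [lambda_rule()].
#'
#' @inheritParams fit_lasso_cox_path
#' @param pair pair identifier per subject (fold-assignment unit).
#' @param nfolds number of folds (default 10).
#' @param rule see [lambda_rule()].
#' @param seed fold-assignment seed.
#' @return A list with `lambda` (the selected value), `rule`, and the
#'   [glmnet::cv.glmnet()] object.
#' @export
select_lambda_cv <- function(X, time, event, pair,
                             penalty_free = c("sexF", "age"), nfolds = 10L,
                             rule = "min_plus_half_se", seed = 1L) {
  X <- as_cov_matrix(X)
  status <- as.integer(event == 1L)
  if (sum(status) < nfolds) {
    warning("fewer events than folds; CV deviance will be unstable")
  }
  foldid <- pair_folds(pair, nfolds, seed)
  pf <- as.numeric(!(colnames(X) %in% penalty_free))
  cvfit <- glmnet::cv.glmnet(X, survival::Surv(time, status), family = "cox",
                             penalty.factor = pf, foldid = foldid)
  list(lambda = lambda_rule(cvfit$lambda, cvfit$cvm, cvfit$cvsd, rule),
       rule = rule, cvfit = cvfit)
}

#' Stability selection for the LASSO-Cox predictor
#'
#' Repeatedly draws half-samples (by twin pair, without replacement), picks
#' the smoothness parameter on each half-sample by pair-blocked
#' cross-validation, fits the LASSO at that lambda, and records which CpGs
#' enter with nonzero coefficients. CpGs selected in more than
#' `threshold` of the replicates form the predictor; the forced covariates
#' are always in the model and are excluded from the frequencies.
#' Replicates whose half-sample carries no event are redrawn (and counted).
#'
#' @inheritParams select_lambda_cv
#' @param n_replicates number of half-sample replicates (default 1000).
#' @param subsample fraction of pairs per replicate, in (0, 1) (default 0.5).
#' @param threshold selection-frequency cut-off; strict "greater than"
#'   (default 0.8).
#' @param seed master seed; per-replicate streams are derived from it.
#' @return An object of class `stability_result`: a data frame with
#'   `cpg_id`, `selection_frequency`, `selected`, plus attributes
#'   `n_replicates`, `subsample`, `threshold`, `lambda_rule`, `seed` and
#'   `n_redrawn`.
#' @export
stability_selection <- function(X, time, event, pair,
                                n_replicates = 1000L, subsample = 0.5,
                                threshold = 0.8,
                                penalty_free = c("sexF", "age"),
                                nfolds = 10L, rule = "min_plus_half_se",
                                seed = 1L) {
  X <- as_cov_matrix(X)
  check_outcomes(time, event, nrow(X))
  stopifnot_scalar_prob(subsample, "subsample", 1e-6, 1 - 1e-6)
  stopifnot_scalar_prob(threshold, "threshold", 1e-6, 1 - 1e-6)
  cpgs <- setdiff(colnames(X), penalty_free)
  ucl <- unique(pair)
  idx_by <- split(seq_along(pair), match(pair, ucl))
  n_take <- max(1L, floor(subsample * length(ucl)))
  hits <- stats::setNames(numeric(length(cpgs)), cpgs)
  n_redrawn <- 0L
  for (r in seq_len(n_replicates)) {
    rep_seed <- derive_seed(seed, paste0("stab", r))
    sel <- NULL
    for (attempt in 1:100) {
      ix <- with_seed(rep_seed + attempt - 1L, {
        unlist(idx_by[sample.int(length(ucl), n_take)], use.names = FALSE)
      })
      if (sum(event[ix] == 1L) < 2L) {
        n_redrawn <- n_redrawn + 1L
        next
      }
      sel <- tryCatch({
        cv <- select_lambda_cv(X[ix, , drop = FALSE], time[ix], event[ix],
                               pair[ix], penalty_free, nfolds, rule,
                               seed = rep_seed)
        fit <- fit_lasso_cox_path(X[ix, , drop = FALSE], time[ix], event[ix],
                                  penalty_free)
        cf <- as.numeric(stats::coef(fit, s = cv$lambda, exact = FALSE))
        names(cf) <- rownames(stats::coef(fit))
        names(cf)[cf != 0 & names(cf) %in% cpgs]
      }, error = function(e) NULL)
      if (!is.null(sel)) break
      n_redrawn <- n_redrawn + 1L
    }
    if (is.null(sel)) {
      stop("stability selection: a replicate failed after 100 redraws")
    }
    hits[sel] <- hits[sel] + 1
  }
  freq <- hits / n_replicates
  structure(
    data.frame(cpg_id = cpgs, selection_frequency = unname(freq),
               selected = unname(freq > threshold), stringsAsFactors = FALSE),
    n_replicates = n_replicates, subsample = subsample,
    threshold = threshold, lambda_rule = rule, seed = seed,
    n_redrawn = n_redrawn,
    class = c("stability_result", "data.frame"))
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("Stability selection: %d replicates of %.0f%% pair subsamples (rule %s)\n",
              attr(x, "n_replicates"), 100 * attr(x, "subsample"),
              attr(x, "lambda_rule")))
  cat(sprintf("  %d of %d CpGs selected at frequency > %.2f\n",
              sum(x$selected), nrow(x), attr(x, "threshold")))
  print.data.frame(x[order(-x$selection_frequency), ][
    seq_len(min(10L, nrow(x))), ], digits = 3, row.names = FALSE)
  invisible(x)
}

#' Refit the selected predictor as an unpenalized Cox model
#'
#' Fits an ordinary multivariable Cox model on the selected CpGs plus sex
#' and age at blood sampling, with pair-robust standard errors; the linear
#' predictor is the risk score.
#'
#' @param selected_cpgs character vector of CpG ids (nonempty).
#' @param residuals samples x CpGs standardized residual matrix.
#' @param outcomes outcome table.
#' @param phenotypes phenotype table.
#' @return An object of class `predictor_model`: coefficient table (one row
#'   per CpG plus sex and age), the underlying `cox_fit`, the risk score
#'   per training sample, and the training Harrell's C.
#' @export
build_predictor <- function(selected_cpgs, residuals, outcomes, phenotypes) {
  if (length(selected_cpgs) == 0L) stop("empty CpG selection")
  ids <- rownames(residuals)
  X <- predictor_design(residuals, phenotypes, selected_cpgs)
  oc <- outcomes[match(ids, outcomes$individual_id), ]
  pair <- phenotypes$pair_id[match(ids, phenotypes$individual_id)]
  fit <- fit_cox(oc$time, oc$event, X, cluster = pair)
  score <- drop(X %*% fit$coefficients)
  names(score) <- ids
  ctrain <- harrells_c(oc$time, oc$event, score)
  structure(
    list(cpg_ids = selected_cpgs,
         coefficients = data.frame(
           term = names(fit$coefficients),
           log_hr = unname(fit$coefficients),
           hr = unname(fit$hr),
           robust_se = unname(fit$robust_se),
           p = unname(fit$p_value),
           stringsAsFactors = FALSE),
         fit = fit,
         risk_score = score,
         training_c = ctrain$c_index),
    class = "predictor_model")
}

#' @export
print.predictor_model <- function(x, ...) {
  cat(sprintf("Methylation risk predictor: %d CpGs + sex + age (training Harrell's C = %.3f)\n",
              length(x$cpg_ids), x$training_c))
  print(x$coefficients, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
predict.predictor_model <- function(object, residuals, phenotypes, ...) {
  X <- predictor_design(residuals, phenotypes, object$cpg_ids)
  drop(X %*% object$fit$coefficients)
}

#' Pair-blocked cross-validation of the predictor
#'
#' Assigns folds by twin pair, refits the full model (selected CpGs + sex +
#' age) and the basic model (sex + age) on each training split, pools the
#' out-of-fold risk scores, and computes Harrell's C for both models plus,
#' optionally, the IPCW time-varying AUC of each at the requested horizons.
#'
#' @inheritParams build_predictor
#' @param k number of folds (default 5).
#' @param horizons optional AUC evaluation times (years).
#' @param seed fold-assignment seed.
#' @return An object of class `cv_metrics`: `c_full`, `c_basic`, the pooled
#'   out-of-fold scores, and `auc_full` / `auc_basic` curves when horizons
#'   are given.
#' @export
cross_validate <- function(selected_cpgs, residuals, outcomes, phenotypes,
                           k = 5L, horizons = NULL, seed = 1L) {
  if (k < 2L) stop("k must be at least 2")
  ids <- rownames(residuals)
  X_full <- predictor_design(residuals, phenotypes, selected_cpgs)
  X_basic <- X_full[, c("sexF", "age"), drop = FALSE]
  oc <- outcomes[match(ids, outcomes$individual_id), ]
  pair <- phenotypes$pair_id[match(ids, phenotypes$individual_id)]
  fold <- pair_folds(pair, k, seed)
  oof_full <- oof_basic <- rep(NA_real_, length(ids))
  for (f in seq_len(k)) {
    tr <- fold != f
    te <- !tr
    if (sum(oc$event[tr] == 1L) < 1L) {
      stop(sprintf("fold %d training split has no events; reduce k", f))
    }
    fit_f <- fit_cox(oc$time[tr], oc$event[tr], X_full[tr, , drop = FALSE])
    fit_b <- fit_cox(oc$time[tr], oc$event[tr], X_basic[tr, , drop = FALSE])
    oof_full[te] <- drop(X_full[te, , drop = FALSE] %*% fit_f$coefficients)
    oof_basic[te] <- drop(X_basic[te, , drop = FALSE] %*% fit_b$coefficients)
  }
  out <- list(
    c_full = harrells_c(oc$time, oc$event, oof_full)$c_index,
    c_basic = harrells_c(oc$time, oc$event, oof_basic)$c_index,
    oof_score_full = stats::setNames(oof_full, ids),
    oof_score_basic = stats::setNames(oof_basic, ids),
    k = k, seed = seed)
  if (!is.null(horizons)) {
    out$auc_full <- time_varying_auc(oc$time, oc$event, oof_full, horizons)
    out$auc_basic <- time_varying_auc(oc$time, oc$event, oof_basic, horizons)
  }
  structure(out, class = "cv_metrics")
}

#' @export
print.cv_metrics <- function(x, ...) {
  cat(sprintf("%d-fold pair-blocked cross-validation\n", x$k))
  cat(sprintf("  Harrell's C: full model %.3f, basic (sex + age) %.3f\n",
              x$c_full, x$c_basic))
  if (!is.null(x$auc_full)) {
    cat("  time-varying AUC (full | basic):\n")
    for (i in seq_len(nrow(x$auc_full))) {
      cat(sprintf("    %5.1f yr: %.3f | %.3f\n", x$auc_full$horizon[i],
                  x$auc_full$auc[i], x$auc_basic$auc[i]))
    }
  }
  invisible(x)
}

#' Validate the predictor on an external cohort
#'
#' Applies the external-cohort protocol: model CpGs absent from the
#' external matrix are dropped (and listed), then Harrell's C is computed
#' for a Cox model refit on the external cohort with each available CpG
#' (plus sex and age), for the combined model with all available CpGs, and
#' for the basic sex + age model. The selection itself is never
#' re-estimated.
#'
#' @param model a `predictor_model`.
#' @param residuals,outcomes,phenotypes external-cohort tables.
#' @return An object of class `external_validation`: `c_combined`,
#'   `c_basic`, a per-CpG data frame `per_cpg` (`cpg_id`, `c_index`), the
#'   `dropped_cpgs`, and the number of external events.
#' @export
external_validate <- function(model, residuals, outcomes, phenotypes) {
  stopifnot(inherits(model, "predictor_model"))
  avail <- intersect(model$cpg_ids, colnames(residuals))
  dropped <- setdiff(model$cpg_ids, avail)
  if (length(avail) == 0L) {
    stop("no predictor CpGs are present in the external cohort")
  }
  if (length(dropped)) {
    message("external validation drops ", length(dropped),
            " model CpG(s) absent from the cohort: ",
            paste(dropped, collapse = ", "))
  }
  ids <- rownames(residuals)
  oc <- outcomes[match(ids, outcomes$individual_id), ]
  one_c <- function(cpgs) {
    X <- predictor_design(residuals, phenotypes, cpgs)
    f <- fit_cox(oc$time, oc$event, X)
    harrells_c(oc$time, oc$event, drop(X %*% f$coefficients))$c_index
  }
  Xb <- predictor_design(residuals, phenotypes, character(0))
  fb <- fit_cox(oc$time, oc$event, Xb)
  structure(
    list(c_combined = one_c(avail),
         c_basic = harrells_c(oc$time, oc$event,
                              drop(Xb %*% fb$coefficients))$c_index,
         per_cpg = data.frame(
           cpg_id = avail,
           c_index = vapply(avail, function(g) one_c(g), numeric(1)),
           stringsAsFactors = FALSE),
         dropped_cpgs = dropped,
         n_events = sum(oc$event == 1L)),
    class = "external_validation")
}

#' @export
print.external_validation <- function(x, ...) {
  cat(sprintf("External validation (%d events): combined Harrell's C = %.3f, basic = %.3f\n",
              x$n_events, x$c_combined, x$c_basic))
  if (length(x$dropped_cpgs)) {
    cat("  dropped CpGs:", paste(x$dropped_cpgs, collapse = ", "), "\n")
  }
  print(x$per_cpg, digits = 3, row.names = FALSE)
  invisible(x)
}
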
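# Preparation of methylation beta-values for modelling: least-squares
# imputation of missing cells, covariate/batch adjustment through a linear
# mixed model, residual standardization, and dichotomization at zero.

# Fixed-effect design shared by imputation and residualization: sex, age at
# blood sampling, zygosity, data set and the three cell fractions. Factors
# with a single observed level carry no information and are dropped.
meth_design <- function(phenotypes) {
  need <- c("sex", "age_at_entry", "zygosity", "data_set",
            "mono", "lymph", "eos")
  miss <- setdiff(need, names(phenotypes))
  if (length(miss)) {
    stop("phenotype table lacks columns: ", paste(miss, collapse = ", "))
  }
  terms <- c("sex", "zygosity", "data_set")
  terms <- terms[vapply(terms, function(v) {
    length(unique(phenotypes[[v]])) > 1L
  }, logical(1))]
  fml <- stats::reformulate(c(terms, "age_at_entry", "mono", "lymph", "eos"))
  stats::model.matrix(fml, data = phenotypes)
}

#' Impute missing beta-values by covariate regression
#'
#' Replaces each missing cell of the methylation matrix by its expected
#' value under a per-CpG least-squares regression on sex, age at blood
#' sampling, zygosity, data set and cell-type composition, fitted on the
#' CpG's observed samples. Observed cells are never modified; imputed values
#' are clamped to `[0, 1]`.
#'
#' @param methylation samples x CpGs beta matrix with `NA` for missing.
#' @param phenotypes phenotype table aligned with the matrix rows.
#' @return The completed matrix.
#' @export
impute_missing <- function(methylation, phenotypes) {
  if (nrow(methylation) != nrow(phenotypes)) {
    stop("methylation rows and phenotype rows differ")
  }
  if (!anyNA(methylation)) return(methylation)
  X <- meth_design(phenotypes)
  p <- ncol(X)
  todo <- which(colSums(is.na(methylation)) > 0L)
  for (j in todo) {
    y <- methylation[, j]
    obs <- !is.na(y)
    cpg <- colnames(methylation)[j]
    if (sum(obs) < p + 2L) {
      stop(sprintf("CpG '%s' has too few observed values (%d < %d) to impute",
                   cpg, sum(obs), p + 2L))
    }
    Xo <- X[obs, , drop = FALSE]
    if (qr(Xo)$rank < p) {
      stop(sprintf("imputation design is rank deficient on observed subset of CpG '%s'",
                   cpg))
    }
    fit <- stats::lm.fit(Xo, y[obs])
    pred <- drop(X[!obs, , drop = FALSE] %*% fit$coefficients)
    methylation[!obs, j] <- pmin(pmax(pred, 0), 1)
  }
  methylation
}

#' Residualize methylation on covariates and batch
#'
#' Fits, per CpG, a linear mixed model with sex, age at blood sampling,
#' zygosity, data set and cell-type composition as fixed effects and random
#' intercepts for sample plate and array position, by restricted maximum
#' likelihood. The residual (observed minus fixed-effect fit minus predicted
#' random effects) is standardized to sample standard deviation one; these
#' standardized residuals are the inputs of every downstream model. A CpG
#' whose mixed-model fit fails to converge falls back to a fixed-effects-only
#' least-squares fit, with a warning naming the CpGs affected.
#'
#' @param methylation complete samples x CpGs beta matrix (no `NA`).
#' @param phenotypes phenotype table with `plate` and `position` columns in
#'   addition to the fixed-effect covariates.
#' @return Samples x CpGs matrix of standardized residuals, with attribute
#'   `"ols_fallback"` listing CpGs fitted without random effects.
#' @export
residualize <- function(methylation, phenotypes) {
  if (anyNA(methylation)) {
    stop("methylation matrix has missing values; run impute_missing() first")
  }
  if (nrow(methylation) != nrow(phenotypes)) {
    stop("methylation rows and phenotype rows differ")
  }
  sds <- col_sds(methylation)
  if (any(sds == 0)) {
    stop("constant CpG(s): ",
         paste(colnames(methylation)[sds == 0], collapse = ", "))
  }
  X <- meth_design(phenotypes)
  re_terms <- c()
  if (length(unique(phenotypes$plate)) > 1L) re_terms <- c(re_terms, "(1 | plate)")
  if (length(unique(phenotypes$position)) > 1L) re_terms <- c(re_terms, "(1 | position)")

  res <- matrix(NA_real_, nrow(methylation), ncol(methylation),
                dimnames = dimnames(methylation))
  fallback <- character(0)

  if (length(re_terms) == 0L) {
    # single plate/position level: the model is pure fixed effects
    qrX <- qr(X)
    res[] <- qr.resid(qrX, methylation)
  } else {
    df <- phenotypes
    df$.y <- methylation[, 1L]
    fix_terms <- c("sex", "zygosity", "data_set")
    fix_terms <- fix_terms[vapply(fix_terms, function(v) {
      length(unique(phenotypes[[v]])) > 1L
    }, logical(1))]
    fml <- stats::as.formula(paste(
      ".y ~", paste(c(fix_terms, "age_at_entry", "mono", "lymph", "eos",
                      re_terms), collapse = " + ")))
    ctrl <- lme4::lmerControl(
      calc.derivs = FALSE,
      check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4))
    base_fit <- NULL
    qrX <- qr(X)
    for (j in seq_len(ncol(methylation))) {
      y <- methylation[, j]
      fit <- tryCatch({
        withCallingHandlers({
          if (is.null(base_fit)) {
            df$.y <- y
            base_fit <- lme4::lmer(fml, data = df, REML = TRUE,
                                   control = ctrl)
            base_fit
          } else {
            lme4::refit(base_fit, newresp = y)
          }
        }, warning = function(w) {
          if (grepl("conv", conditionMessage(w), ignore.case = TRUE)) {
            stop("mixed-model fit did not converge", call. = FALSE)
          }
          invokeRestart("muffleWarning")
        }, message = function(m) {
          # a singular (zero) variance component is a valid boundary fit
          if (grepl("singular|converge", conditionMessage(m))) {
            invokeRestart("muffleMessage")
          }
        })
      }, error = function(e) NULL)
      if (is.null(fit)) {
        fallback <- c(fallback, colnames(methylation)[j])
        res[, j] <- qr.resid(qrX, y)
      } else {
        res[, j] <- y - stats::fitted(fit)
      }
    }
    if (length(fallback)) {
      warning(sprintf(
        "mixed model did not converge for %d CpG(s); fixed-effects-only fit used: %s",
        length(fallback), paste(utils::head(fallback, 5L), collapse = ", ")))
    }
  }

  rsd <- col_sds(res)
  if (any(rsd == 0)) {
    stop("zero residual variance for CpG(s): ",
         paste(colnames(methylation)[rsd == 0], collapse = ", "))
  }
  res <- sweep(res, 2L, rsd, `/`)
  attr(res, "ols_fallback") <- fallback
  res
}

#' Dichotomize standardized residuals at zero
#'
#' High methylation is a standardized residual greater than or equal to
#' zero; a residual of exactly zero is assigned to the high group, a fixed
#' convention required for reproducibility.
#'
#' @param residuals samples x CpGs matrix of standardized residuals.
#' @return Integer matrix of the same shape with entries 0 (low) / 1 (high).
#' @export
dichotomize <- function(residuals) {
  out <- (residuals >= 0) + 0L
  dimnames(out) <- dimnames(residuals)
  out
}
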
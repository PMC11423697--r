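# Shared fixtures and independent oracles, all built in code.

# Small cohort without nuisance structure: latent signal passes to the beta
# scale through an affine map only, so scaled beta-values stand in for
# standardized residuals without running the mixed model.
plain_config <- function(n_pairs, n_cpgs, n_causal = 0,
                         causal_log_shr = numeric(0), seed = 1,
                         base_rate_cause1 = 0.0013, base_rate_death = 0.03,
                         ...) {
  cohort_config(n_pairs = n_pairs, n_cpgs = n_cpgs, n_causal = n_causal,
                causal_log_shr = causal_log_shr,
                base_rate_cause1 = base_rate_cause1,
                base_rate_death = base_rate_death,
                missing_rate = 0, plate_sd = 0, cell_effect_sd = 0,
                seed = seed, ...)
}

scale_cols <- function(m) {
  out <- scale(m)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

# Independent subjects with exponential event-1 times; x is the only
# covariate, with true log hazard ratio b.
sim_simple_cox <- function(n, b = 0, cens_rate = 0.3, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  t_ev <- rexp(n, rate = 0.2 * exp(b * x))
  t_cn <- rexp(n, rate = cens_rate)
  data.frame(time = pmin(t_ev, t_cn),
             event = as.integer(t_ev <= t_cn),
             x = x)
}

# Brute-force 1-D Cox partial log-likelihood (Breslow-free: continuous
# times assumed, no ties).
cox_loglik_1d <- function(b, time, event, x) {
  ll <- 0
  for (i in which(event == 1L)) {
    at_risk <- time >= time[i]
    ll <- ll + b * x[i] - log(sum(exp(b * x[at_risk])))
  }
  ll
}

# Exhaustive O(n^2) Harrell's C: comparable pairs under censoring, ties in
# score get half credit. event: 1 = event of interest, otherwise censored.
brute_force_c <- function(time, event, score) {
  conc <- disc <- tied <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    if (event[i] != 1L) next
    for (j in seq_len(n)) {
      if (j == i) next
      comparable <- time[j] > time[i] ||
        (time[j] == time[i] && event[j] != 1L)
      if (!comparable) next
      if (score[i] > score[j]) conc <- conc + 1
      else if (score[i] < score[j]) disc <- disc + 1
      else tied <- tied + 1
    }
  }
  list(c_index = (conc + 0.5 * tied) / (conc + disc + tied),
       conc = conc, disc = disc, tied = tied)
}

# Plain empirical cumulative/dynamic AUC at horizon t (no censoring):
# cases fail from cause 1 by t, controls are everyone else still under
# observation or failing from the competing cause.
brute_force_auc <- function(time, event, score, t) {
  case <- which(time <= t & event == 1L)
  ctrl <- c(which(time > t), which(time <= t & event == 2L))
  num <- 0
  for (i in case) {
    num <- num + sum((score[i] > score[ctrl]) + 0.5 * (score[i] == score[ctrl]))
  }
  num / (length(case) * length(ctrl))
}

# 1-D REML grid/profile oracle for y = Xb + Z u + e with a single random
# intercept factor. Returns the standardized conditional residuals.
reml_oracle_residuals <- function(y, X, z_factor) {
  Z <- model.matrix(~ 0 + z_factor)
  n <- nrow(X)
  p <- ncol(X)
  crit <- function(theta) {
    V <- diag(n) + theta * tcrossprod(Z)
    Vi <- solve(V)
    XtVi <- crossprod(X, Vi)
    b <- solve(XtVi %*% X, XtVi %*% y)
    r <- y - X %*% b
    q <- drop(crossprod(r, Vi %*% r))
    determinant(V)$modulus + determinant(XtVi %*% X)$modulus +
      (n - p) * log(q)
  }
  theta <- optimize(crit, c(0, 50), tol = 1e-10)$minimum
  V <- diag(n) + theta * tcrossprod(Z)
  Vi <- solve(V)
  XtVi <- crossprod(X, Vi)
  b <- solve(XtVi %*% X, XtVi %*% y)
  r <- drop(y - X %*% b)
  u <- theta * crossprod(Z, Vi %*% r)
  e <- drop(r - Z %*% u)
  e / sd(e)
}

# Phenotype table for toy designs where the mixed model is exercised
# directly.
toy_phenotypes <- function(n, n_plates = 1, n_positions = 1, seed = 1) {
  set.seed(seed)
  data.frame(
    individual_id = sprintf("S%03d", seq_len(n)),
    pair_id = sprintf("P%03d", rep(seq_len(ceiling(n / 2)), each = 2)[seq_len(n)]),
    zygosity = "MZ",
    sex = rep_len(c("F", "M"), n),
    age_at_entry = runif(n, 50, 80),
    data_set = "set1",
    mono = runif(n, 0.05, 0.12),
    lymph = runif(n, 0.25, 0.45),
    eos = runif(n, 0.01, 0.05),
    plate = factor(rep_len(paste0("plate", seq_len(n_plates)), n)),
    position = factor(rep_len(paste0("pos", seq_len(n_positions)), n)),
    stringsAsFactors = FALSE
  )
}
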
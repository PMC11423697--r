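# Epigenome-wide screen: per-CpG dual-model survival regressions (Cox
# cause-specific and Fine-Gray subdistribution), Benjamini-Hochberg control
# per scale, the dual unadjusted-p rule, and the proportional-hazards
# filter on the significant set.

#' EWAS screen configuration
#'
#' @param fdr_threshold Benjamini-Hochberg FDR cut-off, applied on both the
#'   hazard and the risk scale (default 0.05).
#' @param dual_p_threshold unadjusted p-value bound that must hold
#'   simultaneously on both scales (default 1e-7, calibrated to a
#'   genome-scale screen of ~450,000 sites; simulations at desk scale use a
#'   proportionally relaxed value through this field).
#' @param ph_alpha level of the scaled Schoenfeld test used to filter
#'   significant CpGs (default 0.05).
#' @param event_of_interest event code screened (default 1).
#' @return An object of class `ewas_config`.
#' @export
ewas_config <- function(fdr_threshold = 0.05, dual_p_threshold = 1e-7,
                        ph_alpha = 0.05, event_of_interest = 1L) {
  for (v in c(fdr_threshold, dual_p_threshold, ph_alpha)) {
    stopifnot_scalar_prob(v, "threshold", 1e-300, 1)
  }
  structure(list(fdr_threshold = fdr_threshold,
                 dual_p_threshold = dual_p_threshold,
                 ph_alpha = ph_alpha,
                 event_of_interest = as.integer(event_of_interest)),
            class = "ewas_config")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment; a thin, named wrapper around
#' [stats::p.adjust()] so every stage uses one documented procedure.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values (q-values), elementwise at least `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Run the per-CpG dual-model survival screen
#'
#' For every CpG, fits a single-covariate pair-clustered Cox model (hazard
#' scale) and a pair-clustered Fine-Gray model (risk scale) of the
#' standardized methylation residual on time to malignancy, adjusts each
#' scale's p-values by Benjamini-Hochberg across all CpGs, flags CpGs
#' significant when the FDR rule holds on both scales and both unadjusted
#' p-values fall below `dual_p_threshold`, and runs the scaled Schoenfeld
#' proportional-hazards test on the significant CpGs only. Covariates are
#' not re-entered per CpG: the residualization already removed them.
#'
#' @param residuals samples x CpGs matrix of standardized residuals with
#'   sample ids as row names.
#' @param outcomes data frame with `individual_id`, `time`, `event`.
#' @param phenotypes phenotype table carrying `individual_id` and `pair_id`.
#' @param config an [ewas_config()].
#' @return An object of class `ewas_result`: a data frame with one row per
#'   CpG (`cpg_id`, `hr`, `hr_p`, `shr`, `shr_p`, `fdr_hr`, `fdr_shr`,
#'   `ph_p`, `significant`, `ph_ok`), ordered by `shr_p`.
#' @export
run_ewas <- function(residuals, outcomes, phenotypes, config = ewas_config()) {
  if (ncol(residuals) == 0L || nrow(residuals) == 0L) {
    stop("empty residual matrix")
  }
  ids <- rownames(residuals)
  if (is.null(ids)) stop("residual matrix must carry sample ids as row names")
  bad <- setdiff(ids, outcomes$individual_id)
  bad2 <- setdiff(ids, phenotypes$individual_id)
  if (length(bad) || length(bad2)) {
    stop("sample ids missing from outcome/phenotype tables: ",
         paste(unique(c(bad, bad2)), collapse = ", "))
  }
  oc <- outcomes[match(ids, outcomes$individual_id), ]
  pair <- phenotypes$pair_id[match(ids, phenotypes$individual_id)]
  time <- oc$time
  event <- oc$event
  status <- as.integer(event == config$event_of_interest)
  if (sum(status) < 1L) stop("no events of the cause of interest")

  # the subdistribution risk-set expansion depends only on the outcomes;
  # build it once and re-attach each CpG column
  fgd <- finegray_expand(time, event)
  fg_base <- data.frame(fgd[c("fgstart", "fgstop", "fgstatus", "fgwt")])
  fg_base$.cluster <- pair[fgd$orig_row]

  n_cpg <- ncol(residuals)
  hr <- hr_p <- shr <- shr_p <- rep(NA_real_, n_cpg)
  cox_fits <- vector("list", n_cpg)
  d_cox <- data.frame(.time = time, .status = status, .cluster = pair, x = 0)
  for (j in seq_len(n_cpg)) {
    d_cox$x <- residuals[, j]
    cf <- quiet_cox(survival::coxph(survival::Surv(.time, .status) ~ x,
                                    data = d_cox, cluster = .cluster,
                                    ties = "efron"))
    hr[j] <- exp(cf$coefficients[["x"]])
    zc <- cf$coefficients[["x"]] / sqrt(cf$var[1, 1])
    hr_p[j] <- 2 * stats::pnorm(-abs(zc))
    cox_fits[[j]] <- cf

    fg_base$x <- residuals[fgd$orig_row, j]
    ff <- quiet_cox(survival::coxph(
      survival::Surv(fgstart, fgstop, fgstatus) ~ x, data = fg_base,
      weights = fgwt, cluster = .cluster, ties = "breslow"))
    shr[j] <- exp(ff$coefficients[["x"]])
    zf <- ff$coefficients[["x"]] / sqrt(ff$var[1, 1])
    shr_p[j] <- 2 * stats::pnorm(-abs(zf))
  }

  fdr_hr <- bh_adjust(hr_p)
  fdr_shr <- bh_adjust(shr_p)
  significant <- fdr_hr < config$fdr_threshold &
    fdr_shr < config$fdr_threshold &
    hr_p < config$dual_p_threshold & shr_p < config$dual_p_threshold

  ph_p <- rep(NA_real_, n_cpg)
  for (j in which(significant)) {
    ph_p[j] <- tryCatch(
      survival::cox.zph(cox_fits[[j]], transform = "km",
                        global = FALSE)$table[1L, "p"],
      error = function(e) NA_real_)
  }
  ph_ok <- ifelse(significant, is.na(ph_p) | ph_p >= config$ph_alpha, NA)

  tab <- data.frame(cpg_id = colnames(residuals), hr = hr, hr_p = hr_p,
                    shr = shr, shr_p = shr_p, fdr_hr = fdr_hr,
                    fdr_shr = fdr_shr, ph_p = ph_p,
                    significant = significant, ph_ok = ph_ok,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$shr_p, tab$cpg_id), ]
  rownames(tab) <- NULL
  structure(tab, config = config, n_events = sum(status),
            class = c("ewas_result", "data.frame"))
}

#' @export
print.ewas_result <- function(x, n = 10L, ...) {
  cat(sprintf("EWAS screen: %d CpGs, %d events; %d significant, %d passing the PH filter\n",
              nrow(x), attr(x, "n_events"), sum(x$significant),
              sum(x$significant & x$ph_ok, na.rm = TRUE)))
  print.data.frame(utils::head(x, n), digits = 4)
  if (nrow(x) > n) cat(sprintf("... %d more rows\n", nrow(x) - n))
  invisible(x)
}

#' Select validated markers from an EWAS table
#'
#' Keeps CpGs flagged significant whose proportional-hazards test did not
#' reject, preserving the table's (stable, `shr_p`-ordered) row order.
#'
#' @param table an `ewas_result` from [run_ewas()].
#' @param config the [ewas_config()] used (defaults to the table's own).
#' @return Character vector of CpG ids.
#' @export
select_markers <- function(table, config = attr(table, "config")) {
  stopifnot(is.data.frame(table))
  keep <- table$significant & !is.na(table$ph_ok) & table$ph_ok
  table$cpg_id[which(keep)]
}
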
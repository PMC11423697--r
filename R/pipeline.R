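# File contracts and pipeline orchestration. Matrices travel as (optionally
# gzipped) TSV with CpGs in rows and a header of sample ids; phenotype,
# outcome and result tables as CSV with fixed column names; the fitted
# predictor as JSON. "NA" is the missing-value token throughout.

open_maybe_gz <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write / read a methylation matrix (TSV, CpGs in rows)
#'
#' @param methylation samples x CpGs matrix.
#' @param path output path; a `.gz` suffix gzip-compresses.
#' @return `write_methylation()` returns `path` invisibly;
#'   `read_methylation()` returns the samples x CpGs matrix.
#' @export
write_methylation <- function(methylation, path) {
  m <- t(methylation)
  df <- data.frame(cpg_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  con <- open_maybe_gz(path, "wt")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_methylation
#' @export
read_methylation <- function(path) {
  con <- open_maybe_gz(path, "rt")
  on.exit(close(con))
  df <- utils::read.delim(con, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$cpg_id
  t(m)
}

pheno_columns <- c("individual_id", "pair_id", "zygosity", "sex",
                   "age_at_entry", "data_set", "mono", "lymph", "eos",
                   "plate", "position")

#' Write / read the phenotype table (CSV)
#' @param phenotypes phenotype data frame.
#' @param path file path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  miss <- setdiff(pheno_columns, names(phenotypes))
  if (length(miss)) stop("phenotype table lacks: ", paste(miss, collapse = ", "))
  utils::write.csv(phenotypes, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(pheno_columns, names(df))
  if (length(miss)) stop("phenotype file lacks: ", paste(miss, collapse = ", "))
  df$plate <- factor(df$plate)
  df$position <- factor(df$position)
  df
}

#' Write / read the outcome table (CSV)
#'
#' Event codes are validated on read: anything outside {0, 1, 2} raises an
#' error naming the offending row.
#'
#' @param outcomes data frame with `individual_id`, `time`, `event`.
#' @param path file path.
#' @export
write_outcomes <- function(outcomes, path) {
  validate_outcome_table(outcomes)
  utils::write.csv(outcomes[c("individual_id", "time", "event")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_outcomes
#' @export
read_outcomes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_outcome_table(df)
  df
}

validate_outcome_table <- function(df) {
  miss <- setdiff(c("individual_id", "time", "event"), names(df))
  if (length(miss)) stop("outcome table lacks: ", paste(miss, collapse = ", "))
  bad <- which(!(df$event %in% 0:2))
  if (length(bad)) {
    stop(sprintf("invalid event code at row %d (individual %s): %s",
                 bad[1], df$individual_id[bad[1]], df$event[bad[1]]))
  }
  if (any(df$time <= 0)) stop("nonpositive follow-up time in outcome table")
  if (anyDuplicated(df$individual_id)) {
    stop("duplicated individual_id in outcome table")
  }
  invisible(df)
}

#' Serialize a fitted predictor model to JSON
#' @param model a `predictor_model`.
#' @param path output path.
#' @export
write_predictor_json <- function(model, path) {
  jsonlite::write_json(
    list(cpg_ids = model$cpg_ids,
         coefficients = model$coefficients,
         training_c = model$training_c),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Pipeline configuration
#'
#' @param simulate a [cohort_config()] to generate the cohort, or `NULL`
#'   to read it from `paths`.
#' @param paths named list with `methylation`, `phenotypes`, `outcomes`
#'   (ignored when `simulate` is given).
#' @param ewas an [ewas_config()].
#' @param ate_horizon,ate_n_boot G-computation settings.
#' @param predictor named list: `candidate_p` (dual unadjusted-p bound for
#'   the LASSO candidate set; defaults to the EWAS `dual_p_threshold`),
#'   `n_replicates`, `subsample`, `threshold`, `rule`, `k`,
#'   `auc_horizons`.
#' @param external optional [cohort_config()] for an independent synthetic
#'   validation cohort.
#' @param seed global pipeline seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, paths = NULL,
                            ewas = ewas_config(),
                            ate_horizon = 5, ate_n_boot = 200L,
                            predictor = list(), external = NULL,
                            seed = 1L) {
  if (is.null(simulate)) {
    need <- c("methylation", "phenotypes", "outcomes")
    miss <- setdiff(need, names(paths))
    if (length(miss)) {
      stop("config lacks input path(s): ", paste(miss, collapse = ", "))
    }
    absent <- unlist(paths[need])[!file.exists(unlist(paths[need]))]
    if (length(absent)) {
      stop("input file(s) not found: ", paste(absent, collapse = ", "))
    }
  }
  pdef <- list(candidate_p = ewas$dual_p_threshold, n_replicates = 1000L,
               subsample = 0.5, threshold = 0.8, rule = "min_plus_half_se",
               k = 5L, auc_horizons = NULL)
  pdef[names(predictor)] <- predictor
  structure(list(simulate = simulate, paths = paths, ewas = ewas,
                 ate_horizon = ate_horizon, ate_n_boot = ate_n_boot,
                 predictor = pdef, external = external,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order -- simulate (optional), preprocess, EWAS,
#' causal/twin analyses (ATE, ICC, matched), predictor, external validation
#' (optional) -- writing each stage's tables under `out_dir` together with
#' a manifest of output files, their MD5 hashes, the seed and wall times.
#' Reruns with an identical configuration reproduce identical hashes.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if absent).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest data frame.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  note <- function(stage, files, secs) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, file = files,
      md5 = unname(tools::md5sum(files)),
      seed = config$seed, seconds = round(secs, 2),
      stringsAsFactors = FALSE)
  }
  timed <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- force(expr)
    list(value = v, secs = proc.time()[["elapsed"]] - t0)
  }

  # -- stage 1: simulate or load ------------------------------------------
  st <- timed({
    if (!is.null(config$simulate)) {
      sim <- simulate_cohort(config$simulate)
      list(meth = sim$methylation, pheno = sim$phenotypes,
           outcomes = sim$outcomes, truth = sim$truth)
    } else {
      list(meth = read_methylation(config$paths$methylation),
           pheno = read_phenotypes(config$paths$phenotypes),
           outcomes = read_outcomes(config$paths$outcomes),
           truth = NULL)
    }
  })
  dat <- st$value
  f_meth <- file.path(out_dir, "methylation.tsv.gz")
  f_ph <- file.path(out_dir, "phenotypes.csv")
  f_oc <- file.path(out_dir, "outcomes.csv")
  write_methylation(dat$meth, f_meth)
  write_phenotypes(dat$pheno, f_ph)
  write_outcomes(dat$outcomes, f_oc)
  files <- c(f_meth, f_ph, f_oc)
  if (!is.null(dat$truth)) {
    f_tr <- file.path(out_dir, "truth.csv")
    utils::write.csv(dat$truth, f_tr, row.names = FALSE)
    files <- c(files, f_tr)
  }
  note(if (is.null(config$simulate)) "load" else "simulate", files, st$secs)

  # -- stage 2: preprocess -------------------------------------------------
  st <- timed({
    complete <- impute_missing(dat$meth, dat$pheno)
    residualize(complete, dat$pheno)
  })
  resid <- st$value
  f_res <- file.path(out_dir, "residuals.tsv.gz")
  write_methylation(resid, f_res)
  note("preprocess", f_res, st$secs)

  # -- stage 3: EWAS -------------------------------------------------------
  st <- timed(run_ewas(resid, dat$outcomes, dat$pheno, config$ewas))
  etab <- st$value
  f_ewas <- file.path(out_dir, "ewas_results.csv")
  utils::write.csv(as.data.frame(etab), f_ewas, row.names = FALSE)
  markers <- select_markers(etab)
  f_mark <- file.path(out_dir, "markers.txt")
  writeLines(markers, f_mark)
  note("ewas", c(f_ewas, f_mark), st$secs)

  # -- stage 4: causal / twin analyses ------------------------------------
  st <- timed({
    ids <- rownames(resid)
    oc <- dat$outcomes[match(ids, dat$outcomes$individual_id), ]
    pair <- dat$pheno$pair_id[match(ids, dat$pheno$individual_id)]
    expo <- dichotomize(resid)
    ate <- lapply(markers, function(g) {
      ate_risk_ratio(expo[, g], oc$time, oc$event, pair,
                     horizon = config$ate_horizon,
                     n_boot = config$ate_n_boot,
                     seed = derive_seed(config$seed, paste0("ate", g)))
    })
    icc <- if (length(markers)) {
      icc_by_zygosity(resid, dat$pheno, markers)
    } else NULL
    matched <- if (length(markers)) {
      tryCatch(matched_pair_analysis(resid[, markers, drop = FALSE],
                                     dat$outcomes, dat$pheno),
               error = function(e) NULL)
    } else NULL
    list(ate = ate, icc = icc, matched = matched)
  })
  causal <- st$value
  f_ate <- file.path(out_dir, "ate_results.csv")
  ate_df <- if (length(causal$ate)) {
    cbind(cpg_id = markers,
          do.call(rbind, lapply(causal$ate, function(a) {
            data.frame(risk_high = a$risk_high, risk_low = a$risk_low,
                       ate_ratio = a$ate_ratio, ci_lower = a$ci_lower,
                       ci_upper = a$ci_upper, p = a$p_value)
          })))
  } else {
    data.frame(cpg_id = character(0), risk_high = numeric(0),
               risk_low = numeric(0), ate_ratio = numeric(0),
               ci_lower = numeric(0), ci_upper = numeric(0), p = numeric(0))
  }
  utils::write.csv(ate_df, f_ate, row.names = FALSE)
  f_icc <- file.path(out_dir, "icc_results.csv")
  utils::write.csv(if (is.null(causal$icc)) data.frame() else
    as.data.frame(causal$icc), f_icc, row.names = FALSE)
  note("causal_twin", c(f_ate, f_icc), st$secs)

  # -- stage 5: predictor --------------------------------------------------
  pc <- config$predictor
  cand <- as.data.frame(etab)
  cand <- cand$cpg_id[cand$hr_p < pc$candidate_p & cand$shr_p < pc$candidate_p]
  predictor <- NULL
  cv <- NULL
  st <- timed({
    if (length(cand) >= 1L) {
      ids <- rownames(resid)
      oc <- dat$outcomes[match(ids, dat$outcomes$individual_id), ]
      pair <- dat$pheno$pair_id[match(ids, dat$pheno$individual_id)]
      X <- predictor_design(resid, dat$pheno, cand)
      stab <- stability_selection(
        X, oc$time, oc$event, pair, n_replicates = pc$n_replicates,
        subsample = pc$subsample, threshold = pc$threshold, rule = pc$rule,
        seed = derive_seed(config$seed, "stability"))
      sel <- stab$cpg_id[stab$selected]
      if (length(sel) == 0L) {
        # keep the single most stable CpG so downstream validation runs
        sel <- stab$cpg_id[which.max(stab$selection_frequency)]
      }
      model <- build_predictor(sel, resid, dat$outcomes, dat$pheno)
      cvm <- cross_validate(sel, resid, dat$outcomes, dat$pheno,
                            k = pc$k, horizons = pc$auc_horizons,
                            seed = derive_seed(config$seed, "cv"))
      list(stab = stab, model = model, cv = cvm)
    } else {
      NULL
    }
  })
  if (!is.null(st$value)) {
    predictor <- st$value$model
    cv <- st$value$cv
    f_stab <- file.path(out_dir, "stability_frequencies.csv")
    utils::write.csv(as.data.frame(st$value$stab), f_stab, row.names = FALSE)
    f_model <- file.path(out_dir, "predictor_model.json")
    write_predictor_json(predictor, f_model)
    f_cv <- file.path(out_dir, "cv_metrics.csv")
    utils::write.csv(data.frame(model = c("full", "basic"),
                                harrells_c = c(cv$c_full, cv$c_basic)),
                     f_cv, row.names = FALSE)
    files <- c(f_stab, f_model, f_cv)
    if (!is.null(cv$auc_full)) {
      f_auc <- file.path(out_dir, "auc_curve.csv")
      utils::write.csv(as.data.frame(cv$auc_full), f_auc, row.names = FALSE)
      files <- c(files, f_auc)
    }
    note("predictor", files, st$secs)
  } else {
    f_skip <- file.path(out_dir, "predictor_skipped.txt")
    writeLines("no CpG met the candidate p threshold", f_skip)
    note("predictor", f_skip, st$secs)
  }

  # -- stage 6: external validation ---------------------------------------
  st <- timed({
    if (!is.null(config$external) && !is.null(predictor)) {
      ext <- simulate_cohort(config$external)
      ext_complete <- impute_missing(ext$methylation, ext$phenotypes)
      ext_resid <- residualize(ext_complete, ext$phenotypes)
      external_validate(predictor, ext_resid, ext$outcomes, ext$phenotypes)
    } else NULL
  })
  if (!is.null(st$value)) {
    f_ext <- file.path(out_dir, "external_validation.csv")
    utils::write.csv(data.frame(metric = c("c_combined", "c_basic"),
                                value = c(st$value$c_combined,
                                          st$value$c_basic)),
                     f_ext, row.names = FALSE)
    note("external_validate", f_ext, st$secs)
  } else {
    f_ext <- file.path(out_dir, "external_validation_skipped.txt")
    writeLines("no external cohort configured or no predictor built", f_ext)
    note("external_validate", f_ext, st$secs)
  }

  manifest <- do.call(rbind, manifest)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(list(ewas = etab, markers = markers, causal = causal,
                 predictor = predictor, cv = cv,
                 external = st$value, manifest = manifest,
                 out_dir = out_dir))
}
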
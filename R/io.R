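#' Write a cohort table to CSV
#'
#' One row per subject: metadata columns (`subject_id`, `group`, `age`,
#' `sex`, `co2_percent`) followed by the paired `alv_*` / `env_*`
#' concentration blocks. RFC-4180 dialect with a header row; values keep
#' full double precision.
#'
#' @param cohort A `breath_cohort` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read and validate a cohort table
#'
#' Reads a CSV written by [write_cohort()] (or externally prepared with
#' the same header layout), checks the required columns, verifies every
#' concentration is numeric and non-negative, and reports offending rows
#' by index.
#'
#' @param path CSV file path.
#' @return A validated `breath_cohort` data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("subject_id", "group", "age", "sex", "co2_percent")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("cohort file lacks required column(s): ",
         paste(missing, collapse = ", "))
  conc_cols <- grep("^(alv|env)_", names(df), value = TRUE)
  if (length(conc_cols) == 0)
    stop("cohort file has no alv_*/env_* concentration columns")
  alv <- sub("^alv_", "", grep("^alv_", names(df), value = TRUE))
  env <- sub("^env_", "", grep("^env_", names(df), value = TRUE))
  if (!identical(alv, env))
    stop("alveolar and environmental blocks do not pair up ",
         "(same compounds, same order, required)")
  for (cc in conc_cols) {
    v <- df[[cc]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))
      stop("non-numeric concentration in column ", cc, ", row(s) ",
           paste(head(bad, 5), collapse = ", "))
    }
    if (any(v < 0, na.rm = TRUE)) {
      bad <- which(v < 0)
      stop("negative concentration in column ", cc, ", row(s) ",
           paste(head(bad, 5), collapse = ", "))
    }
  }
  class(df) <- c("breath_cohort", "data.frame")
  df
}

# ---------------------------------------------------------------------------
# Configuration

#' Assemble a pipeline configuration
#'
#' @param contrast `"lung_adk"`, `"lung_sqcc"` or `"colon_adk"`.
#' @param co2_threshold CO2 QC threshold (percent).
#' @param alpha Environmental-exclusion significance level.
#' @param nfolds,grid_size Solver cross-validation settings.
#' @param bootstrap_B Bootstrap resamples for coefficient CIs.
#' @param min_sensitivity Lower sensitivity bound (percent) of the
#'   reported performance table.
#' @param seed Integer seed (stamped into every artifact).
#' @param cohort_path Optional CSV to ingest; if `NULL` a cohort is
#'   simulated from [default_cohort_spec()].
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(contrast = "lung_adk", co2_threshold = 2.0,
                            alpha = 0.05, nfolds = 50, grid_size = 50,
                            bootstrap_B = 200, min_sensitivity = 85,
                            seed = 1L, cohort_path = NULL) {
  stopifnot(co2_threshold > 0, alpha > 0, nfolds > 0, grid_size > 0,
            bootstrap_B > 0)
  structure(list(contrast = contrast, co2_threshold = co2_threshold,
                 alpha = alpha, nfolds = nfolds, grid_size = grid_size,
                 bootstrap_B = bootstrap_B,
                 min_sensitivity = min_sensitivity,
                 seed = as.integer(seed), cohort_path = cohort_path),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the [pipeline_config()] arguments.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    warning("ignoring unknown config key(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  do.call(pipeline_config, raw[intersect(names(raw), known)])
}

# FNV-1a 32-bit hash of a string; used to stamp artifacts with a
# reproducible fingerprint of the configuration that produced them.
#' @noRd
fnv1a_hash <- function(s) {
  h <- 2166136261
  m <- 16777619
  for (b in utf8ToInt(s)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit modular multiply in doubles, split to stay exact
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * m) %% 65536) * 65536 + lo * m) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_hash <- function(config) {
  fnv1a_hash(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, null = "null"))
}

#' Run the full discriminant pipeline
#'
#' Simulate (or ingest) a cohort, apply both QC stages, fit the iterated
#' adaptive LASSO for the configured contrast, compute bootstrap
#' coefficient intervals, and evaluate the model in-sample (ROC, AUC
#' with DeLong SE, sensitivity/specificity table, standardized compound
#' profile). Every artifact is stamped with the seed and a hash of the
#' configuration. Stage decisions (discarded samples, excluded
#' compounds, selected penalties, screened variables, AUC) are logged
#' via `message()`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, `qc_report.json`,
#'   `model.json` and `evaluation.json` are written there.
#' @return List with `cohort`, `qc`, `model`, `cis`, `roc`,
#'   `performance`, `profile`, `provenance`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$cohort_path) && !file.exists(config$cohort_path))
    stop("input cohort not found: ", config$cohort_path)
  cohort <- if (is.null(config$cohort_path)) {
    generate_cohort(default_cohort_spec(config$contrast,
                                        seed = config$seed))
  } else {
    read_cohort(config$cohort_path)
  }
  qc <- qc_cohort(cohort, threshold = config$co2_threshold,
                  alpha = config$alpha)
  message("QC: ", nrow(qc$retained), " samples retained, ",
          length(qc$excluded_compounds),
          " compounds excluded for environmental background")

  design <- build_design(qc$retained, qc$retained_compounds,
                         case_groups = config$contrast)
  model <- fit_iterated(design$x, design$y, nfolds = config$nfolds,
                        grid_size = config$grid_size, seed = config$seed)
  message("screening lambda ", format(model$stage1_lambda), "; ",
          length(model$stage1_selected), " variables screened in: ",
          paste(model$stage1_selected, collapse = ", "))
  cis <- bootstrap_cis(design$x, design$y, model, B = config$bootstrap_B,
                       seed = config$seed)

  prob <- predict(model, design$x)
  roc <- roc_analysis(prob, design$y)
  message("in-sample AUC ", sprintf("%.4f", roc$auc))
  perf <- performance_table(roc, min_sensitivity = config$min_sensitivity)

  cmp <- intersect(model$stage1_selected, qc$retained_compounds)
  prof <- if (length(cmp)) {
    standardized_profile(
      as.matrix(qc$retained[qc$retained$group == config$contrast,
                            paste0("alv_", cmp), drop = FALSE]),
      as.matrix(qc$retained[qc$retained$group == "control",
                            paste0("alv_", cmp), drop = FALSE]))
  } else NULL

  provenance <- list(seed = config$seed, config = unclass(config),
                     config_hash = config_hash(config),
                     package_version =
                       as.character(utils::packageVersion("breathlasso")))

  result <- list(cohort = cohort, qc = qc, model = model, cis = cis,
                 roc = roc, performance = perf, profile = prof,
                 provenance = provenance)
  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir)
  result
}

#' Serialize pipeline artifacts to JSON
#'
#' Writes `qc_report.json` (per-compound statistics and discarded
#' samples), `model.json` (selected variables, coefficients on both
#' scales, penalties, bootstrap CIs) and `evaluation.json` (ROC table,
#' AUC with normal-approximation CI from the DeLong SE, performance
#' table, profile). Every file embeds the seed and configuration hash.
#'
#' @param result A [run_pipeline()] result.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- result$provenance
  wj <- function(obj, file)
    jsonlite::write_json(obj, file.path(out_dir, file), auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null")
  qc <- result$qc
  wj(list(provenance = prov,
          co2_threshold = qc$co2_threshold, alpha = qc$alpha,
          n_retained = nrow(qc$retained),
          discarded_samples = qc$discarded_samples,
          retained_compounds = qc$retained_compounds,
          excluded_compounds = qc$excluded_compounds,
          compound_tests = qc$compound_tests),
     "qc_report.json")
  m <- result$model
  wj(list(provenance = prov,
          n_cases = m$n_cases, n_controls = m$n_controls,
          stage1_selected = m$stage1_selected,
          stage1_lambda = m$stage1_lambda,
          stage2_lambda = m$stage2_lambda,
          final_lambda = m$final_lambda,
          adaptive_weights = as.list(m$adaptive_weights),
          coefficients_standardized =
            c(list("(Intercept)" = m$final_fit$intercept),
              as.list(m$final_fit$coefficients)),
          coefficients_original_scale = as.list(m$coefficients),
          standardization = list(center = as.list(m$standardization$center),
                                 scale = as.list(m$standardization$scale)),
          converged = m$final_fit$converged,
          bootstrap_cis = result$cis),
     "model.json")
  roc <- result$roc
  ci <- roc$auc + c(-1, 1) * qnorm(0.975) * roc$auc_se
  wj(list(provenance = prov,
          auc = roc$auc, auc_se_delong = roc$auc_se,
          auc_ci95_normal = c(max(0, ci[1]), min(1, ci[2])),
          n_cases = roc$n_cases, n_controls = roc$n_controls,
          performance = result$performance,
          roc_table = roc$table,
          profile = result$profile),
     "evaluation.json")
  invisible(out_dir)
}
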
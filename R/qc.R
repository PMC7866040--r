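#' CO2-based alveolar-origin sample filter
#'
#' Breath samples whose CO2 percentage falls below the threshold are
#' discarded: a low CO2 reading indicates the vial was not airtight or
#' the end-expiratory (alveolar) fraction was not captured. The
#' comparison is strict -- a sample at exactly the threshold is retained.
#' Samples with missing CO2 are discarded with their own reason code.
#'
#' @param cohort A `breath_cohort` data frame with a `co2_percent` column.
#' @param threshold CO2 percentage below which a sample is discarded
#'   (default 2).
#' @return List with `retained` (the surviving rows), `discarded`
#'   (data frame `subject_id`, `co2_percent`, `reason` with reasons
#'   `"low_co2"` / `"missing_co2"`), and `threshold`.
#' @export
filter_co2 <- function(cohort, threshold = 2.0) {
  if (!"co2_percent" %in% names(cohort))
    stop("cohort lacks a co2_percent column")
  co2 <- cohort$co2_percent
  missing <- is.na(co2)
  low <- !missing & co2 < threshold
  discard <- missing | low
  reason <- ifelse(missing[discard], "missing_co2", "low_co2")
  if (any(missing))
    message(sum(missing), " sample(s) discarded for missing CO2")
  list(retained = cohort[!discard, , drop = FALSE],
       discarded = data.frame(
         subject_id = cohort$subject_id[discard],
         co2_percent = co2[discard],
         reason = reason,
         stringsAsFactors = FALSE),
       threshold = threshold)
}

#' Environmental-contamination compound exclusion
#'
#' For each compound, a paired two-sided t-test compares the
#' environmental (room-air) concentration with the alveolar concentration
#' across subjects; the pairing reflects that one environmental sample is
#' collected alongside each subject's breath sample. A compound is
#' excluded only when its mean environmental excess is *positive* and the
#' test is significant at `alpha` -- a compound measured higher in breath
#' than in room air is never excluded, however significant the
#' difference. With fewer than 3 paired observations the test is
#' undefined and the compound is retained with a warning. No multiplicity
#' correction is applied (`alpha` is configurable).
#'
#' @param cohort A `breath_cohort` with paired `alv_*` / `env_*` columns.
#' @param alpha Significance level for exclusion (default 0.05).
#' @return List with `retained_compounds`, `excluded_compounds`
#'   (character vectors) and `tests` (per-compound data frame:
#'   `compound`, `mean_diff` = mean environmental minus alveolar,
#'   `statistic`, `df`, `p_value`, `excluded`).
#' @export
environmental_exclusion <- function(cohort, alpha = 0.05) {
  compounds <- cohort_compounds(cohort)
  if (length(compounds) == 0) stop("cohort has no alv_* columns")
  n <- nrow(cohort)
  rows <- vector("list", length(compounds))
  for (k in seq_along(compounds)) {
    cmp <- compounds[k]
    env_col <- paste0("env_", cmp)
    if (!env_col %in% names(cohort))
      stop("no paired environmental column for compound ", cmp)
    diff <- cohort[[env_col]] - cohort[[paste0("alv_", cmp)]]
    diff <- diff[!is.na(diff)]
    if (length(diff) < 3) {
      warning("compound ", cmp, ": fewer than 3 paired observations; ",
              "test undefined, compound retained", call. = FALSE)
      rows[[k]] <- data.frame(compound = cmp, mean_diff = mean(diff),
                              statistic = NA_real_, df = NA_real_,
                              p_value = NA_real_, excluded = FALSE,
                              stringsAsFactors = FALSE)
      next
    }
    md <- mean(diff)
    if (sd(diff) == 0) {
      # identical vectors: zero statistic, certainly not excluded
      rows[[k]] <- data.frame(compound = cmp, mean_diff = md,
                              statistic = 0, df = length(diff) - 1,
                              p_value = 1, excluded = FALSE,
                              stringsAsFactors = FALSE)
      next
    }
    tt <- t.test(diff, mu = 0, alternative = "two.sided")
    excl <- md > 0 && tt$p.value < alpha
    rows[[k]] <- data.frame(compound = cmp, mean_diff = md,
                            statistic = unname(tt$statistic),
                            df = unname(tt$parameter),
                            p_value = tt$p.value, excluded = excl,
                            stringsAsFactors = FALSE)
  }
  tests <- do.call(rbind, rows)
  list(retained_compounds = tests$compound[!tests$excluded],
       excluded_compounds = tests$compound[tests$excluded],
       tests = tests)
}

#' Run both QC stages on a cohort
#'
#' Applies [filter_co2()] then [environmental_exclusion()] (on the
#' retained samples) and assembles a single QC report.
#'
#' @inheritParams filter_co2
#' @inheritParams environmental_exclusion
#' @return An object of class `qc_result`: `retained` (cohort rows),
#'   `discarded_samples`, `retained_compounds`, `excluded_compounds`,
#'   `compound_tests`, `co2_threshold`, `alpha`.
#' @export
qc_cohort <- function(cohort, threshold = 2.0, alpha = 0.05) {
  co2 <- filter_co2(cohort, threshold)
  env <- environmental_exclusion(co2$retained, alpha)
  structure(list(retained = co2$retained,
                 discarded_samples = co2$discarded,
                 retained_compounds = env$retained_compounds,
                 excluded_compounds = env$excluded_compounds,
                 compound_tests = env$tests,
                 co2_threshold = threshold,
                 alpha = alpha),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("QC result:\n")
  cat("  samples: ", nrow(x$retained), " retained, ",
      nrow(x$discarded_samples), " discarded (CO2 < ", x$co2_threshold,
      "% or missing)\n", sep = "")
  cat("  compounds: ", length(x$retained_compounds), " retained, ",
      length(x$excluded_compounds),
      " excluded for environmental background (alpha = ", x$alpha,
      ")\n", sep = "")
  if (length(x$excluded_compounds))
    cat("  excluded:", paste(x$excluded_compounds, collapse = ", "), "\n")
  invisible(x)
}

#' Column standardization for penalized fitting
#'
#' Centers each column to mean 0 and scales to sample SD 1, retaining the
#' parameters so fitted coefficients can be reported back on the original
#' measurement scale. Constant columns cannot be standardized and are
#' rejected by name.
#'
#' @param x Numeric matrix (subjects x variables), with column names.
#' @return List of class `standardization`: `x` (standardized matrix),
#'   `center`, `scale` (named vectors, original units).
#' @export
standardize_columns <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 subjects to standardize")
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  if (any(scl == 0))
    stop("constant column(s) cannot be standardized: ",
         paste(colnames(x)[scl == 0], collapse = ", "))
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  structure(list(x = xs, center = ctr, scale = scl),
            class = "standardization")
}

#' Apply stored standardization parameters to new data
#'
#' @param x Matrix on the original scale, columns matching (a superset
#'   of) the stored parameters.
#' @param params A [standardize_columns()] result.
#' @return The standardized matrix (columns in parameter order).
#' @export
apply_standardization <- function(x, params) {
  x <- as.matrix(x)
  vars <- names(params$center)
  if (!is.null(colnames(x))) x <- x[, vars, drop = FALSE]
  sweep(sweep(x, 2, params$center), 2, params$scale, "/")
}

#' Invert a standardization
#'
#' @param xs Standardized matrix.
#' @param params A [standardize_columns()] result.
#' @return The matrix on the original scale.
#' @export
destandardize <- function(xs, params) {
  vars <- names(params$center)
  xs <- as.matrix(xs)
  if (!is.null(colnames(xs))) xs <- xs[, vars, drop = FALSE]
  sweep(sweep(xs, 2, params$scale, "*"), 2, params$center, "+")
}
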
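# DeLong placement values via midranks. For case i the placement is the
# fraction of controls it out-scores (ties counted 1/2), and vice versa;
# the AUC is the mean placement and its variance follows from the
# placement variances.
.placements <- function(p, y) {
  cases <- p[y == 1]
  ctrls <- p[y == 0]
  n1 <- length(cases)
  n0 <- length(ctrls)
  r_all <- rank(c(cases, ctrls), ties.method = "average")
  v10 <- (r_all[seq_len(n1)] - rank(cases, ties.method = "average")) / n0
  v01 <- 1 - (r_all[n1 + seq_len(n0)] -
                rank(ctrls, ties.method = "average")) / n1
  list(v10 = v10, v01 = v01, auc = mean(v10), n1 = n1, n0 = n0)
}

#' ROC analysis of predicted probabilities
#'
#' Builds the full threshold table (classification rule: predicted
#' probability `>= threshold` is called a case, so the smallest observed
#' probability always gives 100% sensitivity), the AUC as the
#' Mann-Whitney statistic with ties counted 1/2, and its DeLong standard
#' error from placement values.
#'
#' @param probabilities Predicted case probabilities.
#' @param labels Binary outcome (1 = case); at least one case and one
#'   control.
#' @return An object of class `roc_analysis`: `table` (per ascending
#'   threshold: `threshold`, `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity` as fractions), `auc`, `auc_se`, `n_cases`,
#'   `n_controls`.
#' @export
roc_analysis <- function(probabilities, labels) {
  y <- as.integer(labels)
  if (!all(y %in% c(0, 1))) stop("labels must be binary 0/1")
  if (length(unique(y)) < 2)
    stop("ROC analysis needs at least one case and one control")
  p <- as.numeric(probabilities)
  if (length(p) != length(y)) stop("probabilities/labels length mismatch")
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  thr <- sort(unique(p))
  tp <- vapply(thr, function(t) sum(p >= t & y == 1), integer(1))
  fp <- vapply(thr, function(t) sum(p >= t & y == 0), integer(1))
  tab <- data.frame(threshold = thr, tp = tp, fp = fp,
                    tn = n0 - fp, fn = n1 - tp,
                    sensitivity = tp / n1,
                    specificity = (n0 - fp) / n0)
  pl <- .placements(p, y)
  # DeLong variance of a single AUC: var(V10)/n1 + var(V01)/n0
  v <- (if (n1 > 1) stats::var(pl$v10) / n1 else 0) +
       (if (n0 > 1) stats::var(pl$v01) / n0 else 0)
  structure(list(table = tab, auc = pl$auc, auc_se = sqrt(max(v, 0)),
                 n_cases = n1, n_controls = n0),
            class = "roc_analysis")
}

#' @export
print.roc_analysis <- function(x, ...) {
  ci <- x$auc + c(-1, 1) * qnorm(0.975) * x$auc_se
  cat(sprintf("ROC analysis: %d cases vs %d controls\n",
              x$n_cases, x$n_controls))
  cat(sprintf("  AUC %.4f (DeLong SE %.4f; normal 95%% CI %.4f-%.4f)\n",
              x$auc, x$auc_se, max(0, ci[1]), min(1, ci[2])))
  cat("  ", nrow(x$table), "distinct probability thresholds\n")
  invisible(x)
}

#' @export
plot.roc_analysis <- function(x, ...) {
  graphics::plot(1 - x$table$specificity, x$table$sensitivity,
                 type = "s", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("AUC = %.4f", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Sensitivity/specificity table at operating thresholds
#'
#' Reports, for every threshold with sensitivity at or above
#' `min_sensitivity`, the threshold, the sensitivity and specificity as
#' percentages rounded to 2 decimals, and the correct-classification
#' counts behind them (cases correctly called at `p >= t`, controls
#' correctly called at `p < t`).
#'
#' @param roc A [roc_analysis()] result.
#' @param min_sensitivity Minimum sensitivity to report, in percent
#'   (0 reports one row per distinct threshold).
#' @return Data frame: `threshold`, `sensitivity_pct`,
#'   `n_correct_cases`, `specificity_pct`, `n_correct_controls`.
#' @export
performance_table <- function(roc, min_sensitivity = 0) {
  tab <- roc$table
  keep <- 100 * tab$sensitivity >= min_sensitivity
  data.frame(threshold = tab$threshold[keep],
             sensitivity_pct = round(100 * tab$tp[keep] / roc$n_cases, 2),
             n_correct_cases = tab$tp[keep],
             specificity_pct = round(100 * tab$tn[keep] / roc$n_controls, 2),
             n_correct_controls = tab$tn[keep],
             row.names = NULL)
}

#' Paired DeLong test for equality of two ROC areas
#'
#' Compares the AUCs of two probability vectors computed on the *same
#' subjects* (e.g. a generic and a disease-specific model evaluated on
#' one cohort). The AUC difference is referred to its estimated variance,
#' with the covariance between the two correlated AUCs obtained from the
#' per-subject placement values; the squared standardized difference is
#' compared with a chi-squared distribution on 1 degree of freedom.
#'
#' @param probabilities_a,probabilities_b Predicted probabilities from
#'   the two models, aligned subject-for-subject.
#' @param labels Shared binary outcome.
#' @return List: `auc_a`, `auc_b`, `auc_difference`, `variance`,
#'   `chi2`, `p_value`.
#' @export
delong_test <- function(probabilities_a, probabilities_b, labels) {
  if (length(probabilities_a) != length(probabilities_b) ||
      length(probabilities_a) != length(labels))
    stop("the two probability vectors must be paired on the same subjects")
  y <- as.integer(labels)
  pa <- .placements(as.numeric(probabilities_a), y)
  pb <- .placements(as.numeric(probabilities_b), y)
  n1 <- pa$n1
  n0 <- pa$n0
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  # var(auc_a - auc_b) with covariance from the paired placements
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  d <- pa$auc - pb$auc
  if (v <= 0) {
    chi2 <- if (abs(d) < 1e-12) 0 else Inf
  } else {
    chi2 <- d^2 / v
  }
  list(auc_a = pa$auc, auc_b = pb$auc, auc_difference = d,
       variance = max(v, 0), chi2 = chi2,
       p_value = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Compound profiles standardized to the control group
#'
#' Expresses each patient-group compound mean in control-group SD units:
#' \eqn{z = (\bar x_{case} - \bar x_{control}) / s_{control}}. The
#' control profile is identically 0 by construction. Compounds with zero
#' control SD cannot be standardized and are flagged.
#'
#' @param case_matrix,control_matrix Subject-by-compound concentration
#'   matrices (raw ppb scale) with matching column names.
#' @return Data frame: `compound`, `z_case`, `z_control` (0), `flagged`.
#' @export
standardized_profile <- function(case_matrix, control_matrix) {
  case_matrix <- as.matrix(case_matrix)
  control_matrix <- as.matrix(control_matrix)
  if (!identical(colnames(case_matrix), colnames(control_matrix)))
    stop("case and control matrices must share the same compounds")
  m_ctrl <- colMeans(control_matrix)
  s_ctrl <- apply(control_matrix, 2, sd)
  z <- (colMeans(case_matrix) - m_ctrl) / s_ctrl
  flagged <- s_ctrl == 0
  z[flagged] <- NA_real_
  if (any(flagged))
    warning("zero control SD for: ",
            paste(colnames(control_matrix)[flagged], collapse = ", "),
            call. = FALSE)
  data.frame(compound = colnames(case_matrix),
             z_case = unname(z),
             z_control = 0,
             flagged = unname(flagged),
             row.names = NULL, stringsAsFactors = FALSE)
}
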
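#' Build the design matrix for a case/control contrast
#'
#' Assembles the raw (unstandardized) predictor matrix -- one column per
#' retained compound (alveolar ppb) plus `age` (years) and `sex`
#' (0 = female, 1 = male) -- and the binary outcome for a contrast
#' between case and control groups.
#'
#' @param cohort A `breath_cohort` data frame (QC-passed rows).
#' @param compounds Compound labels to include (typically the QC-retained
#'   set).
#' @param case_groups Group label(s) coded 1.
#' @param control_groups Group label(s) coded 0.
#' @param covariates Extra metadata columns to include as predictors.
#' @return List: `x` (raw-scale matrix, columns = compounds then
#'   covariates), `y` (0/1), `subject_id`.
#' @export
build_design <- function(cohort, compounds,
                         case_groups, control_groups = "control",
                         covariates = c("age", "sex")) {
  keep <- cohort$group %in% c(case_groups, control_groups)
  if (!any(keep)) stop("no subjects in the requested groups")
  cohort <- cohort[keep, , drop = FALSE]
  alv <- as.matrix(cohort[, paste0("alv_", compounds), drop = FALSE])
  colnames(alv) <- compounds
  covs <- as.matrix(cohort[, covariates, drop = FALSE])
  list(x = cbind(alv, covs),
       y = as.integer(cohort$group %in% case_groups),
       subject_id = cohort$subject_id)
}

#' Screening LASSO: variable reduction
#'
#' First stage of the iterated procedure: an ordinary (unit-weight) LASSO
#' logistic regression with cross-validated penalty; variables whose
#' coefficients are shrunk to zero are eliminated, and the surviving
#' variables are passed on *by name only* -- their coefficient values are
#' deliberately discarded.
#'
#' @param xs Standardized predictor matrix.
#' @param y Binary outcome.
#' @param nfolds,grid_size,seed Passed to [cv_penalized_logistic()].
#' @param ... Further solver arguments.
#' @return List: `selected` (character), `lambda`, `cv` (the CV path),
#'   `fit`.
#' @export
screen_variables <- function(xs, y, nfolds = 50, grid_size = 50,
                             seed = 1, ...) {
  cv <- cv_penalized_logistic(xs, y, weights = 1, nfolds = nfolds,
                              grid_size = grid_size, seed = seed, ...)
  fit <- penalized_logistic(xs, y, cv$selected_lambda, weights = 1, ...)
  selected <- names(fit$coefficients)[fit$coefficients != 0]
  if (length(selected) == 0)
    warning("screening selected no variables; downstream stages are ",
            "intercept-only", call. = FALSE)
  list(selected = selected, lambda = cv$selected_lambda, cv = cv, fit = fit)
}

#' Adaptive penalty weights from a preliminary fit
#'
#' The adaptive LASSO penalizes each variable by the inverse absolute
#' coefficient of a preliminary (unit-weight) fit: strong preliminary
#' effects get small weights (little shrinkage), zero coefficients get
#' infinite weight (hard exclusion from the adaptive stage).
#'
#' @param fit A `penalized_fit` (the weight-generating stage).
#' @return Named non-negative weights, `Inf` for zero coefficients.
#' @export
adaptive_weights <- function(fit) {
  b <- fit$coefficients
  w <- ifelse(b == 0, Inf, 1 / abs(b))
  if (all(is.infinite(w)))
    warning("all stage-2 coefficients are zero: adaptive stage ",
            "degenerates to intercept-only", call. = FALSE)
  setNames(w, names(b))
}

.intercept_only_fit <- function(y) {
  structure(list(intercept = qlogis(mean(y)),
                 coefficients = setNames(numeric(0), character(0)),
                 lambda = 0, penalty_weights = numeric(0),
                 converged = TRUE, capped = FALSE, n_iterations = 0L),
            class = "penalized_fit")
}

.subset_standardization <- function(params, vars) {
  structure(list(x = NULL, center = params$center[vars],
                 scale = params$scale[vars]),
            class = "standardization")
}

#' Three-stage iterated adaptive LASSO logistic regression
#'
#' The full selection procedure used for breath-compound discriminant
#' panels:
#' \enumerate{
#'   \item *Screening LASSO*: unit weights, CV-selected penalty;
#'     variables with zero coefficients are eliminated.
#'   \item *Weight-generating LASSO* on the screened set: unit weights,
#'     CV-selected penalty; its coefficients define adaptive weights
#'     \eqn{w_j = 1/|\beta_j|}.
#'   \item *Adaptive LASSO* on the screened set with those weights and a
#'     fresh CV-selected penalty: the final model.
#' }
#' All stages run on standardized predictors; 50-fold CV is the default
#' throughout. The procedure is deterministic given `(data, config,
#' seed)`: stage seeds are derived as `seed`, `seed + 1`, `seed + 2`.
#'
#' @param x Raw-scale predictor matrix (compounds + covariates; see
#'   [build_design()]).
#' @param y Binary outcome (1 = case).
#' @param nfolds,grid_size CV configuration (applied to every stage).
#' @param screen If `FALSE`, stage 1 is skipped and all variables enter
#'   the weight-generating stage (a single adaptive LASSO on the full
#'   panel).
#' @param seed Integer seed.
#' @param ... Further solver arguments.
#' @return An object of class `iterated_model`: `stage1_selected`,
#'   `stage1_lambda`, `stage2_fit`, `stage2_lambda`, `adaptive_weights`,
#'   `final_fit`, `final_lambda`, `coefficients` (original scale,
#'   including intercept), `standardization` (screened variables),
#'   `n_cases`, `n_controls`, `seed`, `config`.
#' @export
fit_iterated <- function(x, y, nfolds = 50, grid_size = 50, screen = TRUE,
                         seed = 1, ...) {
  x <- as.matrix(x)
  y <- as.integer(y)
  std <- standardize_columns(x)
  xs <- std$x

  if (screen) {
    s1 <- screen_variables(xs, y, nfolds = nfolds, grid_size = grid_size,
                           seed = seed, ...)
    selected <- s1$selected
    stage1_lambda <- s1$lambda
  } else {
    selected <- colnames(xs)
    stage1_lambda <- NA_real_
  }

  params <- .subset_standardization(std, selected)
  if (length(selected) == 0) {
    final <- .intercept_only_fit(y)
    stage2 <- final
    w <- numeric(0)
    stage2_lambda <- final_lambda <- NA_real_
  } else {
    xs2 <- xs[, selected, drop = FALSE]
    cv2 <- cv_penalized_logistic(xs2, y, weights = 1, nfolds = nfolds,
                                 grid_size = grid_size, seed = seed + 1L,
                                 ...)
    stage2 <- penalized_logistic(xs2, y, cv2$selected_lambda,
                                 weights = 1, ...)
    stage2_lambda <- cv2$selected_lambda
    w <- adaptive_weights(stage2)
    if (all(is.infinite(w))) {
      final <- .intercept_only_fit(y)
      final_lambda <- NA_real_
    } else {
      cv3 <- cv_penalized_logistic(xs2, y, weights = w, nfolds = nfolds,
                                   grid_size = grid_size,
                                   seed = seed + 2L, ...)
      final <- penalized_logistic(xs2, y, cv3$selected_lambda,
                                  weights = w, ...)
      final_lambda <- cv3$selected_lambda
    }
  }

  orig <- if (length(final$coefficients))
    original_scale_coefficients(final, params)
  else list(intercept = final$intercept,
            coefficients = setNames(numeric(0), character(0)))

  structure(list(stage1_selected = selected,
                 stage1_lambda = stage1_lambda,
                 stage2_fit = stage2,
                 stage2_lambda = stage2_lambda,
                 adaptive_weights = w,
                 final_fit = final,
                 final_lambda = final_lambda,
                 coefficients = c("(Intercept)" = orig$intercept,
                                  orig$coefficients),
                 standardization = params,
                 n_cases = sum(y == 1),
                 n_controls = sum(y == 0),
                 seed = seed,
                 config = list(nfolds = nfolds, grid_size = grid_size,
                               screen = screen)),
            class = "iterated_model")
}

#' @export
print.iterated_model <- function(x, ...) {
  nz <- names(x$final_fit$coefficients)[x$final_fit$coefficients != 0]
  cat("Iterated adaptive-LASSO logistic model\n")
  cat("  ", x$n_cases, "cases vs", x$n_controls, "controls\n")
  cat("  screening retained", length(x$stage1_selected), "variables",
      if (!is.na(x$stage1_lambda))
        paste0("(lambda = ", format(x$stage1_lambda), ")"), "\n")
  cat("  final model:", length(nz), "variables (lambda =",
      format(x$final_lambda), ")\n")
  if (length(nz)) {
    cf <- x$coefficients[c("(Intercept)", nz)]
    print(cf)
  }
  invisible(x)
}

#' @export
predict.iterated_model <- function(object, newx, ...) {
  predict(object$final_fit, newx,
          standardization = object$standardization, ...)
}

#' Bootstrap percentile confidence intervals for the final coefficients
#'
#' Draws `B` outcome-stratified bootstrap resamples and refits the
#' pipeline from the weight-generating stage on each: the screened
#' variable set is held fixed, the stage-2 and adaptive penalties are
#' held at their full-data CV selections, and the adaptive weights are
#' recomputed per resample. Per-variable percentile intervals at
#' 2.5%/97.5% are taken over the resampled coefficients on the original
#' measurement scale; a variable absent from a resample's model
#' contributes a coefficient of 0 to that resample.
#'
#' @param x,y The raw-scale design and outcome the model was fitted on.
#' @param model An [fit_iterated()] result.
#' @param B Number of bootstrap resamples (>= 50; default 200).
#' @param seed Integer seed.
#' @param ... Further solver arguments.
#' @return Data frame: `variable`, `estimate` (original scale), `lower`,
#'   `upper`, `unstable` (`TRUE` when the point estimate falls outside
#'   its own interval).
#' @export
bootstrap_cis <- function(x, y, model, B = 200, seed = 1, ...) {
  if (B < 50) stop("B must be >= 50 for stable percentile intervals")
  x <- as.matrix(x)
  y <- as.integer(y)
  vars <- model$stage1_selected
  est <- model$coefficients
  out_vars <- c("(Intercept)", vars)
  if (length(vars) == 0) {
    return(data.frame(variable = "(Intercept)",
                      estimate = unname(est["(Intercept)"]),
                      lower = unname(est["(Intercept)"]),
                      upper = unname(est["(Intercept)"]),
                      unstable = FALSE, stringsAsFactors = FALSE))
  }
  cases <- which(y == 1)
  ctrls <- which(y == 0)
  draws <- matrix(0, nrow = B, ncol = length(out_vars),
                  dimnames = list(NULL, out_vars))
  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- c(sample(cases, length(cases), replace = TRUE),
               sample(ctrls, length(ctrls), replace = TRUE))
      xb <- x[idx, vars, drop = FALSE]
      yb <- y[idx]
      # a resample can make a variable constant; it then contributes 0
      keep <- apply(xb, 2, function(col) sd(col) > 0)
      if (!any(keep)) next
      stdb <- standardize_columns(xb[, keep, drop = FALSE])
      lam2 <- if (is.na(model$stage2_lambda)) 0 else model$stage2_lambda
      f2 <- suppressWarnings(
        penalized_logistic(stdb$x, yb, lam2, weights = 1, ...))
      wb <- suppressWarnings(adaptive_weights(f2))
      if (all(is.infinite(wb))) {
        draws[b, "(Intercept)"] <- qlogis(mean(yb))
        next
      }
      lam3 <- if (is.na(model$final_lambda)) 0 else model$final_lambda
      f3 <- suppressWarnings(
        penalized_logistic(stdb$x, yb, lam3, weights = wb, ...))
      ob <- original_scale_coefficients(f3, stdb)
      draws[b, "(Intercept)"] <- ob$intercept
      draws[b, names(ob$coefficients)] <- ob$coefficients
    }
  })
  ci <- t(apply(draws, 2, quantile, probs = c(0.025, 0.975), names = FALSE))
  point <- ifelse(out_vars %in% names(est), est[out_vars], 0)
  data.frame(variable = out_vars,
             estimate = unname(point),
             lower = ci[, 1],
             upper = ci[, 2],
             unstable = unname(point < ci[, 1] | point > ci[, 2]),
             stringsAsFactors = FALSE)
}
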
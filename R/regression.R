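#' Forced-entry multiple regression of one stance parameter
#'
#' Fits an ordinary least squares model with all predictors retained
#' (forced entry, no stepwise selection). Two predictor sets are
#' supported: the main model uses age, body height, body weight and
#' handgrip strength; the BMI model replaces height and weight by BMI
#' (they intercorrelate and must never share a model). Reports raw
#' coefficients in dependent-units per predictor-unit, standardized Beta
#' coefficients (raw x sd(x)/sd(y), sample SDs), two-sided t-test
#' p-values, adjusted R-squared and the overall F-test p-value.
#'
#' @param data data.frame with one row per subject, containing the
#'   dependent parameter column plus `age`, `height`, `weight`, `bmi`,
#'   `grip`.
#' @param dependent name of the dependent parameter column.
#' @param model `"main"` or `"bmi"`.
#' @return object of class `stance_fit`.
#' @export
fit_model <- function(data, dependent, model = c("main", "bmi")) {
  model <- match.arg(model)
  predictors <- if (model == "main") c("age", "height", "weight", "grip")
                else c("age", "bmi", "grip")
  miss <- setdiff(c(dependent, predictors), names(data))
  if (length(miss) > 0)
    stop("data lacks column(s): ", paste(miss, collapse = ", "))
  if (anyNA(data[, c(dependent, predictors)]))
    stop("missing values in dependent or predictors")
  p <- length(predictors)
  n <- nrow(data)
  if (n < p + 2)
    stop(sprintf("need at least %d subjects for %d predictors", p + 2, p))

  fml <- stats::reformulate(predictors, response = dependent)
  X <- stats::model.matrix(fml, data)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("collinear (rank-deficient) design; offending predictor(s): ",
         paste(dropped, collapse = ", "))
  }
  fit <- stats::lm(fml, data = data)
  sm <- summary(fit)
  ct <- sm$coefficients
  y <- data[[dependent]]
  sds <- vapply(predictors, function(v) stats::sd(data[[v]]), numeric(1))
  beta <- ct[predictors, "Estimate"] * sds / stats::sd(y)
  fstat <- sm$fstatistic
  model_p <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)

  structure(list(
    dependent = dependent, model = model, n = n,
    coefficients = data.frame(
      term = predictors,
      estimate = unname(ct[predictors, "Estimate"]),
      beta = unname(beta),
      se = unname(ct[predictors, "Std. Error"]),
      p = unname(ct[predictors, "Pr(>|t|)"]),
      stringsAsFactors = FALSE),
    intercept = unname(ct["(Intercept)", "Estimate"]),
    r2 = sm$r.squared, adjusted_r2 = sm$adj.r.squared,
    model_p = unname(model_p),
    lm = fit),
    class = "stance_fit")
}

#' @export
print.stance_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<stance_fit> %s ~ %s model (n = %d)\n",
              x$dependent, x$model, x$n))
  cat(sprintf("  adjusted R^2 = %.3f, model p = %.4g\n",
              x$adjusted_r2, x$model_p))
  df <- x$coefficients
  df$estimate <- signif(df$estimate, digits)
  df$beta <- signif(df$beta, digits)
  df$p <- signif(df$p, 3)
  print(df[, c("term", "estimate", "beta", "p")], row.names = FALSE)
  invisible(x)
}

#' @export
coef.stance_fit <- function(object, ...) {
  stats::setNames(c(object$intercept, object$coefficients$estimate),
                  c("(Intercept)", object$coefficients$term))
}

#' @export
predict.stance_fit <- function(object, newdata, ...) {
  stats::predict(object$lm, newdata = newdata, ...)
}

#' @export
residuals.stance_fit <- function(object, ...) stats::residuals(object$lm)

#' @export
summary.stance_fit <- function(object, ...) summary(object$lm, ...)

#' Fit both regression models for all nine parameters
#'
#' Runs [fit_model()] for every stance parameter under both the main and
#' the BMI predictor set: 9 parameters x 2 models = 18 fits.
#'
#' @param data per-subject data.frame: nine parameter columns (means over
#'   accepted events) plus `age`, `height`, `weight`, `bmi`, `grip`. See
#'   [subject_table()].
#' @return object of class `stance_fits`: a list of `stance_fit` with a
#'   tidy `as.data.frame()` and a significance-masked `print()` shaped
#'   like the usual reporting table (coefficients shown only at p < 0.05,
#'   full values retained in the machine representation).
#' @export
fit_all <- function(data) {
  fits <- list()
  for (dep in PARAM_COLUMNS) {
    for (m in c("main", "bmi")) {
      fits[[paste(dep, m, sep = ".")]] <- fit_model(data, dep, m)
    }
  }
  structure(fits, class = "stance_fits")
}

#' @export
as.data.frame.stance_fits <- function(x, ...) {
  do.call(rbind, lapply(unclass(x), function(f) {
    cbind(data.frame(dependent = f$dependent, model = f$model, n = f$n,
                     adjusted_r2 = f$adjusted_r2, model_p = f$model_p),
          f$coefficients, row.names = NULL)
  }))
}

#' Human-readable significance-masked coefficient table
#'
#' One row per parameter; adjusted R-squared of both models, then one
#' column per predictor showing "raw, Beta" only where p < 0.05 (BMI
#' column from the BMI model, all others from the main model).
#'
#' @param fits a `stance_fits` object.
#' @param alpha significance threshold for display (default 0.05).
#' @return data.frame.
#' @export
format_fit_table <- function(fits, alpha = 0.05) {
  stopifnot(inherits(fits, "stance_fits"))
  cell <- function(f, term) {
    r <- f$coefficients[f$coefficients$term == term, ]
    if (nrow(r) == 0 || r$p >= alpha) return("")
    sprintf("%.3f, %.3f", r$estimate, r$beta)
  }
  rows <- lapply(PARAM_COLUMNS, function(dep) {
    fm <- fits[[paste(dep, "main", sep = ".")]]
    fb <- fits[[paste(dep, "bmi", sep = ".")]]
    data.frame(parameter = dep,
               adj_r2_main = round(fm$adjusted_r2, 3),
               adj_r2_bmi = round(fb$adjusted_r2, 3),
               age = cell(fm, "age"), height = cell(fm, "height"),
               weight = cell(fm, "weight"), bmi = cell(fb, "bmi"),
               grip = cell(fm, "grip"), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.stance_fits <- function(x, ...) {
  cat(sprintf("<stance_fits> %d fits (%d parameters x 2 models)\n",
              length(x), length(x) / 2))
  print(format_fit_table(x), row.names = FALSE)
  invisible(x)
}

#' Build the per-subject analysis table
#'
#' Joins subject aggregates (parameter means) with the anthropometric
#' profiles into the flat table [fit_all()] consumes.
#'
#' @param aggregates list of `subject_aggregate` objects.
#' @param profiles subject profile data.frame (see [read_subjects()]).
#' @return data.frame, one row per aggregated subject.
#' @export
subject_table <- function(aggregates, profiles) {
  aggregates <- Filter(Negate(is.null), aggregates)
  if (length(aggregates) == 0) {
    empty <- data.frame(subject_id = character(0), n_steps = integer(0))
    for (cn in c(PARAM_COLUMNS, "age", "height", "weight", "bmi", "grip"))
      empty[[cn]] <- numeric(0)
    return(empty)
  }
  rows <- lapply(aggregates, function(a) {
    pr <- profiles[profiles$subject_id == a$subject_id, , drop = FALSE]
    if (nrow(pr) != 1)
      stop("no unique profile for subject ", a$subject_id)
    cbind(data.frame(subject_id = a$subject_id,
                     n_steps = a$n_steps_accepted),
          as.data.frame(as.list(a$parameter_means)),
          pr[, c("age", "height", "weight", "bmi", "grip")],
          row.names = NULL)
  })
  do.call(rbind, rows)
}
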
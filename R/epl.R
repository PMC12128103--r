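# published EPL coefficient sets (kcal/mol per descriptor unit), one per
# reference level of theory; these are packaged constants, refitting via
# fit_epl() never overwrites them
.epl_published <- list(
  DFT   = c(f_bar = -168.82, n_bar = -66.28, g_bar = 328.10,
            intercept = -18.80),
  CBS   = c(f_bar = -189.01, n_bar = -65.11, g_bar = 266.44,
            intercept = 13.96),
  G4    = c(f_bar = -184.99, n_bar = -64.85, g_bar = 275.10,
            intercept = 8.52),
  DLPNO = c(f_bar = -187.82, n_bar = -72.45, g_bar = 296.14,
            intercept = 7.72)
)

#' Packaged Evans-Polanyi-like barrier models
#'
#' Affine models `dH = c_f * f_bar + c_N * n_bar + c_g * g_bar + c_0`
#' predicting the standard activation enthalpy (kcal/mol, 298 K) of
#' xylopyranose pyrolysis steps from the three aggregated reactant
#' descriptors. One published coefficient set is packaged per reference
#' level: `DFT` (M06-2X/6-311++G(d,p)), `CBS` (CBS-QB3), `G4`, and `DLPNO`
#' (DLPNO-CCSD(T)-F12/cc-pVTZ-F12).
#'
#' @param level one of `"DFT"`, `"CBS"`, `"G4"`, `"DLPNO"`.
#' @return object of class `epl_model`: list with `level`, `coefficients`
#'   (named: `f_bar`, `n_bar`, `g_bar`, `intercept`) and `source`
#'   (`"published"`).
#' @export
epl_model <- function(level = c("DFT", "CBS", "G4", "DLPNO")) {
  level <- match.arg(level)
  structure(list(level = level, coefficients = .epl_published[[level]],
                 source = "published"),
            class = "epl_model")
}

#' Levels with packaged EPL coefficient sets
#' @export
epl_levels <- function() names(.epl_published)

#' @export
print.epl_model <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf(
    "EPL model [%s, %s]:\n  dH = %.2f f_bar %+.2f n_bar %+.2f g_bar %+.2f  [kcal/mol, 298 K]\n",
    x$level, x$source, co["f_bar"], co["n_bar"], co["g_bar"],
    co["intercept"]))
  invisible(x)
}

#' @export
coef.epl_model <- function(object, ...) object$coefficients

as_descriptor_frame <- function(newdata) {
  if (inherits(newdata, "aggregate_descriptors"))
    newdata <- data.frame(f_bar = newdata$f_bar, n_bar = newdata$n_bar,
                          g_bar = newdata$g_bar)
  newdata <- as.data.frame(newdata)
  need <- c("f_bar", "n_bar", "g_bar")
  if (!all(need %in% names(newdata)))
    stop("newdata must supply columns f_bar, n_bar, g_bar")
  newdata
}

#' Predict activation enthalpies from an EPL model
#'
#' @param object an `epl_model` (packaged or fitted).
#' @param newdata an [aggregate_descriptors()] object or a data.frame with
#'   columns `f_bar`, `n_bar`, `g_bar`.
#' @param ... unused.
#' @return numeric vector of predicted `dH` (kcal/mol, 298 K).
#' @export
predict.epl_model <- function(object, newdata, ...) {
  nd <- as_descriptor_frame(newdata)
  co <- object$coefficients
  unname(co["f_bar"] * nd$f_bar + co["n_bar"] * nd$n_bar +
           co["g_bar"] * nd$g_bar + co["intercept"])
}

#' Predict one barrier from aggregated descriptors
#'
#' Thin wrapper around [predict.epl_model()] for a single descriptor set.
#'
#' @param model an `epl_model`.
#' @param agg an [aggregate_descriptors()] object (or data.frame row).
#' @return predicted standard activation enthalpy (kcal/mol, 298 K).
#' @export
predict_barrier <- function(model, agg) predict(model, agg)

#' Regression quality metrics
#'
#' `MAE = mean(|residual|)`, `RMSE = sqrt(mean(residual^2))` and the
#' adjusted coefficient of determination
#' `R2_adj = 1 - (1 - R2) (n - 1) / (n - p - 1)`.
#'
#' @param predictions,references numeric vectors of equal length.
#' @param p number of predictors (3 for the EPL descriptor set).
#' @return named numeric: `mae`, `rmse`, `r2_adj` (the latter `NA` when the
#'   references have zero variance).
#' @export
evaluate_metrics <- function(predictions, references, p = 3) {
  stopifnot(length(predictions) == length(references))
  n <- length(predictions)
  if (n <= p + 1) stop("R2_adj requires n > p + 1")
  res <- references - predictions
  mae <- mean(abs(res))
  rmse <- sqrt(mean(res^2))
  ss_tot <- sum((references - mean(references))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  c(mae = mae, rmse = rmse, r2_adj = r2_adj)
}

#' Fit an EPL model by ordinary least squares
#'
#' Multilinear regression of activation enthalpies on the three aggregated
#' reactant descriptors (plus intercept), following the derivation protocol
#' of the packaged models. Training metrics are always reported; held-out
#' rows, when given, yield validation metrics.
#'
#' @param data data.frame with columns `f_bar`, `n_bar`, `g_bar`, `dH`.
#' @param validation optional data.frame with the same columns.
#' @param level label for the fitted model.
#' @return object of class `c("epl_fit", "epl_model")` with elements
#'   `coefficients`, `fit` (the underlying `lm`), `n`, `metrics`
#'   (training), `validation_metrics` (or `NULL`).
#' @export
fit_epl <- function(data, validation = NULL, level = "custom") {
  data <- as.data.frame(data)
  need <- c("f_bar", "n_bar", "g_bar", "dH")
  if (!all(need %in% names(data)))
    stop("data must supply columns f_bar, n_bar, g_bar, dH")
  if (nrow(data) < 5L)
    stop("underdetermined system: need at least 5 rows to fit 4 coefficients")
  fit <- stats::lm(dH ~ f_bar + n_bar + g_bar, data = data)
  if (fit$rank < 4L)
    stop("rank-deficient design: descriptors are collinear")
  co <- stats::coef(fit)
  coefficients <- c(f_bar = unname(co["f_bar"]),
                    n_bar = unname(co["n_bar"]),
                    g_bar = unname(co["g_bar"]),
                    intercept = unname(co["(Intercept)"]))
  obj <- structure(
    list(level = level, coefficients = coefficients, source = "fitted",
         fit = fit, n = nrow(data), data = data,
         metrics = evaluate_metrics(stats::fitted(fit), data$dH, p = 3),
         validation_metrics = NULL),
    class = c("epl_fit", "epl_model"))
  if (!is.null(validation)) {
    validation <- as.data.frame(validation)
    obj$validation_metrics <-
      evaluate_metrics(predict(obj, validation), validation$dH, p = 3)
  }
  obj
}

#' @export
print.epl_fit <- function(x, ...) {
  NextMethod()
  m <- x$metrics
  cat(sprintf("  n = %d;  MAE = %.2f, RMSE = %.2f kcal/mol, R2_adj = %.3f\n",
              x$n, m["mae"], m["rmse"], m["r2_adj"]))
  if (!is.null(x$validation_metrics)) {
    v <- x$validation_metrics
    cat(sprintf("  validation: MAE = %.2f, RMSE = %.2f, R2_adj = %.3f\n",
                v["mae"], v["rmse"], v["r2_adj"]))
  }
  invisible(x)
}

#' @export
summary.epl_fit <- function(object, ...) {
  list(level = object$level, coefficients = object$coefficients,
       n = object$n, metrics = object$metrics,
       validation_metrics = object$validation_metrics,
       lm_summary = summary(object$fit))
}

#' @export
residuals.epl_fit <- function(object, ...) stats::residuals(object$fit)

#' Parity plot of an EPL fit
#'
#' Predicted versus reference activation enthalpies with the identity line.
#'
#' @param x an `epl_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.epl_fit <- function(x, ...) {
  ref <- x$data$dH
  pred <- stats::fitted(x$fit)
  graphics::plot(ref, pred,
                 xlab = "reference dH (kcal/mol)",
                 ylab = "predicted dH (kcal/mol)",
                 main = sprintf("EPL parity plot [%s]", x$level), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Deterministic train/validation split
#'
#' @param n number of rows (or a data.frame, whose row count is used).
#' @param fraction training fraction in (0, 1).
#' @param seed RNG seed; the same seed always yields the same split.
#' @param stratify optional factor of length `n`; per-class training
#'   proportions are then preserved within one row.
#' @return list with integer vectors `train` and `validation`.
#' @export
split_dataset <- function(n, fraction = 0.8, seed = 1L, stratify = NULL) {
  if (is.data.frame(n)) n <- nrow(n)
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  with_seed(seed, {
    if (is.null(stratify)) {
      k <- round(fraction * n)
      train <- sort(sample.int(n, k))
    } else {
      stopifnot(length(stratify) == n)
      tab <- table(stratify)
      if (any(tab < 2L))
        stop("every class needs >= 2 rows for a stratified split")
      train <- sort(unlist(lapply(split(seq_len(n), stratify), function(ix) {
        sample(ix, round(fraction * length(ix)))
      }), use.names = FALSE))
    }
    list(train = train, validation = setdiff(seq_len(n), train))
  })
}

# run code under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
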
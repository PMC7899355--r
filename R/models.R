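# Published multivariate corneal-power models, one per best-focus criterion.
# Coefficients are stored verbatim to all published digits; units: radii and
# CCT in mm, asphericities dimensionless, PUP in mm, prediction in dioptres.
PRINTED_MODELS <- list(
  `1` = list(criterion = "WF",  n_K = 1.3317, b0 = 0.86129,
             bRf = -0.90224, bQf = 1.7446,  bRb = 0.97129,
             bQb = -0.33023, bCCT = 0.29098, bPUP = 0.062371),
  `2` = list(criterion = "RMS", n_K = 1.3309, b0 = 0.40217,
             bRf = -0.84386, bQf = 0.81261, bRb = 0.93662,
             bQb = -0.15142, bCCT = 0.32146, bPUP = 0.029592),
  `3` = list(criterion = "MA",  n_K = 1.3308, b0 = 0.33451,
             bRf = -0.83496, bQf = 0.67492, bRb = 0.93097,
             bQb = -0.12361, bCCT = 0.32598, bPUP = 0.02504),
  `4` = list(criterion = "TSD", n_K = 1.3311, b0 = 0.50409,
             bRf = -0.85727, bQf = 1.0176,  bRb = 0.94506,
             bQb = -0.19287, bCCT = 0.31454, bPUP = 0.036352)
)

new_model_coefficients <- function(n_K, b0, bRf, bQf, bRb, bQb, bCCT, bPUP,
                                   criterion = NA_character_,
                                   rms_error = NA_real_, r_squared = NA_real_) {
  structure(list(n_K = n_K, b0 = b0, bRf = bRf, bQf = bQf, bRb = bRb,
                 bQb = bQb, bCCT = bCCT, bPUP = bPUP, criterion = criterion,
                 rms_error = rms_error, r_squared = r_squared),
            class = "model_coefficients")
}

#' @export
print.model_coefficients <- function(x, ...) {
  cat(sprintf("Corneal power model (criterion %s):\n", x$criterion))
  cat(sprintf(
    "  CP = 1000*(%.4f - 1)/Rf %+0.5f %+0.5f*Rf %+0.5f*Qf %+0.5f*Rb %+0.5f*Qb %+0.5f*CCT %+0.6f*PUP\n",
    x$n_K, x$b0, x$bRf, x$bQf, x$bRb, x$bQb, x$bCCT, x$bPUP))
  if (is.finite(x$rms_error))
    cat(sprintf("  fit: RMS error %.4f dpt, R^2 %.4f\n",
                x$rms_error, x$r_squared))
  invisible(x)
}

#' Predict corneal power from model coefficients
#'
#' Evaluates `CP = 1000 (n_K - 1)/R_f + b0 + bRf R_f + bQf Q_f + bRb R_b +
#' bQb Q_b + bCCT CCT + bPUP PUP` with all lengths in mm.
#'
#' @param model a `model_coefficients` object.
#' @param eyes data frame with columns `R_f`, `Q_f`, `R_b`, `Q_b`, `CCT`
#'   (mm), `PUP`.
#' @return predicted corneal power in dioptres.
#' @export
predict_corneal_power <- function(model, eyes) {
  stopifnot(inherits(model, "model_coefficients"))
  eyes <- as.data.frame(eyes)
  1000 * (model$n_K - 1) / eyes$R_f + model$b0 +
    model$bRf * eyes$R_f + model$bQf * eyes$Q_f +
    model$bRb * eyes$R_b + model$bQb * eyes$Q_b +
    model$bCCT * eyes$CCT + model$bPUP * eyes$PUP
}

#' Evaluate one of the four published corneal-power models
#'
#' Reference implementation of the four published multivariate models, one
#' per best-focus criterion (1 = wavefront error, 2 = RMS ray scatter,
#' 3 = mean absolute ray scatter, 4 = total spot diameter), with their exact
#' published coefficients.
#'
#' @param model_id integer 1 to 4.
#' @param eyes data frame with columns `R_f`, `Q_f`, `R_b`, `Q_b`, `CCT`
#'   (mm), `PUP` (mm).
#' @return predicted corneal power in dioptres.
#' @examples
#' mean_eye <- data.frame(R_f = 7.733, Q_f = -0.3141, R_b = 6.534,
#'                        Q_b = -0.007, CCT = 0.547, PUP = 4.408)
#' evaluate_printed_model(1, mean_eye)
#' @export
evaluate_printed_model <- function(model_id, eyes) {
  key <- as.character(model_id)
  if (length(model_id) != 1L || !key %in% names(PRINTED_MODELS))
    stop("evaluate_printed_model: model_id must be 1, 2, 3 or 4")
  predict_corneal_power(printed_model(model_id), eyes)
}

#' Retrieve a published model as a coefficients object
#'
#' @inheritParams evaluate_printed_model
#' @return a `model_coefficients` object.
#' @export
printed_model <- function(model_id) {
  key <- as.character(model_id)
  if (length(model_id) != 1L || !key %in% names(PRINTED_MODELS))
    stop("printed_model: model_id must be 1, 2, 3 or 4")
  p <- PRINTED_MODELS[[key]]
  new_model_coefficients(p$n_K, p$b0, p$bRf, p$bQf, p$bRb, p$bQb,
                         p$bCCT, p$bPUP, criterion = p$criterion)
}

#' Fit a customised keratometer index to a population
#'
#' Finds the keratometer index `n_K` converting front radius to corneal power
#' via `P_K = 1000 (n_K - 1)/R_f`. Mode `"least_squares"` (default) minimizes
#' `sum((CP - 1000 (n_K - 1)/R_f)^2)` in closed form; mode `"mean_zero"`
#' chooses `n_K` so that the mean deviation `mean(CP - P_K)` is exactly zero.
#'
#' @param CP corneal powers in dioptres.
#' @param R_f front radii in mm.
#' @param mode `"least_squares"` or `"mean_zero"`.
#' @return the fitted keratometer index.
#' @export
fit_keratometer_index <- function(CP, R_f,
                                  mode = c("least_squares", "mean_zero")) {
  mode <- match.arg(mode)
  if (length(CP) == 0L || length(CP) != length(R_f))
    stop("fit_keratometer_index: CP and R_f must be nonempty, equal length")
  if (any(R_f <= 0)) stop("fit_keratometer_index: R_f must be positive")
  x <- 1000 / R_f
  switch(mode,
         least_squares = 1 + sum(x * CP) / sum(x^2),
         mean_zero     = 1 + mean(CP) / mean(x))
}

#' Fit a multivariate corneal-power model
#'
#' Ordinary least squares for the deviation of corneal power from
#' keratometric power: the keratometric offset `1000 (n_K - 1)/R_f` is fixed,
#' and the residual `CP - offset` is regressed on the six covariates
#' (`R_f`, `Q_f`, `R_b`, `Q_b`, `CCT`, `PUP`) plus an intercept. The reported
#' `rms_error` is the residual RMS in dioptres and `r_squared` the fraction
#' of the deviation's variance explained.
#'
#' @param eyes data frame with columns `R_f`, `Q_f`, `R_b`, `Q_b`, `CCT`
#'   (mm), `PUP`.
#' @param CP corneal powers in dioptres (one per row of `eyes`).
#' @param n_K keratometer index fixing the offset term.
#' @param criterion optional label stored with the fit.
#' @return a `model_coefficients` object including fit statistics.
#' @export
fit_power_model <- function(eyes, CP, n_K, criterion = NA_character_) {
  eyes <- as.data.frame(eyes)
  need <- c("R_f", "Q_f", "R_b", "Q_b", "CCT", "PUP")
  if (!all(need %in% names(eyes)))
    stop("fit_power_model: eyes must have columns ",
         paste(need, collapse = ", "))
  if (nrow(eyes) < 8) stop("fit_power_model: need at least 8 eyes")
  if (length(CP) != nrow(eyes))
    stop("fit_power_model: CP must match rows of eyes")
  y <- CP - 1000 * (n_K - 1) / eyes$R_f
  fit <- stats::lm(y ~ R_f + Q_f + R_b + Q_b + CCT + PUP, data = eyes)
  if (any(is.na(stats::coef(fit))))
    stop("fit_power_model: rank-deficient design")
  b <- stats::coef(fit)
  res <- stats::residuals(fit)
  new_model_coefficients(
    n_K = n_K, b0 = unname(b["(Intercept)"]),
    bRf = unname(b["R_f"]), bQf = unname(b["Q_f"]),
    bRb = unname(b["R_b"]), bQb = unname(b["Q_b"]),
    bCCT = unname(b["CCT"]), bPUP = unname(b["PUP"]),
    criterion = criterion,
    rms_error = sqrt(mean(res^2)),
    r_squared = 1 - sum(res^2) / sum((y - mean(y))^2))
}

#' Export / import model coefficients as JSON
#'
#' Flat key-value serialization of a `model_coefficients` object. Units:
#' `b0`, `bQf`, `bQb` in dpt; `bRf`, `bRb`, `bCCT`, `bPUP` in dpt/mm.
#'
#' @param model a `model_coefficients` object.
#' @param path file path.
#' @return `write_model_coefficients` returns `path` invisibly;
#'   `read_model_coefficients` returns the object.
#' @export
write_model_coefficients <- function(model, path) {
  stopifnot(inherits(model, "model_coefficients"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_model_coefficients
#' @export
read_model_coefficients <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_model_coefficients(x$n_K, x$b0, x$bRf, x$bQf, x$bRb, x$bQb,
                         x$bCCT, x$bPUP,
                         criterion = if (is.null(x$criterion)) NA_character_
                                     else x$criterion,
                         rms_error = if (is.null(x$rms_error)) NA_real_
                                     else x$rms_error,
                         r_squared = if (is.null(x$r_squared)) NA_real_
                                     else x$r_squared)
}
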
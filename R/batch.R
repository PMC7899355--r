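#' Descriptive summary in the cohort-table layout
#'
#' Mean, SD, median, minimum, maximum and the 0.5%, 5%, 95% and 99.5%
#' quantiles (90% and 99% confidence intervals) per column, with quantiles
#' linearly interpolated between order statistics.
#'
#' @param x data frame or matrix of numeric columns.
#' @return data frame with one row per statistic.
#' @export
describe_population <- function(x) {
  x <- as.data.frame(x)
  x <- x[vapply(x, is.numeric, logical(1))]
  qs <- c(0.005, 0.05, 0.95, 0.995)
  stat <- function(v) c(Mean = mean(v), SD = stats::sd(v),
                        Median = stats::median(v),
                        Minimum = min(v), Maximum = max(v),
                        stats::quantile(v, qs, type = 7, names = FALSE))
  out <- as.data.frame(lapply(x, stat))
  rownames(out) <- c("Mean", "SD", "Median", "Minimum", "Maximum",
                     "Quantile 0.5%", "Quantile 5%", "Quantile 95%",
                     "Quantile 99.5%")
  out
}

#' Raytrace a batch of eyes and summarize the population
#'
#' For each eye: trace the collimated fan over the individual pupil, locate
#' the four best focal planes, convert to corneal power and per-eye
#' keratometer index, and (optionally) fit the Zernike spherical aberration
#' Z40 over the fixed 6 mm zone referenced to each best plane. Eyes whose
#' rays miss a surface, suffer total internal reflection or yield no focus
#' are flagged with a machine-readable reason code and excluded from
#' population summaries.
#'
#' Population-level post-processing fits the customised keratometer index per
#' criterion (both least-squares and mean-zero modes), computes the deviation
#' of corneal power from keratometric power, and refits the multivariate
#' corneal-power model per criterion.
#'
#' @param eyes data frame of eyes (columns `eye_id`, `R_f`, `Q_f`, `R_b`,
#'   `Q_b`, `CCT` in mm, `PUP` in mm).
#' @param n_rays rays across the pupil (default 1001).
#' @param weighting fan weighting, see [build_fan()].
#' @param method focus search method, see [best_focus()].
#' @param seed seed for the annealing path.
#' @param compute_sa fit Z40 per eye (default TRUE).
#' @param sa_rays rays across the 6 mm Zernike zone (default 201).
#' @param nk_mode keratometer-index mode used for the deviation columns.
#' @param constants an [optical_constants()] object.
#' @return object of class `batch_result`: `results` (per-eye data frame
#'   with, per criterion `c`, columns `zF_c`, `CP_c`, `nK_c`, `Z40_c`,
#'   `dev_c`), `failed` (eye_id + reason), `nK` (fitted indices, both
#'   modes), `models` (refitted `model_coefficients` per criterion), and
#'   `summaries` (descriptive tables for inputs, focus/power, SA/index,
#'   deviations).
#' @export
analyze_batch <- function(eyes, n_rays = 1001,
                          weighting = c("area_linear", "quadratic"),
                          method = c("brent", "anneal"), seed = 1L,
                          compute_sa = TRUE, sa_rays = 201,
                          nk_mode = c("least_squares", "mean_zero"),
                          constants = optical_constants()) {
  weighting <- match.arg(weighting)
  method <- match.arg(method)
  nk_mode <- match.arg(nk_mode)
  eyes <- as.data.frame(eyes)
  if (nrow(eyes) == 0L) stop("analyze_batch: empty eye list")
  if (is.null(eyes$eye_id)) eyes$eye_id <- sprintf("eye%05d", seq_len(nrow(eyes)))

  per_eye <- vector("list", nrow(eyes))
  failed <- list()
  for (i in seq_len(nrow(eyes))) {
    e <- eyes[i, ]
    res <- tryCatch({
      cm <- cornea_model(e$R_f, e$Q_f, e$R_b, e$Q_b, e$CCT, constants)
      traced <- trace_eye(cm, build_fan(e$PUP, n_rays, weighting))
      foci <- find_best_foci(traced, method = method, seed = seed)
      row <- list(eye_id = e$eye_id)
      for (cr in CRITERIA) {
        row[[paste0("zF_", cr)]] <- foci$z_F[[cr]]
        row[[paste0("CP_", cr)]] <- foci$CP[[cr]]
        row[[paste0("nK_", cr)]] <- foci$nK[[cr]]
        row[[paste0("Z40_", cr)]] <-
          if (compute_sa) spherical_aberration_z40(cm, foci$z_F[[cr]],
                                                   n_rays = sa_rays,
                                                   weighting = weighting)
          else NA_real_
      }
      as.data.frame(row, stringsAsFactors = FALSE)
    }, corneatrace_miss = function(c) c("miss"),
       corneatrace_tir = function(c) c("TIR"),
       corneatrace_nofocus = function(c) c("no-focus"),
       error = function(c) c(paste0("error: ", conditionMessage(c))))
    if (is.character(res)) {
      failed[[length(failed) + 1L]] <-
        data.frame(eye_id = e$eye_id, reason = res,
                   stringsAsFactors = FALSE)
    } else {
      per_eye[[i]] <- res
    }
  }
  results <- do.call(rbind, per_eye[!vapply(per_eye, is.null, logical(1))])
  failed <- if (length(failed)) do.call(rbind, failed) else
    data.frame(eye_id = character(), reason = character())
  if (is.null(results) || nrow(results) == 0L)
    stop("analyze_batch: all eyes failed")
  ok_inputs <- eyes[match(results$eye_id, eyes$eye_id), ]

  nK_fit <- list()
  models <- list()
  for (cr in CRITERIA) {
    CPc <- results[[paste0("CP_", cr)]]
    nK_fit[[cr]] <- c(
      least_squares = fit_keratometer_index(CPc, ok_inputs$R_f,
                                            "least_squares"),
      mean_zero = fit_keratometer_index(CPc, ok_inputs$R_f, "mean_zero"))
    nK_use <- nK_fit[[cr]][[nk_mode]]
    results[[paste0("dev_", cr)]] <-
      CPc - keratometric_power(ok_inputs$R_f, nK_use)
    models[[cr]] <- if (nrow(results) >= 8)
      fit_power_model(ok_inputs, CPc, nK_use, criterion = cr) else NULL
  }

  summaries <- list(
    inputs = describe_population(
      data.frame(R_f = ok_inputs$R_f, Q_f = ok_inputs$Q_f,
                 R_b = ok_inputs$R_b, Q_b = ok_inputs$Q_b,
                 CCT_um = ok_inputs$CCT * 1000, PUP = ok_inputs$PUP)),
    focus = describe_population(
      results[, unlist(lapply(CRITERIA,
                              function(cr) paste0(c("zF_", "CP_"), cr)))]),
    sa_index = describe_population(
      results[, c(if (compute_sa) paste0("Z40_", CRITERIA),
                  paste0("nK_", CRITERIA))]),
    deviation = describe_population(results[, paste0("dev_", CRITERIA)]))

  structure(list(results = results, failed = failed, nK = nK_fit,
                 models = models, summaries = summaries,
                 nk_mode = nk_mode, n_rays = n_rays,
                 weighting = weighting),
            class = "batch_result")
}

#' @export
print.batch_result <- function(x, ...) {
  cat(sprintf("Batch of %d eye(s) (%d failed), %d rays, %s weighting\n",
              nrow(x$results) + nrow(x$failed), nrow(x$failed),
              x$n_rays, x$weighting))
  cat("Fitted keratometer indices (least squares / mean zero):\n")
  for (cr in CRITERIA)
    cat(sprintf("  BFP-%-3s  %.4f / %.4f\n", cr,
                x$nK[[cr]][["least_squares"]], x$nK[[cr]][["mean_zero"]]))
  invisible(x)
}

#' Write batch results to disk
#'
#' Emits the per-eye results CSV, one summary CSV per descriptive table, and
#' the refitted model coefficients as JSON, under a common directory.
#'
#' @param batch a [analyze_batch()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_batch_results <- function(batch, dir) {
  stopifnot(inherits(batch, "batch_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(batch$results, file.path(dir, "per_eye_results.csv"),
                   row.names = FALSE)
  for (nm in names(batch$summaries)) {
    tab <- batch$summaries[[nm]]
    utils::write.csv(cbind(statistic = rownames(tab), tab),
                     file.path(dir, paste0("summary_", nm, ".csv")),
                     row.names = FALSE)
  }
  for (cr in names(batch$models))
    if (!is.null(batch$models[[cr]]))
      write_model_coefficients(batch$models[[cr]],
                               file.path(dir, paste0("model_", cr, ".json")))
  invisible(dir)
}
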
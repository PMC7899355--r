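#' Default marginal statistics for the synthetic population
#'
#' Mean, SD, minimum and maximum of the six biometry inputs in a large
#' cataract cohort (10,218 eyes): front/back central radius (mm), front/back
#' asphericity, central corneal thickness (micrometres) and pupil size (mm).
#' Used as the default `stats` argument of [population_spec()].
#'
#' @format data frame with columns `variable`, `mean`, `sd`, `min`, `max`.
#' @export
POPULATION_DEFAULTS <- data.frame(
  variable = c("R_f", "Q_f", "R_b", "Q_b", "CCT_um", "PUP"),
  mean = c(7.733, -0.3141, 6.534, -0.007, 547, 4.408),
  sd   = c(0.283,  0.249,  0.274,  0.213,  37,  0.789),
  min  = c(6.770, -1.486,  5.500, -0.988, 395, 1.528),
  max  = c(8.800,  0.584,  7.500,  0.602, 794, 6.800),
  stringsAsFactors = FALSE)

#' Specification of a synthetic biometry population
#'
#' Defines truncated-Gaussian marginals (mean, SD, min, max) for the six
#' per-eye inputs — front/back radius and asphericity, central corneal
#' thickness (micrometres) and pupil size — plus an optional 6x6 correlation
#' matrix. The defaults are the marginal statistics of a large cataract
#' cohort; only marginals are published for that cohort, so the default
#' correlation is the identity. A literature-style correlation (e.g. between
#' the two radii) can be supplied but is a modelling choice, not ground
#' truth.
#'
#' @param n number of eyes.
#' @param stats data frame like `POPULATION_DEFAULTS` (columns `variable`,
#'   `mean`, `sd`, `min`, `max`).
#' @param correlation 6x6 correlation matrix in the variable order of
#'   `stats` (default identity).
#' @param seed RNG seed.
#' @return object of class `population_spec`.
#' @export
population_spec <- function(n, stats = POPULATION_DEFAULTS,
                            correlation = diag(6), seed = 1L) {
  stats <- as.data.frame(stats)
  stopifnot(n >= 1, nrow(stats) == 6,
            all(c("variable", "mean", "sd", "min", "max") %in% names(stats)))
  if (any(stats$sd <= 0)) stop("population_spec: SDs must be positive")
  if (any(stats$min >= stats$mean) || any(stats$mean >= stats$max))
    stop("population_spec: need min < mean < max per variable")
  correlation <- as.matrix(correlation)
  if (!isTRUE(all.equal(correlation, t(correlation))) ||
      any(eigen(correlation, symmetric = TRUE,
                only.values = TRUE)$values <= 0))
    stop("population_spec: correlation must be symmetric positive-definite")
  structure(list(n = as.integer(n), stats = stats,
                 correlation = correlation, seed = as.integer(seed)),
            class = "population_spec")
}

#' Sample a synthetic biometry population
#'
#' Draws from a multivariate normal with the specified marginal means/SDs and
#' correlation, truncated to the per-variable `[min, max]` bounds by
#' rejection. CCT is sampled in micrometres and stored in mm.
#'
#' @param spec a [population_spec()].
#' @return data frame of eyes: `eye_id`, `R_f`, `Q_f`, `R_b`, `Q_b`,
#'   `CCT` (mm), `PUP` (mm).
#' @examples
#' eyes <- sample_population(population_spec(100, seed = 7))
#' colMeans(eyes[-1])
#' @export
sample_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  st <- spec$stats
  Sigma <- diag(st$sd) %*% spec$correlation %*% diag(st$sd)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)

  out <- matrix(NA_real_, nrow = 0, ncol = 6)
  tried <- 0L
  while (nrow(out) < spec$n) {
    batch <- max(spec$n - nrow(out), 100L)
    draw <- MASS::mvrnorm(2L * batch, mu = st$mean, Sigma = Sigma)
    tried <- tried + 2L * batch
    keep <- rep(TRUE, nrow(draw))
    for (j in 1:6)
      keep <- keep & draw[, j] >= st$min[j] & draw[, j] <= st$max[j]
    out <- rbind(out, draw[keep, , drop = FALSE])
    if (tried >= 200L * spec$n && nrow(out) < 0.01 * tried)
      stop("sample_population: truncation acceptance below 1%; bounds infeasible")
  }
  out <- out[seq_len(spec$n), , drop = FALSE]
  colnames(out) <- st$variable
  data.frame(eye_id = sprintf("syn%05d", seq_len(spec$n)),
             R_f = out[, "R_f"], Q_f = out[, "Q_f"],
             R_b = out[, "R_b"], Q_b = out[, "Q_b"],
             CCT = out[, "CCT_um"] / 1000, PUP = out[, "PUP"],
             stringsAsFactors = FALSE)
}

#' Read corneal biometry from a tomographer-style CSV export
#'
#' Reads per-eye biometry records from a delimited text export (Casia-like
#' dialect: configurable separator and decimal mark). Columns are resolved
#' through a header map; either asphericity (`Qf`/`Qb`) or eccentricity
#' (`ecc_f`/`ecc_b`) columns are accepted, the latter converted via
#' `Q = -e^2`. CCT is read in micrometres and stored in mm. Negative radius
#' magnitudes (a sign convention occasionally seen in exports) are
#' normalized to positive with a warning. Rows with missing required fields
#' are dropped with a reported count.
#'
#' @param path CSV file path.
#' @param header_map named character vector mapping internal names
#'   (`eye_id`, `R_f`, `Q_f`, `ecc_f`, `R_b`, `Q_b`, `ecc_b`, `CCT_um`,
#'   `PUP`) to file column names.
#' @param sep field separator (default `","`).
#' @param dec decimal mark (default `"."`).
#' @return data frame of eyes as in [sample_population()].
#' @export
read_casia_csv <- function(path,
                           header_map = c(eye_id = "eye_id", R_f = "Rf_mm",
                                          Q_f = "Qf", ecc_f = "ecc_f",
                                          R_b = "Rb_mm", Q_b = "Qb",
                                          ecc_b = "ecc_b", CCT_um = "CCT_um",
                                          PUP = "PUP_mm"),
                           sep = ",", dec = ".") {
  if (!file.exists(path)) stop("read_casia_csv: file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, dec = dec,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) stop("read_casia_csv: empty file")
  col <- function(key) {
    nm <- header_map[[key]]
    if (!is.null(nm) && nm %in% names(raw)) raw[[nm]] else NULL
  }
  q_from <- function(qcol, ecol, side) {
    q <- col(qcol)
    if (!is.null(q)) return(q)
    e <- col(ecol)
    if (is.null(e))
      stop("read_casia_csv: need an asphericity or eccentricity column for the ",
           side, " surface")
    e <- as.numeric(e)
    if (any(e < 0, na.rm = TRUE))
      stop("read_casia_csv: negative eccentricity in the ", side,
           " surface column")
    out <- rep(NA_real_, length(e))      # NA rows dropped downstream
    out[!is.na(e)] <- eccentricity_to_asphericity(e[!is.na(e)])
    out
  }
  R_f <- col("R_f"); R_b <- col("R_b")
  CCT_um <- col("CCT_um"); PUP <- col("PUP")
  if (is.null(R_f) || is.null(R_b) || is.null(CCT_um) || is.null(PUP))
    stop("read_casia_csv: missing required column(s) among R_f, R_b, CCT_um, PUP")
  Q_f <- q_from("Q_f", "ecc_f", "front")
  Q_b <- q_from("Q_b", "ecc_b", "back")
  id <- col("eye_id")
  if (is.null(id)) id <- sprintf("eye%05d", seq_len(nrow(raw)))

  eyes <- data.frame(eye_id = as.character(id),
                     R_f = as.numeric(R_f), Q_f = as.numeric(Q_f),
                     R_b = as.numeric(R_b), Q_b = as.numeric(Q_b),
                     CCT = as.numeric(CCT_um) / 1000, PUP = as.numeric(PUP),
                     stringsAsFactors = FALSE)
  neg <- which(eyes$R_f < 0 | eyes$R_b < 0)
  if (length(neg)) {
    warning("read_casia_csv: ", length(neg),
            " negative radius value(s) normalized to positive magnitude")
    eyes$R_f <- abs(eyes$R_f); eyes$R_b <- abs(eyes$R_b)
  }
  complete <- stats::complete.cases(eyes[, c("R_f", "Q_f", "R_b", "Q_b",
                                             "CCT", "PUP")])
  if (any(!complete))
    message("read_casia_csv: dropped ", sum(!complete), " incomplete row(s)")
  eyes[complete, , drop = FALSE]
}

#' Write corneal biometry to CSV
#'
#' Inverse of [read_casia_csv()] with the default header map; CCT is written
#' in micrometres.
#'
#' @param eyes data frame of eyes (CCT in mm).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_casia_csv <- function(eyes, path) {
  out <- data.frame(eye_id = eyes$eye_id, Rf_mm = eyes$R_f, Qf = eyes$Q_f,
                    Rb_mm = eyes$R_b, Qb = eyes$Q_b,
                    CCT_um = eyes$CCT * 1000, PUP_mm = eyes$PUP)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
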
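#' Optical constants of the corneal model
#'
#' Refractive indices of the media surrounding and forming the cornea. The
#' defaults (cornea 1.376, aqueous humour 1.336) follow the Liou & Brennan
#' schematic model eye.
#'
#' @param n_air refractive index in front of the cornea.
#' @param n_cornea refractive index of the corneal stroma.
#' @param n_aqueous refractive index of the aqueous humour.
#' @return object of class `optical_constants`.
#' @export
optical_constants <- function(n_air = 1.0, n_cornea = 1.376,
                              n_aqueous = 1.336) {
  stopifnot(n_air > 0, n_cornea > n_aqueous, n_aqueous > n_air)
  structure(list(n_air = n_air, n_cornea = n_cornea, n_aqueous = n_aqueous),
            class = "optical_constants")
}

#' Two-surface conic model of the cornea
#'
#' Front and back surfaces are conics of revolution; the front apex sits at
#' the origin and the back apex at `z = CCT`. All lengths in mm.
#'
#' @param R_f,Q_f front surface central radius (mm) and asphericity.
#' @param R_b,Q_b back surface central radius (mm) and asphericity.
#' @param CCT central corneal thickness in mm.
#' @param constants an [optical_constants()] object.
#' @return object of class `cornea_model` with elements `front`, `back`,
#'   `CCT`, `constants`.
#' @examples
#' # population-mean cornea of a cataract cohort
#' eye <- cornea_model(7.733, -0.3141, 6.534, -0.007, 0.547)
#' @export
cornea_model <- function(R_f, Q_f, R_b, Q_b, CCT,
                         constants = optical_constants()) {
  stopifnot(R_f > 0, R_b > 0, CCT > 0, inherits(constants, "optical_constants"))
  if (CCT > 2)
    warning("cornea_model: CCT = ", CCT,
            " mm looks like micrometres; expected ~0.5 mm")
  structure(list(front = conic_surface(R_f, Q_f, z0 = 0),
                 back  = conic_surface(R_b, Q_b, z0 = CCT),
                 CCT = CCT, constants = constants),
            class = "cornea_model")
}

#' @export
print.cornea_model <- function(x, ...) {
  cat(sprintf(
    "Cornea: front R=%.4f Q=%+.4f | back R=%.4f Q=%+.4f | CCT=%.1f um\n",
    x$front$R, x$front$Q, x$back$R, x$back$Q, 1000 * x$CCT))
  cat(sprintf("  indices: cornea %.3f, aqueous %.3f\n",
              x$constants$n_cornea, x$constants$n_aqueous))
  invisible(x)
}

#' Refract a ray direction with Snell's law
#'
#' Vector form of Snell's law in the meridional plane. The normal must point
#' toward the incident side (`sum(direction * normal) < 0`).
#'
#' @param direction incident unit 2-vector.
#' @param normal unit surface normal, oriented toward the incident medium.
#' @param n1,n2 refractive indices before and after the interface.
#' @return refracted unit 2-vector. Signals an error of class
#'   `corneatrace_tir` on total internal reflection.
#' @examples
#' refract_snell(c(sin(pi / 6), cos(pi / 6)), c(0, -1), 1.0, 1.376)
#' @export
refract_snell <- function(direction, normal, n1, n2) {
  stopifnot(length(direction) == 2L, length(normal) == 2L, n1 > 0, n2 > 0)
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-9 ||
      abs(sqrt(sum(normal^2)) - 1) > 1e-9)
    stop("refract_snell: direction and normal must be unit vectors")
  out <- refract_vec(direction[1], direction[2], normal[1], normal[2], n1, n2)
  if (any(out$tir))
    stop(structure(class = c("corneatrace_tir", "error", "condition"),
                   list(message = "refract_snell: total internal reflection",
                        call = sys.call(-1))))
  c(out$dy, out$dz)
}

# Vectorized Snell refraction. Normals must point toward the incident side.
# t = mu d + (mu cos_i - cos_t) n, mu = n1/n2, cos_i = -d.n
refract_vec <- function(dy, dz, ny, nz, n1, n2) {
  mu <- n1 / n2
  ci <- -(dy * ny + dz * nz)
  s2 <- mu^2 * (1 - ci^2)
  tir <- s2 > 1
  ct <- sqrt(pmax(0, 1 - s2))
  k <- mu * ci - ct
  ty <- mu * dy + k * ny
  tz <- mu * dz + k * nz
  nrm <- sqrt(ty^2 + tz^2)
  list(dy = ty / nrm, dz = tz / nrm, tir = tir)
}

#' Build a collimated, area-weighted ray fan
#'
#' Rays are equally spaced in the radial direction across the aperture
#' diameter, from `-aperture/2` to `+aperture/2` (an odd count includes the
#' chief ray at 0). Because a meridional ray at height `r` represents an
#' annulus of area proportional to `r`, the default weighting is
#' `w ~ |r|` (`area_linear`); `w ~ r^2` (`quadratic`) is available as an
#' alternative area-correction convention. Weights are normalized to sum 1;
#' the chief ray carries zero weight in statistics but is retained.
#'
#' @param aperture_diameter aperture (pupil projected to the corneal front
#'   surface) in mm.
#' @param n_rays number of rays (default 1001).
#' @param weighting `"area_linear"` (default) or `"quadratic"`.
#' @return object of class `ray_fan` with `heights`, `weights`, `n_rays`.
#' @examples
#' fan <- build_fan(4.408, 1001)
#' sum(fan$weights)
#' @export
build_fan <- function(aperture_diameter, n_rays = 1001,
                      weighting = c("area_linear", "quadratic")) {
  weighting <- match.arg(weighting)
  if (!is.numeric(aperture_diameter) || aperture_diameter <= 0)
    stop("build_fan: aperture_diameter must be positive")
  if (n_rays < 3) stop("build_fan: need at least 3 rays")
  # symmetric integer index grid: exact mirror pairs, spacing D/(n-1),
  # endpoints at +/- D/2, chief ray included for odd counts
  idx <- seq_len(n_rays) - (n_rays + 1) / 2
  h <- idx * (aperture_diameter / (n_rays - 1))
  w <- switch(weighting, area_linear = abs(h), quadratic = h^2)
  w <- w / sum(w)
  structure(list(heights = h, weights = w, n_rays = as.integer(n_rays),
                 aperture = aperture_diameter, weighting = weighting),
            class = "ray_fan")
}

#' Trace a collimated fan through the cornea
#'
#' Each ray starts on the plano wavefront at `z = 0` at its fan height,
#' travelling along +z. It is intersected with the corneal front surface,
#' refracted into the stroma, intersected with the back surface and refracted
#' into the aqueous. The cumulative optical path length (OPL) is accumulated
#' as `sum(n_medium * segment length)` from the starting plane to the
#' back-surface exit point, so the chief ray carries
#' `OPL = n_cornea * CCT`.
#'
#' @param cornea a [cornea_model()].
#' @param fan a [ray_fan()].
#' @return object of class `traced_fan`: vectors `y`, `z` (exit point on the
#'   back surface, mm), `dy`, `dz` (exit unit direction in aqueous), `opl`
#'   (mm), `weights`, plus the generating `cornea` and `fan`. Signals an
#'   error of class `corneatrace_miss` when rays fall outside a surface and
#'   `corneatrace_tir` on total internal reflection.
#' @examples
#' eye <- cornea_model(7.733, -0.3141, 6.534, -0.007, 0.547)
#' tf <- trace_eye(eye, build_fan(4.408, 101))
#' @export
trace_eye <- function(cornea, fan) {
  stopifnot(inherits(cornea, "cornea_model"), inherits(fan, "ray_fan"))
  k <- cornea$constants
  h <- fan$heights
  n <- length(h)
  dy <- rep(0, n); dz <- rep(1, n)

  hit1 <- conic_intersect_vec(cornea$front, h, rep(0, n), dy, dz)
  if (!all(hit1$ok))
    stop(miss_condition("front", which(!hit1$ok)))
  nrm1 <- conic_normal_vec(cornea$front, hit1$y)
  r1 <- refract_vec(dy, dz, nrm1$ny, nrm1$nz, k$n_air, k$n_cornea)
  if (any(r1$tir)) stop(tir_condition("front", which(r1$tir)))

  hit2 <- conic_intersect_vec(cornea$back, hit1$y, hit1$z, r1$dy, r1$dz)
  if (!all(hit2$ok))
    stop(miss_condition("back", which(!hit2$ok)))
  nrm2 <- conic_normal_vec(cornea$back, hit2$y)
  r2 <- refract_vec(r1$dy, r1$dz, nrm2$ny, nrm2$nz, k$n_cornea, k$n_aqueous)
  if (any(r2$tir)) stop(tir_condition("back", which(r2$tir)))

  opl <- k$n_air * hit1$t + k$n_cornea * hit2$t
  structure(list(y = hit2$y, z = hit2$z, dy = r2$dy, dz = r2$dz,
                 opl = opl, weights = fan$weights,
                 cornea = cornea, fan = fan),
            class = "traced_fan")
}

miss_condition <- function(surface, idx) {
  structure(class = c("corneatrace_miss", "error", "condition"),
            list(message = sprintf(
              "trace_eye: %d ray(s) miss the %s surface", length(idx), surface),
              call = NULL, surface = surface, rays = idx))
}

tir_condition <- function(surface, idx) {
  structure(class = c("corneatrace_tir", "error", "condition"),
            list(message = sprintf(
              "trace_eye: total internal reflection at the %s surface for %d ray(s)",
              surface, length(idx)),
              call = NULL, surface = surface, rays = idx))
}
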
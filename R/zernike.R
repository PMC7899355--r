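# Radial Zernike polynomials, OSA/ANSI normalization, on rho in [0, 1]
zernike_radial_basis <- function(rho) {
  cbind(Z00 = rep(1, length(rho)),
        Z20 = sqrt(3) * (2 * rho^2 - 1),
        Z40 = sqrt(5) * (6 * rho^4 - 6 * rho^2 + 1),
        Z60 = sqrt(7) * (20 * rho^6 - 30 * rho^4 + 12 * rho^2 - 1))
}

#' Optical path difference map over the 6 mm zone
#'
#' Traces a fan spanning a fixed-diameter zone (default 6 mm, independent of
#' the pupil) through the cornea and computes, at the corneal front apex
#' plane, the optical path difference of each ray relative to the bundle:
#' `OPD_i = mean_w(L) - L_i` in micrometres, where `L_i` is the total optical
#' path from the `z = 0` plane to the reference focus point `(0, z_F)` along
#' ray i and `mean_w` is the fan-weighted mean (piston removal). Rays that
#' arrive phase-advanced (shorter path) carry positive OPD, so a cornea with
#' positive spherical aberration yields positive marginal OPD.
#'
#' @param cornea a [cornea_model()].
#' @param z_F reference focus distance in mm (typically a best-focus plane).
#' @param n_rays rays across the zone (default 201).
#' @param zone_diameter zone diameter in mm (default 6).
#' @param weighting fan weighting, as in [build_fan()].
#' @return object of class `opd_map` with `radii` (mm), `opd` (micrometres),
#'   `weights`, `focus_plane`, `zone_diameter`.
#' @export
opd_at_apex_plane <- function(cornea, z_F, n_rays = 201, zone_diameter = 6,
                              weighting = "area_linear") {
  stopifnot(inherits(cornea, "cornea_model"), z_F > 0)
  half <- zone_diameter / 2
  if (surface_extent(cornea$front) < half || surface_extent(cornea$back) < half)
    stop("opd_at_apex_plane: surface extent smaller than the requested zone")
  fan <- build_fan(zone_diameter, n_rays, weighting)
  traced <- trace_eye(cornea, fan)
  L <- opl_to_point(traced, z_F)
  w <- traced$weights
  opd <- 1000 * (sum(w * L) / sum(w) - L)
  structure(list(radii = fan$heights, opd = opd, weights = w,
                 focus_plane = z_F, zone_diameter = zone_diameter),
            class = "opd_map")
}

#' Fit rotationally symmetric Zernike coefficients to an OPD map
#'
#' Weighted least-squares fit of the radial Zernike polynomials Z00, Z20,
#' Z40 and Z60 (OSA/ANSI normalization; e.g. the Z40 radial polynomial is
#' `sqrt(5) (6 rho^4 - 6 rho^2 + 1)`) on the normalized radius
#' `rho = r / (zone_diameter/2)`. Z60 is included to stabilize Z40 against
#' higher-order leakage under discrete, weighted sampling.
#'
#' @param map an [opd_at_apex_plane()] result.
#' @return object of class `zernike_result`: coefficients `Z00`, `Z20`,
#'   `Z40`, `Z60` in micrometres and the RMS fit residual.
#' @export
fit_radial_zernikes <- function(map) {
  stopifnot(inherits(map, "opd_map"))
  if (length(unique(abs(map$radii))) < 8)
    stop("fit_radial_zernikes: need at least 8 distinct radii")
  rho <- abs(map$radii) / (map$zone_diameter / 2)
  X <- zernike_radial_basis(rho)
  w <- map$weights
  # weighted normal equations (4x4); weights are the fan area weights
  XtW <- t(X * w)
  coefs <- solve(XtW %*% X, XtW %*% map$opd)
  fitted <- as.numeric(X %*% coefs)
  rms <- sqrt(sum(w * (map$opd - fitted)^2) / sum(w))
  structure(list(Z00 = unname(coefs["Z00", 1]), Z20 = unname(coefs["Z20", 1]),
                 Z40 = unname(coefs["Z40", 1]), Z60 = unname(coefs["Z60", 1]),
                 residual_rms = rms, zone_diameter = map$zone_diameter),
            class = "zernike_result")
}

#' @export
print.zernike_result <- function(x, ...) {
  cat(sprintf(
    "Radial Zernike fit over %.1f mm zone (um): Z00 %+0.4f  Z20 %+0.4f  Z40 %+0.4f  Z60 %+0.4f  (residual RMS %.2e)\n",
    x$zone_diameter, x$Z00, x$Z20, x$Z40, x$Z60, x$residual_rms))
  invisible(x)
}

#' Spherical aberration of a cornea at a reference focus
#'
#' Convenience wrapper: OPD map over the fixed zone referenced to `z_F`,
#' followed by the radial Zernike fit; returns the Z40 coefficient in
#' micrometres.
#'
#' @inheritParams opd_at_apex_plane
#' @return Z40 in micrometres.
#' @export
spherical_aberration_z40 <- function(cornea, z_F, n_rays = 201,
                                     zone_diameter = 6,
                                     weighting = "area_linear") {
  fit_radial_zernikes(
    opd_at_apex_plane(cornea, z_F, n_rays, zone_diameter, weighting))$Z40
}
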
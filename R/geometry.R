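#' Conic (quadric-of-revolution) corneal surface
#'
#' Represents one rotationally symmetric refracting interface of the cornea as
#' a conic section of revolution: apex at axial position `z0`, central radius
#' of curvature `R` and asphericity `Q` (conic constant). `Q = 0` is a sphere,
#' `Q < 0` a prolate ellipsoid (the typical cornea), `Q = -1` a paraboloid.
#'
#' The sag relative to the apex is
#' \deqn{z - z_0 = \frac{r^2/R}{1 + \sqrt{1 - (1+Q)\,r^2/R^2}}}
#' which has central curvature `1/R` and, for `Q > -1`, a bounded radial
#' extent `r_max = R / sqrt(1+Q)`.
#'
#' @param R central radius of curvature in mm (> 0 for a surface convex toward
#'   the incoming light, i.e. toward -z).
#' @param Q asphericity (dimensionless conic constant).
#' @param z0 axial position of the surface apex in mm (default 0).
#' @return An object of class `conic_surface`.
#' @examples
#' s <- conic_surface(R = 7.733, Q = -0.3141)
#' conic_sag(s, 3.0)
#' @export
conic_surface <- function(R, Q, z0 = 0) {
  stopifnot(is.numeric(R), length(R) == 1L, is.finite(R),
            is.numeric(Q), length(Q) == 1L, is.finite(Q),
            is.numeric(z0), length(z0) == 1L, is.finite(z0))
  if (R == 0) stop("conic_surface: radius R must be nonzero")
  structure(list(R = R, Q = Q, z0 = z0), class = "conic_surface")
}

#' @export
print.conic_surface <- function(x, ...) {
  cat(sprintf("Conic surface: R = %.4f mm, Q = %+.4f, apex z0 = %.4f mm\n",
              x$R, x$Q, x$z0))
  ext <- surface_extent(x)
  if (is.finite(ext)) cat(sprintf("  radial extent: %.4f mm\n", ext))
  invisible(x)
}

#' Maximum radial extent of a conic surface
#'
#' For `Q > -1` the conic closes at `r = R/sqrt(1+Q)`; paraboloids (`Q = -1`)
#' and hyperboloids (`Q < -1`) are unbounded.
#'
#' @param surface a [conic_surface()].
#' @return extent in mm (possibly `Inf`).
#' @export
surface_extent <- function(surface) {
  stopifnot(inherits(surface, "conic_surface"))
  p <- 1 + surface$Q
  if (p > 0) abs(surface$R) / sqrt(p) else Inf
}

#' Convert corneal eccentricity to asphericity
#'
#' Uses the standard corneal-topography convention `Q = -e^2`: a sphere
#' (`e = 0`) has `Q = 0`, a parabola (`e = 1`) has `Q = -1`.
#'
#' @param e numeric vector of eccentricities, all >= 0.
#' @return asphericity values `-e^2`.
#' @examples
#' eccentricity_to_asphericity(0.5604)  # ~ -0.314, a typical cornea
#' @export
eccentricity_to_asphericity <- function(e) {
  if (!is.numeric(e) || any(!is.finite(e)) || any(e < 0))
    stop("eccentricity_to_asphericity: e must be finite and >= 0")
  -e^2
}

#' Sag of a conic surface
#'
#' Axial depth `z - z0` of the surface at radial height `r`, even in `r`.
#'
#' @param surface a [conic_surface()].
#' @param r radial height(s) in mm; must lie within the surface extent.
#' @return sag in mm (0 at the apex).
#' @export
conic_sag <- function(surface, r) {
  stopifnot(inherits(surface, "conic_surface"), is.numeric(r))
  R <- surface$R; Q <- surface$Q
  disc <- 1 - (1 + Q) * r^2 / R^2
  if (any(disc < 0))
    stop("conic_sag: r beyond the geometric extent of the surface")
  (r^2 / R) / (1 + sqrt(disc))
}

#' Outward surface normal of a conic surface
#'
#' Unit normal at radial height `r`, oriented toward the incident side
#' (-z). Returned as `c(radial, axial)`. On axis it is `c(0, -1)`.
#'
#' @param surface a [conic_surface()].
#' @param r radial height in mm within the surface extent.
#' @return unit 2-vector `c(ny, nz)`.
#' @export
surface_normal <- function(surface, r) {
  stopifnot(inherits(surface, "conic_surface"), is.numeric(r), length(r) == 1L)
  n <- conic_normal_vec(surface, r)
  c(n$ny, n$nz)
}

# Vectorized normal; dz/dr = (r/R) / sqrt(1 - (1+Q) r^2/R^2).
# Normal along (dz/dr, -1), normalized; points toward -z.
conic_normal_vec <- function(surface, r) {
  R <- surface$R; Q <- surface$Q
  disc <- 1 - (1 + Q) * r^2 / R^2
  if (any(disc <= 0))
    stop("surface_normal: r beyond the geometric extent of the surface")
  slope <- (r / R) / sqrt(disc)
  nrm <- sqrt(slope^2 + 1)
  list(ny = slope / nrm, nz = -1 / nrm)
}

#' Intersection of a ray with a conic surface
#'
#' Finds the first intersection of the ray `origin + t * direction` (t > 0)
#' with the apex-side branch of the conic. The conic in implicit form is
#' `y^2 - 2 R (z - z0) + (1+Q) (z - z0)^2 = 0`; substituting the ray gives a
#' quadratic in the travel parameter, solved in the numerically stable
#' formulation (no subtraction of nearly equal terms for paraxial rays).
#'
#' @param origin numeric 2-vector `c(y, z)` in mm.
#' @param direction unit 2-vector `c(dy, dz)` with `dz > 0` (propagating
#'   toward +z).
#' @param surface a [conic_surface()].
#' @return intersection point `c(y, z)` in mm.
#' @export
ray_surface_intersection <- function(origin, direction, surface) {
  stopifnot(inherits(surface, "conic_surface"),
            is.numeric(origin), length(origin) == 2L,
            is.numeric(direction), length(direction) == 2L)
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-9)
    stop("ray_surface_intersection: direction must be a unit vector")
  if (direction[2] <= 0)
    stop("ray_surface_intersection: ray must propagate toward +z")
  hit <- conic_intersect_vec(surface, origin[1], origin[2],
                             direction[1], direction[2])
  if (!hit$ok)
    stop("ray_surface_intersection: ray misses the surface")
  c(hit$y, hit$z)
}

# Vectorized ray/conic intersection.  oy,oz,dy,dz are equal-length vectors.
# Returns list(ok, t, y, z).  Chooses the smallest positive root on the
# apex branch (sag <= R/(1+Q) for prolate/oblate ellipsoids, sag >= 0 always).
conic_intersect_vec <- function(surface, oy, oz, dy, dz) {
  R <- surface$R; Q <- surface$Q; z0 <- surface$z0
  p <- 1 + Q
  zr <- oz - z0
  A <- dy^2 + p * dz^2
  B <- 2 * (oy * dy + p * zr * dz - R * dz)
  C <- oy^2 + p * zr^2 - 2 * R * zr

  n <- length(oy)
  t1 <- rep(NA_real_, n); t2 <- rep(NA_real_, n)

  lin <- abs(A) < 1e-14 * pmax(abs(B), 1)
  # linear case (paraboloid hit axially): B t + C = 0
  t1[lin] <- -C[lin] / B[lin]

  qd <- !lin
  disc <- B^2 - 4 * A * C
  real <- qd & disc >= 0
  if (any(real)) {
    sq <- sqrt(disc[real])
    qq <- -0.5 * (B[real] + sign(B[real] + (B[real] == 0)) * sq)
    r1 <- qq / A[real]
    r2 <- ifelse(qq != 0, C[real] / qq, r1)
    t1[real] <- r1
    t2[real] <- r2
  }

  sag_max <- if (p > 0) R / p else Inf
  pick <- function(tt) {
    zz <- oz + tt * dz - z0
    ok <- !is.na(tt) & tt > -1e-12 & zz > -1e-9 & zz <= sag_max + 1e-9
    ifelse(ok, tt, Inf)
  }
  tbest <- pmin(pick(t1), pick(t2))
  ok <- is.finite(tbest)
  tbest[!ok] <- NA_real_
  list(ok = ok, t = tbest, y = oy + tbest * dy, z = oz + tbest * dz)
}
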
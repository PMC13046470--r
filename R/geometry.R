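#' Polar radius of a spherical cap
#'
#' Evaluates the polar-coordinate profile of a spherical cap whose centre
#' lies on the symmetry axis,
#' \deqn{r(\theta; \kappa, \gamma) = \cos\theta/\gamma +
#'   \sqrt{1/\kappa^2 - \sin^2\theta/\gamma^2},}
#' where \eqn{\kappa = 1/R} is the curvature and \eqn{\gamma = 1/C} the
#' reciprocal of the centre offset along the axis. The polar angle
#' \eqn{\theta} is measured from the positive axis (the alpha-cap apex).
#'
#' @param theta Polar angle(s) in radians.
#' @param kappa Curvature, \eqn{1/R} (inverse length).
#' @param gamma Reciprocal centre offset, \eqn{1/C} (inverse length). Use
#'   `Inf` for a cap centred at the origin.
#' @return Numeric vector of radii, same length as `theta`.
#' @examples
#' cap_radius(0, kappa = 1, gamma = 1 / 0.2)      # C + R
#' cap_radius(pi / 2, kappa = 0.5, gamma = 2)     # sqrt(4 - 0.25)
#' @export
cap_radius <- function(theta, kappa, gamma) {
  stopifnot(is.numeric(theta), length(kappa) == 1, length(gamma) == 1)
  if (kappa <= 0) rlang::abort("`kappa` must be positive.")
  cap_radius_rc(theta, R = 1 / kappa, C = if (is.infinite(gamma)) 0 else 1 / gamma)
}

# (R, C) parameterization of the same profile; regular at C = 0.
cap_radius_rc <- function(theta, R, C) {
  radicand <- R^2 - C^2 * sin(theta)^2
  if (any(radicand < -1e-12 * R^2)) {
    rlang::abort("Point not on cap: negative radicand in the cap profile.",
                 class = "polartissue_domain_error")
  }
  C * cos(theta) + sqrt(pmax(radicand, 0))
}

#' Construct a two-spherical-cap tissue geometry
#'
#' The tissue boundary is modelled as two spherical caps joined at the
#' equator (polar angle \eqn{\pi/2}): the alpha cap (ExE-facing interface,
#' \eqn{\theta \in [0, \pi/2]}) and the beta cap (VE-facing interface,
#' \eqn{\theta \in [\pi/2, \pi]}). Each cap has radius \eqn{R_\mu} and an
#' axial centre offset \eqn{C_\mu}. Continuity at the equator requires
#' \eqn{\sqrt{R_\alpha^2 - C_\alpha^2} = \sqrt{R_\beta^2 - C_\beta^2}}.
#'
#' The enclosed volume \eqn{V_0} and the characteristic length
#' \eqn{R_0 = (3 V_0 / 4\pi)^{1/3}} are computed on construction.
#'
#' @param R_alpha,C_alpha Radius and centre offset of the alpha cap.
#' @param R_beta,C_beta Radius and centre offset of the beta cap.
#' @param tol Relative tolerance for the equator-continuity check.
#' @return An object of class `cap_geometry` with fields `R_alpha`,
#'   `C_alpha`, `R_beta`, `C_beta`, the equivalent `kappa_*`/`gamma_*`,
#'   `V0` and `R0`.
#' @examples
#' geom <- cap_geometry(1, 0.2, 1, 0.2)  # a sphere centred at z = 0.2
#' geom$V0 / (4 * pi / 3)                # == 1
#' @export
cap_geometry <- function(R_alpha, C_alpha, R_beta, C_beta, tol = 1e-6) {
  stopifnot(R_alpha > 0, R_beta > 0)
  if (abs(C_alpha) >= R_alpha || abs(C_beta) >= R_beta) {
    rlang::abort("Centre offsets must satisfy |C| < R for a cap crossing the equator.")
  }
  r_eq_a <- sqrt(R_alpha^2 - C_alpha^2)
  r_eq_b <- sqrt(R_beta^2 - C_beta^2)
  geom <- structure(
    list(
      R_alpha = R_alpha, C_alpha = C_alpha,
      R_beta = R_beta, C_beta = C_beta,
      kappa_alpha = 1 / R_alpha, gamma_alpha = 1 / C_alpha,
      kappa_beta = 1 / R_beta, gamma_beta = 1 / C_beta,
      r_equator = r_eq_a
    ),
    class = "cap_geometry"
  )
  scale <- max(R_alpha, R_beta)
  if (abs(r_eq_a - r_eq_b) > tol * scale) {
    rlang::abort(sprintf(
      "Caps do not meet at the equator: r_alpha(pi/2) = %.8g, r_beta(pi/2) = %.8g.",
      r_eq_a, r_eq_b))
  }
  # apex radii must be positive
  if (boundary_radius(geom, 0) <= 0 || boundary_radius(geom, pi) <= 0) {
    rlang::abort("Degenerate geometry: non-positive apex radius.")
  }
  geom$V0 <- enclosed_volume(geom)
  geom$R0 <- (3 * geom$V0 / (4 * pi))^(1 / 3)
  geom
}

#' @export
print.cap_geometry <- function(x, ...) {
  cat("<cap_geometry>\n")
  cat(sprintf("  alpha cap: R = %.6g, C = %.6g\n", x$R_alpha, x$C_alpha))
  cat(sprintf("  beta  cap: R = %.6g, C = %.6g\n", x$R_beta, x$C_beta))
  cat(sprintf("  V0 = %.6g, R0 = %.6g\n", x$V0, x$R0))
  invisible(x)
}

#' Boundary radius of the full two-cap profile
#'
#' Piecewise cap profile: the alpha cap for \eqn{\theta \le \pi/2}, the beta
#' cap beyond.
#'
#' @param geom A [cap_geometry()].
#' @param theta Polar angle(s) in radians, in \eqn{[0, \pi]}.
#' @return Radii at `theta`.
#' @export
boundary_radius <- function(geom, theta) {
  out <- numeric(length(theta))
  a <- theta <= pi / 2
  out[a] <- cap_radius_rc(theta[a], geom$R_alpha, geom$C_alpha)
  out[!a] <- cap_radius_rc(theta[!a], geom$R_beta, geom$C_beta)
  out
}

#' Test whether slice points lie inside the tissue domain
#'
#' @param geom A [cap_geometry()].
#' @param x,z Coordinates in the meridional half-plane (`x >= 0`).
#' @return Logical vector.
#' @export
inside_domain <- function(geom, x, z) {
  r <- sqrt(x^2 + z^2)
  theta <- atan2(x, z)
  r <= boundary_radius(geom, theta)
}

#' Enclosed volume and characteristic length
#'
#' `enclosed_volume()` integrates the solid of revolution
#' \eqn{V_0 = \frac{2\pi}{3}\int_0^\pi r_b(\theta)^3 \sin\theta\, d\theta};
#' `characteristic_length()` returns \eqn{R_0 = (3V_0/4\pi)^{1/3}}.
#'
#' @param geom A [cap_geometry()].
#' @return A scalar volume / length.
#' @export
enclosed_volume <- function(geom) {
  f_a <- function(th) cap_radius_rc(th, geom$R_alpha, geom$C_alpha)^3 * sin(th)
  f_b <- function(th) cap_radius_rc(th, geom$R_beta, geom$C_beta)^3 * sin(th)
  va <- stats::integrate(f_a, 0, pi / 2, rel.tol = 1e-10)$value
  vb <- stats::integrate(f_b, pi / 2, pi, rel.tol = 1e-10)$value
  (2 * pi / 3) * (va + vb)
}

#' @rdname enclosed_volume
#' @export
characteristic_length <- function(geom) (3 * enclosed_volume(geom) / (4 * pi))^(1 / 3)

#' Assemble a boundary point set for cap fitting
#'
#' Accepts either polar (`r`, `theta`) or Cartesian (`x`, `z`) meridional
#' coordinates; Cartesian input is converted to polar about `centroid`
#' (an `(x, z)` offset subtracted before conversion).
#'
#' @param mu Cap identity per point, `"alpha"` or `"beta"` (recycled).
#' @param r,theta Polar coordinates about the tissue centroid.
#' @param x,z Cartesian coordinates (alternative to `r`, `theta`).
#' @param centroid Length-2 `(x, z)` origin used for Cartesian conversion.
#' @return A tibble with columns `mu`, `r`, `theta`.
#' @export
boundary_points <- function(mu, r = NULL, theta = NULL, x = NULL, z = NULL,
                            centroid = c(0, 0)) {
  if (is.null(r)) {
    stopifnot(!is.null(x), !is.null(z))
    xs <- x - centroid[1]
    zs <- z - centroid[2]
    r <- sqrt(xs^2 + zs^2)
    theta <- atan2(xs, zs)
  }
  pts <- tibble::tibble(mu = as.character(mu), r = as.numeric(r),
                        theta = as.numeric(theta))
  if (!all(pts$mu %in% c("alpha", "beta"))) {
    rlang::abort('`mu` must be "alpha" or "beta".')
  }
  pts
}

# Axis-constrained algebraic circle fit: x^2 + (z - C)^2 = R^2 rewritten as
# r^2 = 2 C z + (R^2 - C^2), linear in (C, R^2 - C^2).
algebraic_cap_fit <- function(r, theta) {
  if (diff(range(theta)) < 1e-8) {
    rlang::abort("Degenerate boundary points: all points share one polar angle.",
                 class = "polartissue_fit_error")
  }
  z <- r * cos(theta)
  y <- r^2
  X <- cbind(2 * z, 1)
  if (qr(X)$rank < 2) {
    rlang::abort("Degenerate boundary points: cannot identify a circle.",
                 class = "polartissue_fit_error")
  }
  beta <- qr.solve(X, y)
  C <- beta[1]
  R2 <- beta[2] + C^2
  if (R2 <= 0) {
    rlang::abort("Degenerate boundary points: negative squared radius.",
                 class = "polartissue_fit_error")
  }
  c(R = sqrt(R2), C = C)
}

#' Fit a two-cap geometry to boundary points
#'
#' Least-squares fit of the two cap profiles to measured boundary points,
#' minimizing the summed squared radial residuals
#' \eqn{h = \sum_\mu \sum_i [r_{\mu i} - r(\theta_{\mu i}; \kappa_\mu,
#' \gamma_\mu)]^2} subject to equator continuity
#' \eqn{r_\alpha(\pi/2) = r_\beta(\pi/2)}. The constraint is enforced by
#' penalty continuation inside a Levenberg--Marquardt solver; starting
#' values come from independent axis-constrained algebraic circle fits per
#' cap.
#'
#' @param points A tibble from [boundary_points()] (columns `mu`, `r`,
#'   `theta`) with at least 3 points per cap.
#' @param constraint_tol Absolute equator-continuity violation accepted
#'   before the penalty stops increasing.
#' @return A [cap_geometry()] with attributes `h` (final sum of squared
#'   residuals), `constraint_violation`, and `converged`.
#' @export
fit_caps <- function(points, constraint_tol = 1e-8) {
  stopifnot(all(c("mu", "r", "theta") %in% names(points)))
  pa <- points[points$mu == "alpha", ]
  pb <- points[points$mu == "beta", ]
  if (nrow(pa) < 3 || nrow(pb) < 3) {
    rlang::abort("Need at least 3 boundary points per cap.")
  }
  start_a <- algebraic_cap_fit(pa$r, pa$theta)
  start_b <- algebraic_cap_fit(pb$r, pb$theta)
  par <- c(start_a[["R"]], start_a[["C"]], start_b[["R"]], start_b[["C"]])
  scale <- mean(points$r)

  resid_fn <- function(par, w_pen) {
    Ra <- par[1]; Ca <- par[2]; Rb <- par[3]; Cb <- par[4]
    # keep |C| < R softly: large residuals outside the valid region
    pen_valid <- 1e3 * c(max(0, abs(Ca) - 0.999 * abs(Ra)),
                         max(0, abs(Cb) - 0.999 * abs(Rb)))
    ra <- Ca * cos(pa$theta) + sqrt(pmax(Ra^2 - Ca^2 * sin(pa$theta)^2, 0))
    rb <- Cb * cos(pb$theta) + sqrt(pmax(Rb^2 - Cb^2 * sin(pb$theta)^2, 0))
    viol <- sqrt(pmax(Ra^2 - Ca^2, 0)) - sqrt(pmax(Rb^2 - Cb^2, 0))
    c(pa$r - ra, pb$r - rb, sqrt(w_pen) * viol, pen_valid)
  }

  converged <- TRUE
  for (w_pen in 10^seq(2, 12, by = 2)) {
    fit <- minpack.lm::nls.lm(
      par, fn = resid_fn, w_pen = w_pen,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                           ptol = 1e-15))
    par <- fit$par
    viol <- abs(sqrt(max(par[1]^2 - par[2]^2, 0)) -
                  sqrt(max(par[3]^2 - par[4]^2, 0)))
    if (viol < constraint_tol * max(scale, 1)) break
  }
  if (fit$info %in% c(0, 9)) converged <- FALSE

  # project exactly onto the constraint for the returned geometry: shift the
  # beta radius so both equator radii agree (violation is already <= tol).
  Ra <- par[1]; Ca <- par[2]; Cb <- par[4]
  r_eq <- sqrt(max(Ra^2 - Ca^2, 0))
  Rb <- sqrt(r_eq^2 + Cb^2)
  geom <- cap_geometry(Ra, Ca, Rb, Cb)

  res <- resid_fn(c(Ra, Ca, Rb, Cb), w_pen = 0)
  h <- sum(res[seq_len(nrow(pa) + nrow(pb))]^2)
  attr(geom, "h") <- h
  attr(geom, "constraint_violation") <- viol
  attr(geom, "converged") <- converged
  if (!converged) {
    rlang::warn("fit_caps: optimizer did not report convergence; inspect attr(, 'h').")
  }
  geom
}

#' Read / write a cap geometry as JSON
#'
#' @param geom A [cap_geometry()].
#' @param path File path.
#' @return `read_geometry()` returns a [cap_geometry()];
#'   `write_geometry()` returns `path` invisibly.
#' @export
write_geometry <- function(geom, path) {
  jsonlite::write_json(
    list(R_alpha = geom$R_alpha, C_alpha = geom$C_alpha,
         R_beta = geom$R_beta, C_beta = geom$C_beta,
         V0 = geom$V0, R0 = geom$R0),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  cap_geometry(rec$R_alpha, rec$C_alpha, rec$R_beta, rec$C_beta)
}
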
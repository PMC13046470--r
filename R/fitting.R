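# Scale factor between model coordinates (units of R0, domain volume
# 4*pi/3) and the experimental normalized frame (tissue volume 1).
norm_scale <- function() (4 * pi / 3)^(-1 / 3)

#' Experimental polarity magnitude from a nematic map
#'
#' Defines \eqn{p_{exp} = \Lambda/\Lambda_{max}} on the map grid and the
#' experimental global order \eqn{P_{exp}}, the cylindrical-measure
#' average of \eqn{p_{exp}} over the area enclosed by the averaged
#' boundary and the z axis.
#'
#' @param map A [nematic_map()].
#' @param Lambda_max Normalization (cohort maximum; defaults to the map's).
#' @return List: `p_exp` (matrix over the grid), `P_exp`, `A` (enclosed
#'   area), `grid`, `boundary`, `d`.
#' @export
experimental_polarity <- function(map, Lambda_max = map$Lambda_max) {
  stopifnot(Lambda_max > 0)
  p_exp <- map$Lambda / Lambda_max
  G <- map$grid
  th <- atan2(G[, 1], G[, 2])
  rr <- sqrt(G[, 1]^2 + G[, 2]^2)
  rb <- stats::approx(map$boundary$theta, map$boundary$r, xout = th, rule = 2)$y
  ins <- rr <= rb
  wgt <- G[, 1] * ins
  P_exp <- sum(wgt * as.vector(p_exp)) / sum(wgt)
  dx <- diff(map$x[1:2]); dz <- diff(map$z[1:2])
  list(p_exp = p_exp, P_exp = P_exp, A = sum(ins) * dx * dz,
       grid = G, boundary = map$boundary, d = map$d, map = map)
}

#' Comparison points for model-data fitting
#'
#' Deterministic set of grid points lying in the intersection of the
#' theoretical (two-cap) and experimental (averaged-boundary) shapes, at
#' least `axis_margin` from the symmetry axis and `d` from the closest
#' boundary (`d` is the mean standard deviation of the averaged boundary,
#' excluding regions where the cross-embryo field has poor statistics).
#'
#' @param pexp From [experimental_polarity()] (or any list with `grid`,
#'   `boundary`, `d`).
#' @param geom The fitted [cap_geometry()] (model shape).
#' @param axis_margin Minimal distance from the symmetry axis
#'   (normalized units, default 0.05).
#' @param d Boundary margin; defaults to the experimental boundary spread.
#' @return A tibble `x`, `z` (normalized coordinates) with the selection
#'   mask index in `attr(, "index")`.
#' @export
comparison_points <- function(pexp, geom, axis_margin = 0.05, d = NULL) {
  d <- d %||% pexp$d
  G <- pexp$grid
  th <- atan2(G[, 1], G[, 2])
  rr <- sqrt(G[, 1]^2 + G[, 2]^2)
  rb_exp <- stats::approx(pexp$boundary$theta, pexp$boundary$r, xout = th,
                          rule = 2)$y
  s <- norm_scale()
  rb_mod <- boundary_radius(rescale_geom(geom), th) * s
  keep <- G[, 1] > axis_margin &
    rr <= rb_exp - d & rr <= rb_mod - d
  if (!any(keep)) {
    rlang::abort("No comparison points survive the margins; reduce `d`.")
  }
  out <- tibble::tibble(x = G[keep, 1], z = G[keep, 2])
  attr(out, "index") <- which(keep)
  out
}

# cap geometry rescaled to units of its own R0
rescale_geom <- function(geom) {
  cap_geometry(geom$R_alpha / geom$R0, geom$C_alpha / geom$R0,
               geom$R_beta / geom$R0, geom$C_beta / geom$R0)
}

#' Cost between model and experimental field magnitudes
#'
#' \eqn{C = \sum_i [p(r_i) - p_{exp}(r_i)]^2} over the comparison points.
#'
#' @param p_model,p_exp Numeric vectors of field magnitudes at the same
#'   points.
#' @return Non-negative scalar.
#' @export
fit_cost <- function(p_model, p_exp) {
  if (length(p_model) != length(p_exp)) {
    rlang::abort("Model and experimental values must align.")
  }
  if (any(is.na(p_model)) || any(is.na(p_exp))) {
    rlang::abort("Field not evaluable at some comparison points.")
  }
  sum((p_model - p_exp)^2)
}

# interpolate |p| of a field solution at normalized-frame points
model_magnitude <- function(field, points) {
  s <- norm_scale()
  v <- mesh_interpolate(field$mesh, field$p, points$x / s, points$z / s)
  sqrt(v[, 1]^2 + v[, 2]^2)
}

#' Fit the material lengths to an experimental polarity field
#'
#' Grid search over \eqn{(\xi/R_0, \lambda/R_0)}: one free-energy
#' minimization per grid point (warm-started along increasing anchoring
#' length within each correlation-length column, K fixed), comparing the
#' model magnitude \eqn{|p|} with \eqn{p_{exp}} at the comparison points
#' via [fit_cost()] and returning the full cost surface with its argmin.
#'
#' @param p_exp Numeric vector of experimental magnitudes at `points`.
#' @param points Tibble from [comparison_points()] (normalized frame).
#' @param geom The fitted [cap_geometry()].
#' @param xi_grid,lambda_grid Parameter grids (defaults: 12 log-spaced in
#'   0.05--1, 16 log-spaced in 0.1--20).
#' @param K Bend/splay ratio (fixed at 1e-2).
#' @param anchoring An [anchoring_spec()].
#' @param resolution Mesh resolution for the solves.
#' @param fields Optional precomputed field list from a previous fit on
#'   the same grids/geometry (reused, e.g. for noise re-fits).
#' @return A `fit_result`: `surface` (tibble `xi_rel`, `lambda_rel`, `C`,
#'   `P_model`, `converged`), `best` (one-row tibble), `points`, and the
#'   solved `fields` (named list, reusable).
#' @export
fit_material_lengths <- function(p_exp, points, geom,
                                 xi_grid = exp(seq(log(0.05), log(1),
                                                   length.out = 12)),
                                 lambda_grid = exp(seq(log(0.1), log(20),
                                                       length.out = 16)),
                                 K = 1e-2, anchoring = anchoring_spec(),
                                 resolution = 0.05, fields = NULL) {
  stopifnot(length(p_exp) == nrow(points))
  solve_all <- is.null(fields)
  if (solve_all) {
    mesh <- generate_mesh(rescale_geom(geom), resolution)
    fields <- list()
    for (xi in xi_grid) {
      init <- NULL
      for (lam in lambda_grid) {
        key <- sprintf("%.8g_%.8g", xi, lam)
        sol <- tryCatch(
          minimize_field(rescale_geom(geom), material_params(xi, lam, K),
                         anchoring, init = init, mesh = mesh,
                         continuation = FALSE),
          error = function(e) NULL)
        if (!is.null(sol)) init <- sol$p
        fields[[key]] <- sol
      }
    }
  }
  rows <- list()
  for (xi in xi_grid) for (lam in lambda_grid) {
    key <- sprintf("%.8g_%.8g", xi, lam)
    sol <- fields[[key]]
    if (is.null(sol)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        xi_rel = xi, lambda_rel = lam, C = NA_real_, P_model = NA_real_,
        converged = FALSE)
      next
    }
    pm <- model_magnitude(sol, points)
    rows[[length(rows) + 1]] <- tibble::tibble(
      xi_rel = xi, lambda_rel = lam, C = fit_cost(pm, p_exp),
      P_model = sol$P, converged = sol$converged)
  }
  surface <- dplyr::bind_rows(rows)
  ok <- which(!is.na(surface$C))
  best <- surface[ok[which.min(surface$C[ok])], ]
  structure(list(surface = surface, best = best, points = points,
                 fields = fields, geom = geom, K = K),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result> best xi/R0 = %.4g, lambda/R0 = %.4g (C = %.4g, P = %.4g)\n",
    x$best$xi_rel, x$best$lambda_rel, x$best$C, x$best$P_model))
  invisible(x)
}

#' Directional alignment between model and experimental fields
#'
#' \eqn{|\cos\angle(p, p_{exp})| = |p \cdot p_{exp}|/(|p||p_{exp}|)} at
#' the comparison points, using the in-plane model field and the in-plane
#' components of the experimental alignment vector (direction-only: the
#' nematic sign is immaterial). Directions play no role in the magnitude
#' fit, so this is an independent validation.
#'
#' @param field A `field_solution`.
#' @param map A [nematic_map()] (its `w` supplies the directions).
#' @param points Tibble from [comparison_points()].
#' @param zero_tol Magnitudes below this are skipped (counted in
#'   `n_skipped`).
#' @return List: `values` (per retained point), `mean`, `n_skipped`,
#'   `points` (the retained points).
#' @export
alignment_validation <- function(field, map, points, zero_tol = 1e-8) {
  s <- norm_scale()
  v <- mesh_interpolate(field$mesh, field$p, points$x / s, points$z / s)
  wx <- bilinear_at(map$x, map$z, map$w[, , 1], points$x, points$z)
  wz <- bilinear_at(map$x, map$z, map$w[, , 3], points$x, points$z)
  nm <- sqrt(v[, 1]^2 + v[, 2]^2)
  ne <- sqrt(wx^2 + wz^2)
  ok <- !is.na(nm) & !is.na(ne) & nm > zero_tol & ne > zero_tol
  val <- abs(v[ok, 1] * wx[ok] + v[ok, 2] * wz[ok]) / (nm[ok] * ne[ok])
  list(values = val, mean = mean(val), n_skipped = sum(!ok),
       points = points[ok, ])
}

#' Field projections along standard horizontal and vertical paths
#'
#' Profiles of the absolute field projection along three horizontal paths
#' at heights t/4, t/2, 3t/4 above the distal tip and three vertical
#' paths at distances w/6, w/3, 2w/3 from the symmetry axis, where t and
#' w are the tissue thickness and width measured from the boundary. Path
#' coordinates are rescaled to `[0, 1]` between the axis (or tip) and the
#' boundary crossing. Horizontal paths project on \eqn{\hat x}, vertical
#' paths on \eqn{\hat z}.
#'
#' @param obj A `field_solution` or a [nematic_map()].
#' @param n Samples per path.
#' @return Tibble: `path` (`h1..h3`, `v1..v3`), `frac` (t or w fraction),
#'   `s` (rescaled coordinate), `x`, `z`, `value`.
#' @export
path_projections <- function(obj, n = 60) {
  if (inherits(obj, "field_solution")) {
    geom <- obj$mesh$geom
    th_s <- seq(0, pi, length.out = 361)
    rb <- boundary_radius(geom, th_s)
    bx <- rb * sin(th_s); bz <- rb * cos(th_s)
    eval_field <- function(x, z) {
      v <- mesh_interpolate(obj$mesh, obj$p, x, z)
      cbind(v[, 1], v[, 2])
    }
  } else if (inherits(obj, "nematic_map")) {
    bx <- obj$boundary$x; bz <- obj$boundary$z
    wx <- obj$w[, , 1] / obj$Lambda_max
    wz <- obj$w[, , 3] / obj$Lambda_max
    eval_field <- function(x, z) {
      cbind(bilinear_at(obj$x, obj$z, wx, x, z),
            bilinear_at(obj$x, obj$z, wz, x, z))
    }
  } else rlang::abort("Unsupported object for path_projections().")

  z_min <- min(bz); z_max <- max(bz)
  t_thick <- z_max - z_min
  w_emb <- max(bx)
  x_at_z <- function(z) {
    # boundary x at height z (right half, largest crossing)
    cand <- stats::approx(bz[order(bz)], bx[order(bz)], xout = z, rule = 2)$y
    pmax(cand, 1e-6)
  }
  z_at_x <- function(x) {
    # lower/upper boundary heights at distance x from the axis
    up <- bz[bz >= stats::median(bz)]; bu <- bx[bz >= stats::median(bz)]
    lo <- bz[bz < stats::median(bz)]; bl <- bx[bz < stats::median(bz)]
    c(stats::approx(bl, lo, xout = x, rule = 2)$y,
      stats::approx(bu, up, xout = x, rule = 2)$y)
  }

  rows <- list()
  for (i in 1:3) {
    h <- c(1, 2, 3)[i] / 4 * t_thick
    z <- z_min + h
    xmax <- x_at_z(z)
    xs <- seq(0, xmax, length.out = n)
    v <- eval_field(xs, rep(z, n))
    rows[[length(rows) + 1]] <- tibble::tibble(
      path = paste0("h", i), frac = i / 4, s = xs / xmax,
      x = xs, z = z, value = abs(v[, 1]))
  }
  for (i in 1:3) {
    xw <- c(1 / 6, 1 / 3, 2 / 3)[i] * w_emb
    zr <- z_at_x(xw)
    zs <- seq(zr[1], zr[2], length.out = n)
    v <- eval_field(rep(xw, n), zs)
    rows[[length(rows) + 1]] <- tibble::tibble(
      path = paste0("v", i), frac = c(1 / 6, 1 / 3, 2 / 3)[i],
      s = (zs - zr[1]) / (zr[2] - zr[1]), x = xw, z = zs,
      value = abs(v[, 2]))
  }
  dplyr::bind_rows(rows)
}

bilinear_at <- function(xs, zs, f, xq, zq) {
  ix <- pmin(pmax(stats::approx(xs, seq_along(xs), xout = xq, rule = 2)$y, 1),
             length(xs))
  iz <- pmin(pmax(stats::approx(zs, seq_along(zs), xout = zq, rule = 2)$y, 1),
             length(zs))
  fi <- pmin(floor(ix), length(xs) - 1); fz <- pmin(floor(iz), length(zs) - 1)
  wx <- ix - fi; wz <- iz - fz
  f[cbind(fi, fz)] * (1 - wx) * (1 - wz) + f[cbind(fi + 1, fz)] * wx * (1 - wz) +
    f[cbind(fi, fz + 1)] * (1 - wx) * wz + f[cbind(fi + 1, fz + 1)] * wx * wz
}

#' Defect positions under heterogeneous vs uniform anchoring
#'
#' Solves the field on the same geometry and parameters with the
#' heterogeneous anchoring (tangential alpha / normal beta) and with a
#' uniform perpendicular-anchoring control, and reports the paired
#' relative defect positions (see [defect_position()]).
#'
#' @param geom A [cap_geometry()].
#' @param params A [material_params()].
#' @param resolution Mesh resolution.
#' @param heterogeneous,uniform The two anchoring specs.
#' @return Tibble: `anchoring`, `rel_position`, `total_charge`.
#' @export
compare_defect_positions <- function(geom, params, resolution = 0.05,
                                     heterogeneous = anchoring_spec(),
                                     uniform = anchoring_spec(alpha = "normal")) {
  res <- purrr::map2_dfr(
    list(heterogeneous, uniform), c("heterogeneous", "uniform"),
    function(anch, nm) {
      sol <- minimize_field(geom, params, anch, resolution = resolution)
      ds <- detect_defects(sol)
      tibble::tibble(
        anchoring = nm,
        rel_position = defect_position(sol, defects = ds),
        total_charge = ds$total_charge)
    })
  res
}
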
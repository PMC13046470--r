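#' Detect topological defects of a field solution
#'
#' Candidate defects are connected clusters of interior mesh nodes whose
#' order-parameter magnitude falls below `zero_threshold * max|p|`. Each
#' cluster is assigned the winding number of the normalized in-plane field
#' on a loop around its magnitude minimum. Loops start at three times the
#' mesh spacing and grow geometrically until the field direction on the
#' loop is numerically well defined (defect cores are broad at moderate
#' correlation length, so small loops sit in directional noise); loops that
#' would cross the domain boundary are rejected. If no circular loop
#' resolves a single remaining cluster, the winding is taken along the
#' inward-offset domain boundary (counter-clockwise, using the even/odd
#' axis reflection \eqn{p_x(-x) = -p_x(x)}, \eqn{p_z(-x) = p_z(x)}), which
#' equals the total enclosed charge. Clusters with zero winding are not
#' defects (the order parameter merely becomes small there) and are
#' dropped; non-integer windings are flagged and excluded from the total
#' charge.
#'
#' @param field A `field_solution` from [minimize_field()].
#' @param zero_threshold Fraction of `max|p|` below which nodes count as
#'   candidate zeros (default 0.2).
#' @return A `defect_set`: tibble `defects` with columns `x`, `z`, `index`,
#'   `min_magnitude`, `loop_radius`, `winding_ok`; plus `total_charge`.
#' @export
detect_defects <- function(field, zero_threshold = 0.2) {
  mesh <- field$mesh
  mag <- sqrt(rowSums(field$p^2))
  mx <- max(mag)
  thr <- zero_threshold * mx
  boundary_nodes <- unique(c(mesh$boundary_edges$n1, mesh$boundary_edges$n2))
  cand <- setdiff(which(mag < thr), boundary_nodes)

  empty <- structure(
    list(defects = tibble::tibble(x = numeric(0), z = numeric(0),
                                  index = integer(0), min_magnitude = numeric(0),
                                  loop_radius = numeric(0), winding_ok = logical(0)),
         total_charge = 0L),
    class = "defect_set")
  if (length(cand) == 0 || mx == 0) return(empty)

  # connected components of candidate nodes over mesh edges
  tri <- mesh$tri
  ed <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  keep <- ed[, 1] %in% cand & ed[, 2] %in% cand
  gr <- igraph::graph_from_data_frame(
    data.frame(from = as.character(ed[keep, 1]), to = as.character(ed[keep, 2])),
    directed = FALSE,
    vertices = data.frame(name = as.character(cand)))
  comp <- igraph::components(gr)
  membership <- comp$membership[as.character(cand)]

  h <- mesh$resolution
  rows <- list()
  for (ci in seq_len(comp$no)) {
    nodes_i <- cand[membership == ci]
    i0 <- nodes_i[which.min(mag[nodes_i])]
    cx <- mesh$nodes[i0, 1]; cz <- mesh$nodes[i0, 2]
    if (cx < 1.5 * h) cx <- 0  # snap near-axis candidates onto the axis
    res <- winding_number(field, cx, cz, 3 * h)
    rows[[length(rows) + 1]] <- tibble::tibble(
      x = cx, z = cz, index = res$index, min_magnitude = mag[i0],
      loop_radius = res$radius, winding_ok = res$ok, resolved = res$resolved)
  }
  defects <- dplyr::bind_rows(rows)

  # single unresolved cluster: take the total charge from the boundary loop
  if (nrow(defects) == 1 && !defects$resolved[1]) {
    bw <- boundary_winding(field, offset = h)
    if (bw$ok) {
      defects$index[1] <- bw$index
      defects$loop_radius[1] <- NA_real_
      defects$winding_ok[1] <- TRUE
      defects$resolved[1] <- TRUE
    }
  }

  defects <- defects[!(defects$index == 0L & defects$winding_ok) &
                       defects$resolved, , drop = FALSE]
  defects$resolved <- NULL
  structure(list(defects = defects,
                 total_charge = as.integer(sum(defects$index[defects$winding_ok]))),
            class = "defect_set")
}

#' @export
print.defect_set <- function(x, ...) {
  cat(sprintf("<defect_set> %d defect(s), total charge %+d\n",
              nrow(x$defects), x$total_charge))
  if (nrow(x$defects)) print(x$defects)
  invisible(x)
}

#' Winding number of the field on a growing circular loop
#'
#' Sums the angle increments of the in-plane field along circles around
#' `(cx, cz)`, interpolated from the mesh with the axisymmetric reflection
#' for `x < 0`. The radius grows geometrically from `radius` until the
#' loop direction is numerically well defined (all magnitudes above a
#' noise floor relative to `max|p|`); loops crossing the domain boundary
#' stop the search.
#'
#' @param field A `field_solution`.
#' @param cx,cz Loop centre in slice coordinates.
#' @param radius Starting loop radius.
#' @param n Number of loop samples.
#' @param noise_floor Fraction of `max|p|` below which the field direction
#'   on the loop is considered unreliable.
#' @return List with `index` (rounded winding), `winding` (raw), `radius`
#'   (largest valid loop), `ok` (winding integer within tolerance),
#'   `resolved` (valid loops found and mutually consistent).
#' @export
winding_number <- function(field, cx, cz, radius, n = 360,
                           noise_floor = 1e-3) {
  mx <- max(sqrt(rowSums(field$p^2)))
  r <- radius
  windings <- numeric(0)
  radii <- numeric(0)
  for (attempt in 1:25) {
    curve <- local({
      rr <- r
      function(s) cbind(cx + rr * cos(2 * pi * s), cz + rr * sin(2 * pi * s))
    })
    res <- discrete_winding(field, curve, n, noise_floor * mx)
    if (res$outside) break  # loop left the domain; larger loops leave too
    if (res$valid) {
      windings <- c(windings, res$winding)
      radii <- c(radii, r)
    }
    r <- r * 1.3
  }
  if (!length(windings)) {
    return(list(index = 0L, winding = NA_real_, radius = r, ok = FALSE,
                resolved = FALSE))
  }
  idx <- round(windings)
  ok <- all(abs(windings - idx) < 0.15)
  # an isolated defect shows the same winding at every informative radius;
  # radius-dependent windings mean the zero structure is not isolated
  consistent <- ok && length(unique(idx)) == 1L
  list(index = as.integer(idx[length(idx)]),
       winding = windings[length(windings)],
       radius = radii[length(radii)],
       ok = consistent, resolved = consistent)
}

# Discrete winding of the in-plane field along a closed curve s in [0, 1),
# with adaptive bisection where the direction turns too fast between
# samples (this resolves the rapid flips near boundary boojums that a
# fixed sampling aliases by a full turn). Uses the axisymmetric
# reflection for x < 0.
discrete_winding <- function(field, curve, n, floor_abs, max_refine = 14) {
  s <- seq(0, 1, length.out = n + 1)
  pts <- curve(s)
  sx <- ifelse(pts[, 1] < 0, -1, 1)
  v <- mesh_interpolate(field$mesh, field$p, abs(pts[, 1]), pts[, 2])
  if (any(is.na(v))) return(list(winding = NA, valid = FALSE, outside = TRUE))
  ang <- atan2(v[, 2], v[, 1] * sx)
  m <- sqrt(v[, 1]^2 + v[, 2]^2)
  for (round_ in seq_len(max_refine)) {
    d <- diff(ang)
    d <- (d + pi) %% (2 * pi) - pi
    bad <- which(abs(d) > 0.8)
    if (!length(bad)) break
    s_new <- (s[bad] + s[bad + 1]) / 2
    pn <- curve(s_new)
    sxn <- ifelse(pn[, 1] < 0, -1, 1)
    vn <- mesh_interpolate(field$mesh, field$p, abs(pn[, 1]), pn[, 2])
    if (any(is.na(vn))) return(list(winding = NA, valid = FALSE, outside = TRUE))
    ins <- order(c(s, s_new))
    s <- c(s, s_new)[ins]
    ang <- c(ang, atan2(vn[, 2], vn[, 1] * sxn))[ins]
    m <- c(m, sqrt(vn[, 1]^2 + vn[, 2]^2))[ins]
  }
  d <- diff(ang)
  d <- (d + pi) %% (2 * pi) - pi
  list(winding = sum(d) / (2 * pi),
       valid = min(m) >= max(floor_abs, 1e-12) && max(abs(d)) <= 0.8,
       outside = FALSE)
}

# Winding along the inward-offset domain boundary, traversed
# counter-clockwise (right half bottom-to-top, reflected left half
# top-to-bottom). Equals the total interior charge when |p| is bounded away
# from zero along the offset curve.
boundary_winding <- function(field, offset, n = 720, noise_floor = 5e-4) {
  mesh <- field$mesh
  mx <- max(sqrt(rowSums(field$p^2)))
  geom <- mesh$geom
  curve <- function(s) {
    # s in [0, 0.5): right half, bottom to top; [0.5, 1): reflected left half
    right <- s < 0.5
    th <- ifelse(right, pi * (1 - 2 * s), pi * (2 * s - 1))
    rb <- boundary_radius(geom, th) - offset
    cbind(ifelse(right, 1, -1) * rb * sin(th), rb * cos(th))
  }
  res <- discrete_winding(field, curve, n, noise_floor * mx)
  if (!isTRUE(res$valid)) return(list(index = 0L, ok = FALSE))
  w <- res$winding
  list(index = as.integer(round(w)), winding = w,
       ok = abs(w - round(w)) < 0.15)
}

#' Relative axial position of a single defect
#'
#' Reports \eqn{(z_{defect} - c_L)/L} with \eqn{c_L = L/2} the tissue
#' centre, where the tissue length \eqn{L} is the axial extent from the
#' beta-cap apex (the distal tip) to the alpha-cap apex (the interface with
#' the extraembryonic compartment). Positive values lie toward the alpha
#' cap.
#'
#' @param field A `field_solution`.
#' @param geom Optional [cap_geometry()]; defaults to the (rescaled)
#'   geometry stored in the field's mesh.
#' @param defects Optional precomputed [detect_defects()] result.
#' @param ... Passed to [detect_defects()].
#' @return Scalar relative position in `(-1/2, 1/2)`.
#' @export
defect_position <- function(field, geom = NULL, defects = NULL, ...) {
  if (is.null(geom)) geom <- field$mesh$geom
  if (is.null(defects)) defects <- detect_defects(field, ...)
  n <- nrow(defects$defects)
  if (n != 1) {
    cnd <- rlang::error_cnd("polartissue_defect_error",
                            message = sprintf("Expected exactly one defect, found %d.", n),
                            defects = defects)
    rlang::cnd_signal(cnd)
  }
  z_top <- boundary_radius(geom, 0)       # alpha apex at +z
  z_bot <- -boundary_radius(geom, pi)     # beta apex (distal tip) at -z
  L <- z_top - z_bot
  (defects$defects$z[1] - (z_top + z_bot) / 2) / L
}

#' Phase diagram over material parameters
#'
#' Runs one free-energy minimization per grid point of
#' \eqn{(\xi/R_0, \lambda/R_0)}, warm-starting each solve from the previous
#' solution along increasing anchoring length within each correlation-length
#' column, and summarizes the global order and defect content.
#'
#' @param geom A [cap_geometry()].
#' @param xi_grid,lambda_grid Positive parameter grids.
#' @param anchoring An [anchoring_spec()].
#' @param K Bend/splay ratio.
#' @param resolution Mesh resolution.
#' @param zero_threshold Defect-detection threshold.
#' @return A tibble with columns `xi_rel`, `lambda_rel`, `P`, `free_energy`,
#'   `n_defects`, `total_charge`, `converged`; the empirical defect-free /
#'   defect-containing transition (smallest defect-carrying `lambda_rel`
#'   per `xi_rel`) is in `attr(, "transition")`.
#' @export
phase_diagram <- function(geom, xi_grid, lambda_grid,
                          anchoring = anchoring_spec(), K = 1e-2,
                          resolution = 0.05, zero_threshold = 0.2) {
  stopifnot(all(xi_grid > 0), all(lambda_grid > 0))
  mesh <- generate_mesh(geom, resolution)
  rows <- list()
  for (xi in sort(xi_grid)) {
    init <- NULL
    for (lam in sort(lambda_grid)) {
      sol <- tryCatch(
        minimize_field(geom, material_params(xi, lam, K), anchoring,
                       init = init, mesh = mesh, continuation = FALSE),
        error = function(e) NULL)
      if (is.null(sol)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          xi_rel = xi, lambda_rel = lam, P = NA_real_, free_energy = NA_real_,
          n_defects = NA_integer_, total_charge = NA_integer_, converged = FALSE)
        next
      }
      init <- sol$p
      ds <- detect_defects(sol, zero_threshold)
      rows[[length(rows) + 1]] <- tibble::tibble(
        xi_rel = xi, lambda_rel = lam, P = sol$P,
        free_energy = sol$free_energy, n_defects = nrow(ds$defects),
        total_charge = ds$total_charge, converged = sol$converged)
    }
  }
  out <- dplyr::bind_rows(rows)
  trans <- out |>
    dplyr::filter(.data$n_defects > 0) |>
    dplyr::group_by(.data$xi_rel) |>
    dplyr::summarise(lambda_transition = min(.data$lambda_rel), .groups = "drop")
  attr(out, "transition") <- trans
  out
}
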
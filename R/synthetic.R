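#' Specification for a synthetic embryo
#'
#' Describes the study conditions a generated label volume emulates: a
#' two-spherical-cap tissue packed with prolate ellipsoidal cells whose
#' long axes follow a prescribed orientation field with von Mises--Fisher
#' angular dispersion, and whose shape anisotropy spans a target range.
#' Defaults describe a desk-scale late-stage embryo: characteristic radius
#' 25 um, 0.8 um isotropic voxels, 60 cells, anisotropy 0.2--0.8.
#'
#' @param geometry A [cap_geometry()] in units of `R0` (default a mildly
#'   egg-cylinder-shaped two-cap domain).
#' @param n_cells Number of cells (the stage bins span roughly 15--115).
#' @param orientation `"radial"`, `"uniform"`, `"composite"` (tangential
#'   near the alpha cap, radial near the beta cap), or a `field_solution`
#'   whose direction field orients the cells.
#' @param angular_noise_kappa von Mises--Fisher concentration of the cell
#'   long axes about the source direction (`Inf` = no noise).
#' @param eta_range Range from which per-cell target anisotropies are
#'   drawn (uniformly; for field-driven cells, scaled by local `|p|`).
#' @param voxel_size Isotropic voxel edge (um).
#' @param R0_um Characteristic tissue radius in um.
#' @param fill Fraction of the tissue volume allotted to cell ellipsoids.
#' @param seed RNG seed making the embryo reproducible.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(geometry = cap_geometry(1, 0.2, 1.1, 0.5),
                           n_cells = 60, orientation = "radial",
                           angular_noise_kappa = Inf,
                           eta_range = c(0.2, 0.8), voxel_size = 0.8,
                           R0_um = 25, fill = 0.85, seed = 1L) {
  stopifnot(n_cells >= 2, voxel_size > 0, R0_um > 0,
            length(eta_range) == 2, eta_range[1] >= 0, eta_range[2] < 1)
  structure(list(geometry = geometry, n_cells = n_cells,
                 orientation = orientation,
                 angular_noise_kappa = angular_noise_kappa,
                 eta_range = eta_range, voxel_size = voxel_size,
                 R0_um = R0_um, fill = fill, seed = seed),
            class = "synthetic_spec")
}

# prolate aspect ratio a/b achieving anisotropy eta (b = c)
eta_to_aspect <- function(eta) sqrt(2 / (1 - eta)^2 - 1)

# sample one unit vector from a von Mises-Fisher distribution around mu
rvmf <- function(mu, kappa) {
  if (!is.finite(kappa)) return(mu)
  u <- stats::runif(1)
  w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  th <- stats::runif(1, 0, 2 * pi)
  # orthonormal basis around mu
  a <- if (abs(mu[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * mu) * mu; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(mu[2] * e1[3] - mu[3] * e1[2],
          mu[3] * e1[1] - mu[1] * e1[3],
          mu[1] * e1[2] - mu[2] * e1[1])
  s <- sqrt(max(1 - w^2, 0))
  w * mu + s * (cos(th) * e1 + sin(th) * e2)
}

# volume centroid height of the two-cap domain (on the axis, in R0 units)
domain_centroid_z <- function(geom) {
  fz <- function(th) boundary_radius(geom, th)^4 * sin(th) * cos(th) / 4
  fv <- function(th) boundary_radius(geom, th)^3 * sin(th) / 3
  num <- stats::integrate(fz, 0, pi, rel.tol = 1e-9)$value
  den <- stats::integrate(fv, 0, pi, rel.tol = 1e-9)$value
  num / den
}

# orientation source direction at a point (R0 units, embryo frame)
orientation_direction <- function(orientation, pt, geom, cz) {
  if (inherits(orientation, "field_solution")) {
    xs <- sqrt(pt[1]^2 + pt[2]^2)
    v <- mesh_interpolate(orientation$mesh, orientation$p, xs, pt[3])
    if (any(is.na(v))) v <- c(0, 0)
    phi <- atan2(pt[2], pt[1])
    d3 <- c(v[1] * cos(phi), v[1] * sin(phi), v[2])
    n <- sqrt(sum(d3^2))
    if (n < 1e-9) {  # field zero: fall back to radial
      d3 <- pt - c(0, 0, cz); n <- sqrt(sum(d3^2))
    }
    return(d3 / n)
  }
  d <- pt - c(0, 0, cz)
  nd <- sqrt(sum(d^2))
  radial <- if (nd < 1e-9) c(0, 0, 1) else d / nd
  switch(orientation,
    radial = radial,
    uniform = c(0, 0, 1),
    composite = {
      th <- atan2(sqrt(pt[1]^2 + pt[2]^2), pt[3])
      if (th < pi / 2) {
        # meridional tangent (direction of increasing polar angle)
        phi <- atan2(pt[2], pt[1])
        tz <- -sin(th)
        tx <- cos(th) * cos(phi); ty <- cos(th) * sin(phi)
        c(tx, ty, tz)
      } else radial
    },
    rlang::abort("Unknown orientation rule."))
}

#' Sample ellipsoidal cells for a synthetic embryo
#'
#' Dart-throwing placement of prolate cells in the two-cap domain with a
#' minimum centre separation; each cell's long axis is drawn from the
#' orientation source at its centre with von Mises--Fisher dispersion, and
#' its semi-axes invert the target anisotropy (drawn from `eta_range`, or
#' scaled by the local field magnitude for field-driven specs).
#'
#' @param spec A [synthetic_spec()].
#' @return Tibble: `cell`, `x/y/z` (um, embryo frame), semi-axes `a`,
#'   `b` (um), orientation `ux/uy/uz`, `eta_true`, `source_ux/uy/uz`.
#' @export
sample_cells <- function(spec) {
  set.seed(spec$seed)
  geom <- spec$geometry
  R0 <- spec$R0_um
  cz <- domain_centroid_z(geom)
  V0 <- geom$V0 * R0^3
  v_cell <- spec$fill * V0 / spec$n_cells

  field_driven <- inherits(spec$orientation, "field_solution")
  pmax_field <- if (field_driven) max(sqrt(rowSums(spec$orientation$p^2))) else NA

  # ellipsoid radius along a unit direction
  radius_along <- function(u, a, b, dhat) {
    proj <- sum(u * dhat)
    1 / sqrt(proj^2 / a^2 + (1 - proj^2) / b^2)
  }

  r_max <- max(boundary_radius(geom, seq(0, pi, length.out = 91)))
  placed <- 0L
  rows <- vector("list", spec$n_cells)
  cen <- matrix(NA_real_, spec$n_cells, 3)
  ax_u <- matrix(NA_real_, spec$n_cells, 3)
  ab <- matrix(NA_real_, spec$n_cells, 2)
  overlap_factor <- 0.8   # relaxed progressively if packing stalls
  stall <- 0L
  for (try in seq_len(spec$n_cells * 6000)) {
    cand <- stats::runif(3, -r_max, r_max)
    th <- atan2(sqrt(cand[1]^2 + cand[2]^2), cand[3])
    rr <- sqrt(sum(cand^2))
    if (rr > 0.92 * boundary_radius(geom, th)) next
    src <- orientation_direction(spec$orientation, cand, geom, cz)
    u <- rvmf(src, spec$angular_noise_kappa)
    if (field_driven) {
      xs <- sqrt(cand[1]^2 + cand[2]^2)
      v <- mesh_interpolate(spec$orientation$mesh, spec$orientation$p, xs,
                            cand[3])
      mag <- if (any(is.na(v))) 0 else sqrt(sum(v^2))
      eta <- spec$eta_range[1] + diff(spec$eta_range) * mag / pmax_field
    } else {
      eta <- stats::runif(1, spec$eta_range[1], spec$eta_range[2])
    }
    s <- max(eta_to_aspect(eta), 1 + 1e-9)
    b <- (3 * v_cell / (4 * pi * s))^(1 / 3) / R0
    a <- s * b
    # anisotropic dart throwing: reject if the candidate ellipsoid
    # penetrates a placed one beyond a small tolerated overlap
    ok <- TRUE
    if (placed > 0) {
      for (j in seq_len(placed)) {
        dvec <- cand - cen[j, ]
        dist <- sqrt(sum(dvec^2))
        dhat <- dvec / max(dist, 1e-12)
        reach <- radius_along(u, a, b, dhat) +
          radius_along(ax_u[j, ], ab[j, 1], ab[j, 2], dhat)
        if (dist < overlap_factor * reach) { ok <- FALSE; break }
      }
    }
    if (!ok) {
      stall <- stall + 1L
      if (stall > 200L * spec$n_cells && overlap_factor > 0.4) {
        overlap_factor <- overlap_factor * 0.9
        stall <- 0L
      }
      next
    }
    stall <- 0L
    placed <- placed + 1L
    cen[placed, ] <- cand
    ax_u[placed, ] <- u
    ab[placed, ] <- c(a, b)
    rows[[placed]] <- tibble::tibble(
      cell = placed, x = cand[1] * R0, y = cand[2] * R0, z = cand[3] * R0,
      a = a * R0, b = b * R0, ux = u[1], uy = u[2], uz = u[3],
      eta_true = eta, source_ux = src[1], source_uy = src[2],
      source_uz = src[3])
    if (placed == spec$n_cells) break
  }
  if (placed < spec$n_cells) {
    rlang::abort(sprintf(
      "Cell packing failed after bounded retries (%d of %d placed); try fewer cells.",
      placed, spec$n_cells))
  }
  dplyr::bind_rows(rows)
}

#' Rasterize sampled cells into a label volume
#'
#' Each voxel inside the cap domain is assigned to the cell with the
#' smallest normalized ellipsoidal quadratic form
#' \eqn{q = (u \cdot d/a)^2 + |d_\perp|^2/b^2} (an anisotropic Voronoi
#' rule, guaranteeing disjoint labels) provided that form is below
#' `q_max = 1` (the ellipsoid surface). Because an epithelium is
#' confluent, the interstitial space left between truncated ellipsoids is
#' then divided among the adjacent cells by iterative 26-connected label
#' growth (`grow = TRUE`), so the labels tile the whole cap domain while
#' each cell keeps its ellipsoidal core. Cells that render to zero voxels
#' are dropped and recorded.
#'
#' @param cells Tibble from [sample_cells()].
#' @param spec The [synthetic_spec()].
#' @param rotation Optional 3x3 rigid rotation applied to the embryo in
#'   the volume frame.
#' @param q_max Quadratic-form cutoff for the ellipsoid cores.
#' @param grow Fill the interstitial space by label growth (default TRUE).
#' @return List: `volume` (a [label_volume()]), `offset` (um, world
#'   coordinate of the volume origin relative to the embryo centre),
#'   `dropped` (integer labels).
#' @export
rasterize_cells <- function(cells, spec, rotation = diag(3), q_max = 1,
                            grow = TRUE) {
  vs <- spec$voxel_size
  R0 <- spec$R0_um
  geom <- spec$geometry
  r_max <- max(boundary_radius(geom, seq(0, pi, length.out = 91))) * R0
  margin <- 3 * vs
  half <- r_max + margin
  n <- as.integer(ceiling(2 * half / vs))
  dims <- c(n, n, n)
  off <- -half  # world coordinate of the volume corner

  ax <- (seq_len(n) - 0.5) * vs + off
  G <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  # restrict to the cap domain (in the unrotated embryo frame)
  pts <- G %*% rotation  # rows %*% R == R^T applied: back-rotate
  th <- atan2(sqrt(pts[, 1]^2 + pts[, 2]^2), pts[, 3])
  rr <- sqrt(rowSums(pts^2))
  in_dom <- which(rr <= boundary_radius(geom, th) * R0)

  best_q <- rep(Inf, length(in_dom))
  lab_dom <- integer(length(in_dom))
  Gx <- G[in_dom, 1]; Gy <- G[in_dom, 2]; Gz <- G[in_dom, 3]
  for (i in seq_len(nrow(cells))) {
    cen_w <- as.numeric(rotation %*% c(cells$x[i], cells$y[i], cells$z[i]))
    u_w <- as.numeric(rotation %*% c(cells$ux[i], cells$uy[i], cells$uz[i]))
    dx <- Gx - cen_w[1]; dy <- Gy - cen_w[2]; dz <- Gz - cen_w[3]
    pl <- dx * u_w[1] + dy * u_w[2] + dz * u_w[3]        # along the long axis
    q <- (pl / cells$a[i])^2 +
      (dx^2 + dy^2 + dz^2 - pl^2) / cells$b[i]^2         # + perpendicular
    upd <- q < q_max & q < best_q
    best_q[upd] <- q[upd]
    lab_dom[upd] <- i
  }
  lab <- array(0L, dims)
  lab[in_dom] <- lab_dom

  if (grow) {
    dom_mask <- array(FALSE, dims)
    dom_mask[in_dom] <- TRUE
    for (k in 1:50) {
      lab2 <- grow_labels(lab, dom_mask)
      if (identical(lab2, lab)) break
      lab <- lab2
    }
  }

  dropped <- setdiff(cells$cell, setdiff(unique(as.vector(lab)), 0L))
  list(volume = label_volume(lab, vs), offset = rep(off, 3),
       dropped = as.integer(dropped))
}

#' Generate axis annotations for a synthetic embryo
#'
#' Emits the annotation points the axis-determination step expects:
#' `n_interface` points on the cap-interface (equator) circle, the distal
#' tip at the beta-cap apex, and two transverse-edge points at the equator
#' whose mean defines the zero-angle rotation plane. Optional Gaussian
#' jitter emulates manual annotation error.
#'
#' @param spec A [synthetic_spec()].
#' @param rotation Optional 3x3 rotation (same frame as
#'   [rasterize_cells()]).
#' @param jitter_sd Gaussian jitter s.d. in um.
#' @param n_interface Number of interface points (>= 6).
#' @return List with `interface_points`, `tip_point`, `edge_points` (um,
#'   volume frame relative to the embryo centre).
#' @export
make_annotations <- function(spec, rotation = diag(3), jitter_sd = 0,
                             n_interface = 8) {
  stopifnot(n_interface >= 6)
  geom <- spec$geometry
  R0 <- spec$R0_um
  r_eq <- boundary_radius(geom, pi / 2) * R0
  phis <- seq(0, 2 * pi, length.out = n_interface + 1)[-(n_interface + 1)]
  ip <- cbind(r_eq * cos(phis), r_eq * sin(phis), 0)
  tip <- c(0, 0, -boundary_radius(geom, pi) * R0)
  ep <- rbind(c(r_eq * cos(0.1), r_eq * sin(0.1), 0),
              c(r_eq * cos(-0.1), r_eq * sin(-0.1), 0))
  jit <- function(m) m + stats::rnorm(length(m), 0, jitter_sd)
  list(interface_points = t(rotation %*% t(jit(ip))),
       tip_point = as.numeric(rotation %*% jit(tip)),
       edge_points = t(rotation %*% t(jit(ep))))
}

#' Generate a complete synthetic embryo
#'
#' Runs [sample_cells()], [rasterize_cells()] and [make_annotations()]
#' under the spec's seed and packages the result with its ground truth.
#'
#' @param spec A [synthetic_spec()].
#' @param rotation Optional rigid rotation of the whole embryo.
#' @param jitter_sd Annotation jitter s.d. (um).
#' @return A `synthetic_embryo`: `volume`, `annotation`, `cells` (ground
#'   truth tibble), `spec`, `rotation`, `dropped`, and `manifest`.
#' @export
synthetic_embryo <- function(spec, rotation = diag(3), jitter_sd = 0) {
  cells <- sample_cells(spec)
  ras <- rasterize_cells(cells, spec, rotation)
  ann <- make_annotations(spec, rotation, jitter_sd)
  # annotations are emitted about the embryo centre; shift them into the
  # volume's coordinate frame (origin at the array corner)
  shift <- -ras$offset
  ann$interface_points <- sweep(ann$interface_points, 2, shift, "+")
  ann$tip_point <- ann$tip_point + shift
  ann$edge_points <- sweep(ann$edge_points, 2, shift, "+")
  structure(
    list(volume = ras$volume, annotation = ann, cells = cells,
         spec = spec, rotation = rotation, dropped = ras$dropped,
         offset = ras$offset,
         manifest = list(seed = spec$seed, n_cells = spec$n_cells,
                         voxel_size = spec$voxel_size, R0_um = spec$R0_um,
                         eta_range = spec$eta_range,
                         package_version = as.character(
                           utils::packageVersion("polartissue")))),
    class = "synthetic_embryo")
}

#' Generate a cohort of embryos driven by a model field
#'
#' Cell orientations are sampled from the direction of a converged field
#' solution at each cell centre, with anisotropy proportional to the local
#' field magnitude (scaled into `eta_range`); embryo-to-embryo shape
#' variability jitters the cap parameters while preserving equator
#' continuity.
#'
#' @param field A converged `field_solution`.
#' @param n_embryos Number of embryos.
#' @param spec Template [synthetic_spec()] (its `orientation` is replaced
#'   by `field`).
#' @param shape_jitter Relative s.d. of the cap-parameter jitter.
#' @param jitter_sd Annotation jitter (um).
#' @return List of `synthetic_embryo` objects.
#' @export
field_driven_cohort <- function(field, n_embryos, spec = synthetic_spec(),
                                shape_jitter = 0.02, jitter_sd = 0) {
  if (!field$converged) rlang::abort("Field solution did not converge.")
  purrr::map(seq_len(n_embryos), function(k) {
    set.seed(spec$seed + 1000L * k)
    g0 <- spec$geometry
    if (shape_jitter > 0) {
      Ra <- g0$R_alpha * (1 + stats::rnorm(1, 0, shape_jitter))
      Ca <- g0$C_alpha * (1 + stats::rnorm(1, 0, shape_jitter))
      Cb <- g0$C_beta * (1 + stats::rnorm(1, 0, shape_jitter))
      r_eq <- sqrt(max(Ra^2 - Ca^2, 1e-6))
      Rb <- sqrt(r_eq^2 + Cb^2)
      geom <- cap_geometry(Ra, Ca, Rb, Cb)
    } else geom <- g0
    sp <- spec
    sp$geometry <- geom
    sp$orientation <- field
    sp$seed <- spec$seed + 1000L * k + 1L
    synthetic_embryo(sp, jitter_sd = jitter_sd)
  })
}
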
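#' Triangulate the meridional slice of a two-cap domain
#'
#' Builds a structured triangular mesh of the constant-azimuth half-plane
#' slice of the tissue (coordinates `x >= 0` across, `z` along the
#' distal--proximal axis), working in units of the characteristic length
#' \eqn{R_0}. Nodes are laid out in polar coordinates (polar angle columns,
#' radial-fraction rings, with a fan around the origin), the arrangement the
#' axisymmetric solver expects. Boundary facets are tagged by cap identity:
#' `"alpha"` for polar angles below \eqn{\pi/2}, `"beta"` beyond; the angle
#' column count is even so a node sits exactly at the equator.
#'
#' @param geom A [cap_geometry()] (any units; rescaled internally by `R0`).
#' @param resolution Target edge length in units of `R0` (default 0.05).
#' @return A `slice_mesh` object: `nodes` (N x 2 matrix, columns `x`, `z`),
#'   `tri` (M x 3 node indices, positively oriented), `boundary_edges`
#'   (tibble `n1`, `n2`, `cap`), `axis_nodes`, `resolution`, and the
#'   rescaled geometry in `geom`.
#' @export
generate_mesh <- function(geom, resolution = 0.05) {
  if (!is.numeric(resolution) || resolution <= 0) {
    rlang::abort("`resolution` must be a positive length (in units of R0).")
  }
  R0 <- geom$R0
  sg <- cap_geometry(geom$R_alpha / R0, geom$C_alpha / R0,
                     geom$R_beta / R0, geom$C_beta / R0)

  r_max <- max(boundary_radius(sg, seq(0, pi, length.out = 181)))
  n_theta <- max(8L, as.integer(ceiling(pi * r_max / resolution)))
  if (n_theta %% 2L == 1L) n_theta <- n_theta + 1L
  n_r <- max(4L, as.integer(ceiling(r_max / resolution)))

  theta <- seq(0, pi, length.out = n_theta + 1L)
  rb <- boundary_radius(sg, theta)
  s <- seq_len(n_r) / n_r

  idx <- function(i, j) (i - 1L) * (n_theta + 1L) + j + 2L  # j in 0..n_theta
  n_nodes <- 1L + n_r * (n_theta + 1L)
  nodes <- matrix(0, n_nodes, 2L, dimnames = list(NULL, c("x", "z")))
  for (i in seq_len(n_r)) {
    r <- s[i] * rb
    nodes[idx(i, 0:n_theta), 1L] <- r * sin(theta)
    nodes[idx(i, 0:n_theta), 2L] <- r * cos(theta)
  }

  tris <- vector("list", n_r)
  j <- 0:(n_theta - 1L)
  tris[[1L]] <- cbind(1L, idx(1L, j), idx(1L, j + 1L))
  if (n_r > 1L) {
    for (i in seq_len(n_r - 1L)) {
      a <- idx(i, j); b <- idx(i, j + 1L)
      c_ <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
      tris[[i + 1L]] <- rbind(cbind(a, c_, d), cbind(a, d, b))
    }
  }
  tri <- do.call(rbind, tris)

  # enforce positive (counter-clockwise) orientation
  v1 <- nodes[tri[, 2L], ] - nodes[tri[, 1L], ]
  v2 <- nodes[tri[, 3L], ] - nodes[tri[, 1L], ]
  det2 <- v1[, 1L] * v2[, 2L] - v1[, 2L] * v2[, 1L]
  flip <- det2 < 0
  tri[flip, 2:3] <- tri[flip, 3:2]

  theta_mid <- (theta[j + 1L] + theta[j + 2L]) / 2
  boundary_edges <- tibble::tibble(
    n1 = idx(n_r, j), n2 = idx(n_r, j + 1L),
    cap = ifelse(theta_mid < pi / 2, "alpha", "beta"))

  axis_nodes <- c(1L, idx(seq_len(n_r), 0L), idx(seq_len(n_r), n_theta))

  structure(
    list(nodes = nodes, tri = tri, boundary_edges = boundary_edges,
         axis_nodes = sort(unique(axis_nodes)), resolution = resolution,
         geom = sg, R0 = R0, n_theta = n_theta, n_r = n_r, theta = theta,
         rb = rb),
    class = "slice_mesh")
}

#' @export
print.slice_mesh <- function(x, ...) {
  cat(sprintf("<slice_mesh> %d nodes, %d triangles, resolution %.3g R0\n",
              nrow(x$nodes), nrow(x$tri), x$resolution))
  invisible(x)
}

# Per-triangle geometry needed by the FEM assembly: areas, P1 basis
# gradients, degree-2 quadrature points (interior, so the axisymmetric 1/x
# terms stay finite even for triangles touching the axis).
mesh_fem_data <- function(mesh) {
  nodes <- mesh$nodes
  tri <- mesh$tri
  p1 <- nodes[tri[, 1L], , drop = FALSE]
  p2 <- nodes[tri[, 2L], , drop = FALSE]
  p3 <- nodes[tri[, 3L], , drop = FALSE]
  d1 <- p2 - p1; d2 <- p3 - p1
  detJ <- d1[, 1L] * d2[, 2L] - d1[, 2L] * d2[, 1L]
  area <- detJ / 2
  # gradients of the three barycentric basis functions
  gx <- cbind(p2[, 2L] - p3[, 2L], p3[, 2L] - p1[, 2L], p1[, 2L] - p2[, 2L]) / detJ
  gz <- cbind(p3[, 1L] - p2[, 1L], p1[, 1L] - p3[, 1L], p2[, 1L] - p1[, 1L]) / detJ
  # 3-point rule at barycentric (2/3, 1/6, 1/6) cyclic, weights area/3
  bq <- rbind(c(2/3, 1/6, 1/6), c(1/6, 2/3, 1/6), c(1/6, 1/6, 2/3))
  quad <- lapply(1:3, function(q) {
    xq <- bq[q, 1L] * p1[, 1L] + bq[q, 2L] * p2[, 1L] + bq[q, 3L] * p3[, 1L]
    zq <- bq[q, 1L] * p1[, 2L] + bq[q, 2L] * p2[, 2L] + bq[q, 3L] * p3[, 2L]
    list(x = xq, z = zq, bary = bq[q, ], w = area / 3)
  })
  list(area = area, gx = gx, gz = gz, quad = quad)
}

# Boundary edge geometry: lengths, midpoints, per-edge Gauss points (2-point).
mesh_edge_data <- function(mesh) {
  be <- mesh$boundary_edges
  a <- mesh$nodes[be$n1, , drop = FALSE]
  b <- mesh$nodes[be$n2, , drop = FALSE]
  len <- sqrt(rowSums((b - a)^2))
  g <- 0.5 / sqrt(3)
  t1 <- 0.5 - g; t2 <- 0.5 + g
  list(
    a = a, b = b, len = len, cap = be$cap,
    q = list(list(t = t1, x = a[, 1L] + t1 * (b[, 1L] - a[, 1L]),
                  z = a[, 2L] + t1 * (b[, 2L] - a[, 2L]), w = len / 2),
             list(t = t2, x = a[, 1L] + t2 * (b[, 1L] - a[, 1L]),
                  z = a[, 2L] + t2 * (b[, 2L] - a[, 2L]), w = len / 2)))
}

# Locate query points in the mesh and return (triangle index, barycentric
# coordinates). Vectorized over points, exploiting the structured
# (theta-sector, radial-ring) layout; points outside the domain get NA.
mesh_locate <- function(mesh, x, z) {
  n <- length(x)
  tri_idx <- rep(NA_integer_, n)
  bary <- matrix(NA_real_, n, 3L)
  if (n == 0L) return(list(tri = tri_idx, bary = bary))
  nodes <- mesh$nodes; tri <- mesh$tri
  n_theta <- mesh$n_theta; n_r <- mesh$n_r

  r <- sqrt(x^2 + z^2)
  th <- atan2(abs(x), z)
  rb <- boundary_radius(mesh$geom, th)
  inside <- r <= rb * (1 + 1e-9) & x >= -1e-12
  jc <- pmin(pmax(floor(th / pi * n_theta), 0), n_theta - 1)
  ic <- pmin(pmax(floor(r / rb * n_r), 0), n_r - 1)

  # candidate triangles per point: 3x3 (ring, sector) neighbourhood, two
  # triangles per quad cell (fan cells have one)
  cand_for <- function(ii, jj) {
    # returns an n x 2 matrix of triangle indices (NA where not applicable)
    fan <- ii == 0
    block <- n_theta + 2L * n_theta * (ii - 1L)
    c1 <- ifelse(fan, jj + 1L, block + jj + 1L)
    c2 <- ifelse(fan, NA_integer_, block + n_theta + jj + 1L)
    cbind(c1, c2)
  }
  cands <- matrix(NA_integer_, n, 18L)
  k <- 0L
  for (di in -1:1) for (dj in -1:1) {
    ii <- pmin(pmax(ic + di, 0), n_r - 1)
    jj <- pmin(pmax(jc + dj, 0), n_theta - 1)
    cands[, k + 1:2] <- cand_for(ii, jj)
    k <- k + 2L
  }

  unresolved <- which(inside)
  for (col in seq_len(ncol(cands))) {
    if (!length(unresolved)) break
    t <- cands[unresolved, col]
    ok <- !is.na(t)
    if (!any(ok)) next
    u <- unresolved[ok]; t <- t[ok]
    p1 <- nodes[tri[t, 1L], , drop = FALSE]
    p2 <- nodes[tri[t, 2L], , drop = FALSE]
    p3 <- nodes[tri[t, 3L], , drop = FALSE]
    det <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
      (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])
    l2 <- ((x[u] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
             (p3[, 1] - p1[, 1]) * (z[u] - p1[, 2])) / det
    l3 <- ((p2[, 1] - p1[, 1]) * (z[u] - p1[, 2]) -
             (x[u] - p1[, 1]) * (p2[, 2] - p1[, 2])) / det
    l1 <- 1 - l2 - l3
    hit <- l1 >= -1e-9 & l2 >= -1e-9 & l3 >= -1e-9
    if (any(hit)) {
      uh <- u[hit]
      tri_idx[uh] <- t[hit]
      bary[uh, ] <- pmax(cbind(l1[hit], l2[hit], l3[hit]), 0)
      unresolved <- setdiff(unresolved, uh)
    }
  }
  # numerical stragglers exactly on the boundary: nearest-node fallback
  if (length(unresolved)) {
    for (kk in unresolved) {
      d2 <- (nodes[, 1] - x[kk])^2 + (nodes[, 2] - z[kk])^2
      nn <- which.min(d2)
      if (d2[nn] < (2 * mesh$resolution)^2) {
        t <- which(tri[, 1] == nn | tri[, 2] == nn | tri[, 3] == nn)[1]
        b <- c(0, 0, 0); b[which(tri[t, ] == nn)[1]] <- 1
        tri_idx[kk] <- t; bary[kk, ] <- b
      }
    }
  }
  list(tri = tri_idx, bary = bary)
}

#' Interpolate nodal fields at arbitrary slice points
#'
#' Piecewise-linear (barycentric) interpolation on the triangulation, the
#' interpolation order matching the P1 finite elements.
#'
#' @param mesh A `slice_mesh`.
#' @param values Numeric vector (length N nodes) or N x k matrix of nodal
#'   values.
#' @param x,z Query coordinates in mesh units.
#' @return Vector or matrix of interpolated values; `NA` outside the domain.
#' @export
mesh_interpolate <- function(mesh, values, x, z) {
  loc <- mesh_locate(mesh, x, z)
  values <- as.matrix(values)
  out <- matrix(NA_real_, length(x), ncol(values))
  ok <- !is.na(loc$tri)
  if (any(ok)) {
    tv <- mesh$tri[loc$tri[ok], , drop = FALSE]
    for (c_ in seq_len(ncol(values))) {
      out[ok, c_] <- rowSums(loc$bary[ok, , drop = FALSE] *
                               cbind(values[tv[, 1L], c_], values[tv[, 2L], c_],
                                     values[tv[, 3L], c_]))
    }
  }
  if (ncol(out) == 1L) drop(out) else out
}
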
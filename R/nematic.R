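#' Rotational slice set
#'
#' `M` equidistant azimuthal angles \eqn{\theta_m} about the
#' distal--proximal axis; `rotation(theta)` maps the slice at azimuth
#' \eqn{\theta} onto the x--z plane (rotation about z by \eqn{-\theta}).
#'
#' @param M Number of slices (default 36, i.e. 10-degree intervals).
#' @return A `rotational_slices` list with `M`, `theta` and the function
#'   `rotation(theta)`.
#' @export
rotational_slices <- function(M = 36) {
  stopifnot(M >= 1)
  structure(list(
    M = M,
    theta = 2 * pi * (seq_len(M) - 1) / M,
    rotation = function(theta) {
      rbind(c(cos(theta), sin(theta), 0),
            c(-sin(theta), cos(theta), 0),
            c(0, 0, 1))
    }), class = "rotational_slices")
}

# Build the normalized embryo frame: z along the distal-proximal axis,
# origin at the tissue centroid, coordinates scaled so the tissue volume
# is 1. Returns the transform and its inverse.
normalize_frame <- function(vol, frame) {
  n_vox <- sum(vol$voxels > 0)
  V <- n_vox * vol$voxel_size^3
  if (V <= 0) rlang::abort("Zero tissue volume.")
  s <- V^(-1 / 3)
  list(frame = frame, scale = s,
       to_norm = function(p) {
         s * (rbind(p) - matrix(frame$x0, nrow(rbind(p)), 3, byrow = TRUE)) %*%
           t(frame$rotation)
       },
       to_world = function(p) {
         rbind(p) %*% frame$rotation / s +
           matrix(frame$x0, nrow(rbind(p)), 3, byrow = TRUE)
       },
       vec_to_norm = function(u) rbind(u) %*% t(frame$rotation))
}

#' Reorient and volume-normalize a quantified cell table
#'
#' Rotates coordinates so the z axis is the distal--proximal axis and
#' rescales space so the tissue volume is 1.
#'
#' @param cells Tibble from [quantify_cells()].
#' @param frame An `axis_frame` from [determine_axis()].
#' @param vol The [label_volume()] the cells came from.
#' @return The cell table with transformed `centroid_*`, `polarity_*`,
#'   `normal_*` columns; the normalization (`scale`, `frame`) is attached
#'   as attribute `normalization`.
#' @export
reorient_and_normalize <- function(cells, frame, vol) {
  nf <- normalize_frame(vol, frame)
  cen <- nf$to_norm(as.matrix(cells[, c("centroid_x", "centroid_y", "centroid_z")]))
  pol <- nf$vec_to_norm(as.matrix(cells[, c("polarity_x", "polarity_y", "polarity_z")]))
  out <- cells
  out$centroid_x <- cen[, 1]; out$centroid_y <- cen[, 2]; out$centroid_z <- cen[, 3]
  out$polarity_x <- pol[, 1]; out$polarity_y <- pol[, 2]; out$polarity_z <- pol[, 3]
  if ("normal_x" %in% names(out)) {
    nm <- as.matrix(cells[, c("normal_x", "normal_y", "normal_z")])
    ok <- !is.na(nm[, 1])
    nm[ok, ] <- nf$vec_to_norm(nm[ok, , drop = FALSE])
    out$normal_x <- nm[, 1]; out$normal_y <- nm[, 2]; out$normal_z <- nm[, 3]
  }
  attr(out, "normalization") <- nf
  out
}

#' Rotationally averaged, elongation-weighted nematic field
#'
#' Builds the weighted Landau--de Gennes Q tensor on a uniform grid in the
#' x--z plane of the normalized embryo frame:
#' \deqn{Q(r) = \frac{1}{M} \sum_m \|v''_m\| \left(\frac{3}{2}
#'   \frac{v''_m \otimes v''_m}{\|v''_m\|^2} - \frac{I}{2}\right)}
#' where \eqn{v''_m(r) = R(\theta_m) v'(R^T(\theta_m) r)} samples the
#' elongation axis \eqn{v' = \eta v} of the cell occupying the
#' back-rotated position in slice \eqn{m} (background samples contribute
#' zero; the average divides by `M` regardless). The principal eigenvector
#' is the unsigned director \eqn{V(r)} (reported with the hemisphere
#' convention \eqn{V_z \ge 0}, ties broken by \eqn{V_x \ge 0}) and the
#' principal eigenvalue \eqn{\Lambda(r)} the nematic strength; the
#' alignment vector is \eqn{w = \Lambda V}.
#'
#' @param vol A [label_volume()].
#' @param cells Tibble from [quantify_cells()] on `vol`.
#' @param annotation Axis annotation (see [determine_axis()]).
#' @param M Number of rotational slices.
#' @param grid_n Grid resolution per axis (default 64).
#' @param grid_limits Optional list `x_max`, `z_min`, `z_max` fixing the
#'   grid extent in normalized coordinates (so cohort maps share a grid);
#'   the default fits the embryo's own bounding box.
#' @return A `nematic_map`: grid axes `x`, `z` (normalized coordinates),
#'   `Q` (grid_n x grid_n x 6, components xx, xy, xz, yy, yz, zz),
#'   `Lambda`, `V` (grid_n x grid_n x 3), `w`, `n_samples`,
#'   `Lambda_max`, the averaged `boundary` tibble, the boundary spread
#'   `d`, and the `normalization`.
#' @export
nematic_map <- function(vol, cells, annotation, M = 36, grid_n = 64,
                        grid_limits = NULL) {
  frame <- determine_axis(annotation, attr(cells, "tissue_centroid"))
  nf <- normalize_frame(vol, frame)
  slices <- rotational_slices(M)

  # per-cell elongation axes in the normalized frame
  lut_max <- max(cells$label)
  eta_lut <- rep(NA_real_, lut_max)
  eta_lut[cells$label] <- cells$eta
  ax_lut <- matrix(NA_real_, lut_max, 3)
  ax_lut[cells$label, ] <- nf$vec_to_norm(
    as.matrix(cells[, c("polarity_x", "polarity_y", "polarity_z")]))

  # grid over the normalized tissue bounding box
  idx <- which(vol$voxels > 0)
  vox_norm <- nf$to_norm(voxel_coords(dim(vol$voxels), idx, vol$voxel_size))
  if (is.null(grid_limits)) {
    r_max <- max(sqrt(vox_norm[, 1]^2 + vox_norm[, 2]^2)) * 1.02
    z_rng <- range(vox_norm[, 3])
    z_rng <- z_rng + c(-1, 1) * 0.02 * diff(z_rng)
  } else {
    r_max <- grid_limits$x_max
    z_rng <- c(grid_limits$z_min, grid_limits$z_max)
  }
  gx <- seq(0, r_max, length.out = grid_n)
  gz <- seq(z_rng[1], z_rng[2], length.out = grid_n)
  G <- as.matrix(expand.grid(x = gx, z = gz))
  npt <- nrow(G)

  d3 <- dim(vol$voxels)
  lookup_label <- function(pts_norm) {
    w <- nf$to_world(pts_norm)
    i <- ceiling(w[, 1] / vol$voxel_size)
    j <- ceiling(w[, 2] / vol$voxel_size)
    k <- ceiling(w[, 3] / vol$voxel_size)
    ok <- i >= 1 & i <= d3[1] & j >= 1 & j <= d3[2] & k >= 1 & k <= d3[3]
    lab <- integer(nrow(w))
    lab[ok] <- vol$voxels[cbind(i[ok], j[ok], k[ok])]
    lab
  }

  Qacc <- matrix(0, npt, 6)  # xx, xy, xz, yy, yz, zz
  nsamp <- integer(npt)
  for (m in seq_len(M)) {
    th <- slices$theta[m]
    Rm <- slices$rotation(th)
    # back-rotate grid points (y = 0 plane) into slice m
    pts <- cbind(G[, 1], 0, G[, 2]) %*% Rm  # rows %*% R == t(R^T %*% col)
    lab <- lookup_label(pts)
    sel <- lab > 0 & lab <= lut_max
    sel[sel] <- !is.na(eta_lut[lab[sel]])
    if (!any(sel)) next
    u <- ax_lut[lab[sel], , drop = FALSE] %*% t(Rm)  # rotate axis into x-z frame
    eta <- eta_lut[lab[sel]]
    Qacc[sel, 1] <- Qacc[sel, 1] + eta * (1.5 * u[, 1]^2 - 0.5)
    Qacc[sel, 2] <- Qacc[sel, 2] + eta * 1.5 * u[, 1] * u[, 2]
    Qacc[sel, 3] <- Qacc[sel, 3] + eta * 1.5 * u[, 1] * u[, 3]
    Qacc[sel, 4] <- Qacc[sel, 4] + eta * (1.5 * u[, 2]^2 - 0.5)
    Qacc[sel, 5] <- Qacc[sel, 5] + eta * 1.5 * u[, 2] * u[, 3]
    Qacc[sel, 6] <- Qacc[sel, 6] + eta * (1.5 * u[, 3]^2 - 0.5)
    nsamp <- nsamp + as.integer(sel)
  }
  Qacc <- Qacc / M

  ds <- director_strength_matrix(Qacc)

  bnd <- averaged_boundary_mask(vol, nf, slices)

  structure(
    list(x = gx, z = gz, grid = G,
         Q = array(Qacc, dim = c(grid_n, grid_n, 6)),
         Lambda = matrix(ds$Lambda, grid_n, grid_n),
         V = array(ds$V, dim = c(grid_n, grid_n, 3)),
         w = array(ifelse(is.na(ds$V), 0, ds$V) * ds$Lambda,
                   dim = c(grid_n, grid_n, 3)),
         n_samples = matrix(nsamp, grid_n, grid_n),
         Lambda_max = max(ds$Lambda),
         boundary = bnd$curve, boundary_slices = bnd$per_slice,
         d = bnd$d, M = M, normalization = nf),
    class = "nematic_map")
}

#' @export
print.nematic_map <- function(x, ...) {
  cat(sprintf("<nematic_map> %d x %d grid, M = %d, Lambda_max = %.3g, d = %.3g\n",
              length(x$x), length(x$z), x$M, x$Lambda_max, x$d))
  invisible(x)
}

#' Director and strength of Q tensors
#'
#' Principal eigenpair of each symmetric traceless Q tensor: the unsigned
#' director (hemisphere convention \eqn{V_z \ge 0}, ties broken by
#' \eqn{V_x \ge 0}) and the nematic strength (principal eigenvalue).
#' Degenerate top eigenvalues leave the director `NA` but keep the
#' strength.
#'
#' @param Q A symmetric 3x3 matrix, or an N x 6 matrix of components
#'   (xx, xy, xz, yy, yz, zz).
#' @return For a single matrix: list `V`, `Lambda`, `degenerate`. For a
#'   component matrix: list of `V` (N x 3) and `Lambda` (N).
#' @export
director_strength <- function(Q) {
  if (is.matrix(Q) && all(dim(Q) == c(3, 3))) {
    r <- director_strength_matrix(matrix(c(Q[1, 1], Q[1, 2], Q[1, 3],
                                           Q[2, 2], Q[2, 3], Q[3, 3]), 1, 6))
    return(list(V = r$V[1, ], Lambda = r$Lambda[1],
                degenerate = r$degenerate[1]))
  }
  director_strength_matrix(Q)
}

director_strength_matrix <- function(Q6) {
  n <- nrow(Q6)
  V <- matrix(NA_real_, n, 3)
  Lambda <- numeric(n)
  degen <- logical(n)
  nz <- rowSums(abs(Q6)) > 0
  for (i in which(nz)) {
    Qm <- matrix(c(Q6[i, 1], Q6[i, 2], Q6[i, 3],
                   Q6[i, 2], Q6[i, 4], Q6[i, 5],
                   Q6[i, 3], Q6[i, 5], Q6[i, 6]), 3, 3)
    e <- eigen(Qm, symmetric = TRUE)
    Lambda[i] <- e$values[1]
    if (e$values[1] - e$values[2] < 1e-10 * max(abs(e$values), 1e-300)) {
      degen[i] <- TRUE
      next
    }
    v <- e$vectors[, 1]
    if (v[3] < 0 || (v[3] == 0 && v[1] < 0)) v <- -v
    V[i, ] <- v
  }
  list(V = V, Lambda = Lambda, degenerate = degen)
}

#' Weighted Q tensor of a set of sampled elongation axes
#'
#' \eqn{Q = \frac{1}{M}\sum \|v\| (\frac{3}{2} vv^T/\|v\|^2 - I/2)} for
#' embedding dimension 3; zero-length samples are skipped but the divisor
#' stays `M`.
#'
#' @param v N x 3 matrix of weighted axes (each row \eqn{\eta \hat u}).
#' @param M The slice count to divide by (default `nrow(v)`).
#' @return Symmetric traceless 3x3 matrix.
#' @export
q_tensor <- function(v, M = nrow(v)) {
  v <- rbind(v)
  Q <- matrix(0, 3, 3)
  for (i in seq_len(nrow(v))) {
    nv <- sqrt(sum(v[i, ]^2))
    if (nv < 1e-300) next
    u <- v[i, ] / nv
    Q <- Q + nv * (1.5 * tcrossprod(u) - 0.5 * diag(3))
  }
  Q / M
}

# Rotationally averaged boundary by centroid ray-casting on the tissue
# mask: for each slice half-plane and each polar angle, the largest radius
# still inside the tissue; radii averaged across slices.
averaged_boundary_mask <- function(vol, nf, slices, n_angles = 91) {
  d3 <- dim(vol$voxels)
  phis <- seq(0, pi, length.out = n_angles)
  idx <- which(vol$voxels > 0)
  vox_norm <- nf$to_norm(voxel_coords(d3, idx, vol$voxel_size))
  r_hi <- max(sqrt(rowSums(vox_norm^2))) * 1.05
  step <- nf$scale * vol$voxel_size / 2
  rr <- seq(step, r_hi, by = step)

  inside <- function(pts) {
    w <- nf$to_world(pts)
    i <- ceiling(w[, 1] / vol$voxel_size)
    j <- ceiling(w[, 2] / vol$voxel_size)
    k <- ceiling(w[, 3] / vol$voxel_size)
    ok <- i >= 1 & i <= d3[1] & j >= 1 & j <= d3[2] & k >= 1 & k <= d3[3]
    out <- logical(nrow(w))
    out[ok] <- vol$voxels[cbind(i[ok], j[ok], k[ok])] > 0
    out
  }

  per_slice <- matrix(NA_real_, n_angles, slices$M)
  for (m in seq_len(slices$M)) {
    th <- slices$theta[m]
    # ray directions in the normalized frame at azimuth th
    for (a in seq_len(n_angles)) {
      dir <- c(sin(phis[a]) * cos(th), sin(phis[a]) * sin(th), cos(phis[a]))
      pts <- outer(rr, dir)
      ins <- inside(pts)
      # crossing estimated midway between the last inside and the first
      # outside sample (halves the staircase bias)
      if (any(ins)) per_slice[a, m] <- rr[max(which(ins))] + step / 2
    }
  }
  ok_sl <- colSums(!is.na(per_slice)) > 0
  if (!all(ok_sl)) rlang::warn("Some rotational slices had no tissue intersection.")
  r_mean <- rowMeans(per_slice[, ok_sl, drop = FALSE], na.rm = TRUE)
  r_sd <- apply(per_slice[, ok_sl, drop = FALSE], 1, stats::sd, na.rm = TRUE)
  curve <- tibble::tibble(theta = phis, r = r_mean, r_sd = r_sd,
                          x = r_mean * sin(phis), z = r_mean * cos(phis))
  list(curve = curve, per_slice = per_slice,
       d = mean(r_sd, na.rm = TRUE))
}

#' Average nematic magnitude of an embryo
#'
#' \eqn{\Lambda_{avg} = \int \Lambda(r)\,dV / (\Lambda_{max}\,
#' \mathrm{vol}(\Omega_{avg}))}, the volume integral (cylindrical measure
#' \eqn{2\pi x\,dx\,dz}) of the nematic strength over the region enclosed
#' by the rotationally averaged boundary, normalized by the maximal
#' strength (over the cohort, when supplied).
#'
#' @param map A [nematic_map()].
#' @param Lambda_max Normalization constant (defaults to the map's own
#'   maximum; for cohorts pass the maximum over all embryos and
#'   positions).
#' @return Scalar in `[0, 1]`.
#' @export
average_nematic_magnitude <- function(map, Lambda_max = map$Lambda_max) {
  if (!is.numeric(Lambda_max) || Lambda_max <= 0) {
    rlang::abort("`Lambda_max` must be positive.")
  }
  G <- map$grid
  th <- atan2(G[, 1], G[, 2])
  rr <- sqrt(G[, 1]^2 + G[, 2]^2)
  rb <- stats::approx(map$boundary$theta, map$boundary$r, xout = th,
                      rule = 2)$y
  ins <- rr <= rb
  wgt <- G[, 1] * ins  # cylindrical measure (constant grid spacing cancels)
  num <- sum(wgt * as.vector(map$Lambda))
  den <- sum(wgt)
  if (den == 0) rlang::abort("Averaged boundary encloses no grid points.")
  num / (Lambda_max * den)
}

#' Average nematic maps across embryos
#'
#' Q tensors are averaged across embryos (\eqn{Q = \frac{1}{K}\sum Q_k})
#' before the eigen-decomposition (never a mean of directors), on the
#' common normalized grid of the first map (others are resampled with a
#' warning if their grids differ); boundary radii are averaged over all
#' embryos' slice curves.
#'
#' @param maps List of [nematic_map()] objects.
#' @return A `nematic_map` with the averaged fields; `Lambda_max` is the
#'   maximum over all input maps (all embryos, all positions).
#' @export
cross_embryo_average <- function(maps) {
  stopifnot(length(maps) >= 1)
  ref <- maps[[1]]
  gn <- length(ref$x)
  bilinear <- function(xs, zs, f, xt, zt) {
    ix <- pmin(pmax(stats::approx(xs, seq_along(xs), xout = xt, rule = 2)$y,
                    1), length(xs))
    iz <- pmin(pmax(stats::approx(zs, seq_along(zs), xout = zt, rule = 2)$y,
                    1), length(zs))
    fi <- pmin(floor(ix), length(xs) - 1); fz <- pmin(floor(iz), length(zs) - 1)
    wx <- ix - fi; wz <- iz - fz
    f[fi, fz] * outer(1 - wx, 1 - wz) + f[fi + 1, fz] * outer(wx, 1 - wz) +
      f[fi, fz + 1] * outer(1 - wx, wz) + f[fi + 1, fz + 1] * outer(wx, wz)
  }
  Qs <- lapply(maps, function(m) {
    if (!isTRUE(all.equal(m$x, ref$x)) || !isTRUE(all.equal(m$z, ref$z))) {
      rlang::warn("Grid mismatch: resampling a nematic map onto the reference grid.")
      array(sapply(1:6, function(c_) bilinear(m$x, m$z, m$Q[, , c_],
                                              ref$x, ref$z)),
            dim = c(gn, gn, 6))
    } else m$Q
  })
  Qm <- Reduce(`+`, Qs) / length(Qs)
  Q6 <- matrix(Qm, ncol = 6)
  ds <- director_strength_matrix(Q6)

  all_slices <- do.call(cbind, lapply(maps, function(m) m$boundary_slices))
  r_mean <- rowMeans(all_slices, na.rm = TRUE)
  r_sd <- apply(all_slices, 1, stats::sd, na.rm = TRUE)
  phis <- maps[[1]]$boundary$theta
  curve <- tibble::tibble(theta = phis, r = r_mean, r_sd = r_sd,
                          x = r_mean * sin(phis), z = r_mean * cos(phis))

  structure(
    list(x = ref$x, z = ref$z, grid = ref$grid, Q = Qm,
         Lambda = matrix(ds$Lambda, gn, gn),
         V = array(ds$V, dim = c(gn, gn, 3)),
         w = array(ifelse(is.na(ds$V), 0, ds$V) * ds$Lambda,
                   dim = c(gn, gn, 3)),
         n_samples = Reduce(`+`, lapply(maps, function(m) m$n_samples)),
         Lambda_max = max(vapply(maps, function(m) m$Lambda_max, 0)),
         boundary = curve, boundary_slices = all_slices,
         d = mean(r_sd, na.rm = TRUE), M = ref$M,
         normalization = ref$normalization, K_emb = length(maps)),
    class = "nematic_map")
}
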
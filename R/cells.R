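#' Shape anisotropy factor from a principal inertia spectrum
#'
#' \deqn{\eta = (\lambda_3 - \sqrt{\lambda_1 \lambda_2})/\lambda_3} with
#' inertia components sorted ascending: 0 for spheres, approaching 1 for
#' infinitely elongated shapes.
#'
#' @param lambda1,lambda2,lambda3 Principal inertia components,
#'   `0 < lambda1 <= lambda2 <= lambda3`.
#' @return Scalar (or vector) anisotropy in `[0, 1)`.
#' @export
anisotropy <- function(lambda1, lambda2, lambda3) {
  if (any(lambda1 <= 0) || any(lambda1 > lambda2 + 1e-12 * lambda3) ||
      any(lambda2 > lambda3 + 1e-12 * lambda3)) {
    rlang::abort("Inertia components must be positive and sorted ascending.")
  }
  (lambda3 - sqrt(lambda1 * lambda2)) / lambda3
}

#' Cell-to-boundary orientation angle
#'
#' The angle between a cell's polarity vector and the local boundary
#' normal, in degrees folded to `[0, 90]`: 0 degrees means the cell's long
#' axis lies along the normal (the cell stands perpendicular to the
#' boundary surface), 90 degrees means it lies in the boundary plane
#' (parallel orientation).
#'
#' @param polarity,normal Unit 3-vectors (rows of a matrix accepted).
#' @return Angle(s) in degrees in `[0, 90]`.
#' @export
boundary_angle <- function(polarity, normal) {
  p <- rbind(polarity); n <- rbind(normal)
  np <- sqrt(rowSums(p^2)); nn <- sqrt(rowSums(n^2))
  if (any(np < 1e-12) || any(nn < 1e-12)) {
    rlang::abort("Zero-length vector passed to boundary_angle().")
  }
  d <- abs(rowSums(p * n)) / (np * nn)
  unname(acos(pmin(d, 1)) * 180 / pi)
}

#' Fix the sign of a cell's polarity vector
#'
#' The polarity vector is the cell's major principal inertia axis with its
#' sign fixed: boundary cells point along (not against) their boundary
#' normal; interior cells point away from the tissue centroid. An exactly
#' perpendicular axis (zero dot product) keeps its original sign.
#'
#' @param axis Unit major-axis 3-vector (sign-free).
#' @param normal Boundary normal, or `NULL` for interior cells.
#' @param centroid_dir Unit vector from the tissue centroid toward the cell
#'   centre (used for interior cells).
#' @return Signed unit 3-vector.
#' @export
polarity_vector <- function(axis, normal = NULL, centroid_dir = NULL) {
  ref <- if (!is.null(normal)) normal else centroid_dir
  if (is.null(ref)) rlang::abort("Need a normal or a centroid direction.")
  s <- sum(axis * ref)
  if (s < 0) -axis else axis
}

#' Determine the distal-proximal axis frame from annotations
#'
#' Builds the embryo reference frame: the rotation axis runs from the
#' annotated distal tip through the tissue centroid (pointing
#' distal-to-proximal, so the tip is the negative end); the zero-angle
#' rotation plane contains the axis and the mean annotated transverse-edge
#' point; the least-squares plane through the interface points is retained
#' for reporting the alpha/beta split height.
#'
#' @param annotation List with `interface_points` (>= 6 x 3 matrix),
#'   `tip_point` (3-vector), `edge_points` (2 x 3 matrix).
#' @param centroid Tissue centroid 3-vector.
#' @return An `axis_frame`: `axis` (unit, distal to proximal), `x0`
#'   (centroid), `zero_dir` (unit, in the zero-angle plane, perpendicular
#'   to the axis), `rotation` (3x3, world to embryo frame: rows
#'   `zero_dir`, `axis x zero_dir`, `axis`), `interface_plane` (list
#'   `normal`, `offset`), `interface_height` (along the axis, from the
#'   centroid).
#' @export
determine_axis <- function(annotation, centroid) {
  ip <- rbind(annotation$interface_points)
  tp <- as.numeric(annotation$tip_point)
  ep <- rbind(annotation$edge_points)
  if (nrow(ip) < 6) rlang::abort("Need at least 6 interface points.")
  if (nrow(ep) < 2) rlang::abort("Need 2 transverse-edge points.")
  d <- centroid - tp
  if (sqrt(sum(d^2)) < 1e-9) {
    rlang::abort("Tip point coincides with the tissue centroid.")
  }
  axis <- d / sqrt(sum(d^2))

  em <- colMeans(ep)
  xd <- em - centroid
  xd <- xd - sum(xd * axis) * axis
  if (sqrt(sum(xd^2)) < 1e-9) {
    rlang::abort("Edge points lie on the rotation axis.")
  }
  zero_dir <- xd / sqrt(sum(xd^2))
  ydir <- c(axis[2] * zero_dir[3] - axis[3] * zero_dir[2],
            axis[3] * zero_dir[1] - axis[1] * zero_dir[3],
            axis[1] * zero_dir[2] - axis[2] * zero_dir[1])
  # rows x', y', z' with z' the distal-proximal axis (y' = z' x x')
  rotation <- rbind(zero_dir, ydir, axis)
  dimnames(rotation) <- NULL

  ic <- colMeans(ip)
  sv <- svd(sweep(ip, 2, ic))
  pn <- sv$v[, 3]
  structure(
    list(axis = axis, x0 = centroid, zero_dir = zero_dir,
         rotation = rotation,
         interface_plane = list(normal = pn, offset = sum(pn * ic)),
         interface_height = sum((ic - centroid) * axis)),
    class = "axis_frame")
}

#' Quantify per-cell shape and orientation in a label volume
#'
#' The full per-cell pipeline: surface meshes are extracted for every
#' label and for the whole tissue; each cell's solid-body inertia spectrum
#' (voxel moments by default, mesh moments optionally), shape anisotropy
#' \eqn{\eta}, centroid, volume and surface area are computed; boundary
#' cells receive the outward boundary normal averaged over their tissue
#' mesh vertices; polarity vectors are the major axes sign-fixed by the
#' boundary normal (or the centroid direction for interior cells); and the
#' cell-boundary angle is reported for boundary cells.
#'
#' @param vol A [label_volume()].
#' @param moments `"voxel"` (default) or `"mesh"` inertia estimator.
#' @param min_voxels Labels smaller than this are skipped.
#' @return A tibble, one row per cell: `label`, `n_voxels`, `volume_um3`,
#'   `area_um2`, `centroid_x/y/z`, `lambda1/2/3`, `eta`,
#'   `polarity_x/y/z`, `touches_boundary`, `normal_x/y/z`,
#'   `boundary_angle_deg`. The tissue mesh and centroid are attached as
#'   attributes `tissue` and `tissue_centroid`.
#' @export
quantify_cells <- function(vol, moments = c("voxel", "mesh"), min_voxels = 8) {
  moments <- match.arg(moments)
  meshes <- extract_meshes(vol, min_voxels)
  tissue <- meshes$tissue
  tc <- tissue$centroid
  d <- dim(vol$voxels)

  rows <- purrr::map_dfr(names(meshes$cells), function(ln) {
    l <- as.integer(ln)
    mesh <- meshes$cells[[ln]]
    idx <- which(vol$voxels == l)
    mm <- mesh_moments(mesh)
    if (moments == "voxel") {
      co <- voxel_coords(d, idx, vol$voxel_size)
      I <- voxel_inertia(co)
      e <- eigen(I, symmetric = TRUE)
      ord <- order(e$values)
      lambda <- e$values[ord]
      axes <- e$vectors[, ord, drop = FALSE]
      cen <- colMeans(co)
    } else {
      lambda <- mm$lambda; axes <- mm$axes; cen <- mm$centroid
    }
    long_axis <- axes[, 1]  # smallest inertia component = long axis
    nrm <- boundary_normal(l, tissue)
    cdir <- cen - tc
    cdir <- cdir / max(sqrt(sum(cdir^2)), 1e-12)
    pol <- polarity_vector(long_axis, nrm, cdir)
    tibble::tibble(
      label = l, n_voxels = length(idx),
      volume_um3 = mm$volume, area_um2 = mesh_area(mesh),
      centroid_x = cen[1], centroid_y = cen[2], centroid_z = cen[3],
      lambda1 = lambda[1], lambda2 = lambda[2], lambda3 = lambda[3],
      eta = anisotropy(lambda[1], lambda[2], lambda[3]),
      polarity_x = pol[1], polarity_y = pol[2], polarity_z = pol[3],
      touches_boundary = !is.null(nrm),
      normal_x = if (is.null(nrm)) NA_real_ else nrm[1],
      normal_y = if (is.null(nrm)) NA_real_ else nrm[2],
      normal_z = if (is.null(nrm)) NA_real_ else nrm[3],
      boundary_angle_deg = if (is.null(nrm)) NA_real_ else
        boundary_angle(pol, nrm))
  })
  attr(rows, "tissue") <- tissue
  attr(rows, "tissue_centroid") <- tc
  rows
}
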
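#' Construct a labelled cell volume
#'
#' Wraps a 3D integer array of segmented cells (0 = background, `k > 0` =
#' cell `k`) with its isotropic voxel size in micrometres.
#'
#' @param voxels 3D integer array.
#' @param voxel_size Isotropic voxel edge length (um).
#' @return A `label_volume`.
#' @export
label_volume <- function(voxels, voxel_size) {
  stopifnot(length(dim(voxels)) == 3, is.numeric(voxel_size), voxel_size > 0)
  if (!any(voxels > 0)) rlang::abort("Label volume contains no cells.")
  structure(list(voxels = voxels, voxel_size = voxel_size),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<label_volume> %d x %d x %d voxels @ %.3g um, %d cells\n",
              d[1], d[2], d[3], x$voxel_size,
              length(setdiff(unique(as.vector(x$voxels)), 0L))))
  invisible(x)
}

# voxel-centre coordinates (um) of the voxels at linear indices `idx`
voxel_coords <- function(dim3, idx, voxel_size) {
  i <- (idx - 1L) %% dim3[1] + 1L
  j <- ((idx - 1L) %/% dim3[1]) %% dim3[2] + 1L
  k <- (idx - 1L) %/% (dim3[1] * dim3[2]) + 1L
  cbind(i - 0.5, j - 0.5, k - 0.5) * voxel_size
}

#' Resample a raw acquisition to an isotropic volume
#'
#' Mirrors the preprocessing applied to raw multi-channel stacks: channels
#' are summed into one, the result is binned by averaging blocks of
#' `bin` voxels, and finally rescaled onto an isotropic grid whose voxel
#' edge is the geometric mean of the binned voxel dimensions (or
#' `target_size` if given).
#'
#' @param raw 3D array, or 4D array with channels in the 4th dimension.
#' @param voxel_size Length-3 source voxel size (um) in array order.
#' @param bin Length-3 integer binning factors (default `c(2, 2, 1)`).
#' @param target_size Optional isotropic target voxel edge (um).
#' @param method `"linear"` (intensity data) or `"nearest"` (labels).
#' @return List with `volume` (3D array) and `voxel_size` (scalar, um).
#' @export
resample_isotropic <- function(raw, voxel_size, bin = c(2, 2, 1),
                               target_size = NULL, method = "linear") {
  if (any(voxel_size <= 0)) rlang::abort("Voxel sizes must be positive.")
  stopifnot(length(voxel_size) == 3, all(bin >= 1), method %in% c("linear", "nearest"))
  if (length(dim(raw)) == 4) raw <- apply(raw, 1:3, sum)
  stopifnot(length(dim(raw)) == 3)

  # block-average binning (trailing partial blocks dropped)
  d <- dim(raw)
  db <- d %/% bin
  if (any(db < 1)) rlang::abort("Binning factors exceed array extent.")
  cropped <- raw[seq_len(db[1] * bin[1]), seq_len(db[2] * bin[2]),
                 seq_len(db[3] * bin[3]), drop = FALSE]
  a <- array(cropped, dim = c(bin[1], db[1], bin[2], db[2], bin[3], db[3]))
  binned <- apply(a, c(2, 4, 6), mean)
  vs <- voxel_size * bin

  iso <- target_size %||% prod(vs)^(1 / 3)
  dn <- pmax(1L, as.integer(round(dim(binned) * vs / iso)))
  # sample centres of the target grid back in source-grid coordinates
  src <- lapply(1:3, function(ax) ((seq_len(dn[ax]) - 0.5) * iso) / vs[ax] + 0.5)
  if (method == "nearest") {
    ii <- pmin(pmax(round(src[[1]]), 1), dim(binned)[1])
    jj <- pmin(pmax(round(src[[2]]), 1), dim(binned)[2])
    kk <- pmin(pmax(round(src[[3]]), 1), dim(binned)[3])
    out <- binned[ii, jj, kk, drop = FALSE]
    dim(out) <- dn
  } else {
    out <- trilinear_sample(binned, src[[1]], src[[2]], src[[3]])
  }
  list(volume = out, voxel_size = iso)
}

# separable trilinear resampling onto the tensor grid (xi, yj, zk),
# coordinates in source voxel-index units (centre of voxel i is i)
trilinear_sample <- function(a, xi, yj, zk) {
  lin1 <- function(n, q) {
    q <- pmin(pmax(q, 1), n)
    i0 <- pmin(floor(q), n - 1L); if (n == 1) i0 <- rep(1, length(q))
    w <- q - i0
    list(i0 = as.integer(i0), i1 = as.integer(pmin(i0 + 1, n)), w = w)
  }
  lx <- lin1(dim(a)[1], xi); ly <- lin1(dim(a)[2], yj); lz <- lin1(dim(a)[3], zk)
  # interpolate axis by axis
  a1 <- a[lx$i0, , , drop = FALSE] * (1 - lx$w) + a[lx$i1, , , drop = FALSE] * lx$w
  a2 <- a1[, ly$i0, , drop = FALSE] * rep(1 - ly$w, each = dim(a1)[1]) +
    a1[, ly$i1, , drop = FALSE] * rep(ly$w, each = dim(a1)[1])
  a3 <- a2[, , lz$i0, drop = FALSE] *
    rep(1 - lz$w, each = dim(a2)[1] * dim(a2)[2]) +
    a2[, , lz$i1, drop = FALSE] * rep(lz$w, each = dim(a2)[1] * dim(a2)[2])
  a3
}

# 26-neighbourhood shift offsets (half set; the mirror covers the rest)
half_shifts <- function() {
  s <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  s <- s[!(s$dx == 0 & s$dy == 0 & s$dz == 0), ]
  s[s$dz > 0 | (s$dz == 0 & (s$dy > 0 | (s$dy == 0 & s$dx > 0))), ]
}

# overlap (in voxels) of label j with the 1-voxel 26-connected dilation of
# label i, computed inside the joint bounding box
dilation_overlap <- function(vol, i, j) {
  idx <- which(vol == i | vol == j)
  d <- dim(vol)
  co <- arrayInd(idx, d)
  lo <- pmax(apply(co, 2, min) - 1L, 1L)
  hi <- pmin(apply(co, 2, max) + 1L, d)
  sub <- vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  mi <- sub == i
  dil <- mi
  ds <- dim(sub)
  for (s in seq_len(nrow(all_shifts <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)))) {
    dx <- all_shifts$dx[s]; dy <- all_shifts$dy[s]; dz <- all_shifts$dz[s]
    if (dx == 0 && dy == 0 && dz == 0) next
    xs <- pmin(pmax(seq_len(ds[1]) - dx, 1L), ds[1])
    ys <- pmin(pmax(seq_len(ds[2]) - dy, 1L), ds[2])
    zs <- pmin(pmax(seq_len(ds[3]) - dz, 1L), ds[3])
    dil <- dil | mi[xs, ys, zs, drop = FALSE]
  }
  sum(dil & sub == j)
}

#' Angles between the long axes of neighbouring cells
#'
#' Neighbouring cells are found by one-voxel 26-connected dilation overlap;
#' for each unordered pair in contact the angle between the major principal
#' inertia axes (folded to `[0, 90]` degrees, axes being direction-free) is
#' reported together with the dilation-overlap volume. Pairs whose overlap
#' is below `min_overlap` are excluded.
#'
#' @param vol A [label_volume()].
#' @param min_overlap Minimum overlap volume in um^3 (default 20).
#' @return Tibble with columns `label_i`, `label_j`, `angle_deg`,
#'   `overlap_um3`.
#' @export
neighbor_angles <- function(vol, min_overlap = 20) {
  v <- vol$voxels
  d <- dim(v)
  pairs <- list()
  for (s in seq_len(nrow(sh <- half_shifts()))) {
    dx <- sh$dx[s]; dy <- sh$dy[s]; dz <- sh$dz[s]
    x1 <- max(1, 1 + dx):min(d[1], d[1] + dx)
    y1 <- max(1, 1 + dy):min(d[2], d[2] + dy)
    z1 <- max(1, 1 + dz):min(d[3], d[3] + dz)
    a <- v[x1, y1, z1, drop = FALSE]
    b <- v[x1 - dx, y1 - dy, z1 - dz, drop = FALSE]
    sel <- a > 0 & b > 0 & a != b
    if (any(sel)) {
      pairs[[length(pairs) + 1]] <-
        unique(cbind(pmin(a[sel], b[sel]), pmax(a[sel], b[sel])))
    }
  }
  if (!length(pairs)) {
    return(tibble::tibble(label_i = integer(0), label_j = integer(0),
                          angle_deg = numeric(0), overlap_um3 = numeric(0)))
  }
  pr <- unique(do.call(rbind, pairs))
  axes <- voxel_major_axes(v)
  out <- purrr::map_dfr(seq_len(nrow(pr)), function(k) {
    i <- pr[k, 1]; j <- pr[k, 2]
    ov <- max(dilation_overlap(v, i, j), dilation_overlap(v, j, i)) *
      vol$voxel_size^3
    ai <- axes[[as.character(i)]]; aj <- axes[[as.character(j)]]
    ang <- acos(pmin(abs(sum(ai * aj)), 1)) * 180 / pi
    tibble::tibble(label_i = i, label_j = j, angle_deg = ang, overlap_um3 = ov)
  })
  out[out$overlap_um3 >= min_overlap, , drop = FALSE]
}

# major principal inertia axis per label from voxel second moments
voxel_major_axes <- function(v) {
  labs <- setdiff(sort(unique(as.vector(v))), 0L)
  out <- list()
  d <- dim(v)
  for (l in labs) {
    idx <- which(v == l)
    co <- voxel_coords(d, idx, 1)
    I <- voxel_inertia(co)
    e <- eigen(I, symmetric = TRUE)
    out[[as.character(l)]] <- e$vectors[, 3]  # smallest inertia = long axis
  }
  out
}

# solid-body inertia tensor (per unit mass) from point coordinates
voxel_inertia <- function(co) {
  cc <- sweep(co, 2, colMeans(co))
  M <- crossprod(cc) / nrow(cc)
  diag(sum(diag(M)), 3) - M
}
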
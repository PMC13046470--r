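test_that("resample_isotropic bins and rescales as specified", {
  # already-isotropic input passes through up to interpolation tolerance
  a <- array(runif(8 * 8 * 8), dim = c(8, 8, 8))
  out <- resample_isotropic(a, voxel_size = c(1, 1, 1), bin = c(1, 1, 1))
  expect_equal(out$voxel_size, 1)
  expect_equal(out$volume, a, tolerance = 1e-10)

  # constant volume stays constant
  cst <- array(3, dim = c(8, 6, 4))
  out2 <- resample_isotropic(cst, voxel_size = c(0.2, 0.2, 0.4))
  expect_true(all(abs(out2$volume - 3) < 1e-10))

  # stripes along x, binned 2x2x1: block means match direct averaging
  st <- array(rep(c(0, 1), 4), dim = c(8, 4, 2))
  out3 <- resample_isotropic(st, voxel_size = c(1, 1, 1), bin = c(2, 2, 1),
                             target_size = 2)
  expect_true(all(abs(out3$volume - 0.5) < 1e-10))

  expect_error(resample_isotropic(a, voxel_size = c(0, 1, 1)), "positive")
})

test_that("cuberille meshes reproduce analytic sphere properties", {
  lv <- fx_sphere_volume()
  me <- polartissue:::cuberille_mesh(lv$voxels == 1, lv$voxel_size)
  # signed volume equals the voxel volume exactly and the analytic volume
  # of the r = 10 um sphere within 2%
  expect_equal(mesh_volume(me), sum(lv$voxels) * lv$voxel_size^3,
               tolerance = 1e-12)
  expect_lt(abs(mesh_volume(me) - 4 * pi * 1000 / 3) / (4 * pi * 1000 / 3),
            0.02)
  # positive orientation everywhere (closed outward surface)
  expect_gt(mesh_volume(me), 0)
})

test_that("the tissue mesh keeps only the largest connected component", {
  arr <- array(0L, dim = c(24, 12, 12))
  arr[2:11, 2:11, 2:11] <- 1L     # large blob
  arr[20:22, 2:4, 2:4] <- 2L      # small disjoint blob
  lv <- label_volume(arr, 1)
  tm <- polartissue:::tissue_mesh(lv)
  # all surviving vertices belong to the large blob (x < 12)
  expect_lt(max(tm$vertices[, 1]), 12)
  expect_true(all(tm$vertex_labels %in% 1L))
})

test_that("extract_meshes skips tiny labels with a warning", {
  arr <- array(0L, dim = c(10, 10, 10))
  arr[2:7, 2:7, 2:7] <- 1L
  arr[9, 9, 9] <- 2L  # single voxel
  expect_warning(out <- extract_meshes(label_volume(arr, 1)), "Skipping")
  expect_named(out$cells, "1")
})

test_that("inertia spectra match the solid-ellipsoid closed form", {
  # ellipsoid semi-axes (4, 1, 1) um: inertia components prop. to
  # (b^2 + c^2, a^2 + c^2, a^2 + b^2) = (2, 17, 17)
  vs <- 0.08; n <- 108
  arr <- array(0L, dim = c(n, n, n))
  arr <- rasterize_ellipsoid(arr, 1L, centre = rep(n / 2, 3),
                             semi = c(4, 1, 1) / vs)
  lv <- label_volume(arr, vs)
  idx <- which(arr == 1L)
  co <- polartissue:::voxel_coords(dim(arr), idx, vs)
  I <- polartissue:::voxel_inertia(co)
  lam <- sort(eigen(I, symmetric = TRUE)$values)
  expect_equal(lam / lam[1], c(2, 17, 17) / 2, tolerance = 0.02)

  # mesh-moment route agrees with the voxel route
  me <- polartissue:::cuberille_mesh(arr == 1L, vs)
  mm <- mesh_moments(me)
  expect_equal(mm$lambda / mm$lambda[1], c(2, 17, 17) / 2, tolerance = 0.02)
  expect_equal(mm$lambda / lam, rep(1, 3), tolerance = 0.01)

  # sphere: all components equal within 1%
  sph <- fx_sphere_volume()
  ms <- mesh_moments(polartissue:::cuberille_mesh(sph$voxels == 1,
                                                  sph$voxel_size))
  expect_lt(diff(range(ms$lambda)) / ms$lambda[1], 0.01)
})

test_that("inertia axes rotate with the body and spectra are invariant", {
  vs <- 0.25; n <- 60
  semi <- c(6, 2, 2) / vs
  a0 <- rasterize_ellipsoid(array(0L, dim = c(n, n, n)), 1L,
                            centre = rep(n / 2, 3), semi = semi)
  R <- rot_z(pi / 5) %*% rot_y(pi / 7)
  a1 <- rasterize_ellipsoid(array(0L, dim = c(n, n, n)), 1L,
                            centre = rep(n / 2, 3), semi = semi, R = R)
  lam0 <- mesh_moments(polartissue:::cuberille_mesh(a0 == 1L, vs))
  lam1 <- mesh_moments(polartissue:::cuberille_mesh(a1 == 1L, vs))
  expect_equal(lam1$lambda / lam0$lambda, rep(1, 3), tolerance = 0.02)
  # long axis (smallest inertia) maps to R e1
  expect_gt(abs(sum(lam1$axes[, 1] * (R %*% c(1, 0, 0)))), 0.999)
})

test_that("anisotropy matches its closed form and limits", {
  expect_equal(anisotropy(1, 1, 1), 0)
  expect_equal(anisotropy(0.4, 3.4, 3.4), (3.4 - sqrt(0.4 * 3.4)) / 3.4)
  # monotone approach to 1 with prolate aspect ratio
  etas <- sapply(c(1, 2, 4, 8, 16, 100), function(s) {
    lam <- sort(c(2, s^2 + 1, s^2 + 1))  # (b=c=1, a=s)
    anisotropy(lam[1], lam[2], lam[3])
  })
  expect_true(all(diff(etas) > 0))
  expect_equal(etas[1], 0)
  expect_gt(etas[6], 0.98)
  expect_error(anisotropy(3, 2, 1), "sorted")
  expect_error(anisotropy(-1, 1, 2), "positive")
})

test_that("boundary normals point outward on a spherical tissue", {
  # sphere of two labels: label 2 caps the top, label 1 the rest
  vs <- 0.8; n <- 32
  ax <- (seq_len(n) - 0.5) * vs - n * vs / 2
  g <- expand.grid(x = ax, y = ax, z = ax)
  inside <- g$x^2 + g$y^2 + g$z^2 < 100
  arr <- array(0L, dim = c(n, n, n))
  arr[array(inside & g$z > 6, dim = c(n, n, n))] <- 2L
  arr[array(inside & g$z <= 6, dim = c(n, n, n))] <- 1L
  lv <- label_volume(arr, vs)
  tm <- polartissue:::tissue_mesh(lv)
  n2 <- boundary_normal(2L, tm)
  expect_gt(n2[3], 0.9)                       # top cap normal ~ +z
  # patch-mean normal vs analytic sphere normals over the patch
  sel <- tm$vertex_labels == 2L
  ctr <- c(n, n, n) * vs / 2
  vv <- sweep(tm$vertices[sel, , drop = FALSE], 2, ctr)
  ana <- colMeans(vv / sqrt(rowSums(vv^2)))
  ana <- ana / sqrt(sum(ana^2))
  ang <- acos(pmin(abs(sum(n2 * ana)), 1)) * 180 / pi
  expect_lt(ang, 2)
  expect_null(boundary_normal(99L, tm))
})

test_that("polarity sign rules behave as specified", {
  nrm <- c(0, 0, 1)
  # boundary cell anti-parallel to its normal gets flipped
  expect_equal(polarity_vector(c(0, 0, -1), nrm), c(0, 0, 1))
  # interior cell pointing at the centroid gets flipped outward
  expect_equal(polarity_vector(c(-1, 0, 0) / 1, NULL, c(1, 0, 0)),
               c(1, 0, 0))
  # idempotent
  p1 <- polarity_vector(c(0.6, 0, -0.8), nrm)
  expect_equal(polarity_vector(p1, nrm), p1)
  # exact perpendicular keeps its sign
  expect_equal(polarity_vector(c(1, 0, 0), nrm), c(1, 0, 0))
})

test_that("boundary angle follows the 0-90 degree convention", {
  expect_equal(boundary_angle(c(0, 0, 1), c(0, 0, 1)), 0)
  expect_equal(boundary_angle(c(1, 0, 0), c(0, 0, 1)), 90)
  v <- c(sin(pi / 6), 0, cos(pi / 6))
  expect_equal(boundary_angle(v, c(0, 0, 1)), 30, tolerance = 1e-9)
  expect_error(boundary_angle(c(0, 0, 0), c(0, 0, 1)), "Zero-length")
})

test_that("neighbor_angles finds touching pairs with folded angles", {
  vs <- 0.5; n <- 48
  arr <- array(0L, dim = c(n, n, n))
  # two parallel prolate cells side by side, touching
  arr <- rasterize_ellipsoid(arr, 1L, centre = c(16, 24, 24), semi = c(4, 4, 16))
  arr <- rasterize_ellipsoid(arr, 2L, centre = c(24, 24, 24), semi = c(4, 4, 16))
  # an orthogonal cell touching cell 2
  arr <- rasterize_ellipsoid(arr, 3L, centre = c(32, 24, 24),
                             semi = c(4, 4, 16), R = rot_y(pi / 2))
  # a distant cell
  arr <- rasterize_ellipsoid(arr, 4L, centre = c(42, 40, 8), semi = c(3, 3, 3))
  lv <- label_volume(arr, vs)
  na <- neighbor_angles(lv, min_overlap = 5)
  key <- paste(na$label_i, na$label_j)
  expect_true("1 2" %in% key)
  expect_true("2 3" %in% key)
  expect_false(any(grepl("4", key)))
  expect_lt(na$angle_deg[key == "1 2"], 5)
  expect_gt(na$angle_deg[key == "2 3"], 85)
  expect_true(all(na$angle_deg >= 0 & na$angle_deg <= 90))
  # symmetric: each unordered pair appears once
  expect_false(any(duplicated(key)))
})

test_that("determine_axis recovers annotated frames and is equivariant", {
  ann <- list(
    interface_points = cbind(cos(seq(0, 2 * pi, length.out = 7)[-7]) * 10,
                             sin(seq(0, 2 * pi, length.out = 7)[-7]) * 10,
                             rep(5, 6)),
    tip_point = c(0, 0, -12),
    edge_points = rbind(c(10, 0.5, 0), c(10, -0.5, 0)))
  fr <- determine_axis(ann, centroid = c(0, 0, 0))
  expect_equal(fr$axis, c(0, 0, 1), tolerance = 1e-9)
  expect_equal(abs(fr$interface_plane$normal[3]), 1, tolerance = 1e-9)
  expect_equal(fr$interface_height, 5, tolerance = 1e-9)
  # rotation matrix is orthonormal and right-handed
  expect_equal(fr$rotation %*% t(fr$rotation), diag(3), tolerance = 1e-9)
  expect_equal(det(fr$rotation), 1, tolerance = 1e-9)

  # equivariance under a known rotation
  R <- rot_x(0.4) %*% rot_z(1.1)
  ann_r <- list(interface_points = ann$interface_points %*% t(R),
                tip_point = as.numeric(R %*% ann$tip_point),
                edge_points = ann$edge_points %*% t(R))
  fr_r <- determine_axis(ann_r, centroid = c(0, 0, 0))
  expect_equal(fr_r$axis, as.numeric(R %*% fr$axis), tolerance = 1e-9)

  expect_error(determine_axis(ann, centroid = c(0, 0, -12)), "coincides")
})

test_that("quantify_cells is rotation-invariant for eta and angles", {
  vs <- 0.5; n <- 56
  arr <- array(0L, dim = c(n, n, n))
  set.seed(21)
  ctrs <- rbind(c(18, 28, 28), c(30, 28, 22), c(36, 24, 34))
  for (i in 1:3) {
    arr <- rasterize_ellipsoid(arr, i, ctrs[i, ], semi = c(3, 3, 9),
                               R = rot_y(runif(1, 0, pi)) %*%
                                 rot_z(runif(1, 0, pi)))
  }
  lv <- label_volume(arr, vs)
  c0 <- quantify_cells(lv)
  # rotate the whole volume by 90 degrees about z (exact on the grid)
  arr_r <- aperm(arr, c(2, 1, 3))[dim(arr)[2]:1, , ]
  c1 <- quantify_cells(label_volume(array(arr_r, dim(arr)[c(2, 1, 3)]), vs))
  expect_equal(c1$eta, c0$eta, tolerance = 0.02)
  expect_equal(c1$lambda1 / c1$lambda3, c0$lambda1 / c0$lambda3,
               tolerance = 0.02)
  expect_equal(sort(c1$boundary_angle_deg), sort(c0$boundary_angle_deg),
               tolerance = 0.05)
})
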
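# Shared fixtures, computed lazily and cached for the whole test run.
.fx <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = .fx)) assign(name, builder(), envir = .fx)
  get(name, envir = .fx)
}

# a sphere of radius 1 centred at z = 0.2, expressed as two caps
fx_sphere_geom <- function() fx("sphere_geom", function() {
  cap_geometry(1, 0.2, 1, 0.2)
})

# geometry symmetric under z -> -z (for mirror tests)
fx_symmetric_geom <- function() fx("symmetric_geom", function() {
  cap_geometry(1, 0.2, 1, -0.2)
})

# surface-dominated heterogeneous solve (the +1-defect configuration)
fx_t1_solution <- function() fx("t1_solution", function() {
  minimize_field(fx_sphere_geom(), material_params(0.2, 5),
                 anchoring_spec(), resolution = 0.05)
})

# radially oriented synthetic embryo with modest angular noise, on the
# spherical geometry (there the radial rule coincides with the boundary
# normal everywhere)
fx_embryo <- function() fx("embryo", function() {
  synthetic_embryo(synthetic_spec(geometry = cap_geometry(1, 0.2, 1, 0.2),
                                  seed = 7, orientation = "radial",
                                  angular_noise_kappa = 32))
})

fx_cells <- function() fx("cells", function() {
  quantify_cells(fx_embryo()$volume)
})

fx_nematic <- function() fx("nematic", function() {
  emb <- fx_embryo()
  nematic_map(emb$volume, fx_cells(), emb$annotation)
})

# rasterized sphere label volume (r = 10 um, 0.8 um voxels)
fx_sphere_volume <- function() fx("sphere_volume", function() {
  vs <- 0.8; n <- 32
  ax <- (seq_len(n) - 0.5) * vs - n * vs / 2
  g <- expand.grid(x = ax, y = ax, z = ax)
  arr <- array(as.integer(g$x^2 + g$y^2 + g$z^2 < 100), dim = c(n, n, n))
  label_volume(arr, vs)
})

# rasterize an ellipsoid given centre, semi-axes and rotation (voxel units)
rasterize_ellipsoid <- function(arr, label, centre, semi, R = diag(3)) {
  d <- dim(arr)
  g <- expand.grid(x = seq_len(d[1]) - 0.5, y = seq_len(d[2]) - 0.5,
                   z = seq_len(d[3]) - 0.5)
  p <- t(R) %*% rbind(g$x - centre[1], g$y - centre[2], g$z - centre[3])
  q <- (p[1, ] / semi[1])^2 + (p[2, ] / semi[2])^2 + (p[3, ] / semi[3])^2
  arr[array(q < 1, d) & arr == 0] <- label
  arr
}

rot_z <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0),
                           c(0, 0, 1))
rot_y <- function(a) rbind(c(cos(a), 0, sin(a)), c(0, 1, 0),
                           c(-sin(a), 0, cos(a)))
rot_x <- function(a) rbind(c(1, 0, 0), c(0, cos(a), -sin(a)),
                           c(0, sin(a), cos(a)))

# nearest-neighbour rigid rotation of a label volume about its centre
rotate_volume <- function(vol, R) {
  d <- dim(vol$voxels)
  vs <- vol$voxel_size
  ctr <- d * vs / 2
  g <- expand.grid(x = (seq_len(d[1]) - 0.5) * vs,
                   y = (seq_len(d[2]) - 0.5) * vs,
                   z = (seq_len(d[3]) - 0.5) * vs)
  # target voxel centre pulled back through the inverse rotation
  src <- sweep(as.matrix(g), 2, ctr) %*% R  # rows %*% R == R^T applied
  src <- sweep(src, 2, ctr, "+")
  i <- ceiling(src[, 1] / vs); j <- ceiling(src[, 2] / vs)
  k <- ceiling(src[, 3] / vs)
  ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
  out <- array(0L, d)
  out[ok] <- vol$voxels[cbind(i[ok], j[ok], k[ok])]
  label_volume(array(out, d), vs)
}

rotate_annotation <- function(ann, R, centre) {
  rot <- function(p) sweep(sweep(rbind(p), 2, centre) %*% t(R), 2, centre, "+")
  list(interface_points = rot(ann$interface_points),
       tip_point = as.numeric(rot(ann$tip_point)),
       edge_points = rot(ann$edge_points))
}
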
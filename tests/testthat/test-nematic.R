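test_that("q_tensor matches closed forms", {
  # all samples eta0 * zhat: Q = eta0 (3/2 zz' - I/2)
  eta0 <- 0.6
  v <- matrix(rep(c(0, 0, eta0), 5), ncol = 3, byrow = TRUE)
  Q <- q_tensor(v)
  expect_equal(Q, eta0 * (1.5 * tcrossprod(c(0, 0, 1)) - 0.5 * diag(3)),
               tolerance = 1e-12)
  ds <- director_strength(Q)
  expect_equal(ds$Lambda, eta0, tolerance = 1e-12)
  expect_equal(abs(ds$V[3]), 1, tolerance = 1e-12)

  # no samples: Q = 0, Lambda = 0, director undefined
  Q0 <- q_tensor(matrix(0, 1, 3))
  expect_equal(Q0, matrix(0, 3, 3))
  ds0 <- director_strength(Q0)
  expect_equal(ds0$Lambda, 0)

  # trace is zero for arbitrary sample sets
  set.seed(2)
  for (k in 1:10) {
    v <- matrix(rnorm(12), ncol = 3)
    expect_lt(abs(sum(diag(q_tensor(v)))), 1e-12)
  }

  # isotropically random samples: ||Q|| shrinks like M^(-1/2)
  set.seed(4)
  nrm <- sapply(c(100, 10000), function(M) {
    u <- matrix(rnorm(3 * M), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    sqrt(sum(q_tensor(u)^2))
  })
  expect_lt(nrm[2], nrm[1] / 3)
})

test_that("director extraction matches a characteristic-polynomial oracle", {
  set.seed(9)
  for (k in 1:100) {
    A <- matrix(rnorm(9), 3, 3)
    Q <- (A + t(A)) / 2
    Q <- Q - diag(sum(diag(Q)) / 3, 3)  # traceless
    ds <- director_strength(Q)
    # roots of det(Q - x I) via polyroot on the cubic coefficients
    c2 <- 0                                  # -(trace) = 0
    c1 <- (sum(diag(Q))^2 - sum(Q * Q)) / 2  # sum of principal 2x2 minors
    c0 <- -det(Q)
    roots <- sort(Re(polyroot(c(c0, c1, c2, 1))), decreasing = TRUE)
    expect_equal(ds$Lambda, roots[1], tolerance = 1e-8)
    # eigenvector property
    expect_lt(max(abs(Q %*% ds$V - ds$Lambda * ds$V)), 1e-8)
    # hemisphere convention
    expect_gte(ds$V[3], 0)
  }
})

test_that("reorient_and_normalize standardizes the frame", {
  emb <- fx_embryo()
  cells <- fx_cells()
  fr <- determine_axis(emb$annotation, attr(cells, "tissue_centroid"))
  std <- reorient_and_normalize(cells, fr, emb$volume)
  nf <- attr(std, "normalization")
  # the tissue volume is 1 after rescaling
  expect_equal(sum(emb$volume$voxels > 0) *
                 (emb$volume$voxel_size * nf$scale)^3, 1, tolerance = 1e-9)
  # the distal-proximal axis maps to z
  expect_equal(as.numeric(nf$vec_to_norm(fr$axis)), c(0, 0, 1),
               tolerance = 1e-12)
  # transform round-trip
  p <- cbind(1.2, -0.4, 0.7)
  expect_equal(nf$to_norm(nf$to_world(p)), p, tolerance = 1e-9)
})

test_that("the nematic map of a radial embryo is radial with zero trace", {
  nm <- fx_nematic()
  Q6 <- matrix(nm$Q, ncol = 6)
  expect_lt(max(abs(Q6[, 1] + Q6[, 4] + Q6[, 6])), 1e-10)

  occ <- nm$n_samples > nm$M / 2
  V <- matrix(nm$V, ncol = 3)
  G <- nm$grid
  rad <- cbind(G[, 1], 0, G[, 2])
  rad <- rad / pmax(sqrt(rowSums(rad^2)), 1e-9)
  cc <- abs(rowSums(V * rad))
  expect_gt(stats::median(cc[occ & !is.na(cc)]), 0.95)

  # Lambda bounded by the largest cell anisotropy
  expect_lte(max(nm$Lambda), max(fx_cells()$eta) + 1e-9)
})

test_that("the averaged boundary of a spherical tissue is a circle", {
  vs <- 0.4; n <- 56
  ax <- (seq_len(n) - 0.5) * vs - n * vs / 2
  g <- expand.grid(x = ax, y = ax, z = ax)
  lv <- label_volume(array(as.integer(g$x^2 + g$y^2 + g$z^2 < 100),
                           dim = c(n, n, n)), vs)
  cells <- quantify_cells(lv)
  # sphere: annotate a consistent frame by hand
  ctr <- attr(cells, "tissue_centroid")
  ann <- list(
    interface_points = sweep(cbind(10 * cos(seq(0, 2 * pi, length.out = 7)[-7]),
                                   10 * sin(seq(0, 2 * pi, length.out = 7)[-7]),
                                   0), 2, ctr, "+"),
    tip_point = ctr + c(0, 0, -10),
    edge_points = sweep(rbind(c(10, 0.5, 0), c(10, -0.5, 0)), 2, ctr, "+"))
  nm <- nematic_map(lv, cells, ann, M = 12, grid_n = 24)
  # normalized sphere radius: volume 1 ball
  r_expect <- (3 / (4 * pi))^(1 / 3)
  expect_lt(max(abs(nm$boundary$r - r_expect)) / r_expect, 0.05)
  expect_lt(nm$d / r_expect, 0.03)
})

test_that("median boundary angle at the beta cap is near 0 for radial cells", {
  emb <- fx_embryo()
  cells <- fx_cells()
  fr <- determine_axis(emb$annotation, attr(cells, "tissue_centroid"))
  cc <- split_caps(cells, fr)
  beta <- cc[!is.na(cc$cap) & cc$cap == "beta", ]
  expect_gt(nrow(beta), 5)
  expect_lt(stats::median(beta$boundary_angle_deg), 20)
})

test_that("average nematic magnitude normalizes correctly", {
  nm <- fx_nematic()
  # Lambda == Lambda_max everywhere inside: average is 1
  fake <- nm
  fake$Lambda <- matrix(nm$Lambda_max, nrow(nm$Lambda), ncol(nm$Lambda))
  expect_equal(average_nematic_magnitude(fake), 1, tolerance = 1e-12)
  fake$Lambda <- matrix(0, nrow(nm$Lambda), ncol(nm$Lambda))
  expect_equal(average_nematic_magnitude(fake), 0)
  expect_error(average_nematic_magnitude(nm, Lambda_max = 0), "positive")

  # quadrature agrees with dense Monte-Carlo volume integration
  set.seed(6)
  lam_avg <- average_nematic_magnitude(nm)
  n <- 2e5
  x <- runif(n, 0, max(nm$x)); z <- runif(n, min(nm$z), max(nm$z))
  th <- atan2(x, z); rr <- sqrt(x^2 + z^2)
  rb <- stats::approx(nm$boundary$theta, nm$boundary$r, xout = th, rule = 2)$y
  ins <- rr <= rb
  lam_i <- polartissue:::bilinear_at(nm$x, nm$z, nm$Lambda, x, z)
  mc <- sum((x * lam_i)[ins]) / sum(x[ins]) / nm$Lambda_max
  expect_equal(lam_avg, mc, tolerance = 0.02)
})

test_that("cross-embryo averaging combines tensors before eigenvectors", {
  nm <- fx_nematic()
  # identical embryos: the average equals each input
  avg <- cross_embryo_average(list(nm, nm))
  expect_equal(avg$Lambda, nm$Lambda, tolerance = 1e-12)
  expect_equal(avg$boundary$r, nm$boundary$r, tolerance = 1e-12)

  # orthogonal uniform directors of equal strength cancel partially:
  # Q = (Qx + Qz)/2 has top eigenvalue eta/4 (vs eta for each input)
  eta0 <- 0.5
  Qx <- eta0 * (1.5 * tcrossprod(c(1, 0, 0)) - 0.5 * diag(3))
  Qz <- eta0 * (1.5 * tcrossprod(c(0, 0, 1)) - 0.5 * diag(3))
  dsm <- director_strength((Qx + Qz) / 2)
  expect_equal(dsm$Lambda, eta0 / 4, tolerance = 1e-10)
  expect_lt(dsm$Lambda, eta0)

  # order of embryos is immaterial
  nm2 <- nm
  nm2$Q <- nm$Q * 0.5
  nm2$Lambda <- nm$Lambda * 0.5
  a1 <- cross_embryo_average(list(nm, nm2))
  a2 <- cross_embryo_average(list(nm2, nm))
  expect_equal(a1$Lambda, a2$Lambda, tolerance = 1e-12)
})
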
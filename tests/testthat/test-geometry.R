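test_that("cap_radius evaluates the spherical-cap profile", {
  # axis intersection: r(0) = C + R
  expect_equal(cap_radius(0, kappa = 1, gamma = 1 / 0.2), 1.2)
  # direct evaluation at the equator
  expect_equal(cap_radius(pi / 2, kappa = 0.5, gamma = 2), sqrt(4 - 0.25),
               tolerance = 1e-12)
  # C = 0 (gamma infinite): constant radius
  expect_equal(cap_radius(c(0, 1, pi / 2), kappa = 2, gamma = Inf),
               rep(0.5, 3))
  # Cartesian circle identity x^2 + (z - C)^2 = R^2 at random angles
  set.seed(42)
  R <- 1.3; C <- 0.4
  th <- runif(50, 0, pi / 2)
  r <- cap_radius(th, 1 / R, 1 / C)
  x <- r * sin(th); z <- r * cos(th)
  expect_equal(x^2 + (z - C)^2, rep(R^2, 50), tolerance = 1e-10)
  # negative radicand is a domain error
  expect_error(cap_radius(pi / 2, kappa = 2, gamma = 1),
               class = "polartissue_domain_error")
})

test_that("fit_caps recovers known geometries", {
  # forward-generate noiseless points from caps satisfying continuity
  R_a <- 1.0; C_a <- 0.2
  r_eq <- sqrt(R_a^2 - C_a^2)
  R_b <- 1.1; C_b <- sqrt(R_b^2 - r_eq^2)
  th_a <- seq(0.05, pi / 2, length.out = 15)
  th_b <- seq(pi / 2, pi - 0.05, length.out = 15)
  pts <- boundary_points(
    mu = rep(c("alpha", "beta"), each = 15),
    r = c(cap_radius(th_a, 1 / R_a, 1 / C_a),
          cap_radius(th_b, 1 / R_b, 1 / C_b)),
    theta = c(th_a, th_b))
  geom <- fit_caps(pts)
  expect_equal(geom$R_alpha, R_a, tolerance = 1e-6)
  expect_equal(geom$C_alpha, C_a, tolerance = 1e-6)
  expect_equal(geom$R_beta, R_b, tolerance = 1e-6)
  expect_equal(geom$C_beta, C_b, tolerance = 1e-6)
  expect_lt(attr(geom, "h"), 1e-10)
  expect_lt(abs(glance(geom)$r_equator - r_eq), 1e-6 * geom$R0)

  # Monte-Carlo recovery with radial noise
  set.seed(11)
  errs <- replicate(20, {
    noisy <- pts
    noisy$r <- noisy$r + rnorm(nrow(noisy), 0, 0.01)
    gf <- fit_caps(noisy)
    max(abs(c(gf$R_alpha - R_a, gf$C_alpha - C_a,
              gf$R_beta - R_b, gf$C_beta - C_b)) / c(R_a, C_a, R_b, C_b))
  })
  expect_lt(stats::median(errs), 0.05)
  expect_lt(mean(errs > 0.05), 0.25)
})

test_that("fit_caps handles a sphere centred at the origin (C = 0)", {
  th_a <- seq(0.05, pi / 2, length.out = 10)
  th_b <- seq(pi / 2, pi - 0.05, length.out = 10)
  pts <- boundary_points(mu = rep(c("alpha", "beta"), each = 10),
                         r = rep(0.8, 20), theta = c(th_a, th_b))
  geom <- fit_caps(pts)
  expect_equal(geom$R_alpha, 0.8, tolerance = 1e-5)
  expect_lt(abs(geom$C_alpha), 1e-4)
})

test_that("fit_caps rejects degenerate point sets", {
  pts <- boundary_points(mu = rep("alpha", 5), r = 1:5 / 5,
                         theta = rep(0.7, 5))
  ptsb <- boundary_points(mu = rep("beta", 5), r = rep(1, 5),
                          theta = seq(1.6, 3, length.out = 5))
  expect_error(fit_caps(rbind(pts, ptsb)), class = "polartissue_fit_error")
  expect_error(fit_caps(ptsb), "at least 3")
})

test_that("enclosed volume and characteristic length are exact on spheres", {
  # two hemispheres of the unit sphere
  g0 <- cap_geometry(1, 0, 1, 0)
  expect_equal(g0$V0, 4 * pi / 3, tolerance = 1e-8)
  expect_equal(g0$R0, 1, tolerance = 1e-8)
  # dimensional scaling: R -> sR scales V0 by s^3 and R0 by s
  s <- 1.7
  gs <- cap_geometry(s, 0.2 * s, s, 0.2 * s)
  g1 <- cap_geometry(1, 0.2, 1, 0.2)
  expect_equal(gs$V0 / g1$V0, s^3, tolerance = 1e-8)
  expect_equal(gs$R0 / g1$R0, s, tolerance = 1e-8)
})

test_that("enclosed volume matches a Monte-Carlo oracle", {
  set.seed(3)
  for (k in 1:4) {
    R_a <- runif(1, 0.8, 1.3); C_a <- runif(1, 0, 0.5 * R_a)
    r_eq <- sqrt(R_a^2 - C_a^2)
    C_b <- runif(1, -0.3, 0.5)
    R_b <- sqrt(r_eq^2 + C_b^2)
    geom <- cap_geometry(R_a, C_a, R_b, C_b)
    # hit-or-miss in the bounding cylinder box
    n <- 2e5
    r_max <- max(boundary_radius(geom, seq(0, pi, length.out = 181)))
    p <- cbind(runif(n, -r_max, r_max), runif(n, -r_max, r_max),
               runif(n, -r_max, r_max))
    rr <- sqrt(rowSums(p^2))
    th <- acos(pmin(pmax(p[, 3] / pmax(rr, 1e-12), -1), 1))
    hit <- rr <= boundary_radius(geom, th)
    v_box <- (2 * r_max)^3
    v_mc <- mean(hit) * v_box
    se <- sd(hit) / sqrt(n) * v_box
    expect_lt(abs(geom$V0 - v_mc), 3.5 * se)
  }
})

test_that("generate_mesh produces a tagged boundary-conforming mesh", {
  geom <- fx_sphere_geom()
  m <- generate_mesh(geom, 0.1)
  expect_error(generate_mesh(geom, 0), "positive")

  # boundary nodes satisfy the cap equation within resolution
  be <- m$boundary_edges
  bidx <- unique(c(be$n1, be$n2))
  r_n <- sqrt(rowSums(m$nodes[bidx, ]^2))
  th_n <- atan2(m$nodes[bidx, 1], m$nodes[bidx, 2])
  expect_lt(max(abs(r_n - boundary_radius(m$geom, th_n))), 0.1)

  # halving the resolution roughly quadruples the node count
  m2 <- generate_mesh(geom, 0.05)
  expect_gt(nrow(m2$nodes) / nrow(m$nodes), 3)
  expect_lt(nrow(m2$nodes) / nrow(m$nodes), 5.5)

  # cap tags partition the boundary at the equator
  th_mid <- atan2(
    (m$nodes[be$n1, 1] + m$nodes[be$n2, 1]) / 2,
    (m$nodes[be$n1, 2] + m$nodes[be$n2, 2]) / 2)
  expect_true(all(th_mid[be$cap == "alpha"] < pi / 2))
  expect_true(all(th_mid[be$cap == "beta"] > pi / 2))
  expect_setequal(be$cap, c("alpha", "beta"))

  # positive triangle orientation
  v1 <- m$nodes[m$tri[, 2], ] - m$nodes[m$tri[, 1], ]
  v2 <- m$nodes[m$tri[, 3], ] - m$nodes[m$tri[, 1], ]
  expect_true(all(v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1] > 0))
})

test_that("geometry JSON round-trips", {
  geom <- fx_sphere_geom()
  f <- tempfile(fileext = ".json")
  write_geometry(geom, f)
  g2 <- read_geometry(f)
  expect_equal(g2$R_alpha, geom$R_alpha)
  expect_equal(g2$V0, geom$V0, tolerance = 1e-10)
  unlink(f)
})
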
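# small solve grids keep the self-fit studies fast; the acceptance suite
# exercises the full default grid
fit_xi_grid <- c(0.1, 0.2, 0.4, 0.8)
fit_lambda_grid <- c(0.5, 1.5, 5, 15)

# model-generated experimental field at the true parameters (cached).
# The target field is taken from the fit's own solved grid so the self-fit
# is exact by construction (same discretization, same solver path).
fx_selffit <- function() fx("selffit", function() {
  geom <- fx_sphere_geom()
  # comparison points from a synthetic experimental frame: use the model
  # domain itself with a small boundary margin
  s <- polartissue:::norm_scale()
  th <- seq(0, pi, length.out = 61)
  bnd <- tibble::tibble(theta = th, r = boundary_radius(geom, th) * s)
  gx <- seq(0, max(bnd$r) * 1.02, length.out = 40)
  gz <- seq(-max(bnd$r), max(bnd$r) * 1.25, length.out = 40)
  pexp <- list(grid = as.matrix(expand.grid(x = gx, z = gz)),
               boundary = bnd, d = 0.05)
  pts <- comparison_points(pexp, geom, d = 0.05)
  warm <- fit_material_lengths(rep(0, nrow(pts)), pts, geom,
                               xi_grid = fit_xi_grid,
                               lambda_grid = fit_lambda_grid)
  true_sol <- warm$fields[[sprintf("%.8g_%.8g", 0.2, 5)]]
  p_true <- polartissue:::model_magnitude(true_sol, pts)
  fit <- fit_material_lengths(p_true, pts, geom,
                              xi_grid = fit_xi_grid,
                              lambda_grid = fit_lambda_grid,
                              fields = warm$fields)
  list(geom = geom, true_sol = true_sol, pts = pts, p_true = p_true,
       fit = fit)
})

test_that("comparison points respect the axis and boundary margins", {
  sf <- fx_selffit()
  geom <- sf$geom
  s <- polartissue:::norm_scale()
  th <- seq(0, pi, length.out = 61)
  bnd <- tibble::tibble(theta = th, r = boundary_radius(geom, th) * s)
  gx <- seq(0, max(bnd$r) * 1.02, length.out = 40)
  gz <- seq(-max(bnd$r), max(bnd$r) * 1.25, length.out = 40)
  pexp <- list(grid = as.matrix(expand.grid(x = gx, z = gz)),
               boundary = bnd, d = 0)

  # d = 0 with identical shapes retains every off-axis interior point
  pts0 <- comparison_points(pexp, geom, d = 0)
  expect_true(all(pts0$x > 0.05))

  # increasing d strictly shrinks the set
  n_d <- sapply(c(0, 0.05, 0.12), function(d)
    nrow(comparison_points(pexp, geom, d = d)))
  expect_true(all(diff(n_d) < 0))

  # overly aggressive margins error out
  expect_error(comparison_points(pexp, geom, d = 10), "margins")

  # hand-constructed 5-point toy grid: one near-axis and one
  # near-boundary point are excluded, three survive
  toy <- list(grid = rbind(c(0.01, 0), c(0.3, 0), c(0.3, 0.55),
                           c(0.2, -0.3), c(0.3, -0.2)),
              boundary = tibble::tibble(theta = seq(0, pi, length.out = 19),
                                        r = rep(0.62, 19)),
              d = 0.05)
  pts_toy <- comparison_points(toy, fx_sphere_geom(), d = 0.05)
  expect_equal(nrow(pts_toy), 3)
})

test_that("fit_cost is the plain sum of squared differences", {
  expect_equal(fit_cost(c(1, 2, 3), c(1, 2, 3)), 0)
  # constant offset delta at N points: C = N delta^2
  expect_equal(fit_cost(rep(0.7, 12), rep(0.5, 12)), 12 * 0.04)
  set.seed(13)
  a <- runif(50); b <- runif(50)
  loop <- 0; for (i in 1:50) loop <- loop + (a[i] - b[i])^2
  expect_equal(fit_cost(a, b), loop, tolerance = 1e-12)
  expect_error(fit_cost(c(1, NA), c(1, 2)), "not evaluable")
})

test_that("self-fit recovers the generating parameters exactly on-grid", {
  sf <- fx_selffit()
  expect_equal(sf$fit$best$xi_rel, 0.2)
  expect_equal(sf$fit$best$lambda_rel, 5)
  expect_lt(sf$fit$best$C, 1e-10)
  # unique minimum on the scanned grid
  srt <- sort(sf$fit$surface$C)
  expect_gt(srt[2], 1e-6)
  # consistency of the global order at the optimum
  expect_lt(abs(sf$fit$best$P_model - sf$true_sol$P), 0.05)
})

test_that("noisy self-fits stay within one grid cell of the truth", {
  sf <- fx_selffit()
  set.seed(17)
  hits <- replicate(20, {
    noisy <- sf$p_true * (1 + rnorm(length(sf$p_true), 0, 0.05))
    refit <- fit_material_lengths(noisy, sf$pts, sf$geom,
                                  xi_grid = fit_xi_grid,
                                  lambda_grid = fit_lambda_grid,
                                  fields = sf$fit$fields)
    ix <- which(fit_xi_grid == refit$best$xi_rel)
    il <- which(fit_lambda_grid == refit$best$lambda_rel)
    abs(ix - which(fit_xi_grid == 0.2)) <= 1 &&
      abs(il - which(fit_lambda_grid == 5)) <= 1
  })
  expect_gte(mean(hits), 0.9)
})

test_that("cost surfaces are reproducible bit-for-bit", {
  sf <- fx_selffit()
  refit <- fit_material_lengths(sf$p_true, sf$pts, sf$geom,
                                xi_grid = fit_xi_grid,
                                lambda_grid = fit_lambda_grid)
  expect_equal(refit$surface$C, sf$fit$surface$C, tolerance = 1e-12)
})

test_that("alignment validation scores direction overlap in [0, 1]", {
  sf <- fx_selffit()
  # build a synthetic map whose w field equals the model field (in-plane)
  pts <- sf$pts
  gx <- sort(unique(pts$x)); gz <- sort(unique(pts$z))
  # full-grid map matching the comparison grid
  s <- polartissue:::norm_scale()
  gxa <- seq(0, 0.75, length.out = 30); gza <- seq(-0.7, 0.95, length.out = 30)
  G <- as.matrix(expand.grid(x = gxa, z = gza))
  v <- mesh_interpolate(sf$true_sol$mesh, sf$true_sol$p, G[, 1] / s, G[, 2] / s)
  v[is.na(v)] <- 0
  mkmap <- function(fac) {
    w <- array(0, dim = c(30, 30, 3))
    w[, , 1] <- matrix(fac[1] * v[, 1], 30, 30)
    w[, , 3] <- matrix(fac[2] * v[, 2], 30, 30)
    structure(list(x = gxa, z = gza, grid = G, w = w, Lambda_max = 1),
              class = "nematic_map")
  }
  pexp <- list(grid = G, boundary = tibble::tibble(
    theta = seq(0, pi, length.out = 31),
    r = boundary_radius(sf$geom, seq(0, pi, length.out = 31)) * s), d = 0.05)
  ptsA <- comparison_points(pexp, sf$geom, d = 0.05)

  same <- alignment_validation(sf$true_sol, mkmap(c(1, 1)), ptsA)
  expect_gt(same$mean, 0.999)
  neg <- alignment_validation(sf$true_sol, mkmap(c(-1, -1)), ptsA)
  expect_gt(neg$mean, 0.999)   # nematic sign invariance
  # orthogonal field (rotate in-plane by 90 degrees)
  orth_w <- mkmap(c(1, 1))
  tmp <- orth_w$w[, , 1]
  orth_w$w[, , 1] <- -orth_w$w[, , 3]
  orth_w$w[, , 3] <- tmp
  orth <- alignment_validation(sf$true_sol, orth_w, ptsA)
  expect_lt(orth$mean, 1e-6)
})

test_that("self-fit directions agree away from defects", {
  sf <- fx_selffit()
  s <- polartissue:::norm_scale()
  ds <- detect_defects(sf$true_sol)
  gxa <- seq(0, 0.75, length.out = 30); gza <- seq(-0.7, 0.95, length.out = 30)
  G <- as.matrix(expand.grid(x = gxa, z = gza))
  v <- mesh_interpolate(sf$true_sol$mesh, sf$true_sol$p, G[, 1] / s, G[, 2] / s)
  v[is.na(v)] <- 0
  w <- array(0, dim = c(30, 30, 3))
  w[, , 1] <- matrix(v[, 1], 30, 30); w[, , 3] <- matrix(v[, 2], 30, 30)
  map <- structure(list(x = gxa, z = gza, grid = G, w = w, Lambda_max = 1),
                   class = "nematic_map")
  pexp <- list(grid = G, boundary = tibble::tibble(
    theta = seq(0, pi, length.out = 31),
    r = boundary_radius(sf$geom, seq(0, pi, length.out = 31)) * s), d = 0.05)
  pts <- comparison_points(pexp, sf$geom, d = 0.05)
  # margin of 0.1 R0 around the defect
  far <- sqrt((pts$x - ds$defects$x[1] * s)^2 +
                (pts$z - ds$defects$z[1] * s)^2) > 0.1
  av <- alignment_validation(sf$true_sol, map, pts[far, ])
  expect_gt(av$mean, 0.99)
})

test_that("path projections follow the stated conventions", {
  sol <- fx_t1_solution()
  # uniform zhat field: vertical projections = |p|, horizontal = 0
  fake <- sol
  fake$p <- cbind(rep(0, nrow(sol$p)), rep(0.8, nrow(sol$p)))
  pp <- path_projections(fake, n = 25)
  expect_true(all(abs(pp$value[grepl("v", pp$path)] - 0.8) < 1e-9))
  expect_true(all(abs(pp$value[grepl("h", pp$path)]) < 1e-9))
  # rescaled endpoints are exactly 0 and 1
  for (p_ in unique(pp$path)) {
    expect_equal(range(pp$s[pp$path == p_]), c(0, 1))
  }
  # profiles match direct interpolation on the real field
  pp2 <- path_projections(sol, n = 25)
  h2 <- pp2[pp2$path == "h2", ]
  v <- mesh_interpolate(sol$mesh, sol$p, h2$x, h2$z)
  expect_equal(h2$value, abs(v[, 1]), tolerance = 1e-9)
})

test_that("defect positions shift toward alpha only with heterogeneous anchoring", {
  cmp <- compare_defect_positions(fx_sphere_geom(), material_params(0.2, 5))
  het <- cmp$rel_position[cmp$anchoring == "heterogeneous"]
  unif <- cmp$rel_position[cmp$anchoring == "uniform"]
  expect_lt(abs(unif), 0.05)
  expect_gt(het, unif)
  expect_equal(cmp$total_charge, c(1L, 1L))
})
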
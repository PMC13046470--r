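#' Material parameters of the confined polar fluid
#'
#' The rescaled free energy depends on the bare Landau coefficients only
#' through two dimensionless lengths and one ratio: the correlation length
#' \eqn{\xi = \sqrt{k_0/a}} and the anchoring length \eqn{\lambda = w/a},
#' both relative to the characteristic tissue size \eqn{R_0}, plus the
#' bend/splay modulus ratio \eqn{K = k_2/k_0}.
#'
#' @param xi_rel Correlation length over `R0` (\eqn{\xi/R_0 \ge 0}).
#' @param lambda_rel Anchoring length over `R0` (\eqn{\lambda/R_0 \ge 0}).
#' @param K Bend/splay ratio (default `1e-2`).
#' @return A `material_params` list.
#' @export
material_params <- function(xi_rel, lambda_rel, K = 1e-2) {
  stopifnot(xi_rel >= 0, lambda_rel >= 0, K > 0)
  structure(list(xi_rel = xi_rel, lambda_rel = lambda_rel, K = K),
            class = "material_params")
}

#' Surface anchoring specification
#'
#' Defines the preferred boundary field \eqn{p_0} on each cap. The default
#' is the heterogeneous configuration: \eqn{p_0} tangential on the alpha
#' (ExE) cap, oriented from the equator toward the alpha apex, and along the
#' inward normal on the beta (VE) cap (basal at the boundary, apical toward
#' the interior). This relative orientation is the one whose minimizer
#' carries a net interior topological charge of +1 in the surface-dominated
#' regime; flipping a single sign yields charge-0 configurations. Both rules
#' and both signs are configurable; a uniform configuration (e.g.
#' `alpha = "normal"`) serves as the control in defect-position comparisons.
#'
#' @param alpha,beta Anchoring rule per cap: `"tangential"` or `"normal"`.
#' @param alpha_sign,beta_sign `+1` keeps the default orientation
#'   (equator-to-apex tangent; inward normal), `-1` flips it.
#' @param p0_magnitude Magnitude of the preferred boundary field.
#' @return An `anchoring_spec` list.
#' @export
anchoring_spec <- function(alpha = "tangential", beta = "normal",
                           alpha_sign = 1, beta_sign = 1, p0_magnitude = 1) {
  stopifnot(alpha %in% c("tangential", "normal"),
            beta %in% c("tangential", "normal"),
            abs(alpha_sign) == 1, abs(beta_sign) == 1, p0_magnitude >= 0)
  structure(list(alpha = alpha, beta = beta, alpha_sign = alpha_sign,
                 beta_sign = beta_sign, p0_magnitude = p0_magnitude),
            class = "anchoring_spec")
}

# Preferred boundary field p0 at points on a given cap.
# Outward normal of cap mu at (x, z): (x, z - C_mu)/R_mu.
# "normal" rule: sign * inward normal; "tangential": sign * (-n_z, n_x),
# the meridional tangent oriented from the equator toward the alpha apex.
anchoring_p0 <- function(geom, anchoring, cap, x, z) {
  cap <- rep(cap, length.out = length(x))
  C <- ifelse(cap == "alpha", geom$C_alpha, geom$C_beta)
  R <- ifelse(cap == "alpha", geom$R_alpha, geom$R_beta)
  nx <- x / R
  nz <- (z - C) / R
  rule <- ifelse(cap == "alpha", anchoring$alpha, anchoring$beta)
  sgn <- ifelse(cap == "alpha", anchoring$alpha_sign, anchoring$beta_sign)
  p0x <- ifelse(rule == "normal", -sgn * nx, -sgn * nz)
  p0z <- ifelse(rule == "normal", -sgn * nz, sgn * nx)
  cbind(p0x, p0z) * anchoring$p0_magnitude
}

# --- assembly cache ---------------------------------------------------------
# Quadratic-form matrices (E = u' A u for each part, with u = c(px, pz)),
# the surface linear/constant parts at unit lambda, and the per-triangle
# bend geometry for the lagged regularization factor.
field_cache <- function(mesh, anchoring) {
  N <- nrow(mesh$nodes)
  fem <- mesh_fem_data(mesh)
  M <- nrow(mesh$tri)
  phi <- rbind(c(2/3, 1/6, 1/6), c(1/6, 2/3, 1/6), c(1/6, 1/6, 2/3))

  ii <- integer(0); jj <- integer(0)
  vb <- numeric(0)           # bulk
  is_ <- integer(0); js <- integer(0); vs <- numeric(0)  # splay
  tr <- mesh$tri

  for (q in 1:3) {
    wq <- 2 * pi * fem$quad[[q]]$w * fem$quad[[q]]$x   # axisymmetric weight
    xq <- fem$quad[[q]]$x
    # bulk: sum_comp (sum_a phi_a u_a)^2
    for (a in 1:3) for (b in 1:3) {
      v <- wq * phi[q, a] * phi[q, b]
      ii <- c(ii, tr[, a], N + tr[, a])
      jj <- c(jj, tr[, b], N + tr[, b])
      vb <- c(vb, v, v)
    }
    # splay: (sum_a dx_a px_a + dz_a pz_a)^2, dx_a = gx_a + phi_a/x,
    # dz_a = gz_a (assembled at unit xi^2)
    dx <- fem$gx + matrix(phi[q, ], M, 3, byrow = TRUE) / xq
    dz <- fem$gz
    d6i <- cbind(tr, N + tr)
    d6 <- cbind(dx, dz)
    for (a in 1:6) for (b in 1:6) {
      is_ <- c(is_, d6i[, a]); js <- c(js, d6i[, b])
      vs <- c(vs, wq * d6[, a] * d6[, b])
    }
  }
  A_bulk <- Matrix::sparseMatrix(i = ii, j = jj, x = vb, dims = c(2 * N, 2 * N))
  A_splay <- Matrix::sparseMatrix(i = is_, j = js, x = vs, dims = c(2 * N, 2 * N))

  # bend geometry: c_T = sum_a gz_a px_a - gx_a pz_a (constant per triangle)
  bend_idx <- cbind(tr, N + tr)
  bend_g <- cbind(fem$gz, -fem$gx)
  # per-triangle, per-quad axisymmetric weights and p interpolants for s
  bend_w <- sapply(1:3, function(q) 2 * pi * fem$quad[[q]]$w * fem$quad[[q]]$x)

  # surface (unit lambda)
  ed <- mesh_edge_data(mesh)
  iS <- integer(0); jS <- integer(0); vS <- numeric(0)
  b_lin <- numeric(2 * N)
  c0 <- 0
  for (qq in ed$q) {
    w <- 2 * pi * qq$w * qq$x
    p0 <- anchoring_p0(mesh$geom, anchoring, ed$cap, qq$x, qq$z)
    ph <- cbind(1 - qq$t, qq$t)
    nid <- cbind(mesh$boundary_edges$n1, mesh$boundary_edges$n2)
    for (a in 1:2) for (b in 1:2) {
      v <- w * ph[, a] * ph[, b]
      iS <- c(iS, nid[, a], N + nid[, a])
      jS <- c(jS, nid[, b], N + nid[, b])
      vS <- c(vS, v, v)
    }
    for (a in 1:2) {
      b_lin[nid[, a]] <- b_lin[nid[, a]] + w * ph[, a] * p0[, 1]
      b_lin[N + nid[, a]] <- b_lin[N + nid[, a]] + w * ph[, a] * p0[, 2]
    }
    c0 <- c0 + sum(w * (p0[, 1]^2 + p0[, 2]^2))
  }
  A_surf <- Matrix::sparseMatrix(i = iS, j = jS, x = vS, dims = c(2 * N, 2 * N))

  free <- setdiff(seq_len(2 * N), mesh$axis_nodes)  # px fixed to 0 on axis

  list(N = N, fem = fem, phi = phi, A_bulk = A_bulk, A_splay = A_splay,
       A_surf = A_surf, b_lin = b_lin, c0 = c0,
       bend_idx = bend_idx, bend_g = bend_g, bend_w = bend_w,
       free = free,
       volume = 2 * pi * sum(sapply(1:3, function(q)
         sum(fem$quad[[q]]$w * fem$quad[[q]]$x))))
}

# regularization factor s = |p|^2/(|p|^2 + eps^2) per triangle/quad point
bend_s_factors <- function(cache, tri, u, eps = 1e-6) {
  N <- cache$N
  px <- u[seq_len(N)]; pz <- u[N + seq_len(N)]
  sapply(1:3, function(q) {
    pq_x <- px[tri[, 1]] * cache$phi[q, 1] + px[tri[, 2]] * cache$phi[q, 2] +
      px[tri[, 3]] * cache$phi[q, 3]
    pq_z <- pz[tri[, 1]] * cache$phi[q, 1] + pz[tri[, 2]] * cache$phi[q, 2] +
      pz[tri[, 3]] * cache$phi[q, 3]
    m2 <- pq_x^2 + pq_z^2
    m2 / (m2 + eps^2)
  })
}

# per-triangle bend prefactor beta_T (at unit xi^2 K) and the c_T values
bend_beta <- function(cache, s) rowSums(cache$bend_w * s)

bend_c <- function(cache, u) rowSums(cache$bend_g *
                                       matrix(u[cache$bend_idx],
                                              nrow(cache$bend_idx), 6))

# true (regularized) energy decomposition at nodal field u
energy_parts_u <- function(cache, u, params, eps = 1e-6) {
  tri_c <- bend_c(cache, u)
  s <- bend_s_factors(cache, attr(cache, "tri"), u, eps)
  bulk <- as.numeric(u %*% (cache$A_bulk %*% u))
  splay <- params$xi_rel^2 * as.numeric(u %*% (cache$A_splay %*% u))
  bend <- params$xi_rel^2 * params$K * sum(bend_beta(cache, s) * tri_c^2)
  surface <- params$lambda_rel *
    (as.numeric(u %*% (cache$A_surf %*% u)) - 2 * sum(cache$b_lin * u) + cache$c0)
  list(bulk = bulk, distortion = splay + bend, splay = splay, bend = bend,
       surface = surface, total = bulk + splay + bend + surface)
}

#' Minimize the confined polar-fluid free energy
#'
#' Minimizes the rescaled free energy
#' \deqn{F/F_0 = \int_{\Omega'} dV' \left[|p|^2 + (\xi/R_0)^2
#'   \tilde f_D(p, \nabla p)\right] + \int_{\partial\Omega'} dS'
#'   (\lambda/R_0)\, (p - p_0)^2}
#' with \eqn{\tilde f_D = (\nabla \cdot p)^2 + K [\hat p \times (\nabla
#' \times p)]^2}, on the axisymmetric slice mesh with P1 finite elements
#' (all integrals carry the cylindrical measure \eqn{2\pi x}). By the
#' meridional symmetry the bend term reduces to the squared in-plane curl
#' times \eqn{|p|^2/(|p|^2+\epsilon^2)} (regularized where \eqn{\hat p}
#' is undefined); that factor is lagged between damped Newton-type
#' iterations, each of which solves the resulting sparse linear system and
#' backtracks on the true energy so the energy decreases monotonically.
#' Solves warm-start from `init` and optionally continue in
#' \eqn{\lambda/R_0} for the stiff surface-dominated corner. The energy
#' scale is \eqn{F_0 = a R_0^3/2}; all reported energies are \eqn{F/F_0}.
#'
#' @param geom A [cap_geometry()].
#' @param params A [material_params()].
#' @param anchoring An [anchoring_spec()].
#' @param init Optional initial nodal field (N x 2 matrix), e.g. a previous
#'   solution's `$p` for warm starting. Default is the weak radial field
#'   `0.1 * (x, z)`.
#' @param mesh Optional precomputed `slice_mesh` (built from `geom` at
#'   `resolution` otherwise).
#' @param resolution Mesh resolution in units of `R0`.
#' @param rel_tol Relative residual tolerance of the nonlinear solve.
#' @param max_iter Maximum outer iterations.
#' @param continuation Use lambda-continuation when `lambda_rel` is large
#'   and no warm start is supplied.
#' @param eps Regularization scale for \eqn{\hat p} at field zeros.
#' @return A `field_solution`: `mesh`, `p` (N x 2 nodal field), `free_energy`
#'   (total \eqn{F/F_0}), `energy` (decomposition), `P` (global order),
#'   `converged`, `params`, `anchoring`.
#' @export
minimize_field <- function(geom, params, anchoring = anchoring_spec(),
                           init = NULL, mesh = NULL, resolution = 0.05,
                           rel_tol = 1e-6, max_iter = 60,
                           continuation = TRUE, eps = 1e-6) {
  if (is.null(mesh)) mesh <- generate_mesh(geom, resolution)
  cache <- attr(mesh, "field_cache")
  if (is.null(cache) || !identical(attr(cache, "anchoring"), anchoring)) {
    cache <- field_cache(mesh, anchoring)
    attr(cache, "tri") <- mesh$tri
    attr(cache, "anchoring") <- anchoring
    attr(mesh, "field_cache") <- cache  # local copy only
  }
  N <- cache$N

  if (is.null(init)) {
    if (continuation && params$lambda_rel > 5) {
      lams <- exp(seq(log(1), log(params$lambda_rel), length.out = 4))
      sol <- NULL
      for (l in lams) {
        sol <- minimize_field(geom, material_params(params$xi_rel, l, params$K),
                              anchoring, init = if (is.null(sol)) NULL else sol$p,
                              mesh = mesh, rel_tol = rel_tol,
                              max_iter = max_iter, continuation = FALSE,
                              eps = eps)
      }
      return(sol)
    }
    init <- 0.1 * mesh$nodes
  }
  u <- c(init[, 1], init[, 2])
  u[intersect(mesh$axis_nodes, seq_len(N))] <- 0  # px = 0 on the axis

  xi2 <- params$xi_rel^2
  lam <- params$lambda_rel
  A_quad <- cache$A_bulk + xi2 * cache$A_splay + lam * cache$A_surf
  b <- lam * cache$b_lin
  free <- cache$free

  energy_of <- function(u) energy_parts_u(cache, u, params, eps)$total

  E <- energy_of(u)
  energy_trace <- E
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    s <- bend_s_factors(cache, mesh$tri, u, eps)
    beta <- xi2 * params$K * bend_beta(cache, s)
    M6 <- nrow(cache$bend_idx)
    iiB <- rep(cache$bend_idx, times = 6)
    jjB <- as.vector(cache$bend_idx[, rep(1:6, each = 6)])
    vvB <- as.vector(cache$bend_g[, rep(1:6, times = 6)] *
                       cache$bend_g[, rep(1:6, each = 6)] * beta)
    A_bend <- Matrix::sparseMatrix(i = iiB, j = jjB, x = vvB,
                                   dims = c(2 * N, 2 * N))
    A <- A_quad + A_bend
    u_star <- numeric(2 * N)
    u_star[free] <- as.numeric(Matrix::solve(A[free, free], b[free]))
    delta <- u_star - u
    step_norm <- sqrt(sum(delta^2)) / (sqrt(sum(u_star^2)) + 1e-12)

    # damped update: backtrack on the true (regularized) energy
    t <- 1
    repeat {
      u_new <- u + t * delta
      E_new <- energy_of(u_new)
      if (E_new <= E + 1e-12 * abs(E) || t < 1e-6) break
      t <- t / 2
    }
    u <- u_new; E <- E_new
    energy_trace <- c(energy_trace, E)
    if (step_norm * t < rel_tol || (step_norm < rel_tol)) { converged <- TRUE; break }
  }

  p <- cbind(u[seq_len(N)], u[N + seq_len(N)])
  colnames(p) <- c("px", "pz")
  parts <- energy_parts_u(cache, u, params, eps)
  sol <- structure(
    list(mesh = mesh, p = p, free_energy = parts$total, energy = parts,
         P = global_order_u(cache, mesh, u), converged = converged,
         params = params, anchoring = anchoring, iterations = it,
         energy_trace = energy_trace),
    class = "field_solution")
  sol
}

# global order P = int |p| dV / V0 with the cylindrical measure, from the
# same quadrature as the energy
global_order_u <- function(cache, mesh, u) {
  N <- cache$N
  px <- u[seq_len(N)]; pz <- u[N + seq_len(N)]
  tri <- mesh$tri
  num <- 0; den <- 0
  for (q in 1:3) {
    wq <- cache$bend_w[, q]
    pq_x <- px[tri[, 1]] * cache$phi[q, 1] + px[tri[, 2]] * cache$phi[q, 2] +
      px[tri[, 3]] * cache$phi[q, 3]
    pq_z <- pz[tri[, 1]] * cache$phi[q, 1] + pz[tri[, 2]] * cache$phi[q, 2] +
      pz[tri[, 3]] * cache$phi[q, 3]
    num <- num + sum(wq * sqrt(pq_x^2 + pq_z^2))
    den <- den + sum(wq)
  }
  num / den
}

#' Global degree of order of a field solution
#'
#' \eqn{P = \int_\Omega dV |p| / V_0}, the volume average of the order
#' parameter magnitude with the axisymmetric (cylindrical) measure.
#'
#' @param field A `field_solution`.
#' @return Scalar `P`.
#' @export
global_order <- function(field) {
  cache <- attr(field$mesh, "field_cache")
  if (is.null(cache)) {
    an <- field$anchoring
    cache <- field_cache(field$mesh, an)
    attr(cache, "tri") <- field$mesh$tri
  }
  global_order_u(cache, field$mesh, c(field$p[, 1], field$p[, 2]))
}

#' Free energy of an arbitrary nodal field
#'
#' Evaluates the rescaled free energy of a given nodal field on a mesh
#' (not necessarily a minimizer), reporting the bulk, distortion (splay +
#' bend) and surface contributions separately along with their sum. Useful
#' for checking energy decompositions and zero-field baselines.
#'
#' @param mesh A `slice_mesh`.
#' @param p N x 2 matrix of nodal field values (columns `px`, `pz`).
#' @param params A [material_params()].
#' @param anchoring An [anchoring_spec()].
#' @param eps Bend regularization scale.
#' @return A list `bulk`, `distortion`, `splay`, `bend`, `surface`, `total`.
#' @export
free_energy <- function(mesh, p, params, anchoring = anchoring_spec(),
                        eps = 1e-6) {
  cache <- field_cache(mesh, anchoring)
  attr(cache, "tri") <- mesh$tri
  energy_parts_u(cache, c(p[, 1], p[, 2]), params, eps)
}

#' @export
print.field_solution <- function(x, ...) {
  cat(sprintf(
    "<field_solution> F/F0 = %.6g, P = %.4g, xi/R0 = %.3g, lambda/R0 = %.3g%s\n",
    x$free_energy, x$P, x$params$xi_rel, x$params$lambda_rel,
    if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}
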
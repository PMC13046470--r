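#' Tidy a fitted cap geometry
#'
#' @param x A [cap_geometry()].
#' @param ... Unused.
#' @return One row per cap with `cap`, `R`, `C`, `kappa`, `gamma`.
#' @method tidy cap_geometry
#' @export
tidy.cap_geometry <- function(x, ...) {
  tibble::tibble(
    cap = c("alpha", "beta"),
    R = c(x$R_alpha, x$R_beta),
    C = c(x$C_alpha, x$C_beta),
    kappa = c(x$kappa_alpha, x$kappa_beta),
    gamma = c(x$gamma_alpha, x$gamma_beta))
}

#' @rdname tidy.cap_geometry
#' @method glance cap_geometry
#' @export
glance.cap_geometry <- function(x, ...) {
  tibble::tibble(
    V0 = x$V0, R0 = x$R0, r_equator = x$r_equator,
    h = attr(x, "h") %||% NA_real_,
    constraint_violation = attr(x, "constraint_violation") %||% NA_real_,
    converged = attr(x, "converged") %||% NA)
}

#' Tidy a field solution
#'
#' @param x A `field_solution`.
#' @param ... Unused.
#' @return `tidy()`: one row per mesh node (`x`, `z`, `px`, `pz`,
#'   `magnitude`); `glance()`: one-row summary.
#' @method tidy field_solution
#' @export
tidy.field_solution <- function(x, ...) {
  tibble::tibble(
    x = x$mesh$nodes[, 1], z = x$mesh$nodes[, 2],
    px = x$p[, 1], pz = x$p[, 2],
    magnitude = sqrt(rowSums(x$p^2)))
}

#' @rdname tidy.field_solution
#' @method glance field_solution
#' @export
glance.field_solution <- function(x, ...) {
  tibble::tibble(
    free_energy = x$free_energy, bulk = x$energy$bulk,
    distortion = x$energy$distortion, surface = x$energy$surface,
    P = x$P, xi_rel = x$params$xi_rel, lambda_rel = x$params$lambda_rel,
    K = x$params$K, converged = x$converged, iterations = x$iterations)
}

#' Tidy a material-length fit
#'
#' @param x A `fit_result`.
#' @param ... Unused.
#' @return `tidy()`: the cost surface; `glance()`: the best-fit row.
#' @method tidy fit_result
#' @export
tidy.fit_result <- function(x, ...) x$surface

#' @rdname tidy.fit_result
#' @method glance fit_result
#' @export
glance.fit_result <- function(x, ...) x$best

#' Tidy a defect set
#'
#' @param x A `defect_set`.
#' @param ... Unused.
#' @return `tidy()`: the defect table; `glance()`: count and total charge.
#' @method tidy defect_set
#' @export
tidy.defect_set <- function(x, ...) x$defects

#' @rdname tidy.defect_set
#' @method glance defect_set
#' @export
glance.defect_set <- function(x, ...) {
  tibble::tibble(n_defects = nrow(x$defects), total_charge = x$total_charge)
}

#' Tidy a nematic map
#'
#' @param x A `nematic_map`.
#' @param ... Unused.
#' @return `tidy()`: one row per grid point (`x`, `z`, `Lambda`, director
#'   `Vx/Vy/Vz`, alignment `wx/wz`, `n_samples`); `glance()`: summary.
#' @method tidy nematic_map
#' @export
tidy.nematic_map <- function(x, ...) {
  tibble::tibble(
    x = x$grid[, 1], z = x$grid[, 2],
    Lambda = as.vector(x$Lambda),
    Vx = as.vector(x$V[, , 1]), Vy = as.vector(x$V[, , 2]),
    Vz = as.vector(x$V[, , 3]),
    wx = as.vector(x$w[, , 1]), wz = as.vector(x$w[, , 3]),
    n_samples = as.vector(x$n_samples))
}

#' @rdname tidy.nematic_map
#' @method glance nematic_map
#' @export
glance.nematic_map <- function(x, ...) {
  tibble::tibble(
    Lambda_max = x$Lambda_max, Lambda_avg = average_nematic_magnitude(x),
    d = x$d, M = x$M, grid_n = length(x$x))
}
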
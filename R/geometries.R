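# Trade-off analysis beyond the localized-source 1D model: a 1D system with a
# spatially distributed source, and diffusion-depletion on a spherical
# surface with an azimuthally symmetric polar source cap. Both solvers return
# a common "geometry_solution" carrying the stationary profile, the discrete
# linear generator (for resolvent-based relaxation times) and the total
# production rate, from which tradeoff_geometry() assembles cost, precision
# and their product exactly as in the localized 1D model.

#' Distributed-source specification for the 1D model
#'
#' Source density \code{s(x)} (concentration/time) on \eqn{[0, L]}: either a
#' boxcar of width \code{w} carrying a total influx equivalent \code{j_total}
#' (concentration x length / time, the analogue of \code{jin}), or an
#' arbitrary nonnegative function.
#'
#' @param L,lcell,vcell,D,kd as in [sdd_params()].
#' @param w boxcar source width (\code{w <= L}); ignored if \code{s_fun}
#'   given.
#' @param j_total total source strength \eqn{\int_0^L s\,dx}.
#' @param s_fun optional vectorized source-density function of x.
#' @return object of class \code{"distributed_source_spec"}.
#' @export
distributed_source_spec <- function(L, lcell = 1, vcell = 1, D, kd,
                                    w = NULL, j_total = NULL, s_fun = NULL) {
  if (is.null(s_fun)) {
    if (is.null(w) || is.null(j_total)) {
      stop("invalid parameter: give either s_fun or (w, j_total)")
    }
    if (w <= 0 || w > L) stop("invalid parameter: require 0 < w <= L")
    if (j_total <= 0) stop("invalid parameter: j_total must be > 0")
    dens <- j_total / w
    s_fun <- function(x) ifelse(x >= 0 & x <= w, dens, 0)
  }
  structure(list(L = L, lcell = lcell, vcell = vcell, D = D, kd = kd,
                 lambda = sqrt(D / kd), s_fun = s_fun, w = w,
                 j_total = j_total),
            class = "distributed_source_spec")
}

# Green's function of -D rho'' + kd rho = s with zero-flux ends, written with
# decaying exponentials only (overflow-safe for any L/lambda):
#   G(x, x') = (lambda / 2D) e^{-|x-x'|/lambda}
#              (1 + e^{-2 min(x,x')/lambda}) (1 + e^{-2 (L-max(x,x'))/lambda})
#              / (1 - e^{-2L/lambda})
.green_1d <- function(x, xp, lam, D, L) {
  lo <- pmin(x, xp); hi <- pmax(x, xp)
  (lam / (2 * D)) * exp(-(hi - lo) / lam) *
    (1 + exp(-2 * lo / lam)) * (1 + exp(-2 * (L - hi) / lam)) /
    (1 - exp(-2 * L / lam))
}

#' Steady state of the 1D model with a distributed source
#'
#' Solves \eqn{D\rho'' - k_d\rho + s(x) = 0} with zero-flux ends by
#' superposition of the localized-source kernel:
#' \eqn{\rho(x) = \int_0^L G(x,x') s(x')\,dx'} via adaptive quadrature. A
#' boxcar shrunk to zero width at fixed total production recovers the
#' localized-source profile; a source uniform over the whole domain gives the
#' flat balance \eqn{\rho = s/k_d}.
#'
#' @param spec a [distributed_source_spec()].
#' @param x positions at which to evaluate (default: 400 cell centers).
#' @return object of class \code{"concentration_profile"} (data frame
#'   \code{x}, \code{rho}).
#' @export
steady_state_distributed <- function(spec, x = NULL) {
  stopifnot(inherits(spec, "distributed_source_spec"))
  if (is.null(x)) x <- (seq_len(400) - 0.5) * spec$L / 400
  # integrate piecewise so that narrow source supports and the kink of the
  # kernel at x' = x are segment endpoints (adaptive quadrature would miss a
  # boxcar much narrower than the domain otherwise)
  upper <- if (!is.null(spec$w)) spec$w else spec$L
  rho <- vapply(x, function(xi) {
    cuts <- sort(unique(pmin(pmax(c(0, xi, upper, spec$L), 0), spec$L)))
    total <- 0
    for (k in seq_len(length(cuts) - 1)) {
      if (cuts[k + 1] <= cuts[k]) next
      int <- tryCatch(
        stats::integrate(function(xp) spec$s_fun(xp) *
                           .green_1d(xi, xp, spec$lambda, spec$D, spec$L),
                         cuts[k], cuts[k + 1], rel.tol = 1e-10,
                         abs.tol = 0, subdivisions = 500L),
        error = function(e) stop("numerical error: quadrature failed at x = ",
                                 xi, ": ", conditionMessage(e))
      )
      total <- total + int$value
    }
    total
  }, numeric(1))
  structure(data.frame(x = x, rho = rho),
            is_steady = TRUE, spec = spec,
            class = c("concentration_profile", "data.frame"))
}

# Finite-volume generator of the 1D dynamics on nx cells: d n/dt = A n + b,
# n = counts per grid cell.
.generator_1d <- function(spec, nx) {
  h <- spec$L / nx
  xc <- (seq_len(nx) - 0.5) * h
  r <- spec$D / h^2
  diag_main <- rep(-spec$kd - 2 * r, nx)
  diag_main[c(1, nx)] <- -spec$kd - r  # reflecting ends
  A <- Matrix::bandSparse(nx, nx, k = c(-1, 0, 1),
                          diagonals = list(rep(r, nx - 1), diag_main,
                                           rep(r, nx - 1)))
  # source in count units: s [conc/time] * vcell * h / lcell molecules/time
  b <- spec$s_fun(xc) * spec$vcell * h / spec$lcell
  list(A = A, b = b, x = xc, h = h)
}

#' Geometry-agnostic stationary solution for trade-off evaluation
#'
#' Internal constructor shared by the 1D distributed and spherical solvers.
#'
#' @keywords internal
.geometry_solution <- function(x, sensor_counts, A, b, production_total,
                               coord = "x", x_origin = 0) {
  structure(list(x = x, sensor_counts = sensor_counts, A = A, b = b,
                 production_total = production_total, coord = coord,
                 x_origin = x_origin),
            class = "geometry_solution")
}

#' Full 1D distributed-source solution for trade-off analysis
#'
#' Solves the finite-volume discretization of the distributed-source model
#' and packages profile, generator and production for [tradeoff_geometry()].
#' Sensor counts are \eqn{\rho(x) v_{cell}}, as in the localized model.
#'
#' @param spec a [distributed_source_spec()].
#' @param nx grid resolution (default 2000).
#' @return object of class \code{"geometry_solution"}.
#' @export
solve_distributed_1d <- function(spec, nx = 2000) {
  stopifnot(inherits(spec, "distributed_source_spec"))
  g <- .generator_1d(spec, nx)
  n_ss <- as.numeric(Matrix::solve(-g$A, g$b))
  if (any(!is.finite(n_ss)) || any(n_ss < 0)) {
    stop("numerical error: stationary solve failed")
  }
  # counts per grid cell -> concentration -> counts per sensor cell (vcell)
  rho <- n_ss * spec$lcell / (spec$vcell * g$h)
  .geometry_solution(g$x, rho * spec$vcell, g$A, g$b,
                     production_total = sum(g$b), coord = "x")
}

#' Spherical-surface specification
#'
#' Diffusion-depletion on a sphere of radius \code{R} with production
#' uniformly distributed over the polar cap \eqn{\theta < \theta_0}
#' (azimuthally symmetric):
#' \eqn{(D/R^2)\,(\sin\theta)^{-1}\partial_\theta(\sin\theta\,
#' \partial_\theta\rho) - k_d \rho + s(\theta) = 0} with regularity at both
#' poles. \eqn{\rho} is a surface density (molecules/area); a sensor is a
#' patch of area \code{lcell^2}.
#'
#' @param R sphere radius.
#' @param theta0 source cap half-angle, in \eqn{(0, \pi)}.
#' @param D diffusivity on the surface.
#' @param kd depletion rate.
#' @param production total production rate over the cap (molecules/time).
#' @param lcell sensor patch edge length.
#' @param n_theta polar grid resolution (>= 400).
#' @return object of class \code{"sphere_spec"}.
#' @export
sphere_spec <- function(R, theta0, D, kd, production, lcell = 1,
                        n_theta = 800L) {
  if (theta0 <= 0 || theta0 >= pi) stop("invalid parameter: 0 < theta0 < pi")
  vals <- c(R = R, D = D, production = production, lcell = lcell)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("invalid parameter: R, D, production, lcell must be positive")
  }
  if (kd < 0) stop("invalid parameter: kd must be >= 0")
  if (n_theta < 400) stop("invalid parameter: n_theta must be >= 400")
  structure(list(R = R, theta0 = theta0, D = D, kd = kd,
                 production = production, lcell = lcell,
                 n_theta = as.integer(n_theta),
                 lambda = if (kd > 0) sqrt(D / kd) else Inf),
            class = "sphere_spec")
}

# Conservative finite-volume generator on the staggered polar grid
# theta_i = (i - 1/2) h, h = pi/n: fluxes vanish at both poles because
# sin(0) = sin(pi) = 0. State = counts per annulus.
.generator_sphere <- function(spec) {
  n <- spec$n_theta
  h <- pi / n
  th <- (seq_len(n) - 0.5) * h
  faces <- sin(seq_len(n - 1) * h)            # sin(theta) at interior faces
  # annulus areas: 2 pi R^2 sin(theta_i) h (midpoint rule)
  area <- 2 * pi * spec$R^2 * sin(th) * h
  # count flux between annuli i, i+1: (D/R^2 h^2) * 2 pi R^2 sin(face) h *
  # (c_{i+1} - c_i) with c = n/area; in count coordinates the hop coefficients
  # are k_{i->i+1} = (D/(R h)^2) * sin(face)/sin(th_i) etc.
  kf <- (spec$D / (spec$R * h)^2) * faces / sin(th[-n])  # i -> i+1
  kb <- (spec$D / (spec$R * h)^2) * faces / sin(th[-1])  # i+1 -> i
  diag_main <- rep(-spec$kd, n)
  diag_main[-n] <- diag_main[-n] - kf
  diag_main[-1] <- diag_main[-1] - kb
  A <- Matrix::bandSparse(n, n, k = c(-1, 0, 1),
                          diagonals = list(kf, diag_main, kb))
  cap <- th < spec$theta0
  cap_area <- 2 * pi * spec$R^2 * (1 - cos(spec$theta0))
  b <- numeric(n)
  b[cap] <- spec$production * area[cap] / sum(area[cap])
  list(A = A, b = b, theta = th, h = h, area = area, cap_area = cap_area)
}

#' Steady state of diffusion-depletion on the sphere
#'
#' Second-order conservative finite-volume solve on a staggered polar grid
#' (fluxes vanish identically at both poles, so total production balances
#' total degradation exactly). With \code{kd = 0} the stationary problem has
#' no solution (production with no sink) and a no-steady-state error is
#' raised.
#'
#' @param spec a [sphere_spec()].
#' @return object of class \code{"sphere_solution"}: list with \code{theta}
#'   (grid), \code{rho} (surface density), \code{counts} (per annulus),
#'   \code{generator}, \code{spec}.
#' @export
steady_state_sphere <- function(spec) {
  stopifnot(inherits(spec, "sphere_spec"))
  if (spec$kd <= 0) {
    stop("no-steady-state error: kd = 0 leaves production unbalanced ",
         "(no sink on a closed surface)")
  }
  g <- .generator_sphere(spec)
  n_ss <- as.numeric(Matrix::solve(-g$A, g$b))
  if (any(!is.finite(n_ss))) {
    stop("numerical error: non-finite values in the spherical solve")
  }
  structure(list(theta = g$theta, rho = n_ss / g$area, counts = n_ss,
                 generator = g, spec = spec),
            class = "sphere_solution")
}

#' Package a spherical solution for trade-off evaluation
#'
#' Sensor counts are \eqn{\rho(\theta) l_{cell}^2} (a cell-sized patch);
#' the boundary coordinate is the arc length \eqn{R(\theta - \theta_0)} from
#' the edge of the source cap, which makes positions comparable to the 1D
#' model.
#'
#' @param sol a \code{"sphere_solution"} from [steady_state_sphere()].
#' @return object of class \code{"geometry_solution"}.
#' @export
solve_sphere <- function(sol) {
  if (inherits(sol, "sphere_spec")) sol <- steady_state_sphere(sol)
  stopifnot(inherits(sol, "sphere_solution"))
  spec <- sol$spec
  x <- spec$R * sol$theta  # arc length from the pole
  .geometry_solution(x, sol$rho * spec$lcell^2, sol$generator$A,
                     sol$generator$b, production_total = spec$production,
                     coord = "arc", x_origin = spec$R * spec$theta0)
}

#' Cost-precision trade-off in a general geometry
#'
#' Generalizes the localized-source trade-off: the cost at a boundary is the
#' per-molecule cost times total production times the local relaxation time
#' (the time-integrated relaxation deficit, evaluated exactly through the
#' discrete generator's resolvent: \eqn{\tau(x) = (-A^{-1} n_{ss})_x /
#' (n_{ss})_x}); the precision is the Poisson positional error of the sensor
#' count profile with lever arm measured from the source edge. Their product
#' is the analogue of the localized-model trade-off product.
#'
#' @param sol a \code{"geometry_solution"} ([solve_distributed_1d()] or
#'   [solve_sphere()]).
#' @param xb boundary coordinate (same units as \code{sol$x}; for the sphere,
#'   arc length from the pole).
#' @param cost a [cost_params()] (default unit cost).
#' @return object of class \code{"tradeoff_result"} with the additional field
#'   \code{product_per_production} (\eqn{\tau \epsilon^2}, independent of the
#'   production normalization and so comparable across geometries).
#' @export
tradeoff_geometry <- function(sol, xb, cost = cost_params()) {
  stopifnot(inherits(sol, "geometry_solution"))
  n_ss <- as.numeric(Matrix::solve(-sol$A, sol$b))
  i <- which.min(abs(sol$x - xb))
  if (i <= 1 || i >= length(sol$x)) {
    stop("domain error: xb at the edge of the solved grid")
  }
  # relaxation time via resolvent (exact time integral of the deficit)
  integ <- as.numeric(Matrix::solve(-sol$A, n_ss))
  tau <- integ[i] / n_ss[i]
  # precision from the sensor-count profile
  counts <- sol$sensor_counts
  logc <- log(counts)
  slope <- (logc[i + 1] - logc[i - 1]) / (sol$x[i + 1] - sol$x[i - 1])
  if (!is.finite(slope) || slope >= 0) {
    stop("singular input: profile slope at xb must be strictly negative")
  }
  lever <- sol$x[i] - sol$x_origin
  if (lever <= 0) stop("domain error: xb must lie beyond the source edge")
  eps2 <- 1 / ((slope * lever)^2 * counts[i])
  C <- cost$alpha_o * sol$production_total * tau
  structure(
    list(xb = sol$x[i], lam = NA_real_, cost = C, precision_sq = eps2,
         product = C * eps2,
         product_normalized = C * eps2 / cost$alpha_o,
         product_per_production = tau * eps2,
         lambda_min = NA_real_, product_min = NA_real_,
         measurement_model = paste0("geometry:", sol$coord)),
    class = "tradeoff_result"
  )
}
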
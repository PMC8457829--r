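# Closed-form quantities of the 1D SDD model with a localized source at x = 0,
# depletion everywhere, influx boundary condition -D rho'(0) = jin and a
# reflecting wall at x = L.
#
# All hyperbolic ratios are rewritten in terms of exp(-2L/lambda)-type decaying
# exponentials so that no intermediate cosh/sinh can overflow, whatever L/lambda;
# the rewritten forms reduce analytically to the exponential large-L limits.

# coth(z) for z > 0 without overflow
.coth <- function(z) (1 + exp(-2 * z)) / (1 - exp(-2 * z))

.check_position <- function(x, L, name = "x") {
  if (any(!is.finite(x))) stop("domain error: ", name, " must be finite")
  if (any(x < 0 | x > L)) {
    stop("domain error: ", name, " must lie within [0, L] = [0, ", L, "]")
  }
}

#' Steady-state concentration profile of the SDD model
#'
#' Evaluates the stationary solution of the reaction-diffusion dynamics
#' \eqn{\partial_t \rho = D \partial_x^2 \rho - k_d \rho} with influx
#' \eqn{-D\partial_x\rho(0) = j_{in}} and zero flux at \eqn{x = L}:
#' \deqn{\rho_{ss}(x) = \frac{j_{in}}{\sqrt{D k_d}}
#'   \frac{\cosh((L-x)/\lambda)}{\sinh(L/\lambda)},}
#' which decays exponentially with length \eqn{\lambda = \sqrt{D/k_d}} when
#' \eqn{L \gg \lambda}. Evaluation is overflow-safe for arbitrarily large
#' \eqn{L/\lambda}.
#'
#' @param params an [sdd_params()] object.
#' @param x numeric vector of positions in \eqn{[0, L]}.
#' @return An object of class \code{"concentration_profile"}: a data frame
#'   with columns \code{x} and \code{rho} and attribute \code{is_steady=TRUE}.
#' @export
steady_state_profile <- function(params, x) {
  stopifnot(inherits(params, "sdd_params"))
  .check_position(x, params$L)
  lam <- params$lambda
  amp <- params$jin / sqrt(params$D * params$kd)
  # cosh((L-x)/lam)/sinh(L/lam) = e^{-x/lam} (1+e^{-2(L-x)/lam}) / (1-e^{-2L/lam})
  rho <- amp * exp(-x / lam) * (1 + exp(-2 * (params$L - x) / lam)) /
    (1 - exp(-2 * params$L / lam))
  structure(data.frame(x = x, rho = rho),
            is_steady = TRUE, params = params,
            class = c("concentration_profile", "data.frame"))
}

#' Dimensionless accumulation-time factor f(x; lambda)
#'
#' The factor \eqn{f(x;\lambda) = \frac{1}{2}\left[1 +
#' \frac{L}{\lambda}\coth\frac{L}{\lambda} -
#' \frac{L-x}{\lambda}\tanh\frac{L-x}{\lambda}\right]}, such that the local
#' accumulation time is \eqn{\tau(x) = f(x;\lambda)/k_d}. For \eqn{L \gg
#' \lambda} it approaches \eqn{(1 + x/\lambda)/2}.
#'
#' @param x position(s) in \eqn{[0, L]}.
#' @param lam decay length.
#' @param L system length.
#' @return numeric vector of dimensionless factors.
#' @export
accumulation_factor <- function(x, lam, L) {
  .check_position(x, L)
  0.5 * (1 + (L / lam) * .coth(L / lam) - ((L - x) / lam) * tanh((L - x) / lam))
}

#' Mean local accumulation time
#'
#' Mean time scale for the concentration at position \code{x} to build up to
#' its steady-state value, starting from an empty system:
#' \eqn{\tau(x) = \int_0^\infty R(x,t)\,dt = f(x;\lambda)/k_d} with
#' \eqn{R(x,t) = (\rho_{ss}(x) - \rho(x,t))/\rho_{ss}(x)}. Monotone
#' nondecreasing in \code{x}; at the source of a long system it equals
#' \eqn{1/(2 k_d)}.
#'
#' @inheritParams steady_state_profile
#' @return accumulation time(s), same unit as \code{1/kd}.
#' @export
accumulation_time <- function(params, x) {
  stopifnot(inherits(params, "sdd_params"))
  accumulation_factor(x, params$lambda, params$L) / params$kd
}

#' Thermodynamic cost of profile formation (point measurement)
#'
#' The number of molecules produced while the profile builds up at position
#' \code{x}, times the per-molecule cost:
#' \eqn{C(x) = \alpha_o n_m f(x;\lambda)} with
#' \eqn{n_m = v_{cell} j_{in} / (l_{cell} k_d)}. Linear in \code{jin}; for
#' \eqn{L \gg \lambda} it grows as \eqn{\alpha_o n_m (1 + x/\lambda)/2}.
#'
#' @inheritParams steady_state_profile
#' @param cost a [cost_params()] object.
#' @return cost in ATP-equivalents (units of \code{alpha_o}).
#' @export
cost_point <- function(params, cost, x) {
  stopifnot(inherits(params, "sdd_params"), inherits(cost, "cost_params"))
  cost$alpha_o * params$nm * accumulation_factor(x, params$lambda, params$L)
}

#' Squared relative positional error (point measurement)
#'
#' The squared relative error of the boundary position inferred from a single
#' instantaneous concentration measurement at \code{x}, assuming Poisson
#' copy-number statistics of the stationary profile:
#' \deqn{\epsilon^2(x) = \frac{\lambda^3}{x^2 l_{cell}} \frac{1}{n_m}
#'   \frac{\sinh(L/\lambda)\cosh((L-x)/\lambda)}{\sinh^2((L-x)/\lambda)},}
#' which reduces to \eqn{(\lambda^3/x^2 l_{cell}) e^{x/\lambda}/n_m} for
#' \eqn{L \gg \lambda}. Diverges at both \code{x = 0} (vanishing lever arm)
#' and \code{x = L} (vanishing slope at the reflecting wall); those inputs are
#' rejected.
#'
#' @inheritParams steady_state_profile
#' @return dimensionless squared relative error.
#' @export
positional_error_point <- function(params, x) {
  stopifnot(inherits(params, "sdd_params"))
  .check_position(x, params$L)
  if (any(x == 0)) stop("singular input: epsilon^2 diverges at x = 0")
  if (any(x == params$L)) {
    stop("singular input: epsilon^2 diverges at x = L (zero slope at the wall)")
  }
  lam <- params$lambda
  L <- params$L
  # sinh(L/l) cosh((L-x)/l) / sinh((L-x)/l)^2
  #  = e^{x/l} (1 - e^{-2L/l}) (1 + e^{-2(L-x)/l}) / (1 - e^{-2(L-x)/l})^2
  hyp <- exp(x / lam) * (1 - exp(-2 * L / lam)) *
    (1 + exp(-2 * (L - x) / lam)) / (1 - exp(-2 * (L - x) / lam))^2
  (lam^3 / (x^2 * params$lcell)) / params$nm * hyp
}

#' Positional variance from concentration noise
#'
#' Converts concentration noise into positional variance by the local slope of
#' the mean profile: \eqn{\sigma_x^2 = \sigma_\rho^2 / (\partial_x \rho)^2}.
#' The relative form \eqn{\epsilon^2 = \sigma_x^2/x^2} is what
#' [positional_error_point()] computes for the SDD profile.
#'
#' @param profile_slope local slope of the mean profile (concentration/length).
#' @param conc_variance variance of the measured concentration.
#' @return squared positional error (length^2).
#' @export
positional_variance <- function(profile_slope, conc_variance) {
  if (any(profile_slope == 0)) {
    stop("singular input: zero profile slope gives unbounded positional error")
  }
  if (any(conc_variance < 0)) stop("invalid parameter: variance must be >= 0")
  conc_variance / profile_slope^2
}

#' Normalized point-measurement trade-off product
#'
#' The production-independent product \eqn{\pi_o(x_b;\lambda) =
#' C(x_b)\,\epsilon^2(x_b)} in units of \eqn{\alpha_o L/l_{cell}}. Depends
#' only on the two ratios \eqn{x_b/L} and \eqn{\lambda/L}; \code{jin},
#' \code{vcell} and \code{lcell} all cancel.
#'
#' @param xb boundary position, \eqn{0 < x_b < L}.
#' @param lam decay length.
#' @param L system length.
#' @return dimensionless normalized product.
#' @export
point_product_normalized <- function(xb, lam, L) {
  if (any(xb <= 0 | xb >= L)) stop("domain error: require 0 < xb < L")
  f <- accumulation_factor(xb, lam, L)
  hyp <- exp(xb / lam) * (1 - exp(-2 * L / lam)) *
    (1 + exp(-2 * (L - xb) / lam)) / (1 - exp(-2 * (L - xb) / lam))^2
  (lam^3 / (xb^2 * L)) * f * hyp
}

#' Cost-precision trade-off at a target boundary (point measurement)
#'
#' Assembles cost, precision and their product at the boundary position
#' \code{xb}, together with the decay length \eqn{\lambda_{min}} that would
#' minimize the product at this boundary and the attained minimum. The product
#' is independent of the production amplitude (\code{jin}, \code{vcell}); only
#' the geometry (\code{xb}, \code{lambda}, \code{L}, \code{lcell}) matters.
#'
#' @inheritParams cost_point
#' @param xb target boundary position, strictly inside \eqn{(0, L)}.
#' @return An object of class \code{"tradeoff_result"}: list with fields
#'   \code{xb}, \code{lam}, \code{cost}, \code{precision_sq}, \code{product},
#'   \code{product_normalized}, \code{lambda_min}, \code{product_min}.
#' @export
tradeoff_point <- function(params, cost, xb) {
  stopifnot(inherits(params, "sdd_params"), inherits(cost, "cost_params"))
  if (xb <= 0 || xb >= params$L) stop("domain error: require 0 < xb < L")
  C <- cost_point(params, cost, xb)
  eps2 <- positional_error_point(params, xb)
  opt <- optimal_lambda_point(xb, params$L)
  structure(
    list(xb = xb, lam = params$lambda,
         cost = C, precision_sq = eps2, product = C * eps2,
         product_normalized = C * eps2 / (cost$alpha_o * params$L / params$lcell),
         lambda_min = opt$lambda_min, product_min = opt$product_min,
         measurement_model = "point"),
    class = "tradeoff_result"
  )
}

#' @export
print.tradeoff_result <- function(x, ...) {
  cat(sprintf("Cost-precision trade-off (%s measurement)\n", x$measurement_model))
  cat(sprintf("  xb = %g, lambda = %g (lambda/xb = %.4f)\n", x$xb, x$lam, x$lam / x$xb))
  cat(sprintf("  cost = %.6g, epsilon^2 = %.6g\n", x$cost, x$precision_sq))
  cat(sprintf("  product = %.6g, normalized = %.6g\n", x$product, x$product_normalized))
  cat(sprintf("  lambda_min = %.6g, product at lambda_min = %.6g\n",
              x$lambda_min, x$product_min))
  invisible(x)
}

# Two-stage Brent minimization on log(lambda): a wide scan followed by a
# refinement pass on a narrow bracket around the first minimum.
.minimize_log_bracket <- function(fn, lower, upper) {
  obj <- function(loglam) fn(exp(loglam))
  o1 <- stats::optimize(obj, c(log(lower), log(upper)), tol = 1e-10)
  if (!is.finite(o1$objective)) {
    stop("numerical error: trade-off minimization failed on bracket [",
         lower, ", ", upper, "]")
  }
  o2 <- stats::optimize(obj, o1$minimum + c(-1e-4, 1e-4), tol = 1e-12)
  if (o2$objective <= o1$objective) o1 <- o2
  list(lambda_min = exp(o1$minimum), product_min = o1$objective)
}

#' Optimal decay length for the point measurement
#'
#' Minimizes the normalized trade-off product over the decay length
#' \eqn{\lambda} at a fixed boundary \code{xb}, by Brent minimization on
#' \eqn{\log\lambda} over \eqn{[x_b/50, 10 x_b]}. In the large-system limit
#' the minimizer satisfies \eqn{s^2 - s - 3 = 0} with \eqn{s = x_b/\lambda},
#' i.e. \eqn{\lambda_{min}/x_b = 2/(1+\sqrt{13}) \approx 0.4343}.
#'
#' @param xb boundary position, \eqn{0 < x_b < L}.
#' @param L system length.
#' @return list with \code{lambda_min} and \code{product_min} (normalized by
#'   \eqn{\alpha_o L / l_{cell}}).
#' @export
optimal_lambda_point <- function(xb, L) {
  if (xb <= 0 || xb >= L) stop("domain error: require 0 < xb < L")
  .minimize_log_bracket(function(l) point_product_normalized(xb, l, L),
                        xb / 50, 10 * xb)
}

#' Closed-form large-system optimum of the point trade-off
#'
#' In the limit \eqn{L \gg \lambda} the normalized product is proportional to
#' \eqn{(1+s) s^{-3} e^s} with \eqn{s = x_b/\lambda}; its stationary point
#' solves \eqn{s^2 - s - 3 = 0}, giving \eqn{s = (1+\sqrt{13})/2} and hence
#' \eqn{\lambda_{min}/x_b = 2/(1+\sqrt{13})}. Used as an independent check of
#' the numerical optimizer.
#'
#' @return the ratio \eqn{\lambda_{min}/x_b} (about 0.43426).
#' @export
optimal_lambda_ratio_closed_form <- function() {
  2 / (1 + sqrt(13))
}

#' Boundary concentration as a fraction of the source amplitude
#'
#' In the large-system limit the profile is \eqn{c(x) = c_0 e^{-x/\lambda}},
#' so the threshold concentration at the boundary is the fraction
#' \eqn{e^{-x_b/\lambda}} of the source-end amplitude. At the point-model
#' optimum \eqn{\lambda = 0.4343 x_b} this fraction is about 0.10: boundaries
#' form where the profile has decayed to a tenth of its amplitude.
#'
#' @param xb boundary position.
#' @param lam decay length (> 0).
#' @return dimensionless fraction \eqn{c(x_b)/c_0}.
#' @export
threshold_fraction <- function(xb, lam) {
  if (any(!is.finite(lam)) || any(lam <= 0)) {
    stop("invalid parameter: lam must be positive")
  }
  exp(-xb / lam)
}
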
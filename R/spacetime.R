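# Space-time-averaged measurement: a sensor of half-width a at position x
# integrates molecular counts over (x - a, x + a) for a duration T. The model
# is posed on a semi-infinite domain (the stated large-L form); finite-L users
# should use the point-measurement model instead.

# Bracketed sensor factor of the squared relative error:
#   B(u) = (e^{-u} + 3 e^{3u} - 4 (1+u) e^{u}) / (2 (e^{2u} - 1)^2), u = a/lambda.
# Numerator and denominator are both 8 u^2 + O(u^3), so for small u the direct
# expression cancels catastrophically; below u = 1e-3 a series is used:
#   B(u) = 1 - (2/3) u + (1/6) u^2 + O(u^3).
#' Sensor averaging factor of the space-time measurement
#'
#' Dimensionless factor by which spatial averaging over a window of half-width
#' \code{a} reduces the squared relative error, as a function of
#' \eqn{u = a/\lambda}. Lies in \eqn{(0, 1]} and tends to 1 as the sensor
#' shrinks.
#'
#' @param u ratio of sensor half-width to decay length (> 0 allowed; 0 gives
#'   the limit 1).
#' @return numeric vector of factors.
#' @export
sensor_factor <- function(u) {
  if (any(!is.finite(u)) || any(u < 0)) stop("invalid parameter: u must be >= 0")
  out <- numeric(length(u))
  small <- u < 1e-3
  us <- u[small]
  out[small] <- 1 - (2 / 3) * us + us^2 / 6
  ub <- u[!small]
  out[!small] <- (exp(-ub) + 3 * exp(3 * ub) - 4 * (1 + ub) * exp(ub)) /
    (2 * (exp(2 * ub) - 1)^2)
  out
}

.check_T_validity <- function(T_avg, kd) {
  if (T_avg < 10 / kd) {
    stop("validity error: the window-variance formula requires T >> 1/kd; ",
         "got T = ", T_avg, " < 10/kd = ", 10 / kd)
  }
  if (T_avg < 50 / kd) {
    warning("averaging time T = ", T_avg, " is below 50/kd; ",
            "the long-time variance approximation may be inaccurate")
  }
}

#' Mean space-time-averaged molecular count
#'
#' Expected count registered by a sensor spanning \eqn{(x-a, x+a)}:
#' \eqn{\langle m(x)\rangle = 2 (j_{in}/k_d) e^{-x/\lambda}\sinh(a/\lambda)}.
#' As \eqn{a \to 0}, \eqn{\langle m \rangle / (2a)} recovers the point
#' concentration \eqn{(j_{in}/k_d\lambda) e^{-x/\lambda}}.
#'
#' @param p a [spacetime_params()] object.
#' @param s a [sensor_spec()] object.
#' @param x sensor center position; must satisfy \code{x >= a} so the window
#'   stays inside the domain.
#' @return expected molecule count (dimensionless).
#' @export
mean_window_count <- function(p, s, x) {
  stopifnot(inherits(p, "spacetime_params"), inherits(s, "sensor_spec"))
  if (any(x < s$a)) stop("domain error: require x >= a (window inside domain)")
  2 * (p$jin / p$kd) * exp(-x / p$lam) * sinh(s$a / p$lam)
}

#' Variance of the space-time-averaged count
#'
#' Long-measurement approximation of the variance of the windowed count,
#' valid for \eqn{T \gg 1/k_d}:
#' \deqn{\sigma_m^2(x) = \frac{4 j_{in} e^{-x/\lambda} \sinh(a/\lambda)}
#'   {T k_d^2}\,\sinh(a/\lambda)\, B(a/\lambda),}
#' where \eqn{B} is [sensor_factor()]; this form is exactly consistent with
#' the squared relative error of [precision_spacetime()]. Inversely
#' proportional to \code{T}. Calls with \code{T < 10/kd} are rejected;
#' \code{T < 50/kd} triggers a warning.
#'
#' @inheritParams mean_window_count
#' @return variance of the windowed molecule count.
#' @export
window_count_variance <- function(p, s, x) {
  stopifnot(inherits(p, "spacetime_params"), inherits(s, "sensor_spec"))
  if (any(x < s$a)) stop("domain error: require x >= a")
  .check_T_validity(s$T_avg, p$kd)
  u <- s$a / p$lam
  4 * p$jin * exp(-x / p$lam) * sinh(u)^2 * sensor_factor(u) /
    (s$T_avg * p$kd^2)
}

#' Squared relative positional error of the space-time measurement
#'
#' \deqn{\epsilon_T^2(x) = \frac{(\lambda/x)^2 e^{x/\lambda}}{j_{in} T}\,
#'   B(a/\lambda),}
#' with the sensor factor \eqn{B} of [sensor_factor()]. Halves when the
#' measurement collects twice the molecules (doubling either \code{jin} or
#' \code{T}); diverges as \eqn{x \to 0}.
#'
#' @inheritParams mean_window_count
#' @return dimensionless squared relative error.
#' @export
precision_spacetime <- function(p, s, x) {
  stopifnot(inherits(p, "spacetime_params"), inherits(s, "sensor_spec"))
  if (any(x <= 0)) stop("singular input: epsilon_T^2 diverges at x = 0")
  .check_T_validity(s$T_avg, p$kd)
  (p$lam / x)^2 * exp(x / p$lam) * sensor_factor(s$a / p$lam) /
    (p$jin * s$T_avg)
}

#' Cost of maintaining the profile during a measurement
#'
#' Total number of morphogen molecules produced during the averaging time,
#' times the per-molecule cost: \eqn{C_T = \alpha_o j_{in} T}. Independent of
#' position.
#'
#' @inheritParams mean_window_count
#' @param cost a [cost_params()] object.
#' @return cost in ATP-equivalents (units of \code{alpha_o}).
#' @export
cost_spacetime <- function(p, s, cost) {
  stopifnot(inherits(p, "spacetime_params"), inherits(s, "sensor_spec"),
            inherits(cost, "cost_params"))
  cost$alpha_o * p$jin * s$T_avg
}

#' Normalized space-time trade-off product
#'
#' \eqn{\pi_T(x_b;\lambda)/\alpha_o = (\lambda/x_b)^2 e^{x_b/\lambda}
#' B(a/\lambda)}: the production term \eqn{j_{in} T} cancels between cost and
#' precision, leaving a function of \eqn{x_b/\lambda} and \eqn{a/\lambda}
#' only.
#'
#' @param xb boundary position (> 0).
#' @param lam decay length (> 0).
#' @param a sensor half-width (> 0).
#' @return dimensionless product in units of \eqn{\alpha_o}.
#' @export
spacetime_product_normalized <- function(xb, lam, a) {
  if (any(xb <= 0) || any(lam <= 0) || any(a <= 0)) {
    stop("domain error: xb, lam, a must be positive")
  }
  (lam / xb)^2 * exp(xb / lam) * sensor_factor(a / lam)
}

#' Cost-precision trade-off at a boundary (space-time measurement)
#'
#' Product of [cost_spacetime()] and [precision_spacetime()] at the boundary
#' \code{xb}, with the minimizing decay length attached. The product is
#' independent of \eqn{j_{in} T}.
#'
#' @inheritParams cost_spacetime
#' @param xb target boundary position.
#' @return An object of class \code{"tradeoff_result"} (see
#'   [tradeoff_point()]); \code{product_normalized} is in units of
#'   \eqn{\alpha_o}.
#' @export
tradeoff_spacetime <- function(p, s, cost, xb) {
  C <- cost_spacetime(p, s, cost)
  eps2 <- precision_spacetime(p, s, xb)
  opt <- optimal_lambda_spacetime(xb, s$a)
  structure(
    list(xb = xb, lam = p$lam,
         cost = C, precision_sq = eps2, product = C * eps2,
         product_normalized = C * eps2 / cost$alpha_o,
         lambda_min = opt$lambda_min, product_min = opt$product_min,
         measurement_model = "spacetime"),
    class = "tradeoff_result"
  )
}

#' Optimal decay length for the space-time measurement
#'
#' Minimizes the normalized product \eqn{(\lambda/x_b)^2 e^{x_b/\lambda}
#' B(a/\lambda)} over \eqn{\lambda}. The minimizer always lies in
#' \eqn{[(x_b-a)/2,\; x_b/2]}; in the small-sensor limit the product reduces
#' to \eqn{(\lambda/x_b)^2 e^{x_b/\lambda}} whose optimum is exactly
#' \eqn{\lambda = x_b/2}.
#'
#' @param xb boundary position.
#' @param a sensor half-width, \eqn{0 < a < x_b}.
#' @return list with \code{lambda_min} and \code{product_min} (units of
#'   \eqn{\alpha_o}).
#' @export
optimal_lambda_spacetime <- function(xb, a) {
  if (a <= 0 || a >= xb) stop("domain error: require 0 < a < xb")
  out <- .minimize_log_bracket(function(l) spacetime_product_normalized(xb, l, a),
                               xb / 50, 10 * xb)
  tol <- 1e-6 * xb
  if (out$lambda_min < (xb - a) / 2 - tol || out$lambda_min > xb / 2 + tol) {
    stop("numerical error: optimizer left the analytic bracket [",
         (xb - a) / 2, ", ", xb / 2, "]; got ", out$lambda_min)
  }
  out
}

#' Minimum morphogen production for a target positional error
#'
#' Solves \eqn{\epsilon_T(x_b) = \epsilon_{target}} for the total production
#' \eqn{j_{in} T}, either at a user-supplied decay length or (default) at the
#' optimal \eqn{\lambda_{min}(x_b)}. Because \eqn{\epsilon_T^2 \propto
#' 1/(j_{in}T)}, halving the target error quadruples the required production.
#'
#' @param xb boundary position.
#' @param a sensor half-width.
#' @param epsilon_target target relative positional error (not squared).
#' @param lam optional decay length; \code{NULL} (default) uses
#'   \eqn{\lambda_{min}(x_b)}.
#' @return list with \code{jin_T} (real-valued solution), \code{molecules}
#'   (integer ceiling, since molecules are produced whole), and the
#'   \code{lam} at which it was evaluated.
#' @export
min_production_for_error <- function(xb, a, epsilon_target, lam = NULL) {
  if (epsilon_target <= 0) stop("invalid parameter: epsilon_target must be > 0")
  if (is.null(lam)) lam <- optimal_lambda_spacetime(xb, a)$lambda_min
  jin_T <- spacetime_product_normalized(xb, lam, a) / epsilon_target^2
  list(jin_T = jin_T, molecules = ceiling(jin_T), lam = lam)
}
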
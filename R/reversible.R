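# Reversible-kinetics extension of the lattice model: every elementary step
# (synthesis into cell 1, degradation in every cell, hops between neighbors)
# has a well-defined reverse rate. Because all reactions are of zeroth or
# first order, the mean-field dynamics are linear, the stationary copy-number
# law is product-form Poisson, and steady states, relaxation times and
# entropy production rates follow from small linear solves.
#
# Rate conventions (per cell counts n_i, i = 1..n):
#   synth_fwd : molecules/time created in cell 1        (zeroth order)
#   synth_rev : per-molecule removal rate at cell 1     (first order)
#   deg_fwd   : per-molecule degradation rate, all cells
#   deg_rev   : molecules/time created per cell         (zeroth order)
#   hop_fwd   : per-molecule rightward hop rate
#   hop_rev   : per-molecule leftward hop rate

#' Rates of the reversible lattice model
#'
#' @param n_cells number of cells (>= 3).
#' @param synth_fwd forward synthesis rate into cell 1 (molecules/time).
#' @param synth_rev reverse synthesis: per-molecule removal rate at cell 1.
#' @param deg_fwd per-molecule degradation rate (all cells).
#' @param deg_rev reverse degradation: creation rate per cell
#'   (molecules/time).
#' @param hop_fwd per-molecule rightward hop rate.
#' @param hop_rev per-molecule leftward hop rate.
#' @param lcell cell length.
#' @return object of class \code{"reversible_rates"}; the field
#'   \code{irreversible_limit} flags parameterizations in which some forward
#'   step has a zero-rate reverse partner (the classic SDD limit, where the
#'   entropy production diverges).
#' @export
reversible_rates <- function(n_cells, synth_fwd, synth_rev = 0,
                             deg_fwd, deg_rev = 0,
                             hop_fwd, hop_rev = hop_fwd, lcell = 1) {
  if (n_cells < 3) stop("invalid parameter: n_cells must be >= 3")
  vals <- c(synth_fwd = synth_fwd, synth_rev = synth_rev, deg_fwd = deg_fwd,
            deg_rev = deg_rev, hop_fwd = hop_fwd, hop_rev = hop_rev)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("invalid parameter: rates must be nonnegative and finite")
  }
  irr <- (synth_fwd > 0 && synth_rev == 0) || (deg_fwd > 0 && deg_rev == 0) ||
    (hop_fwd > 0) != (hop_rev > 0)
  structure(
    list(n_cells = as.integer(n_cells), synth_fwd = synth_fwd,
         synth_rev = synth_rev, deg_fwd = deg_fwd, deg_rev = deg_rev,
         hop_fwd = hop_fwd, hop_rev = hop_rev, lcell = lcell,
         irreversible_limit = irr),
    class = "reversible_rates"
  )
}

# Mean-field generator: d n / dt = A n + b
.reversible_system <- function(rates) {
  n <- rates$n_cells
  diag_main <- rep(-rates$deg_fwd, n)
  diag_main[1] <- diag_main[1] - rates$synth_rev
  diag_main[-n] <- diag_main[-n] - rates$hop_fwd
  diag_main[-1] <- diag_main[-1] - rates$hop_rev
  A <- Matrix::bandSparse(n, n, k = c(-1, 0, 1),
                          diagonals = list(rep(rates$hop_fwd, n - 1),
                                           diag_main,
                                           rep(rates$hop_rev, n - 1)))
  b <- rep(rates$deg_rev, n)
  b[1] <- b[1] + rates$synth_fwd
  list(A = A, b = b)
}

#' Stationary mean occupancy of the reversible lattice
#'
#' Solves the linear stationary balance of the mean-field master equation
#' (a tridiagonal system). With reverse rates set to zero this is exactly the
#' discretized irreversible SDD steady state.
#'
#' @param rates a [reversible_rates()] object.
#' @return numeric vector of mean molecule numbers per cell.
#' @export
steady_state_reversible <- function(rates) {
  stopifnot(inherits(rates, "reversible_rates"))
  if (rates$deg_fwd == 0 && rates$synth_rev == 0) {
    stop("no-steady-state error: no removal channel, occupancy grows without bound")
  }
  sys <- .reversible_system(rates)
  n_ss <- as.numeric(Matrix::solve(-sys$A, sys$b))
  if (any(!is.finite(n_ss)) || any(n_ss < 0)) {
    stop("no-steady-state error: stationary solve failed or is negative")
  }
  n_ss
}

#' Entropy production rate of the stationary lattice
#'
#' Sums \eqn{(J^+ - J^-)\ln(J^+/J^-)} over every synthesis, degradation and
#' hop transition, with stationary one-way fluxes evaluated at the mean
#' occupancies. Nonnegative always; zero exactly at detailed balance (for
#' symmetric hops this is the condition \code{synth_fwd*deg_fwd ==
#' synth_rev*deg_rev}). If any forward flux has a zero reverse partner the
#' entropy production is divergent (strictly irreversible limit); this is
#' reported as a structured result, not an error, since the classic SDD model
#' is exactly this limit.
#'
#' @param rates a [reversible_rates()] object.
#' @param steady_state stationary occupancies from
#'   [steady_state_reversible()] (computed if missing).
#' @return object of class \code{"entropy_rate"}: list with \code{rate}
#'   (k_B/time; \code{Inf} when divergent), \code{divergent},
#'   and a per-edge-class breakdown \code{by_class}.
#' @export
entropy_production_rate <- function(rates, steady_state = NULL) {
  stopifnot(inherits(rates, "reversible_rates"))
  if (is.null(steady_state)) steady_state <- steady_state_reversible(rates)
  n <- rates$n_cells
  ns <- steady_state

  edge_sum <- function(Jp, Jm) {
    # entropy of a set of edges; divergent if one-way flux has no partner
    active <- Jp > 0 | Jm > 0
    Jp <- Jp[active]; Jm <- Jm[active]
    if (length(Jp) == 0) return(list(s = 0, divergent = FALSE))
    if (any((Jp > 0) != (Jm > 0))) return(list(s = Inf, divergent = TRUE))
    list(s = sum((Jp - Jm) * log(Jp / Jm)), divergent = FALSE)
  }

  synth <- edge_sum(rates$synth_fwd, rates$synth_rev * ns[1])
  deg <- edge_sum(rates$deg_fwd * ns, rep(rates$deg_rev, n))
  hop <- edge_sum(rates$hop_fwd * ns[-n], rates$hop_rev * ns[-1])

  divergent <- synth$divergent || deg$divergent || hop$divergent
  total <- synth$s + deg$s + hop$s
  if (!divergent && total < 0) total <- max(total, 0)  # guard tiny negatives
  structure(
    list(rate = if (divergent) Inf else total, divergent = divergent,
         by_class = c(synthesis = synth$s, degradation = deg$s, hop = hop$s)),
    class = "entropy_rate"
  )
}

#' @export
print.entropy_rate <- function(x, ...) {
  if (x$divergent) {
    cat("Entropy production rate: divergent (strictly irreversible step present)\n")
  } else {
    cat(sprintf("Entropy production rate: %.6g k_B/time\n", x$rate))
  }
  cat("  by class:", paste(sprintf("%s = %.4g", names(x$by_class), x$by_class),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Relaxation time to the reversible steady state
#'
#' The accumulation-time analogue for the reversible model, starting from an
#' empty lattice: \eqn{\tau_{rev}(x) = \int_0^\infty R(x,t)\,dt} with
#' \eqn{R(x,t) = (n_{ss} - n(t))/n_{ss}}. For the linear dynamics
#' \eqn{\dot n = A n + b} the deficit integrates in closed form to
#' \eqn{(-A^{-1} n_{ss})_x / (n_{ss})_x} (a resolvent solve, no quadrature).
#' Reduces to the discrete accumulation time of the irreversible model when
#' the reverse rates vanish.
#'
#' @param rates a [reversible_rates()] object.
#' @param x position(s) in length units (cell centers at
#'   \code{(i-1/2)*lcell}).
#' @return relaxation time(s) at the cells containing \code{x}.
#' @export
relaxation_time_reversible <- function(rates, x) {
  stopifnot(inherits(rates, "reversible_rates"))
  sys <- .reversible_system(rates)
  ev_ok <- rates$deg_fwd > 0 || rates$synth_rev > 0
  if (!ev_ok) stop("no-steady-state error: dynamics have a non-decaying mode")
  n_ss <- steady_state_reversible(rates)
  integ <- as.numeric(Matrix::solve(-sys$A, n_ss))
  cell <- pmin(pmax(ceiling(x / rates$lcell), 1L), rates$n_cells)
  integ[cell] / n_ss[cell]
}

#' Squared relative positional error of the reversible profile
#'
#' Poisson copy-number statistics (exact for this zeroth/first-order network)
#' applied to the reversible stationary profile:
#' \eqn{\epsilon^2(x) = (\partial\ln n/\partial\ln x)^{-2} / n(x)}, with the
#' log-slope from central differences of the stationary occupancies on the
#' cell-center grid.
#'
#' @inheritParams relaxation_time_reversible
#' @return squared relative error(s).
#' @export
positional_error_reversible <- function(rates, x) {
  n_ss <- steady_state_reversible(rates)
  xc <- (seq_len(rates$n_cells) - 0.5) * rates$lcell
  logn <- log(n_ss)
  dlogn <- numeric(length(xc))
  dlogn[-c(1, length(xc))] <- (logn[-(1:2)] - logn[1:(length(xc) - 2)]) /
    (xc[-(1:2)] - xc[1:(length(xc) - 2)])
  dlogn[1] <- (logn[2] - logn[1]) / (xc[2] - xc[1])
  dlogn[length(xc)] <- (logn[length(xc)] - logn[length(xc) - 1]) /
    (xc[length(xc)] - xc[length(xc) - 1])
  cell <- pmin(pmax(ceiling(x / rates$lcell), 1L), rates$n_cells)
  slope_log <- dlogn[cell] * xc[cell]  # d ln n / d ln x
  if (any(slope_log == 0)) {
    stop("singular input: flat profile at x, positional error unbounded")
  }
  1 / (slope_log^2 * n_ss[cell])
}

#' Three-way cost-speed-precision trade-off of the reversible model
#'
#' Assembles \eqn{\pi_{o,rev}(x_b) = \dot S_{tot}\,\tau_{rev}(x_b)\,
#' \epsilon^2_{rev}(x_b)}: entropy production rate times relaxation time
#' times squared relative positional error. At detailed balance the entropy
#' rate is zero and the product degenerates to zero -- but so does the
#' gradient (the profile is flat away from the boundary condition), which is
#' flagged. In the strictly irreversible limit the product is divergent.
#'
#' @param rates a [reversible_rates()] object.
#' @param xb boundary position (length units).
#' @return object of class \code{"thermo_result"}: list with
#'   \code{entropy_rate}, \code{tau_rev}, \code{epsilon_rev_sq},
#'   \code{product}, \code{divergent}, \code{detailed_balance}.
#' @export
tradeoff_reversible <- function(rates, xb) {
  stopifnot(inherits(rates, "reversible_rates"))
  if (xb <= 0 || xb >= rates$n_cells * rates$lcell) {
    stop("domain error: xb must lie inside the lattice")
  }
  ns <- steady_state_reversible(rates)
  ent <- entropy_production_rate(rates, ns)
  tau <- relaxation_time_reversible(rates, xb)
  db <- !ent$divergent && ent$rate < 1e-10 * max(1, rates$synth_fwd)
  if (db) {
    # equilibrium: zero dissipation, but also no gradient -- the profile is
    # flat and carries no positional information. Degenerate zero product.
    return(structure(
      list(entropy_rate = ent$rate, tau_rev = tau,
           epsilon_rev_sq = NA_real_, product = 0,
           divergent = FALSE, detailed_balance = TRUE),
      class = "thermo_result"
    ))
  }
  eps2 <- positional_error_reversible(rates, xb)
  structure(
    list(entropy_rate = ent$rate, tau_rev = tau, epsilon_rev_sq = eps2,
         product = ent$rate * tau * eps2, divergent = ent$divergent,
         detailed_balance = db),
    class = "thermo_result"
  )
}

#' @export
print.thermo_result <- function(x, ...) {
  cat("Reversible-kinetics trade-off\n")
  cat(sprintf("  entropy rate = %.6g k_B/time%s\n", x$entropy_rate,
              if (x$divergent) " (divergent: irreversible limit)" else ""))
  cat(sprintf("  tau_rev = %.6g, epsilon^2 = %.6g\n", x$tau_rev, x$epsilon_rev_sq))
  cat(sprintf("  product = %.6g k_B%s\n", x$product,
              if (x$detailed_balance) " (detailed balance: degenerate, no gradient)" else ""))
  invisible(x)
}

#' Stochastic simulation of the reversible lattice
#'
#' Gillespie simulation of the reversible network with per-event entropy
#' bookkeeping: each event adds the log-ratio of the forward propensity
#' (pre-jump state) to the reverse propensity (post-jump state), whose
#' long-time average per unit time estimates the entropy production rate.
#'
#' @inheritParams simulate_ssa
#' @param rates a [reversible_rates()] object.
#' @param seed RNG seed.
#' @return a \code{"sim_result"} whose \code{entropy} field holds the
#'   accumulated entropy at every snapshot (Inf if an irreversible event
#'   fired).
#' @export
simulate_reversible_ssa <- function(rates, t_end, sample_dt = NULL,
                                    init = NULL, seed = 1L,
                                    max_events = 5e9) {
  stopifnot(inherits(rates, "reversible_rates"))
  if (is.null(sample_dt)) {
    sample_dt <- 0.1 / max(rates$deg_fwd, rates$synth_rev)
  }
  sample_times <- seq(sample_dt, t_end, by = sample_dt)
  if (is.null(init)) init <- integer(rates$n_cells)
  set.seed(seed)
  res <- ssa_lattice_cpp(rates$n_cells, rates$synth_fwd, rates$synth_rev,
                         rates$deg_fwd, rates$deg_rev,
                         rates$hop_fwd, rates$hop_rev,
                         as.numeric(sample_times), as.integer(init),
                         TRUE, -1, max_events)
  cfg <- list(n_cells = rates$n_cells, lcell = rates$lcell,
              kd = rates$deg_fwd, rates = rates)
  out <- .new_sim_result(sample_times, res$counts, cfg, seed,
                         "ssa_reversible", res$n_events, res$entropy)
  out
}
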
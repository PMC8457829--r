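# Particle-level stochastic simulator of the birth-hop-death lattice whose
# continuum limit is the SDD reaction-diffusion equation: injection into cell
# 1 at a constant rate, symmetric nearest-neighbor hopping, first-order
# degradation everywhere, reflecting walls at both ends. Serves as the
# synthetic-data generator and as the independent oracle for the analytic
# formulas (Poisson copy-number statistics, accumulation time, window-average
# moments).

#' Configuration of the stochastic lattice
#'
#' @param n_cells number of lattice cells (>= 3).
#' @param lcell cell length (sets the length unit).
#' @param hop_rate per-molecule hop rate to each neighbor, \eqn{D/l_{cell}^2}.
#' @param kd per-molecule depletion rate.
#' @param injection_rate molecules/time injected into cell 1
#'   (\eqn{v_{cell} j_{in} / l_{cell}} in continuum variables).
#' @param seed integer RNG seed recorded in every output.
#' @return object of class \code{"lattice_config"} with derived decay length
#'   \code{lambda = lcell * sqrt(hop_rate/kd)} and production scale
#'   \code{nm = injection_rate/kd}.
#' @export
lattice_config <- function(n_cells, lcell = 1, hop_rate, kd, injection_rate,
                           seed = 1L) {
  if (n_cells < 3) stop("invalid parameter: n_cells must be >= 3")
  vals <- c(lcell = lcell, hop_rate = hop_rate, kd = kd,
            injection_rate = injection_rate)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("invalid parameter: all rates must be positive and finite")
  }
  structure(
    list(n_cells = as.integer(n_cells), lcell = lcell, hop_rate = hop_rate,
         kd = kd, injection_rate = injection_rate, seed = as.integer(seed),
         lambda = lcell * sqrt(hop_rate / kd),
         nm = injection_rate / kd),
    class = "lattice_config"
  )
}

#' Standard simulation fixture
#'
#' The reference lattice used throughout the oracle tests: 50 cells, decay
#' length of 5 cell lengths (hop rate 25 kd), injection fixing the production
#' scale at 1000 molecules per depletion time, fixed seed.
#'
#' @param seed RNG seed (default 20210817).
#' @return a [lattice_config()].
#' @export
standard_lattice_fixture <- function(seed = 20210817L) {
  lattice_config(n_cells = 50L, lcell = 1, hop_rate = 25, kd = 1,
                 injection_rate = 1000, seed = seed)
}

#' Continuum-limit SDD parameters equivalent to a lattice configuration
#'
#' @param config a [lattice_config()].
#' @param vcell cell volume to attribute (default 1).
#' @return an [sdd_params()] with \code{D = hop_rate*lcell^2},
#'   \code{L = n_cells*lcell} and \code{jin} chosen so that \code{nm}
#'   matches \code{injection_rate/kd}.
#' @export
as_sdd_params <- function(config, vcell = 1) {
  stopifnot(inherits(config, "lattice_config"))
  sdd_params(L = config$n_cells * config$lcell, lcell = config$lcell,
             vcell = vcell, D = config$hop_rate * config$lcell^2,
             kd = config$kd,
             jin = config$injection_rate * config$lcell / vcell)
}

# cell centers of a lattice, in length units
.cell_centers <- function(config) {
  (seq_len(config$n_cells) - 0.5) * config$lcell
}

.new_sim_result <- function(times, counts, config, seed, method,
                            n_events = NA_real_, entropy = NULL) {
  structure(
    list(times = times, counts = counts, config = config, seed = seed,
         method = method, n_events = n_events, entropy = entropy),
    class = "sim_result"
  )
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("Stochastic lattice trajectory (%s), seed %d\n", x$method, x$seed))
  cat(sprintf("  %d cells, %d sample times in [%g, %g]\n",
              ncol(x$counts), nrow(x$counts), min(x$times), max(x$times)))
  cat(sprintf("  final total count: %d\n", sum(x$counts[nrow(x$counts), ])))
  invisible(x)
}

#' Exact stochastic simulation of the lattice
#'
#' Event-driven (Gillespie) simulation from an all-zero initial state (by
#' default). Reproducible bit-exactly for a fixed (config, seed); the seed
#' used is recorded in the result.
#'
#' @param config a [lattice_config()].
#' @param t_end final time.
#' @param sample_dt spacing of recorded snapshots (default \code{0.1/kd}).
#' @param sample_times explicit snapshot times (overrides \code{sample_dt}).
#' @param init integer vector of initial counts (default all zero).
#' @param seed RNG seed; defaults to \code{config$seed}.
#' @param track_entropy accumulate the trajectory's entropy production
#'   (log-ratio of forward to reverse propensities per event); for this
#'   irreversible lattice every event is irreversible, so the entropy is
#'   reported divergent -- the flag exists for the reversible extension.
#' @param max_events abort with a resource error beyond this many events
#'   (suggesting [simulate_tau_leap()]).
#' @return object of class \code{"sim_result"} with fields \code{times},
#'   \code{counts} (snapshots x cells matrix), \code{config}, \code{seed},
#'   \code{n_events}, and (if tracked) \code{entropy} at each snapshot.
#' @export
simulate_ssa <- function(config, t_end, sample_dt = NULL, sample_times = NULL,
                         init = NULL, seed = config$seed,
                         track_entropy = FALSE, integrate_from = NULL,
                         max_events = 5e9) {
  stopifnot(inherits(config, "lattice_config"))
  if (t_end <= 0) stop("invalid parameter: t_end must be > 0")
  if (is.null(sample_times)) {
    if (is.null(sample_dt)) sample_dt <- 0.1 / config$kd
    sample_times <- seq(sample_dt, t_end, by = sample_dt)
  }
  if (is.null(init)) init <- integer(config$n_cells)
  set.seed(seed)
  res <- ssa_lattice_cpp(config$n_cells, config$injection_rate, 0,
                         config$kd, 0, config$hop_rate, config$hop_rate,
                         as.numeric(sample_times), as.integer(init),
                         track_entropy,
                         if (is.null(integrate_from)) -1 else integrate_from,
                         max_events)
  out <- .new_sim_result(sample_times, res$counts, config, seed, "ssa",
                         res$n_events,
                         if (track_entropy) res$entropy else NULL)
  if (!is.null(integrate_from)) {
    out$occ_integral <- res$occ_integral
    out$occ_duration <- res$occ_duration
    out$integrate_from <- integrate_from
  }
  out
}

#' Ensemble of independent stochastic runs
#'
#' Runs [simulate_ssa()] with consecutive seeds \code{base_seed + 0, 1, ...}.
#'
#' @inheritParams simulate_ssa
#' @param n_runs number of independent trajectories.
#' @param base_seed seed of the first run (defaults to \code{config$seed}).
#' @return list of \code{"sim_result"} objects.
#' @export
simulate_ensemble <- function(config, n_runs, t_end, sample_dt = NULL,
                              sample_times = NULL, base_seed = config$seed) {
  lapply(seq_len(n_runs) - 1L, function(i) {
    simulate_ssa(config, t_end, sample_dt = sample_dt,
                 sample_times = sample_times, seed = base_seed + i)
  })
}

#' Approximate tau-leaping simulation of the lattice
#'
#' Poisson-update approximation with fixed leap \code{dt}: every channel fires
#' a Poisson number of times per leap at its current propensity. Steps that
#' would drive any count negative are retried with a halved leap (error after
#' 10 halvings). Converges to the SSA moments as \code{dt -> 0}.
#'
#' @inheritParams simulate_ssa
#' @param dt leap size.
#' @return object of class \code{"sim_result"} (method \code{"tau_leap"}).
#' @export
simulate_tau_leap <- function(config, t_end, dt, sample_dt = NULL,
                              init = NULL, seed = config$seed) {
  stopifnot(inherits(config, "lattice_config"))
  if (t_end <= 0 || dt <= 0) stop("invalid parameter: t_end and dt must be > 0")
  # stability guard: expected per-molecule events per leap must stay modest
  total_exit <- config$kd + 2 * config$hop_rate
  if (dt * total_exit > 1) {
    stop("invalid parameter: dt too large for tau-leaping (dt*(kd+2*hop) = ",
         dt * total_exit, " > 1)")
  }
  if (is.null(sample_dt)) sample_dt <- 0.1 / config$kd
  n <- config$n_cells
  state <- if (is.null(init)) integer(n) else as.integer(init)
  set.seed(seed)
  sample_times <- seq(sample_dt, t_end, by = sample_dt)
  counts <- matrix(0L, length(sample_times), n)
  t <- 0; k <- 1
  while (k <= length(sample_times)) {
    dt_try <- min(dt, sample_times[k] - t + 1e-12)
    halvings <- 0
    repeat {
      births <- integer(n)
      births[1] <- stats::rpois(1, config$injection_rate * dt_try)
      deaths <- stats::rpois(n, config$kd * state * dt_try)
      hop_r <- c(stats::rpois(n - 1, config$hop_rate * state[-n] * dt_try), 0L)
      hop_l <- c(0L, stats::rpois(n - 1, config$hop_rate * state[-1] * dt_try))
      new_state <- state + births - deaths - hop_r - hop_l +
        c(0L, hop_r[-n]) + c(hop_l[-1], 0L)
      if (all(new_state >= 0)) break
      halvings <- halvings + 1
      if (halvings > 10) {
        stop("numerical error: tau-leap step still produces negative counts ",
             "after 10 halvings; reduce dt")
      }
      dt_try <- dt_try / 2
    }
    state <- new_state
    t <- t + dt_try
    while (k <= length(sample_times) && sample_times[k] <= t + 1e-12) {
      counts[k, ] <- state
      k <- k + 1
    }
  }
  .new_sim_result(sample_times, counts, config, seed, "tau_leap")
}

#' Stationary moments of an ensemble of trajectories
#'
#' Pools decorrelated post-burn-in snapshots (spacing at least \code{2/kd};
#' more closely spaced snapshots are thinned) across runs and times, and
#' returns per-cell mean, variance, Fano factor and standard errors. Under
#' the model's zeroth/first-order kinetics the stationary copy numbers are
#' Poisson, so Fano factors should be near 1 in every cell.
#'
#' @param runs list of \code{"sim_result"} objects (or a single one).
#' @param t_burnin discard snapshots before this time; should exceed several
#'   accumulation times of the slowest cell.
#' @return object of class \code{"ensemble_stats"}: data frame with columns
#'   \code{cell}, \code{x}, \code{mean}, \code{var}, \code{fano},
#'   \code{se_mean}, \code{se_fano}, attribute \code{n_samples}.
#' @export
estimate_stationary_moments <- function(runs, t_burnin) {
  if (inherits(runs, "sim_result")) runs <- list(runs)
  if (length(runs) == 0) stop("estimation error: empty run list")
  config <- runs[[1]]$config
  spacing <- 2 / config$kd
  pooled <- do.call(rbind, lapply(runs, function(r) {
    if (max(r$times) < t_burnin) return(NULL)
    # thin to >= 2/kd spacing
    wanted <- seq(t_burnin, max(r$times), by = spacing)
    sel <- unique(vapply(wanted, function(s) which.min(abs(r$times - s)), 1L))
    r$counts[sel, , drop = FALSE]
  }))
  if (is.null(pooled) || nrow(pooled) < 2) {
    stop("estimation error: fewer than 2 post-burn-in snapshots")
  }
  m <- colMeans(pooled)
  v <- apply(pooled, 2, stats::var)
  nsamp <- nrow(pooled)
  fano <- v / m
  # large-sample SE of the Fano estimator for near-Poisson counts
  se_fano <- sqrt((2 + 1 / pmax(m, .Machine$double.eps)) / nsamp)
  out <- data.frame(cell = seq_len(config$n_cells),
                    x = .cell_centers(config),
                    mean = m, var = v, fano = fano,
                    se_mean = sqrt(v / nsamp), se_fano = se_fano)
  structure(out, n_samples = nsamp, config = config,
            class = c("ensemble_stats", "data.frame"))
}

# map a position (length units) to its cell index
.cell_of <- function(config, x) {
  i <- findInterval(x, seq(0, config$n_cells * config$lcell,
                           by = config$lcell),
                    rightmost.closed = TRUE)
  pmin(pmax(i, 1L), config$n_cells)
}

#' Empirical local accumulation time
#'
#' Estimates \eqn{\tau(x) = \int_0^{t_{end}} R(x,t)\,dt} with
#' \eqn{R(x,t) = (\rho_{ss} - \rho(x,t))/\rho_{ss}} from the ensemble-mean
#' trajectory of runs started from the empty state, by trapezoidal
#' quadrature. The stationary level is estimated from the final third of the
#' time window; a bootstrap over runs gives the standard error.
#'
#' The relaxation deficit is integrated over \eqn{[0, t_{integrate}]} only
#' (the tail beyond is exponentially small once \eqn{t_{integrate} \gg
#' \tau(x)}), while the stationary reference is estimated from the later
#' window \eqn{[t_{ss}, t_{end}]}; keeping the integration window short
#' limits the estimate's sensitivity to noise in the stationary reference,
#' which enters as \eqn{(t_{integrate} - \tau)} times the reference's
#' relative error.
#'
#' @param runs list of \code{"sim_result"} objects started from zero counts.
#' @param x position (length units).
#' @param t_integrate end of the deficit integration (default
#'   \code{0.5 * t_end}).
#' @param t_ss start of the stationary-reference window (default
#'   \code{0.6 * t_end}).
#' @param n_boot bootstrap replicates for the SE (default 200).
#' @return list with \code{tau}, \code{se}, \code{cell}.
#' @export
estimate_accumulation_time <- function(runs, x, t_integrate = NULL,
                                       t_ss = NULL, n_boot = 200) {
  if (inherits(runs, "sim_result")) runs <- list(runs)
  if (length(runs) == 0) stop("estimation error: empty run list")
  config <- runs[[1]]$config
  times <- runs[[1]]$times
  if (max(times) < 10 / config$kd) {
    stop("validity error: t_end must be at least 10/kd for the ",
         "accumulation-time integral to converge")
  }
  if (is.null(t_integrate)) t_integrate <- 0.5 * max(times)
  if (is.null(t_ss)) t_ss <- 0.6 * max(times)
  cell <- .cell_of(config, x)
  traj <- vapply(runs, function(r) as.numeric(r$counts[, cell]),
                 numeric(length(times)))
  in_int <- times <= t_integrate
  tau_of <- function(mean_traj) {
    ss <- mean(mean_traj[times >= t_ss])
    if (ss <= 0) return(NA_real_)
    R <- 1 - mean_traj[in_int] / ss
    tt <- times[in_int]
    # trapezoid, including the initial segment from t=0 where R=1
    sum(diff(c(0, tt)) * (c(1, R[-length(R)]) + R) / 2)
  }
  tau <- tau_of(rowMeans(traj))
  boots <- vapply(seq_len(n_boot), function(b) {
    tau_of(rowMeans(traj[, sample(ncol(traj), replace = TRUE), drop = FALSE]))
  }, numeric(1))
  list(tau = tau, se = stats::sd(boots, na.rm = TRUE), cell = cell)
}

#' One space-time-averaged count sample from a trajectory
#'
#' Time average over \eqn{[t_{start}, t_{start}+T]} of the total molecule
#' count in the window \eqn{(x-a, x+a)}, with end cells weighted by their
#' fractional overlap with the window (the window is a continuum interval,
#' not a set of whole cells).
#'
#' If the trajectory was produced with \code{integrate_from = t_start} and its
#' sampled interval ends at \code{t_start + T_avg}, the exact occupancy-time
#' integral accumulated during the simulation is used (no snapshot
#' discretization error); otherwise the average is taken over the recorded
#' snapshots in the interval, which is only accurate when the snapshot
#' spacing is well below the window's correlation time.
#'
#' @param run a \code{"sim_result"}.
#' @param x window center (length units).
#' @param a window half-width.
#' @param T_avg averaging duration.
#' @param t_start start of the averaging interval (after burn-in).
#' @return one scalar sample of the windowed count \eqn{m_i(x)}.
#' @export
window_average_counts <- function(run, x, a, T_avg, t_start) {
  stopifnot(inherits(run, "sim_result"))
  config <- run$config
  L <- config$n_cells * config$lcell
  if (x - a < 0 || x + a > L) stop("domain error: window outside lattice")
  edges <- seq(0, L, by = config$lcell)
  lo <- pmin(pmax(x - a, edges[-length(edges)]), edges[-1])
  hi <- pmin(pmax(x + a, edges[-length(edges)]), edges[-1])
  w <- pmax(hi - lo, 0) / config$lcell  # fractional overlap per cell
  tol <- 1e-9 / config$kd
  if (!is.null(run$occ_integral) &&
      abs(run$integrate_from - t_start) < tol &&
      abs(run$occ_duration - T_avg) < tol) {
    return(sum(run$occ_integral * w) / run$occ_duration)
  }
  keep <- run$times >= t_start & run$times <= t_start + T_avg
  if (!any(keep)) stop("domain error: no snapshots in the averaging interval")
  mean(run$counts[keep, , drop = FALSE] %*% w)
}

#' Deterministic method-of-lines integration of the SDD dynamics
#'
#' Integrates \eqn{\partial_t\rho = D\partial_x^2\rho - k_d\rho} with influx
#' at \eqn{x=0} and a reflecting wall at \eqn{x=L} on a fine grid of cell
#' centers, via \code{deSolve} with a banded Jacobian. The long-time limit
#' converges to the closed-form stationary profile as the grid is refined
#' (second-order in the grid spacing).
#'
#' @param params an [sdd_params()].
#' @param nx number of grid cells (default 1200).
#' @param t_end final time.
#' @param dt_out output time spacing (default \code{0.05/kd}).
#' @param init initial profile on the grid centers (default zero).
#' @param influx boundary influx; defaults to \code{params$jin}, may be set
#'   to 0 to follow the decay of an existing profile.
#' @return list with \code{x} (grid centers), \code{times}, \code{rho}
#'   (times x cells matrix), \code{params}.
#' @export
pde_oracle <- function(params, t_end, nx = 1200, dt_out = NULL,
                       init = NULL, influx = NULL) {
  stopifnot(inherits(params, "sdd_params"))
  if (is.null(dt_out)) dt_out <- 0.05 / params$kd
  h <- params$L / nx
  x <- (seq_len(nx) - 0.5) * h
  times <- seq(0, t_end, by = dt_out)
  D <- params$D; kd <- params$kd
  jin <- if (is.null(influx)) params$jin else influx
  if (is.null(init)) init <- numeric(nx)
  rhs <- function(t, rho, parms) {
    flux_in <- c(jin, D * (rho[-nx] - rho[-1]) / h)  # flux at left faces
    flux_out <- c(flux_in[-1], 0)                    # reflecting right wall
    list((flux_in - flux_out) / h - kd * rho)
  }
  sol <- deSolve::ode(y = init, times = times, func = rhs,
                      parms = NULL, method = "lsoda",
                      jactype = "bandint", bandup = 1, banddown = 1,
                      rtol = 1e-9, atol = 1e-12 * params$jin / sqrt(D * kd))
  if (attr(sol, "istate")[1] < 0 || any(!is.finite(sol[, -1]))) {
    stop("numerical error: PDE integration failed or blew up")
  }
  list(x = x, times = sol[, 1], rho = unname(sol[, -1, drop = FALSE]),
       params = params)
}

#' Accumulation time from the deterministic PDE trajectory
#'
#' Trapezoidal quadrature of the relaxation deficit
#' \eqn{R(x,t) = 1 - \rho(x,t)/\rho_{ss}(x)} along a [pde_oracle()] solution,
#' using the final profile as the stationary reference.
#'
#' @param pde result of [pde_oracle()]; integrate long enough that the final
#'   snapshot is stationary (e.g. \code{t_end >= 25/kd}).
#' @param x position at which to evaluate.
#' @return accumulation time estimate.
#' @export
pde_accumulation_time <- function(pde, x) {
  i <- which.min(abs(pde$x - x))
  traj <- pde$rho[, i]
  ss <- traj[length(traj)]
  if (ss <= 0) stop("numerical error: stationary level is zero at x")
  R <- 1 - traj / ss
  tt <- pde$times
  sum(diff(tt) * (R[-length(R)] + R[-1]) / 2)
}

#' Export a trajectory as a tidy table
#'
#' @param run a \code{"sim_result"}.
#' @return data frame with columns \code{time}, \code{cell}, \code{count}
#'   (long format, suitable for CSV export).
#' @export
sim_result_table <- function(run) {
  stopifnot(inherits(run, "sim_result"))
  data.frame(time = rep(run$times, times = ncol(run$counts)),
             cell = rep(seq_len(ncol(run$counts)), each = nrow(run$counts)),
             count = as.vector(run$counts))
}
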
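# Reversible-kinetics lattice: stationary solve, entropy production,
# relaxation times, and the three-way trade-off.

test_that("the reversible steady state reduces to the irreversible lattice", {
  base <- reversible_rates(40, synth_fwd = 100, synth_rev = 0,
                           deg_fwd = 1, deg_rev = 0, hop_fwd = 25)
  tiny <- reversible_rates(40, synth_fwd = 100, synth_rev = 1e-10,
                           deg_fwd = 1, deg_rev = 1e-10, hop_fwd = 25)
  expect_rel(steady_state_reversible(tiny), steady_state_reversible(base),
             1e-8)
  expect_false(tiny$irreversible_limit)
  expect_true(base$irreversible_limit)
  expect_error(steady_state_reversible(
    reversible_rates(5, synth_fwd = 1, deg_fwd = 0, hop_fwd = 1)),
    "no-steady-state")
})

test_that("irreversible limit recovers the continuum closed forms on a fine lattice", {
  # L = 5 lambda resolved by 2400 cells: lambda = 480 lcell
  n <- 2400
  hop <- 480^2
  rr <- reversible_rates(n, synth_fwd = 1000, synth_rev = 0,
                         deg_fwd = 1, deg_rev = 0, hop_fwd = hop)
  ns <- steady_state_reversible(rr)
  p <- sdd_params(L = n, lcell = 1, vcell = 1, D = hop, kd = 1, jin = 1000)
  xc <- (seq_len(n) - 0.5)
  expect_rel(ns, steady_state_profile(p, xc)$rho, 1e-6)
  for (x in c(240.5, 1200.5, 2100.5)) {
    expect_equal(relaxation_time_reversible(rr, x),
                 accumulation_time(p, x), tolerance = 1e-6)
  }
})

test_that("detailed balance gives a flat equilibrium profile and zero entropy", {
  # condition (symmetric hops): synth_fwd * deg_fwd == synth_rev * deg_rev
  db <- reversible_rates(12, synth_fwd = 6, synth_rev = 2,
                         deg_fwd = 1, deg_rev = 3, hop_fwd = 4)
  ns <- steady_state_reversible(db)
  expect_rel(ns, rep(3, 12), 1e-10)  # n_i = deg_rev/deg_fwd everywhere
  ep <- entropy_production_rate(db, ns)
  expect_false(ep$divergent)
  expect_lt(abs(ep$rate), 1e-10)
})

test_that("entropy production is the flux-weighted log-ratio over edges", {
  # a single active synthesis edge with J+ = 2, J- = 1: (2-1) ln 2
  rates <- reversible_rates(3, synth_fwd = 2, synth_rev = 1,
                            deg_fwd = 0, deg_rev = 0, hop_fwd = 0,
                            hop_rev = 0)
  ep <- entropy_production_rate(rates, steady_state = c(1, 1, 1))
  expect_equal(ep$rate, log(2), tolerance = 1e-12)
  # strictly irreversible inputs are reported divergent, not an error
  irr <- reversible_rates(5, synth_fwd = 10, deg_fwd = 1, hop_fwd = 2)
  ep2 <- entropy_production_rate(irr)
  expect_true(ep2$divergent)
  expect_identical(ep2$rate, Inf)
})

test_that("entropy production is nonnegative and zero only at detailed balance", {
  set.seed(99)
  for (i in 1:20) {
    r <- reversible_rates(8, synth_fwd = runif(1, 1, 50),
                          synth_rev = runif(1, 0.1, 2),
                          deg_fwd = runif(1, 0.5, 2),
                          deg_rev = runif(1, 0.1, 2),
                          hop_fwd = runif(1, 1, 10))
    ep <- entropy_production_rate(r)
    db <- abs(r$synth_fwd * r$deg_fwd - r$synth_rev * r$deg_rev) <
      1e-12 * r$synth_fwd * r$deg_fwd
    expect_gte(ep$rate, 0)
    if (!db) expect_gt(ep$rate, 0)
  }
})

test_that("SSA entropy production matches the stationary formula", {
  rr <- reversible_rates(5, synth_fwd = 50, synth_rev = 0.5,
                         deg_fwd = 1, deg_rev = 0.2, hop_fwd = 4)
  ep <- entropy_production_rate(rr)
  run <- simulate_reversible_ssa(rr, t_end = 2000, sample_dt = 1, seed = 7)
  keep <- run$times >= 50
  ent <- run$entropy[keep]
  tt <- run$times[keep]
  sel <- seq(1, length(ent), by = 150)
  rates_hat <- diff(ent[sel]) / diff(tt[sel])
  se <- stats::sd(rates_hat) / sqrt(length(rates_hat))
  expect_lt(abs(mean(rates_hat) - ep$rate), 3 * se + 0.01 * ep$rate)
})

test_that("reversible copy numbers stay Poisson (zeroth/first-order network)", {
  rr <- reversible_rates(5, synth_fwd = 50, synth_rev = 0.5,
                         deg_fwd = 1, deg_rev = 0.2, hop_fwd = 4)
  run <- simulate_reversible_ssa(rr, t_end = 4000, sample_dt = 2, seed = 21)
  counts <- run$counts[run$times >= 40, ]
  fano <- apply(counts, 2, stats::var) / colMeans(counts)
  expect_true(all(fano > 0.9 & fano < 1.1))
  # and the SSA means agree with the linear stationary solve
  ns <- steady_state_reversible(rr)
  se <- sqrt(colMeans(counts) / nrow(counts))
  expect_true(all(abs(colMeans(counts) - ns) < 3 * se + 0.02 * ns))
})

test_that("relaxation time matches time integration and varies continuously", {
  rr <- reversible_rates(20, synth_fwd = 30, synth_rev = 0.4,
                         deg_fwd = 1, deg_rev = 0.5, hop_fwd = 6)
  tau <- relaxation_time_reversible(rr, 5.5)
  # independent path: integrate the linear ODE and quadrature the deficit
  sys <- morphotradeoff:::.reversible_system(rr)
  rhs <- function(t, y, p) list(as.numeric(sys$A %*% y + sys$b))
  times <- seq(0, 60, by = 0.0025)
  sol <- deSolve::ode(numeric(20), times, rhs, NULL,
                      rtol = 1e-11, atol = 1e-11)
  traj <- sol[, 7]  # cell 6 (x = 5.5)
  ss <- steady_state_reversible(rr)[6]
  R <- 1 - traj / ss
  tau_quad <- sum(diff(times) * (R[-length(R)] + R[-1]) / 2)
  expect_equal(tau, tau_quad, tolerance = 1e-6)
  # continuity in the reverse-synthesis rate
  taus <- vapply(seq(0.1, 0.5, by = 0.05), function(sr) {
    r <- reversible_rates(20, synth_fwd = 30, synth_rev = sr,
                          deg_fwd = 1, deg_rev = 0.5, hop_fwd = 6)
    relaxation_time_reversible(r, 5.5)
  }, numeric(1))
  expect_true(all(abs(diff(taus)) < 0.05))
})

test_that("the three-way trade-off behaves across the reversibility spectrum", {
  # detailed balance: zero product, flagged degenerate
  db <- reversible_rates(12, synth_fwd = 6, synth_rev = 2,
                         deg_fwd = 1, deg_rev = 3, hop_fwd = 4)
  # detailed-balance profile is flat: zero dissipation, zero product,
  # flagged degenerate (no gradient, no positional information)
  res_db <- tradeoff_reversible(db, 5.5)
  expect_identical(res_db$product, 0)
  expect_true(res_db$detailed_balance)

  # near-irreversible: entropy * relaxation time tracks the formation cost
  rr <- reversible_rates(50, synth_fwd = 1000, synth_rev = 1e-6,
                         deg_fwd = 1, deg_rev = 1e-6, hop_fwd = 25)
  ns <- steady_state_reversible(rr)
  ep <- entropy_production_rate(rr, ns)
  p <- as_sdd_params(lattice_config(50, 1, 25, 1, 1000))
  xs <- c(10.5, 15.5, 20.5, 25.5)
  ratio <- vapply(xs, function(x) {
    ep$rate * relaxation_time_reversible(rr, x) /
      (p$nm * accumulation_factor(x, p$lambda, p$L))
  }, numeric(1))
  expect_rel(ratio, ratio[1], 0.05)

  # the lambda-minimized product increases with the boundary position
  pmin_of_xb <- vapply(c(10, 15, 20, 25), function(xb) {
    prods <- vapply(seq(2, 12, by = 0.25), function(lam) {
      r <- reversible_rates(50, synth_fwd = 1000, synth_rev = 0.01,
                            deg_fwd = 1, deg_rev = 0.01, hop_fwd = lam^2)
      tradeoff_reversible(r, xb + 0.5)$product
    }, numeric(1))
    min(prods)
  }, numeric(1))
  expect_true(all(diff(pmin_of_xb) > 0))
})
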
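# Stochastic lattice simulator: determinism, small-fixture statistics,
# windowed averages, tau-leaping, and the deterministic PDE oracle.
# Long-run statistical validations of the analytic formulas live in
# test-acceptance.R.

test_that("equal seeds give bit-identical trajectories", {
  cfg <- lattice_config(n_cells = 10, hop_rate = 5, kd = 1,
                        injection_rate = 50, seed = 42)
  r1 <- simulate_ssa(cfg, 5, sample_dt = 0.5)
  r2 <- simulate_ssa(cfg, 5, sample_dt = 0.5)
  expect_identical(r1$counts, r2$counts)
  r3 <- simulate_ssa(cfg, 5, sample_dt = 0.5, seed = 43)
  expect_false(identical(r1$counts, r3$counts))
  # tau-leaping is deterministic under a fixed seed too
  t1 <- simulate_tau_leap(cfg, 5, dt = 0.01, sample_dt = 0.5)
  t2 <- simulate_tau_leap(cfg, 5, dt = 0.01, sample_dt = 0.5)
  expect_identical(t1$counts, t2$counts)
})

test_that("birth-death limit: cell counts are Poisson with mean inj/kd", {
  # strong depletion, negligible hopping: cell 1 is a plain birth-death unit
  cfg <- lattice_config(n_cells = 3, hop_rate = 1e-9, kd = 2,
                        injection_rate = 100, seed = 7)
  run <- simulate_ssa(cfg, 1000 + 5, sample_dt = 0.5)
  st <- estimate_stationary_moments(run, t_burnin = 5)
  expect_gt(attr(st, "n_samples"), 400)
  expect_equal(st$mean[1], cfg$injection_rate / cfg$kd, tolerance = 0.05)
  expect_gt(st$fano[1], 0.9)
  expect_lt(st$fano[1], 1.1)
})

test_that("moment estimation rejects empty or too-short inputs", {
  expect_error(estimate_stationary_moments(list(), 1), "empty")
  cfg <- lattice_config(n_cells = 3, hop_rate = 1, kd = 1,
                        injection_rate = 10, seed = 1)
  run <- simulate_ssa(cfg, 2, sample_dt = 0.5)
  expect_error(estimate_stationary_moments(run, t_burnin = 10), "snapshots")
  expect_error(estimate_accumulation_time(run, 1.5), "validity")
})

test_that("tau-leap converges to the SSA stationary mean and guards its step", {
  cfg <- lattice_config(n_cells = 10, hop_rate = 4, kd = 1,
                        injection_rate = 200, seed = 11)
  ssa <- simulate_ssa(cfg, 60, sample_dt = 0.5)
  tau <- simulate_tau_leap(cfg, 60, dt = 0.002, sample_dt = 0.5, seed = 12)
  ms <- estimate_stationary_moments(ssa, 10)$mean
  mt <- estimate_stationary_moments(tau, 10)$mean
  # total stationary content within 2% (plus shared sampling slack)
  expect_equal(sum(mt), sum(ms), tolerance = 0.05)
  expect_error(simulate_tau_leap(cfg, 1, dt = 1), "dt too large")
  # vanishing rates: no events, state unchanged from the initial condition
  cfg0 <- lattice_config(n_cells = 3, hop_rate = 1e-12, kd = 1e-12,
                         injection_rate = 1e-12, seed = 5)
  r0 <- simulate_tau_leap(cfg0, 1, dt = 0.01, sample_dt = 0.5,
                          init = c(3L, 2L, 1L))
  expect_true(all(r0$counts[nrow(r0$counts), ] == c(3, 2, 1)))
})

test_that("windowed counts use fractional cell overlap and exact time averages", {
  cfg <- lattice_config(n_cells = 6, hop_rate = 2, kd = 1,
                        injection_rate = 20, seed = 3)
  run <- simulate_ssa(cfg, 10, sample_dt = 0.05)
  # window covering exactly cell 3, vanishing T: that cell's snapshot count
  i <- which.min(abs(run$times - 5))
  m <- window_average_counts(run, x = 2.5, a = 0.5, T_avg = 1e-6,
                             t_start = run$times[i])
  expect_equal(m, run$counts[i, 3])
  # fractional weighting: window (2, 3.5) = all of cell 3 + half of cell 4
  m2 <- window_average_counts(run, x = 2.75, a = 0.75, T_avg = 1e-6,
                              t_start = run$times[i])
  expect_equal(m2, run$counts[i, 3] + 0.5 * run$counts[i, 4])
  expect_error(window_average_counts(run, x = 0.2, a = 0.5, T_avg = 1,
                                     t_start = 5), "domain")
  # exact occupancy-time integral equals the fine-snapshot average
  run_i <- simulate_ssa(cfg, 10, sample_dt = 0.001, seed = 9,
                        integrate_from = 5)
  exact <- window_average_counts(run_i, 2.5, 0.5, T_avg = 5, t_start = 5)
  snap <- mean(run_i$counts[run_i$times >= 5, 3])
  expect_equal(exact, snap, tolerance = 0.02)
})

test_that("the PDE oracle is stable, conservative, and decays without influx", {
  p <- sdd_params(L = 5, lcell = 1, vcell = 1, D = 1, kd = 1, jin = 1)
  pde <- pde_oracle(p, t_end = 10, nx = 400, dt_out = 1)
  expect_true(all(is.finite(pde$rho)))
  # switching off the influx: total mass decays exactly at rate kd
  ss <- steady_state_profile(p, pde$x)$rho
  dec <- pde_oracle(p, t_end = 6, nx = 400, dt_out = 1, init = ss, influx = 0)
  mass <- rowSums(dec$rho)
  expect_rel(mass[length(mass)], mass[1] * exp(-p$kd * 6), 1e-6)
})

test_that("trajectories export to a tidy long table", {
  cfg <- lattice_config(n_cells = 4, hop_rate = 1, kd = 1,
                        injection_rate = 5, seed = 2)
  run <- simulate_ssa(cfg, 2, sample_dt = 1)
  tab <- sim_result_table(run)
  expect_equal(nrow(tab), 2 * 4)
  expect_named(tab, c("time", "cell", "count"))
  expect_equal(tab$count[tab$time == 2 & tab$cell == 1],
               run$counts[2, 1])
})
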
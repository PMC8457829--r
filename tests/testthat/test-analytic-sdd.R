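# Closed-form SDD quantities: steady state, accumulation time, cost,
# positional error, trade-off product and its lambda-optimum.

test_that("steady-state profile has the correct amplitude, decay and limits", {
  p <- sdd_large()  # L = 50 lambda
  prof <- steady_state_profile(p, c(0, 1, 2))
  amp <- p$jin / sqrt(p$D * p$kd)
  # source-end amplitude: cosh(L/lam)/sinh(L/lam) -> 1
  expect_equal(prof$rho[1], amp, tolerance = 1e-12)
  # pure exponential decay in the long-system limit
  expect_equal(prof$rho[2] / prof$rho[1], exp(-1), tolerance = 1e-10)
  # strictly decreasing
  x <- seq(0, p$L, length.out = 200)
  expect_true(all(diff(steady_state_profile(p, x)$rho) < 0))
  # no overflow at extreme L/lambda
  px <- sdd_params(L = 5000, lcell = 1, vcell = 1, D = 1, kd = 1, jin = 1)
  expect_true(all(is.finite(steady_state_profile(px, c(0, 1, 2500, 5000))$rho)))

  expect_error(steady_state_profile(p, c(-1, 2)), "domain")
  expect_error(steady_state_profile(p, p$L + 1), "domain")
  expect_error(sdd_params(L = 1, D = Inf, kd = 1, jin = 1), "finite")
})

test_that("steady state matches the long-time limit of the dynamics (PDE oracle)", {
  p <- sdd_params(L = 5, lcell = 1, vcell = 1, D = 1, kd = 1, jin = 1)
  pde <- pde_oracle(p, t_end = 30, nx = 2400, dt_out = 0.5)
  final <- pde$rho[nrow(pde$rho), ]
  an <- steady_state_profile(p, pde$x)$rho
  expect_rel(final, an, 1e-6)
  # zero-flux condition at x = L: vanishing slope of the analytic profile
  eps <- 1e-7
  slope_L <- diff(steady_state_profile(p, c(p$L - eps, p$L))$rho) / eps
  expect_lt(abs(slope_L) / an[length(an)], 1e-5)
})

test_that("flux balance holds at steady state: kd * integral(rho) = jin", {
  for (lam_rel in c(0.1, 0.3, 0.9)) {
    p <- sdd_rel(lam_rel)
    f <- function(x) steady_state_profile(p, x)$rho
    tot <- stats::integrate(f, 0, p$L, rel.tol = 1e-10)$value
    expect_equal(p$kd * tot, p$jin, tolerance = 1e-8)
  }
})

test_that("accumulation time matches its closed form and limits", {
  p <- sdd_large()
  # source of a long system equilibrates in half a depletion time
  expect_equal(accumulation_time(p, 0), 1 / (2 * p$kd), tolerance = 1e-9)
  # deep in the long-system regime: tau ~ (1 + x/lambda)/(2 kd)
  expect_equal(accumulation_time(p, 10 * p$lambda), (1 + 10) / 2,
               tolerance = 1e-6)
  # monotone nondecreasing in x
  x <- seq(0, p$L, length.out = 100)
  expect_true(all(diff(accumulation_time(p, x)) >= 0))
  expect_error(accumulation_time(p, -0.1), "domain")
})

test_that("accumulation time equals the integrated relaxation deficit", {
  p <- sdd_params(L = 5, lcell = 1, vcell = 1, D = 1, kd = 1, jin = 1)
  pde <- pde_oracle(p, t_end = 30, nx = 2400, dt_out = 0.01)
  for (x_target in c(0.5, 1.5, 2.5, 3.5, 4.5)) {
    xg <- pde$x[which.min(abs(pde$x - x_target))]
    expect_equal(pde_accumulation_time(pde, xg), accumulation_time(p, xg),
                 tolerance = 1e-4)
  }
})

test_that("formation cost is linear in production and tracks f(x; lambda)", {
  p1 <- sdd_rel(0.2, jin = 1)
  p2 <- sdd_rel(0.2, jin = 2)
  co <- cost_params(1)
  expect_equal(cost_point(p2, co, 0.3), 2 * cost_point(p1, co, 0.3))
  # f at the Bicoid working point
  expect_equal(accumulation_factor(0.4, 0.2, 1), 1.507645, tolerance = 1e-6)
  # long-system source limit: alpha_o * nm / 2
  pl <- sdd_large(jin = 3)
  expect_equal(cost_point(pl, co, 0), pl$nm / 2, tolerance = 1e-9)
})

test_that("positional error scales inversely with production and as written", {
  p1 <- sdd_rel(0.2, jin = 2)
  p2 <- sdd_rel(0.2, jin = 1)
  expect_equal(positional_error_point(p2, 0.3),
               2 * positional_error_point(p1, 0.3), tolerance = 1e-12)
  # large-L functional form: eps^2 * x^2 * exp(-x/lambda) constant in x
  pl <- sdd_large()
  x <- seq(2, 20, by = 2)
  val <- positional_error_point(pl, x) * x^2 * exp(-x / pl$lambda)
  expect_rel(val, val[1], 1e-9)
  expect_error(positional_error_point(pl, 0), "singular")
  expect_error(positional_error_point(pl, pl$L), "singular")
})

test_that("positional variance converts concentration noise through the slope", {
  expect_equal(positional_variance(-2, 4), 1)
  expect_equal(positional_variance(3, 0), 0)
  expect_error(positional_variance(0, 1), "singular")
  # exponential profile with Poisson noise: sigma_x^2 = lambda^2/(vcell rho);
  # normalized by x^2 this is the long-system positional error formula
  p <- sdd_large()
  x <- 7
  rho <- steady_state_profile(p, x)$rho
  slope <- -rho / p$lambda
  sig_x2 <- positional_variance(slope, rho / p$vcell)
  expect_equal(sig_x2 / x^2, positional_error_point(p, x), tolerance = 1e-3)
})

test_that("trade-off product is production-independent and matches Bcd numbers", {
  co <- cost_params(1)
  r1 <- tradeoff_point(sdd_rel(0.2, jin = 1), co, 0.4)
  r2 <- tradeoff_point(sdd_rel(0.2, jin = 1e6), co, 0.4)
  expect_equal(r1$product, r2$product, tolerance = 1e-12)
  # vcell rescaling also cancels
  r3 <- tradeoff_point(sdd_rel(0.2, jin = 1, vcell = 50), co, 0.4)
  expect_equal(r1$product, r3$product, tolerance = 1e-12)
  expect_equal(r1$product, r1$cost * r1$precision_sq, tolerance = 1e-12)
  expect_gte(r1$product, r1$product_min)
  # normalized product at the Bicoid configuration
  expect_equal(r1$product_normalized, 0.5611373, tolerance = 1e-6)
  # implied cost: pi / eps^2 with the measured precision, in alpha_o units
  cost_bcd <- r1$product_normalized * 50 / 7e-4
  expect_equal(cost_bcd, 4e4, tolerance = 0.15)
})

test_that("optimal decay length follows the 0.43 law and is a true minimum", {
  # closed form from the stationarity condition s^2 - s - 3 = 0
  expect_equal(optimal_lambda_ratio_closed_form(), 2 / (1 + sqrt(13)))
  opt <- optimal_lambda_point(1, 50)
  expect_equal(opt$lambda_min, optimal_lambda_ratio_closed_form(),
               tolerance = 1e-6)
  # local optimality
  for (s in c(1 - 1e-3, 1 + 1e-3)) {
    expect_gte(point_product_normalized(1, opt$lambda_min * s, 50),
               opt$product_min)
  }
  # linear law: slope of lambda_min vs xb in the large-system regime
  xb <- seq(0.5, 5, length.out = 10)
  lm_ <- vapply(xb, function(x) optimal_lambda_point(x, 50 * x)$lambda_min,
                numeric(1))
  slope <- stats::coef(stats::lm(lm_ ~ xb))[["xb"]]
  expect_equal(slope, 0.43, tolerance = 0.005 / 0.43)
  expect_error(optimal_lambda_point(2, 1), "domain")
})

test_that("lambda_min and the minimized product increase with the boundary position", {
  L <- 1
  xb <- seq(0.05, 0.5, length.out = 21)
  opt <- lapply(xb, optimal_lambda_point, L = L)
  lmin <- vapply(opt, `[[`, numeric(1), "lambda_min")
  pmin_ <- vapply(opt, `[[`, numeric(1), "product_min")
  expect_true(all(diff(lmin) > 0))
  expect_true(all(diff(pmin_) > 0))
})

test_that("finite-L formulas converge to the exponential limit for large L", {
  lam <- 1
  p60 <- sdd_params(L = 60, lcell = 1, vcell = 1, D = 1, kd = 1, jin = 1)
  x <- c(2, 5, 10)
  amp <- p60$jin / sqrt(p60$D * p60$kd)
  expect_rel(steady_state_profile(p60, x)$rho, amp * exp(-x / lam), 1e-6)
  expect_rel(accumulation_time(p60, x), (1 + x / lam) / 2, 1e-6)
  eps_lim <- (lam^3 / x^2) * exp(x / lam) / p60$nm
  expect_rel(positional_error_point(p60, x), eps_lim, 1e-6)
})

test_that("threshold fraction puts the optimal boundary at a tenth of the amplitude", {
  expect_equal(threshold_fraction(1, 1), exp(-1))
  expect_equal(threshold_fraction(1, 0.5), exp(-2))
  expect_equal(threshold_fraction(1, optimal_lambda_ratio_closed_form()),
               0.100, tolerance = 0.001)
  expect_error(threshold_fraction(1, 0), "positive")
})
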
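# Relaxation module: pooled noise, decay fits, Monte-Carlo errors,
# tilted-field correction, hetNOE, flexibility bands.

test_that("pooled noise follows the duplicate-pair formula", {
  same <- cbind(c(10, 20, 30), c(10, 20, 30))
  expect_equal(estimate_pooled_noise(same)$sigma, 0)
  pairs <- cbind(c(5, 9), c(7, 13))        # differences 2 and 4, k = 2
  est <- estimate_pooled_noise(pairs)
  expect_equal(est$k, 2L)
  expect_equal(est$sigma, sqrt(5), tolerance = 1e-12)
  expect_error(estimate_pooled_noise(matrix(numeric(), ncol = 2)),
               class = "foxdyn_insufficient_duplicates")
})

test_that("pooled noise recovers a known per-measurement sigma", {
  pairs <- foxdyn:::with_seed(202, {
    s <- rnorm(1e4 * 2)                    # per-measurement sigma = 1
    cbind(100 + s[1:1e4], 100 + s[1e4 + 1:1e4])
  })
  expect_equal(estimate_pooled_noise(pairs)$sigma, 1, tolerance = 0.02)
})

test_that("noiseless decays are recovered to machine precision", {
  tt <- as.numeric(default_r1_delays())
  fit <- fit_decay(list(t = tt, I = 100 * exp(-1.5 * tt)))
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)[["rate"]]), 1.5, tolerance = 1e-9)
  expect_equal(unname(coef(fit)[["I0"]]), 100, tolerance = 1e-9)
  expect_lt(max(abs(residuals(fit))), 1e-7)
  # constant intensities: a zero-rate decay
  flat <- fit_decay(list(t = tt, I = rep(42, length(tt))))
  expect_equal(unname(coef(flat)[["rate"]]), 0, tolerance = 1e-6)
  expect_equal(unname(predict(flat, 5)), 42, tolerance = 1e-4)
})

test_that("decay_fit methods behave like a fitted-model object", {
  tab <- gen_decay_dataset(2, i0 = 80, sigma = 1, seed = 5)
  noise <- estimate_pooled_noise(tab)
  fit <- fit_decay(tab, noise, residue = 1)
  expect_s3_class(fit, "decay_fit")
  expect_named(coef(fit), c("I0", "rate"))
  expect_equal(predict(fit), fit$fitted.values)
  expect_equal(fit$I - predict(fit), residuals(fit))
  expect_output(print(fit), "rate")
  expect_output(print(summary(fit)), "distinct delays")
  sims <- simulate(fit, nsim = 4, seed = 9)
  expect_equal(dim(sims), c(4L, length(fit$t)))
  expect_identical(sims, simulate(fit, nsim = 4, seed = 9))
})

test_that("rate estimation is nearly unbiased over many synthetic residues", {
  n <- 150
  rates <- foxdyn:::with_seed(77, runif(n, 0.5, 3))
  tab <- gen_decay_dataset(rates, i0 = 100, sigma = 2, seed = 78)  # SNR 50
  res <- fit_relaxation(tab, config = run_config(seed = 79), mc = FALSE)
  rel <- (res$rate - rates) / rates
  expect_lt(abs(median(rel)), 0.01)
})

test_that("the batch fitter agrees with an independent LM implementation", {
  tab <- gen_decay_dataset(c(0.7, 1.9, 2.8), i0 = 100, sigma = 2, seed = 21)
  for (r in 1:3) {
    fit <- fit_decay(tab, residue = r)
    ser <- decay_series(tab, r)
    ref <- minpack.lm::nlsLM(I ~ A * exp(-k * t),
                             data = data.frame(t = ser$t, I = ser$I),
                             start = list(A = max(ser$I), k = 1))
    expect_equal(unname(coef(fit)[["rate"]]), unname(coef(ref)[["k"]]),
                 tolerance = 1e-6)
    expect_equal(unname(coef(fit)[["I0"]]), unname(coef(ref)[["A"]]),
                 tolerance = 1e-6)
  }
})

test_that("Monte-Carlo rate errors are deterministic and track the noise", {
  tab <- gen_decay_dataset(1.5, i0 = 100, sigma = 2, seed = 31)
  noise <- estimate_pooled_noise(tab)
  fit <- fit_decay(tab, noise, residue = 1)
  a <- monte_carlo_rate_error(fit, noise, n_mc = 400, seed = 13)
  b <- monte_carlo_rate_error(fit, noise, n_mc = 400, seed = 13)
  expect_identical(a$sigma_rate, b$sigma_rate)
  expect_equal(a$ci95, 2 * a$sigma_rate)
  # zero-noise limit
  z <- monte_carlo_rate_error(fit, structure(list(sigma = 0, k = 1),
                                            class = "noise_estimate"),
                              n_mc = 50, seed = 13)
  expect_equal(z$sigma_rate, 0)
  # histogram-fit sigma close to the plain sample SD on a well-behaved series
  full <- monte_carlo_rate_error(fit, noise, n_mc = 1000, seed = 17)
  expect_equal(full$sigma_rate, sd(full$rates), tolerance = 0.1)
})

test_that("Monte-Carlo sigma matches the linearised covariance", {
  tab <- gen_decay_dataset(c(0.9, 2.1), i0 = 100, sigma = 2, seed = 41)
  noise <- estimate_pooled_noise(tab)
  for (r in 1:2) {
    fit <- fit_decay(tab, noise, residue = r)
    mc <- monte_carlo_rate_error(fit, noise, n_mc = 1000, width_factor = 2,
                                 seed = 50 + r)
    analytic <- linearized_rate_sigma(fit, 2 * noise$sigma)
    expect_equal(mc$sigma_rate, analytic, tolerance = 0.25)
  }
})

test_that("tilted-field correction satisfies its closed forms and identity", {
  # on resonance: theta = 90 degrees, R2 = R1rho
  expect_equal(r1rho_to_r2(10, 2, spinlock_context(1.9, 0)), 10)
  # omega1 = |Omega|: theta = 45 degrees, R2 = 2 R1rho - R1
  ctx45 <- spinlock_context(1.9, 1900)
  expect_equal(ctx45$theta, pi / 4)
  expect_equal(r1rho_to_r2(10, 2, ctx45), 18)
  # algebraic identity R2 = R1rho + cot^2(theta) (R1rho - R1)
  draws <- foxdyn:::with_seed(8, {
    list(r1rho = runif(1e4, 0, 50), r1 = runif(1e4, 0, 10),
         theta = runif(1e4, pi / 8, pi / 2))
  })
  r2 <- r1rho_to_r2(draws$r1rho, draws$r1, draws$theta)
  oracle <- draws$r1rho + (draws$r1rho - draws$r1) / tan(draws$theta)^2
  expect_lt(max(abs(r2 - oracle) / pmax(1, abs(oracle))), 1e-12)
  # monotonicity: r1rho > r1 implies r2 >= r1rho, equal only at theta = pi/2
  expect_true(all(r2[draws$r1rho > draws$r1] >=
                    draws$r1rho[draws$r1rho > draws$r1]))
  expect_error(spinlock_context(0, 0), class = "foxdyn_precondition_error")
})

test_that("hetNOE values and errors follow the propagation formula", {
  noise <- structure(list(sigma = 2, k = 5), class = "noise_estimate")
  expect_equal(compute_hetnoe(55, 55, noise)$value, 1)
  z <- compute_hetnoe(0, 40, noise)
  expect_equal(z$value, 0)
  expect_equal(z$sigma, 2 / 40)
  expect_error(compute_hetnoe(10, 0, noise),
               class = "foxdyn_invalid_reference")
  # MC oracle for the propagated sigma
  sat0 <- 30; ref0 <- 60
  prop <- compute_hetnoe(sat0, ref0, noise)
  mc_sd <- foxdyn:::with_seed(99, {
    sd(rnorm(1e5, sat0, 2) / rnorm(1e5, ref0, 2))
  })
  expect_equal(prop$sigma, mc_sd, tolerance = 0.05)
})

test_that("flexibility bands split at 0.5 and 0 with the stated conventions", {
  expect_equal(as.character(classify_flexibility(0.7)), "ordered")
  expect_equal(as.character(classify_flexibility(-0.2)), "highly_flexible")
  expect_equal(as.character(classify_flexibility(0.5)), "intermediate")
  expect_equal(as.character(classify_flexibility(0)), "intermediate")
})

test_that("relaxation_analysis chains rates, R2 and hetNOE per residue", {
  rates_r1 <- c(1.2, 1.5, 1.8)
  rates_r1rho <- c(8, 10, 12)
  r1_tab <- gen_decay_dataset(rates_r1, i0 = 100, sigma = 0.5, seed = 61)
  r1rho_tab <- gen_decay_dataset(rates_r1rho, i0 = 100,
                                 delays = default_r1rho_delays(),
                                 sigma = 0.5, seed = 62,
                                 experiment_kind = "T1rho")
  sat <- peak_table(1:3, rep(0.001, 3), c(40, 50, -5), 0, "hetnoe_sat")
  ref <- peak_table(1:3, rep(0.001, 3), c(60, 62, 58), 0, "hetnoe_ref")
  out <- relaxation_analysis(r1_tab, r1rho_tab, sat, ref,
                             config = run_config(n_mc = 200, seed = 63))
  expect_equal(out$residue, 1:3)
  expect_equal(out$R1, rates_r1, tolerance = 0.05)
  # on-resonance default: R2 equals R1rho
  expect_equal(out$R2, out$R1rho)
  expect_equal(out$hetNOE, c(40, 50, -5) / c(60, 62, 58), tolerance = 1e-12)
  expect_equal(out$flexibility_band,
               c("ordered", "ordered", "highly_flexible"))
  expect_true(all(out$R1_err > 0))
})
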
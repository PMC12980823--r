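test_that("exponential fit recovers exact parameters from noiseless data", {
  d <- data.frame(speed = c(0.7, 1.0, 1.3, 1.6))
  d$scaled_mo2 <- 100 * exp(0.5 * d$speed)
  fit <- fit_mo2(scaled_mo2 ~ speed, d)
  expect_equal(unname(coef(fit)["a"]), 100, tolerance = 1e-9)
  expect_equal(unname(coef(fit)["b"]), 0.5, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_equal(fit$smr, predict(fit, speed = 0), tolerance = 1e-12)

  dc <- data.frame(speed = c(0.7, 1.0, 1.3), scaled_mo2 = 150)
  fc <- fit_mo2(scaled_mo2 ~ speed, dc)
  expect_equal(unname(coef(fc)["a"]), 150, tolerance = 1e-9)
  expect_equal(unname(coef(fc)["b"]), 0, tolerance = 1e-12)
})

test_that("log-linear fit matches a brute-force Nelder-Mead minimizer", {
  d <- simulate_mo2_records(105, 0.9, sigma_mult = 0)  # noiseless
  fit <- fit_mo2(scaled_mo2 ~ speed, d)
  obj <- function(p) sum((log(d$scaled_mo2) - (p[1] + p[2] * d$speed))^2)
  opt <- optim(c(0, 0), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  opt <- optim(opt$par, obj, method = "Nelder-Mead",  # polish restart
               control = list(reltol = 1e-15, maxit = 5000))
  expect_equal(unname(coef(fit)["a"]), exp(opt$par[1]), tolerance = 1e-6)
  expect_equal(unname(coef(fit)["b"]), opt$par[2], tolerance = 1e-6)
  # nls sensitivity mode agrees on noiseless and on noisy data
  fn <- fit_mo2(scaled_mo2 ~ speed, d, method = "nls")
  expect_equal(coef(fn), coef(fit), tolerance = 1e-6)
  dn <- simulate_mo2_records(105, 0.9, sigma_mult = 0.05, seed = 12)
  fnn <- fit_mo2(scaled_mo2 ~ speed, dn, method = "nls")
  fln <- fit_mo2(scaled_mo2 ~ speed, dn)
  expect_equal(coef(fnn), coef(fln), tolerance = 0.1)
})

test_that("SMR is recovered within tolerance under multiplicative noise", {
  d <- simulate_mo2_records(105, 0.9, sigma_mult = 0.02, seed = 3)
  fit <- fit_mo2(scaled_mo2 ~ speed, d)
  expect_lt(abs(fit$smr - 105) / 105, 0.05)
})

test_that("fit preconditions are enforced", {
  d <- simulate_mo2_records(105, 0.9, sigma_mult = 0)
  expect_error(fit_mo2(scaled_mo2 ~ speed, d[1:2, ]), "at least 3")
  d2 <- d; d2$speed <- 1
  expect_error(fit_mo2(scaled_mo2 ~ speed, d2), "distinct speeds")
  d3 <- d; d3$scaled_mo2[2] <- -5
  expect_error(fit_mo2(scaled_mo2 ~ speed, d3), "onpositive")
  d4 <- d; d4$valid <- c(FALSE, TRUE, rep(FALSE, nrow(d) - 2))
  expect_error(fit_mo2(scaled_mo2 ~ speed, d4), "at least 3")
})

test_that("MMR is the maximum over valid steps, first step on ties", {
  rec <- data.frame(step_index = 0:3, scaled_mo2 = c(180, 420, 515, 498),
                    valid = TRUE)
  expect_equal(as.numeric(compute_mmr(rec)), 515)
  expect_equal(attr(compute_mmr(rec), "step_index"), 2)
  expect_equal(as.numeric(compute_mmr(data.frame(scaled_mo2 = 300, valid = TRUE))), 300)
  tie <- data.frame(step_index = 5:6, scaled_mo2 = c(500, 500), valid = TRUE)
  expect_equal(attr(compute_mmr(tie), "step_index"), 5)
  # invalid steps are ignored; none valid is an error
  rec$valid <- c(FALSE, TRUE, FALSE, TRUE)
  expect_equal(as.numeric(compute_mmr(rec)), 498)
  rec$valid <- FALSE
  expect_error(compute_mmr(rec), "insufficient data")
})

test_that("aerobic scope is MMR minus SMR, negative flagged", {
  expect_equal(compute_as(101.5, 512.3), 410.8)
  expect_equal(compute_as(7, 7), 0)
  expect_warning(as <- compute_as(110, 100), "negative")
  expect_equal(as, -10)
})

test_that("Ucrit follows the fatigue-time interpolation formula", {
  expect_equal(compute_ucrit(2.1, 7, 14, 0.3), 2.25)
  expect_equal(compute_ucrit(2.1, 0), 2.1)
  expect_equal(compute_ucrit(2.1, 14), 2.4)  # full-step limit: U_t + U1
  expect_error(compute_ucrit(2.1, 7, t = 0), "positive")
  expect_error(compute_ucrit(2.1, 15), "t1")
  # monotone nondecreasing in each argument
  set.seed(5)
  for (i in 1:20) {
    u_t <- runif(1, 0.7, 3); t1 <- runif(1, 0, 13); u1 <- runif(1, 0.1, 0.5)
    base <- compute_ucrit(u_t, t1, 14, u1)
    expect_gte(compute_ucrit(u_t + 0.1, t1, 14, u1), base)
    expect_gte(compute_ucrit(u_t, min(t1 + 1, 14), 14, u1), base)
    expect_gte(compute_ucrit(u_t, t1, 14, u1 + 0.1), base)
  }
})

test_that("metabolic_traits assembles a consistent per-fish record", {
  sim <- simulate_trial(trial_truth(noise_sd = 0))
  rec <- process_trial(sim$trace, sim$truth$mass)
  tr <- metabolic_traits(rec, sim$ucrit_inputs, "fish1")
  expect_equal(tr$as, tr$mmr - tr$smr)  # exact identity
  expect_equal(tr$ucrit, sim$truth$ucrit_true, tolerance = 1e-12)
  expect_equal(tr$n_valid_steps, length(sim$truth$speeds))
  expect_identical(tr$flags, "")
})

test_that("mo2_fit methods are coherent", {
  d <- simulate_mo2_records(100, 0.5, sigma_mult = 0.05, seed = 9)
  fit <- fit_mo2(scaled_mo2 ~ speed, d)
  expect_output(print(fit), "SMR")
  expect_output(print(summary(fit)), "coefficients")
  expect_equal(residuals(fit, "response"), d$scaled_mo2 - fitted(fit),
               tolerance = 1e-12)
  expect_equal(length(residuals(fit)), nrow(d))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(nrow(d), 3L))
  expect_true(all(sims > 0))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
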
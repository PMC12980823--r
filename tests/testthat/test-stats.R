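test_that("a programmed interaction is detected and its sign pattern recovered", {
  d <- simulate_interaction_data(slopes = c(0, 0.5, -0.5), n_per_level = 20,
                                 sigma = 0.1, seed = 42)
  fit <- fit_interaction_model(d, "y", "x", temperature = "temp",
                               log_pfas = FALSE)
  expect_lt(fit$interaction_p, 0.01)
  sl <- fit$simple_slopes
  expect_false(is.null(sl))
  expect_equal(sl$slope, c(0, 0.5, -0.5), tolerance = 0.15)
  expect_lt(abs(sl$slope[1]), 0.1)
  expect_gt(sl$slope[2], 0.3)
  expect_lt(sl$slope[3], -0.3)
})

test_that("zero-noise linear data is recovered exactly and slopes match per-level OLS", {
  d <- simulate_interaction_data(slopes = c(0.3, 1.1, -0.7), n_per_level = 10,
                                 sigma = 0, seed = 2)
  fit <- suppressWarnings(fit_interaction_model(d, "y", "x", temperature = "temp",
                                                log_pfas = FALSE))
  expect_equal(fit$simple_slopes$slope, c(0.3, 1.1, -0.7), tolerance = 1e-8)
  # level-wise reparameterization of the interaction model agrees with the
  # independently fitted per-level OLS slopes
  d2 <- simulate_interaction_data(slopes = c(0.2, 0.9, -0.4), n_per_level = 15,
                                  sigma = 0.3, seed = 13)
  f2 <- fit_interaction_model(d2, "y", "x", temperature = "temp", log_pfas = FALSE)
  cf <- coef(f2$model)
  model_slopes <- c(cf[".x"], cf[".x"] + cf[grep("^\\.x:", names(cf))])
  per_level <- vapply(sort(unique(d2$temp)), function(lv)
    unname(coef(lm(y ~ x, d2[d2$temp == lv, ]))[2]), numeric(1))
  expect_equal(unname(model_slopes), per_level, tolerance = 1e-9)
})

test_that("no simple slopes are reported when the interaction is not significant", {
  d <- simulate_interaction_data(slopes = c(0.4, 0.4, 0.4), n_per_level = 20,
                                 sigma = 0.5, seed = 7)
  fit <- fit_interaction_model(d, "y", "x", temperature = "temp", log_pfas = FALSE)
  if (fit$interaction_p >= 0.05) expect_null(fit$simple_slopes)
  expect_output(print(fit), "Interaction")
})

test_that("mixed-model contract: random intercept used, OLS fallback on one level", {
  d <- simulate_interaction_data(slopes = c(0, 0.6, -0.6), n_per_level = 15,
                                 sigma = 0.2, seed = 5)
  fm <- fit_interaction_model(d, "y", "x", temperature = "temp",
                              random = "aquarium_id", log_pfas = FALSE)
  expect_s4_class(fm$model, "lmerMod")
  d$one_group <- "A"
  f1 <- fit_interaction_model(d, "y", "x", temperature = "temp",
                              random = "one_group", log_pfas = FALSE)
  f0 <- fit_interaction_model(d, "y", "x", temperature = "temp", log_pfas = FALSE)
  expect_s3_class(f1$model, "lm")
  expect_equal(coef(f1$model), coef(f0$model), tolerance = 1e-6)
  expect_match(f1$provenance$notes, "single grouping level")
})

test_that("degenerate designs raise instructive errors", {
  d <- simulate_interaction_data(slopes = 0.3, temps = 24, n_per_level = 10,
                                 sigma = 0.1, seed = 1)
  expect_error(fit_interaction_model(d, "y", "x", temperature = "temp",
                                     log_pfas = FALSE), "slope-only")
  expect_error(simple_slopes(d[1:2, ], "y", "x", log_pfas = FALSE), "degenerate")
  expect_equal(unname(suppressWarnings(
    simple_slopes(data.frame(x = 1:5, y = 2 * (1:5)), "y", "x",
                  log_pfas = FALSE))["slope"]), 2, tolerance = 1e-12)
})

test_that("log transform of censored concentrations uses the half-MRL offset", {
  x <- c(0, 0.5, 10)
  lx <- log_conc(x)
  expect_equal(attr(lx, "offset"), min(mrl_tissue) / 2)
  expect_equal(as.numeric(lx), log(x + min(mrl_tissue) / 2))
  lp <- log_conc(c(1, 2))
  expect_equal(attr(lp, "offset"), 0)
  expect_equal(as.numeric(lp), log(c(1, 2)))
})

test_that("model selection prefers AIC and applies the drop-sex rule", {
  set.seed(32)
  d <- data.frame(x = rnorm(80), sex = rep(c("M", "F"), 40))
  d$y <- 1 + 0.8 * d$x + rnorm(80, 0, 0.3)           # no sex effect
  sel <- model_select(list(y ~ x, y ~ x + sex), d)
  expect_false(grepl("sex", deparse(sel$formula)))
  d$y2 <- d$y + 2 * (d$sex == "M")                    # strong sex effect
  sel2 <- model_select(list(y2 ~ x, y2 ~ x + sex), d)
  expect_true(grepl("sex", deparse(sel2$formula)))
  expect_lt(sel2$lrt_p, 0.05)
  sel3 <- model_select(list(y ~ x, y ~ x), d)         # identical: first kept
  expect_equal(sel3$best, 1L)
})

test_that("two-sample test picks the method from the data distribution", {
  x <- c(1, 2, 3, 4, 5)
  r <- two_sample_test(x, x, method = "wilcoxon")
  expect_equal(r$p, 1)
  set.seed(19)
  a <- rnorm(50); b <- rnorm(50, 2)                   # shift of 2 SDs
  r2 <- two_sample_test(a, b)
  expect_lt(r2$p, 0.001)
  expect_equal(r2$method, "welch_t")
  sk <- rexp(60)                                      # skewed: wilcoxon chosen
  r3 <- two_sample_test(sk, sk + 0.1)
  expect_equal(r3$method, "wilcoxon")
  expect_warning(r4 <- two_sample_test(rep(3, 5), rep(3, 5)), "degenerate")
  expect_true(is.na(r4$p))
})
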
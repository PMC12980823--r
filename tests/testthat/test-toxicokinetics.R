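test_that("censoring zeroes values below the reporting limit and is idempotent", {
  expect_equal(as.numeric(censor_conc(0.20, 0.35)), 0)
  expect_true(attr(censor_conc(0.20, 0.35), "below_mrl"))
  expect_equal(as.numeric(censor_conc(0.35, 0.35)), 0.35)  # boundary kept
  expect_equal(as.numeric(censor_conc(5.0, 0.49)), 5.0)
  expect_error(censor_conc(-1, 0.35), "negative")
  set.seed(8)
  x <- runif(50, 0, 2)
  once <- as.numeric(censor_conc(x, 0.49))
  expect_identical(as.numeric(censor_conc(once, 0.49)), once)
})

test_that("apply_censoring uses per-compound reporting limits", {
  p <- data.frame(fish_id = "f", tissue = "muscle",
                  compound = c("PFOS", "PFOA"), conc = c(0.34, 0.48))
  cp <- apply_censoring(p)
  expect_equal(cp$conc, c(0, 0))
  expect_true(all(cp$below_mrl))
  p$conc <- c(0.36, 0.48)  # above PFOS MRL, below PFOA MRL
  expect_equal(apply_censoring(p)$conc, c(0.36, 0))
})

test_that("compound sum and PFOS fraction behave as ratios of the panel", {
  p <- make_panel(pfos = c(muscle = 50), pfoa = c(muscle = 2))
  expect_equal(sum_pfas(p, "f1", "muscle"), 52)
  expect_equal(sum_pfas(make_panel(pfos = c(liver = 744.5), pfoa = c(liver = 32.5)),
                        "f1", "liver"), 777.0)
  z <- make_panel(pfos = c(muscle = 0), pfoa = c(muscle = 0))
  expect_equal(sum_pfas(z, "f1", "muscle"), 0)
  expect_true(is.na(pfos_fraction(z, "f1", "muscle")))  # undefined, not 0
  expect_error(sum_pfas(p[p$compound == "PFOS", ], "f1", "muscle"), "missing data")

  expect_equal(pfos_fraction(make_panel(pfos = c(blood = 99), pfoa = c(blood = 1)),
                             "f1", "blood"), 99)
  expect_equal(pfos_fraction(make_panel(pfos = c(blood = 50), pfoa = c(blood = 50)),
                             "f1", "blood"), 50)
  expect_equal(pfos_fraction(make_panel(pfos = c(blood = 470), pfoa = c(blood = 30)),
                             "f1", "blood"), 94)
  # scale invariance
  p1 <- make_panel(pfos = c(blood = 470), pfoa = c(blood = 30))
  p2 <- p1; p2$conc <- p2$conc * 17.3
  expect_equal(pfos_fraction(p1, "f1", "blood"), pfos_fraction(p2, "f1", "blood"),
               tolerance = 1e-12)
})

test_that("tissue percent shares cover the four core tissues and sum to 100", {
  eq <- make_panel(pfos = c(blood = 10, liver = 10, muscle = 10, ovary = 10))
  expect_equal(unname(tissue_percent_share(eq, "f1", "PFOS")), rep(25, 4))
  one <- make_panel(pfos = c(blood = 7, liver = 0, muscle = 0, ovary = 0))
  expect_equal(unname(tissue_percent_share(one, "f1", "PFOS")), c(100, 0, 0, 0))
  p <- make_panel(pfos = c(blood = 800, liver = 150, muscle = 30, ovary = 20))
  s <- tissue_percent_share(p, "f1", "PFOS")
  expect_equal(unname(s[c("blood", "liver", "muscle", "ovary")]), c(80, 15, 3, 2))
  expect_equal(sum(s), 100, tolerance = 1e-9)
  set.seed(3)
  for (i in 1:20) {
    pr <- make_panel(pfos = setNames(runif(4, 0.1, 1000),
                                     c("blood", "liver", "muscle", "ovary")))
    expect_equal(sum(tissue_percent_share(pr, "f1", "total")), 100, tolerance = 1e-9)
  }
  incomplete <- p[p$tissue != "blood", ]
  expect_error(tissue_percent_share(incomplete, "f1", "PFOS"), "incomplete panel")
})

test_that("organ:blood ratios quantify partitioning", {
  p <- make_panel(pfos = c(blood = 60, muscle = 30, liver = 84, ovary = 0))
  expect_equal(organ_blood_ratio(p, "f1", "muscle", "PFOS"), 0.5)
  expect_equal(organ_blood_ratio(p, "f1", "ovary", "PFOS"), 0)
  p35 <- make_panel(pfos = c(blood = 35, liver = 84, muscle = 1, ovary = 1))
  expect_equal(organ_blood_ratio(p35, "f1", "liver", "PFOS"), 2.4)
  z <- make_panel(pfos = c(blood = 0, muscle = 30, liver = 1, ovary = 1),
                  pfoa = c(blood = 0, muscle = 1, liver = 1, ovary = 1))
  expect_true(is.na(organ_blood_ratio(z, "f1", "muscle", "PFOS")))
  expect_error(organ_blood_ratio(p[p$tissue != "blood", ], "f1", "muscle", "PFOS"),
               "missing data")
})

test_that("fold-change ranges reproduce the range-wise quotients", {
  f <- fold_change_range(c(25.8, 56.5), c(1470, 1530))
  expect_equal(unname(f$rounded), c(26, 59))
  f2 <- fold_change_range(c(3.30, 8.10), c(388, 543))
  expect_equal(unname(f2$rounded), c(48, 165))
  expect_equal(unname(fold_change_range(c(1, 1), c(1, 1))$rounded), c(1, 1))
  expect_error(fold_change_range(c(0, 1), c(2, 3)), "positive")
  # antitone in control bounds, monotone in exposed bounds
  base <- fold_change_range(c(10, 20), c(100, 200))$fold
  wider_ctrl <- fold_change_range(c(12, 24), c(100, 200))$fold
  expect_true(all(wider_ctrl <= base))
  bigger_exp <- fold_change_range(c(10, 20), c(120, 240))$fold
  expect_true(all(bigger_exp >= base))
})

test_that("criterion ratios and residue IO round-trip", {
  expect_equal(criterion_ratio(50, 0.25), 200)
  expect_equal(criterion_ratio(100, 50), 2)
  expect_error(criterion_ratio(1, 0), "positive")
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(fish_id = "f1", tissue = c("muscle", "muscle"),
                       compound = c("PFOS", "PFOA"), conc_ng_g = c(0.2, 5),
                       mrl_ng_g = c(0.35, 0.49)),
            path, row.names = FALSE)
  p <- read_residue_table(path)
  expect_equal(p$conc, c(0, 5))  # PFOS censored on read
  expect_equal(sum_pfas(p, "f1", "muscle"), 5)
})
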
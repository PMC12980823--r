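# Small in-code fixtures shared across test files.

# One measure-phase segment with a programmed O2 decline (rate per hour).
make_segment <- function(decline = 0.5, n = 20, o2_0 = 8.0, noise_sd = 0,
                         step_index = 0L, speed = 0.7, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  time_h <- (seq_len(n) - 1L) / 360  # 10 s cadence
  o2 <- o2_0 - decline * time_h +
    (if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0)
  data.frame(trial_id = "t1", time_h = time_h, o2 = o2, phase = "measure",
             step_index = step_index, speed = speed, temp = 24,
             stringsAsFactors = FALSE)
}

# Independent closed-form OLS via the normal equations (the oracle the
# slope extractor is checked against; deliberately not lm()).
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxy <- sum(x * y); sxx <- sum(x^2)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - sy / n)^2)
  list(slope = slope, r2 = r2)
}

# Minimal long residue panel for one fish.
make_panel <- function(fish_id = "f1",
                       pfos = c(blood = 800, liver = 150, muscle = 30, ovary = 20),
                       pfoa = pfos / 20) {
  rbind(
    data.frame(fish_id = fish_id, tissue = names(pfos), compound = "PFOS",
               conc = unname(pfos), stringsAsFactors = FALSE),
    data.frame(fish_id = fish_id, tissue = names(pfoa), compound = "PFOA",
               conc = unname(pfoa), stringsAsFactors = FALSE)
  )
}
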
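## Seeded generators: oxygen traces with known bioenergetic ground truth,
## tissue-residue cohorts with known medians and temperature multipliers,
## Poisson egg-count series, and per-temperature linear datasets.

#' Ground truth for a simulated swim trial
#'
#' The inverse model of the respirometry pipeline: a programmed standard
#' metabolic rate and exponential rate coefficient, a critical swimming
#' speed, a background respiration rate, additive oxygen-reading noise and
#' a fish mass. Defaults emulate the study conditions for adult sheepshead
#' minnows: SMR 105 mg O2 kg^-1 h^-1 and MMR near 560 (via b = 0.6 at a
#' last completed step of 2.8 BL/s), a Ucrit of 2.95 BL/s, and a 3.26 g
#' fish.
#'
#' @param smr_true Mass-standardized SMR, mg O2 kg^-1 h^-1.
#' @param b_true Exponential rate coefficient, per BL/s.
#' @param ucrit_true Critical swimming speed, BL/s (must be at least the
#'   first step speed, 0.7).
#' @param background_true Empty-chamber oxygen decline, mg O2 L^-1 h^-1.
#' @param noise_sd Additive Gaussian noise SD on oxygen readings, mg/L.
#' @param mass Fish body mass, kg.
#' @return A list of class \code{"trial_truth"}.
#' @export
trial_truth <- function(smr_true = 105, b_true = 0.6, ucrit_true = 2.95,
                        background_true = 0.05, noise_sd = 0.002,
                        mass = 0.00326) {
  stopifnot(smr_true > 0, b_true > 0, ucrit_true > 0, background_true >= 0,
            noise_sd >= 0, mass > 0)
  structure(list(smr_true = smr_true, b_true = b_true, ucrit_true = ucrit_true,
                 background_true = background_true, noise_sd = noise_sd,
                 mass = mass),
            class = "trial_truth")
}

## evenly spaced sample times (hours) covering [t0, t0 + dur_min minutes)
seg_times <- function(t0_h, dur_min, hz) {
  n <- max(2L, as.integer(round(dur_min * 60 * hz)))
  t0_h + (seq_len(n) - 1L) / (3600 * hz)
}

#' Simulate one intermittent-flow swim trial
#'
#' Builds a full oxygen trace for an incremental-velocity trial at speeds
#' 0.7, 1.0, 1.3, ... BL/s. Per step, the programmed mass-standardized
#' oxygen consumption \code{smr_true * exp(b_true * U)} is inverted through
#' the allometric standardization and the volume/mass conversion into an
#' oxygen decline slope (plus background); closed-phase oxygen falls
#' linearly from saturation while flush phases reset it. The fish fatigues
#' partway through the first step whose speed exceeds \code{ucrit_true},
#' with the time-at-fatigue chosen so the Ucrit formula recovers the truth
#' exactly in the noise-free case; no measurement samples are emitted for
#' the aborted fatigue step. Empty-chamber background segments (20 min)
#' precede and follow the swim.
#'
#' @param truth A \code{\link{trial_truth}}.
#' @param cfg A \code{\link{respirometry_config}}.
#' @param seed Integer seed for the oxygen-reading noise (ignored when
#'   \code{noise_sd = 0}).
#' @param trial_id Identifier stamped on the trace.
#' @param temp Water temperature recorded on the trace, deg C.
#' @param o2_sat Oxygen saturation baseline, mg/L (default 8.0).
#' @param sample_hz Sampling rate, Hz (default 1).
#' @param background_min Background segment duration, minutes (default 20).
#' @return List: \code{trace} (an oxygen trace), \code{ucrit_inputs}
#'   (\code{u_t}, \code{t1}, \code{t}, \code{u1}), and \code{truth}
#'   augmented with the completed-step \code{speeds}, per-step programmed
#'   \code{scaled_mo2}, and \code{mmr_true} (the programmed rate at the
#'   last completed step).
#' @export
simulate_trial <- function(truth, cfg = respirometry_config(), seed = NULL,
                           trial_id = "sim1", temp = 24, o2_sat = 8.0,
                           sample_hz = 1, background_min = 20) {
  stopifnot(inherits(truth, "trial_truth"))
  u0 <- 0.7
  u1 <- cfg$step_increment
  if (truth$ucrit_true < u0)
    stop("ucrit_true is below the first step speed (", u0, " BL/s)")
  k <- floor((truth$ucrit_true - u0) / u1 + 1e-9)
  u_t <- u0 + k * u1
  t1 <- cfg$step_duration * (truth$ucrit_true - u_t) / u1
  if (t1 >= cfg$step_duration - 1e-9) {  # ucrit lands on the next grid speed
    k <- k + 1L
    u_t <- u0 + k * u1
    t1 <- 0
  }
  t1 <- min(max(t1, 0), cfg$step_duration)
  speeds <- u0 + u1 * (0:k)

  scale_factor <- (truth$mass / cfg$reference_mass)^(1 - cfg$allometric_exponent)
  v_resp <- cfg$chamber_volume - (truth$mass * 1000 / cfg$fish_density) / 1000
  scaled <- truth$smr_true * exp(truth$b_true * speeds)
  unscaled <- scaled / scale_factor
  declines <- unscaled * truth$mass / v_resp + truth$background_true

  hz <- sample_hz
  pieces <- list()
  t0 <- 0
  add <- function(dur_min, phase, step, speed, o2fun) {
    tt <- seg_times(t0, dur_min, hz)
    pieces[[length(pieces) + 1L]] <<- data.frame(
      time_h = tt, o2 = o2fun(tt), phase = phase,
      step_index = step, speed = speed)
    t0 <<- tt[length(tt)] + 1 / (3600 * hz)
  }
  add(background_min, "background_pre", NA_integer_, NA_real_,
      function(tt) o2_sat - truth$background_true * (tt - tt[1L]))
  for (i in seq_along(speeds)) {
    add(cfg$flush_min, "flush", i - 1L, speeds[i], function(tt) rep(o2_sat, length(tt)))
    tw <- t0
    add(cfg$wait_min, "wait", i - 1L, speeds[i],
        function(tt) o2_sat - declines[i] * (tt - tw))
    add(cfg$measure_min, "measure", i - 1L, speeds[i],
        function(tt) o2_sat - declines[i] * (tt - tw))
  }
  add(background_min, "background_post", NA_integer_, NA_real_,
      function(tt) o2_sat - truth$background_true * (tt - tt[1L]))
  trace <- do.call(rbind, pieces)
  trace <- data.frame(trial_id = trial_id, trace, temp = temp,
                      stringsAsFactors = FALSE)
  if (truth$noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    trace$o2 <- trace$o2 + stats::rnorm(nrow(trace), 0, truth$noise_sd)
  }
  trace <- as_oxygen_trace(trace)
  list(trace = trace,
       ucrit_inputs = list(u_t = u_t, t1 = t1, t = cfg$step_duration, u1 = u1),
       truth = c(unclass(truth),
                 list(speeds = speeds, scaled_mo2 = scaled,
                      mmr_true = scaled[length(scaled)])))
}

#' Simulate per-step MO2 records with multiplicative noise
#'
#' Draws \code{smr * exp(b * speed) * exp(N(0, sigma_mult))} at each speed:
#' the measurement model behind the log-scale trait fit.
#'
#' @param smr,b True SMR and rate coefficient.
#' @param speeds Step speeds, BL/s.
#' @param sigma_mult Log-scale (multiplicative) noise SD.
#' @param seed Optional integer seed.
#' @return A data frame usable by \code{\link{fit_mo2}}: \code{step_index},
#'   \code{speed}, \code{scaled_mo2}, \code{valid}.
#' @export
simulate_mo2_records <- function(smr, b, speeds = seq(0.7, 2.8, by = 0.3),
                                 sigma_mult = 0.02, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  eps <- if (sigma_mult > 0) stats::rnorm(length(speeds), 0, sigma_mult) else 0
  data.frame(step_index = seq_along(speeds) - 1L, speed = speeds,
             scaled_mo2 = smr * exp(b * speeds) * exp(eps), valid = TRUE)
}

#' Ground truth for a simulated tissue-residue cohort
#'
#' Defaults emulate a two-temperature design with exposed and nonexposed
#' groups, three aquaria per treatment and three sampled females per
#' aquarium (12 aquaria in all). Exposed-group medians put PFOS at roughly
#' 95-98 percent of the compound sum in every tissue, with blood carrying
#' the largest share; nonexposed medians are the exposed ones divided by
#' \code{background_divisor}. Temperature multipliers act on the warm
#' group (second temperature) relative to the first.
#'
#' @param temps Two temperature levels, deg C.
#' @param aquaria_per_treatment,fish_per_aquarium Design sizes.
#' @param medians Named list \code{PFOS}, \code{PFOA} of per-tissue median
#'   concentrations (ng/g ww) in exposed fish at \code{temps[1]}.
#' @param temp_mult Named list per compound of per-tissue multiplicative
#'   temperature effects at \code{temps[2]}.
#' @param gsd Geometric standard deviation of individual variation.
#' @param aquarium_gsd Geometric SD of the aquarium-level random intercept.
#' @param background_divisor Exposed/nonexposed median ratio.
#' @param mrls Tissue reporting limits used for censoring.
#' @return A list of class \code{"cohort_truth"}.
#' @export
cohort_truth <- function(temps = c(24, 28.5),
                         aquaria_per_treatment = 3,
                         fish_per_aquarium = 3,
                         medians = list(
                           PFOS = c(blood = 5000, liver = 2500, ovary = 1400, muscle = 500),
                           PFOA = c(blood = 60, liver = 25, ovary = 20, muscle = 10)),
                         temp_mult = list(
                           PFOS = c(blood = 1, liver = 1, ovary = 1, muscle = 1),
                           PFOA = c(blood = 2.4, liver = 4.0, ovary = 4.3, muscle = 2.0)),
                         gsd = 1.5, aquarium_gsd = 1.15,
                         background_divisor = 40,
                         mrls = mrl_tissue) {
  stopifnot(length(temps) == 2L, all(unlist(medians) > 0), gsd >= 1,
            aquarium_gsd >= 1, background_divisor > 0)
  for (cmp in names(medians)) {
    if (is.null(names(medians[[cmp]])))
      stop("medians entries must be named by tissue")
    if (is.null(names(temp_mult[[cmp]])) ||
        !all(names(medians[[cmp]]) %in% names(temp_mult[[cmp]])))
      stop("temp_mult entries must be named by the same tissues as medians")
  }
  structure(list(temps = temps, aquaria_per_treatment = aquaria_per_treatment,
                 fish_per_aquarium = fish_per_aquarium, medians = medians,
                 temp_mult = temp_mult, gsd = gsd, aquarium_gsd = aquarium_gsd,
                 background_divisor = background_divisor, mrls = mrls),
            class = "cohort_truth")
}

#' Simulate a tissue-residue cohort
#'
#' Lognormal concentrations per fish x tissue x compound with
#' compound-specific temperature multipliers, an aquarium-level random
#' intercept on the log scale, and left-censoring at the reporting limits.
#' Also emits the matching fish biometrics and somatic-weight tables.
#'
#' @param truth A \code{\link{cohort_truth}}.
#' @param seed Integer seed.
#' @return List of data frames: \code{residues} (long, censored),
#'   \code{fish}, \code{somatic}.
#' @export
simulate_cohort <- function(truth = cohort_truth(), seed = 1) {
  stopifnot(inherits(truth, "cohort_truth"))
  set.seed(seed)
  design <- expand.grid(temp = truth$temps, pfas_group = c("exposed", "nonexposed"),
                        rep = seq_len(truth$aquaria_per_treatment),
                        stringsAsFactors = FALSE)
  design$aquarium_id <- sprintf("A%02d", seq_len(nrow(design)))
  tissues <- names(truth$medians$PFOS)
  sdlog <- log(truth$gsd)
  aq_sd <- log(truth$aquarium_gsd)

  fish <- residues <- somatic <- list()
  fid <- 0L
  for (a in seq_len(nrow(design))) {
    aq <- design[a, ]
    aq_eff <- stats::rnorm(1, 0, aq_sd)
    for (f in seq_len(truth$fish_per_aquarium)) {
      fid <- fid + 1L
      id <- sprintf("F%03d", fid)
      mass_g <- 2.40 * exp(stats::rnorm(1, 0, log(1.15)))
      fish[[fid]] <- data.frame(
        fish_id = id, mass_g = mass_g,
        length_mm = 49.2 * (mass_g / 2.40)^(1 / 3), sex = "F",
        temp_C = aq$temp, pfas_group = aq$pfas_group,
        aquarium_id = aq$aquarium_id, stringsAsFactors = FALSE)
      for (cmp in c("PFOS", "PFOA")) {
        med <- truth$medians[[cmp]][tissues]
        if (aq$pfas_group == "nonexposed") med <- med / truth$background_divisor
        mult <- if (aq$temp == truth$temps[2L]) truth$temp_mult[[cmp]][tissues] else 1
        conc <- exp(log(med * mult) + aq_eff + stats::rnorm(length(tissues), 0, sdlog))
        residues[[length(residues) + 1L]] <- data.frame(
          fish_id = id, tissue = tissues, compound = cmp,
          conc = unname(conc), mrl = unname(truth$mrls[cmp]),
          stringsAsFactors = FALSE)
      }
      somatic[[length(somatic) + 1L]] <- data.frame(
        fish_id = id, organ = c("liver", "gonad"),
        organ_weight_g = mass_g * c(0.02, 0.08) *
          exp(stats::rnorm(2, 0, log(1.2))),
        body_weight_g = mass_g, stringsAsFactors = FALSE)
    }
  }
  res <- apply_censoring(do.call(rbind, residues))
  list(residues = res, fish = do.call(rbind, fish),
       somatic = do.call(rbind, somatic))
}

#' Simulate a daily egg-count series
#'
#' Poisson counts with mean \code{n_females * (rate + trend * day)}
#' (floored at zero), emulating per-aquarium daily egg collection.
#'
#' @param rate_per_female_day Baseline eggs per female per day.
#' @param n_females Number of females in the aquarium.
#' @param n_days Number of collection days.
#' @param trend Linear change in the per-female rate per day.
#' @param seed Integer seed.
#' @param aquarium_id,period Labels stamped on the series.
#' @return An egg-series data frame (\code{aquarium_id}, \code{day},
#'   \code{egg_count}, \code{n_females}, \code{period}).
#' @export
simulate_eggs <- function(rate_per_female_day = 5, n_females = 12, n_days = 28,
                          trend = 0, seed = 1, aquarium_id = "A01",
                          period = "exposure") {
  stopifnot(n_females > 0, n_days >= 1)
  set.seed(seed)
  day <- seq_len(n_days)
  mu <- pmax(0, n_females * (rate_per_female_day + trend * day))
  data.frame(aquarium_id = aquarium_id, day = day,
             egg_count = stats::rpois(n_days, mu),
             n_females = n_females, period = period,
             stringsAsFactors = FALSE)
}

#' Simulate per-temperature linear concentration-trait data
#'
#' Generates a trait responding linearly to a (log-scale) concentration
#' covariate with a possibly different slope at each temperature level:
#' the testbed for the interaction model and its type-I error.
#'
#' @param slopes Named or unnamed vector of per-temperature slopes.
#' @param temps Temperature labels (same length as \code{slopes}).
#' @param n_per_level Observations per temperature.
#' @param sigma Residual SD.
#' @param intercept Common intercept.
#' @param seed Integer seed.
#' @return Data frame \code{temp}, \code{x} (log-concentration scale),
#'   \code{y}, plus an \code{aquarium_id} assigning rows round-robin to
#'   two aquaria per temperature.
#' @export
simulate_interaction_data <- function(slopes = c(0, 0.5, -0.5),
                                      temps = c(24, 26, 28.5),
                                      n_per_level = 20, sigma = 0.2,
                                      intercept = 1, seed = 1) {
  stopifnot(length(slopes) == length(temps))
  set.seed(seed)
  out <- do.call(rbind, lapply(seq_along(temps), function(i) {
    x <- stats::rnorm(n_per_level)
    data.frame(temp = temps[i], x = x,
               y = intercept + slopes[i] * x +
                 (if (sigma > 0) stats::rnorm(n_per_level, 0, sigma) else 0),
               aquarium_id = sprintf("T%d_Q%d", i, (seq_len(n_per_level) %% 2) + 1L))
  }))
  rownames(out) <- NULL
  out
}
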
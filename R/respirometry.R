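## Intermittent-flow respirometry: oxygen-trace handling, per-step decline
## slopes, background correction and mass standardization.

PHASES <- c("flush", "wait", "measure", "background_pre", "background_post")

#' Validate an oxygen trace
#'
#' An oxygen trace is a long-format data frame describing one swim trial:
#' one row per oxygen reading, with the phase of the intermittent-flow cycle
#' and the swimming step it belongs to. Internal time units are hours so
#' that decline slopes come out in mg O2 L^-1 h^-1.
#'
#' @param df Data frame with columns \code{trial_id}, \code{time_h},
#'   \code{o2} (mg O2 per L), \code{phase} (one of flush, wait, measure,
#'   background_pre, background_post), \code{step_index} (integer, NA for
#'   background rows), \code{speed} (BL per s, NA for background rows) and
#'   \code{temp} (deg C).
#' @return The validated data frame, invisibly classed \code{"oxygen_trace"}.
#' @export
as_oxygen_trace <- function(df) {
  need <- c("trial_id", "time_h", "o2", "phase", "step_index", "speed", "temp")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("oxygen trace missing columns: ", paste(miss, collapse = ", "))
  if (!all(df$phase %in% PHASES))
    stop("unknown phase labels: ",
         paste(unique(setdiff(df$phase, PHASES)), collapse = ", "))
  if (is.unsorted(df$time_h, strictly = TRUE))
    stop("trace time must be strictly increasing within a trial")
  fg <- df$phase %in% c("flush", "wait", "measure")
  if (anyNA(df$step_index[fg]) || anyNA(df$speed[fg]))
    stop("step_index and speed are required on flush/wait/measure rows")
  sp <- unique(df[df$phase == "measure", c("step_index", "speed")])
  if (anyDuplicated(sp$step_index))
    stop("speed must be constant within a step")
  sp <- sp[order(sp$step_index), ]
  if (is.unsorted(sp$speed)) stop("step speeds must be non-decreasing across steps")
  class(df) <- c("oxygen_trace", "data.frame")
  invisible(df)
}

#' Read oxygen traces from a delimited file
#'
#' Expects the long-format dialect \code{trial_id, time_s, o2_mgL, phase,
#' step_index, speed_bls, temp_C}; time is converted from seconds to hours.
#'
#' @param path Path to a CSV (or TSV, by extension) file.
#' @return A list of \code{oxygen_trace} data frames, one per trial, named
#'   by \code{trial_id}.
#' @export
read_oxygen_traces <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("trial_id", "time_s", "o2_mgL", "phase", "step_index", "speed_bls", "temp_C")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("trace file missing columns: ", paste(miss, collapse = ", "))
  df <- data.frame(trial_id = raw$trial_id, time_h = raw$time_s / 3600,
                   o2 = raw$o2_mgL, phase = raw$phase,
                   step_index = raw$step_index, speed = raw$speed_bls,
                   temp = raw$temp_C, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$trial_id), as_oxygen_trace)
  out[unique(df$trial_id)]
}

## OLS of o2 on time for one segment; r2 := 0 when the response has zero
## variance (a flat segment carries no slope information).
segment_slope <- function(time_h, o2) {
  if (length(o2) < 2L) stop("segment has fewer than 2 samples")
  if (stats::var(o2) == 0) {
    return(list(slope = 0, r2 = 0))
  }
  fit <- stats::lm(o2 ~ time_h)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((o2 - mean(o2))^2)
  list(slope = unname(stats::coef(fit)[2L]), r2 = r2)
}

#' Extract per-step oxygen decline slopes
#'
#' Fits an ordinary least-squares line of dissolved oxygen on time within
#' each closed measurement segment of a trial and reports the decline rate
#' (the negated slope, positive when oxygen falls), the coefficient of
#' determination, and a validity flag (\code{r2 > r2_min}).
#'
#' @param trace An \code{\link{as_oxygen_trace}}-valid data frame.
#' @param cfg A \code{\link{respirometry_config}}.
#' @return A data frame of class \code{"slope_estimates"} with one row per
#'   measurement segment: \code{step_index}, \code{speed},
#'   \code{decline_rate} (mg O2 L^-1 h^-1), \code{r2}, \code{valid},
#'   \code{n}.
#' @examples
#' tr <- data.frame(trial_id = "t1", time_h = (0:9) / 60, phase = "measure",
#'                  step_index = 0L, speed = 0.7, temp = 24)
#' tr$o2 <- 8 - 0.5 * tr$time_h
#' extract_slopes(as_oxygen_trace(tr), respirometry_config())
#' @export
extract_slopes <- function(trace, cfg = respirometry_config()) {
  trace <- as_oxygen_trace(as.data.frame(trace))
  meas <- trace[trace$phase == "measure", , drop = FALSE]
  if (nrow(meas) == 0L) stop("trace contains no measurement segments")
  res <- lapply(split(meas, meas$step_index), function(seg) {
    if (nrow(seg) < 2L)
      stop(sprintf("malformed trace: measurement segment of step %s has %d sample(s)",
                   seg$step_index[1L], nrow(seg)))
    s <- segment_slope(seg$time_h, seg$o2)
    data.frame(step_index = seg$step_index[1L], speed = seg$speed[1L],
               decline_rate = -s$slope, r2 = s$r2,
               valid = s$r2 > cfg$r2_min, n = nrow(seg))
  })
  out <- do.call(rbind, res)
  out <- out[order(out$step_index), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("slope_estimates", "data.frame")
  out
}

#' Oxygen decline slopes of the empty-chamber background segments
#'
#' @inheritParams extract_slopes
#' @return A data frame with one row per background segment present
#'   (\code{background_pre}, \code{background_post}) and columns
#'   \code{phase}, \code{decline_rate}, \code{r2}, \code{n}.
#' @export
background_slopes <- function(trace, cfg = respirometry_config()) {
  bg <- trace[trace$phase %in% c("background_pre", "background_post"), , drop = FALSE]
  if (nrow(bg) == 0L)
    return(data.frame(phase = character(), decline_rate = numeric(),
                      r2 = numeric(), n = integer()))
  res <- lapply(split(bg, bg$phase), function(seg) {
    if (nrow(seg) < 2L)
      stop(sprintf("malformed trace: background segment '%s' has %d sample(s)",
                   seg$phase[1L], nrow(seg)))
    s <- segment_slope(seg$time_h, seg$o2)
    data.frame(phase = seg$phase[1L], decline_rate = -s$slope, r2 = s$r2,
               n = nrow(seg))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Background (microbial) respiration rate
#'
#' The background oxygen decline is the arithmetic mean of the two
#' empty-chamber measurements taken before and after the swimming test.
#'
#' @param pre,post Decline rates (mg O2 L^-1 h^-1) of the pre- and
#'   post-trial background segments; either may be \code{NA} or \code{NULL}
#'   when missing.
#' @param allow_single If \code{TRUE}, fall back to the single available
#'   measurement when one is missing; otherwise missing measurements are an
#'   error.
#' @return The background decline rate, mg O2 L^-1 h^-1.
#' @examples
#' background_rate(0.10, 0.06) # 0.08
#' @export
background_rate <- function(pre, post, allow_single = FALSE) {
  pre <- if (is.null(pre)) NA_real_ else pre
  post <- if (is.null(post)) NA_real_ else post
  have <- c(pre, post)[!is.na(c(pre, post))]
  if (length(have) == 2L) return(mean(have))
  if (length(have) == 1L) {
    if (isTRUE(allow_single)) return(have)
    stop("only one background measurement available; set allow_single = TRUE ",
         "(or allow_single_background in the configuration) to use it alone")
  }
  stop("no background measurements available")
}

#' Unscaled mass-specific oxygen consumption
#'
#' Converts a background-corrected oxygen decline rate into a mass-specific
#' oxygen consumption rate,
#' \deqn{\mathrm{MO_2^{unscaled}} = [(\Delta[O_2]/\Delta t) -
#'   (\Delta[O_2]/\Delta t)_{bact}] \times V_{resp} / m,}
#' where the effective respirometer volume \eqn{V_{resp}} is the chamber
#' volume minus the fish volume inferred from its mass and an assumed
#' density.
#'
#' @param decline_rate Oxygen decline rate during the measurement, mg O2
#'   L^-1 h^-1 (positive when O2 falls). Vectorized over steps.
#' @param background Background decline rate from
#'   \code{\link{background_rate}}.
#' @param mass Fish body mass in kg.
#' @param cfg A \code{\link{respirometry_config}}.
#' @return Unscaled MO2 in mg O2 kg^-1 h^-1. Negative values (background
#'   exceeding the fish signal) are returned with a warning, not dropped.
#' @examples
#' cfg <- respirometry_config()
#' unscaled_mo2(0.5, 0.1, 0.003, cfg) # (0.4) * 1.497 / 0.003 = 199.6
#' @export
unscaled_mo2 <- function(decline_rate, background, mass, cfg = respirometry_config()) {
  if (!is.numeric(mass) || length(mass) != 1L || mass <= 0)
    stop("mass must be a single positive number (kg)")
  fish_volume_L <- (mass * 1000 / cfg$fish_density) / 1000
  v_resp <- cfg$chamber_volume - fish_volume_L
  if (v_resp <= 0)
    stop(sprintf("configuration error: effective respirometer volume %.3g L is not positive",
                 v_resp))
  out <- (decline_rate - background) * v_resp / mass
  if (any(out < 0, na.rm = TRUE))
    warning("background respiration exceeds fish oxygen decline for ",
            sum(out < 0, na.rm = TRUE), " step(s); negative MO2 flagged, not dropped")
  out
}

#' Allometric mass standardization of MO2
#'
#' Standardizes a mass-specific metabolic rate to the reference body mass
#' via the power law
#' \deqn{\mathrm{MO_2} = \mathrm{MO_2^{unscaled}} \times (m / m_{corr})^{1 - A}.}
#'
#' @param unscaled Unscaled MO2, mg O2 kg^-1 h^-1 (vectorized).
#' @param mass Fish body mass in kg.
#' @param cfg A \code{\link{respirometry_config}} supplying the exponent
#'   \code{allometric_exponent} and \code{reference_mass}.
#' @return Mass-standardized MO2, mg O2 kg^-1 h^-1.
#' @examples
#' scale_mo2(199.6, 0.003, respirometry_config()) # ~65.0
#' @export
scale_mo2 <- function(unscaled, mass, cfg = respirometry_config()) {
  if (!is.numeric(mass) || length(mass) != 1L || mass <= 0)
    stop("mass must be a single positive number (kg)")
  unscaled * (mass / cfg$reference_mass)^(1 - cfg$allometric_exponent)
}

#' Process one swim trial into per-step MO2 records
#'
#' Runs the full per-trial respirometry pipeline: per-step decline slopes,
#' background correction, unscaled MO2 and allometric standardization.
#' Invalid steps (slope \code{r2 <= r2_min}) are retained in the output but
#' flagged; downstream trait fitting uses valid steps only.
#'
#' @param trace An oxygen trace containing measurement and background
#'   segments.
#' @param mass Fish body mass in kg.
#' @param cfg A \code{\link{respirometry_config}}.
#' @return Data frame of class \code{"mo2_records"}: \code{step_index},
#'   \code{speed}, \code{decline_rate}, \code{r2}, \code{valid},
#'   \code{unscaled_mo2}, \code{scaled_mo2}, \code{flag_negative}; the
#'   background rate used is attached as attribute \code{"background"}.
#' @export
process_trial <- function(trace, mass, cfg = respirometry_config()) {
  slopes <- extract_slopes(trace, cfg)
  bg <- background_slopes(trace, cfg)
  bact <- background_rate(
    pre = if ("background_pre" %in% bg$phase) bg$decline_rate[bg$phase == "background_pre"] else NA_real_,
    post = if ("background_post" %in% bg$phase) bg$decline_rate[bg$phase == "background_post"] else NA_real_,
    allow_single = cfg$allow_single_background
  )
  n_valid <- sum(slopes$valid)
  if (n_valid < cfg$min_valid_steps)
    stop(sprintf("insufficient data: %d valid step(s), need at least %d",
                 n_valid, cfg$min_valid_steps))
  um <- suppressWarnings(unscaled_mo2(slopes$decline_rate, bact, mass, cfg))
  out <- slopes
  out$unscaled_mo2 <- um
  out$scaled_mo2 <- scale_mo2(um, mass, cfg)
  out$flag_negative <- out$unscaled_mo2 < 0
  if (any(out$flag_negative & out$valid))
    warning("negative MO2 on ", sum(out$flag_negative & out$valid), " valid step(s)")
  attr(out, "background") <- bact
  class(out) <- c("mo2_records", "data.frame")
  out
}
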
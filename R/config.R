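#' Respirometry protocol configuration
#'
#' Bundles the physical and protocol constants of an intermittent-flow
#' swim-respirometry trial: chamber volume, the slope-validity threshold,
#' the allometric mass-standardization parameters, and the timing of the
#' flush/wait/measure cycle.
#'
#' @param chamber_volume Respirometer volume in litres (default 1.5).
#' @param r2_min Minimum coefficient of determination for a measure-phase
#'   oxygen decline slope to be considered valid (default 0.85, strict
#'   inequality).
#' @param allometric_exponent Allometric exponent \eqn{A} of the metabolic
#'   rate vs body mass power law (default 0.68).
#' @param reference_mass Reference body mass \eqn{m_{corr}} in kg to which
#'   metabolic rates are standardized (default 0.1).
#' @param flush_min,wait_min,measure_min Duration in minutes of the flush,
#'   wait and closed measurement phases (defaults 3, 1, 10).
#' @param step_increment Velocity increment \eqn{U_1} between consecutive
#'   swimming steps, in body lengths per second (default 0.3).
#' @param step_duration Full step duration \eqn{t} in minutes; must equal
#'   \code{flush_min + wait_min + measure_min} (default 14).
#' @param fish_density Assumed fish density in g per mL, used to infer fish
#'   volume from body mass when computing the effective respirometer volume
#'   (default 1.0, near neutral buoyancy).
#' @param min_valid_steps Minimum number of valid steps required before a
#'   trial is fitted (default 3; an exponential fit needs at least 3 points).
#' @param allow_single_background If \code{TRUE}, a missing pre- or
#'   post-trial background measurement falls back to the single available
#'   one instead of raising an error.
#'
#' @return An object of class \code{"respirometry_config"} (a named list).
#' @examples
#' cfg <- respirometry_config()
#' cfg$chamber_volume
#' @export
respirometry_config <- function(chamber_volume = 1.5,
                                r2_min = 0.85,
                                allometric_exponent = 0.68,
                                reference_mass = 0.1,
                                flush_min = 3,
                                wait_min = 1,
                                measure_min = 10,
                                step_increment = 0.3,
                                step_duration = flush_min + wait_min + measure_min,
                                fish_density = 1.0,
                                min_valid_steps = 3,
                                allow_single_background = FALSE) {
  cfg <- list(
    chamber_volume = chamber_volume, r2_min = r2_min,
    allometric_exponent = allometric_exponent, reference_mass = reference_mass,
    flush_min = flush_min, wait_min = wait_min, measure_min = measure_min,
    step_increment = step_increment, step_duration = step_duration,
    fish_density = fish_density, min_valid_steps = min_valid_steps,
    allow_single_background = isTRUE(allow_single_background)
  )
  num <- cfg[!names(cfg) %in% "allow_single_background"]
  if (!all(vapply(num, function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0,
                  logical(1))))
    stop("all respirometry_config numeric fields must be single positive finite numbers")
  if (r2_min <= 0 || r2_min >= 1) stop("r2_min must lie strictly in (0, 1)")
  if (abs(step_duration - (flush_min + wait_min + measure_min)) > 1e-9)
    stop("step_duration must equal flush_min + wait_min + measure_min")
  class(cfg) <- "respirometry_config"
  cfg
}

#' @export
print.respirometry_config <- function(x, ...) {
  cat("Intermittent-flow respirometry configuration\n")
  cat(sprintf("  chamber %.3g L; slope validity R^2 > %.2f\n", x$chamber_volume, x$r2_min))
  cat(sprintf("  allometric exponent %.2f, reference mass %.3g kg\n",
              x$allometric_exponent, x$reference_mass))
  cat(sprintf("  cycle %g + %g + %g = %g min; increment %.2g BL/s\n",
              x$flush_min, x$wait_min, x$measure_min, x$step_duration, x$step_increment))
  invisible(x)
}

#' Read a respirometry configuration from YAML
#'
#' Reads a YAML file whose keys mirror the arguments of
#' \code{\link{respirometry_config}}; missing keys take the defaults.
#'
#' @param path Path to a YAML file.
#' @return A \code{respirometry_config} object.
#' @export
read_respirometry_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(respirometry_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(respirometry_config, vals)
}
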
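## Metabolic traits: exponential MO2-speed model, SMR/MMR/aerobic scope,
## and critical swimming speed.

#' Fit the exponential oxygen consumption vs swimming speed model
#'
#' Fits \deqn{\mathrm{MO_2}(U) = a \, e^{bU}} to per-step oxygen consumption
#' measurements from an incremental-velocity swim trial. The default
#' estimator is ordinary least squares on the log scale (a multiplicative
#' error model), which is standard practice for Ucrit respirometry and
#' robust at the small number of steps a trial yields; a nonlinear
#' least-squares mode is available for sensitivity checks. The intercept
#' \eqn{a} is the predicted rate at a null swimming velocity, i.e. the
#' standard metabolic rate (SMR).
#'
#' @param formula Model formula, response on speed, e.g.
#'   \code{scaled_mo2 ~ speed} (the default when \code{data} is a
#'   \code{mo2_records} frame).
#' @param data Data frame holding the response and the speed covariate. If
#'   it carries a logical \code{valid} column, only valid rows are used.
#' @param method \code{"loglinear"} (default) or \code{"nls"}.
#' @return An object of class \code{"mo2_fit"} with components
#'   \code{coefficients} (\code{a}, \code{b}), \code{smr}, \code{r2} (of the
#'   log-linear regression; \code{NA} when the response is constant),
#'   \code{sigma_log}, \code{n}, \code{data}, \code{method}, \code{call}.
#' @examples
#' d <- data.frame(speed = c(0.7, 1.0, 1.3, 1.6))
#' d$scaled_mo2 <- 100 * exp(0.5 * d$speed)
#' fit <- fit_mo2(scaled_mo2 ~ speed, d)
#' coef(fit)         # a = 100, b = 0.5
#' predict(fit, speed = 0)
#' @seealso \code{\link{metabolic_traits}}, \code{\link{compute_mmr}},
#'   \code{\link{compute_ucrit}}
#' @export
fit_mo2 <- function(formula = scaled_mo2 ~ speed, data,
                    method = c("loglinear", "nls")) {
  method <- match.arg(method)
  if ("valid" %in% names(data)) data <- data[data$valid, , drop = FALSE]
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  u <- mf[[2L]]
  if (length(y) < 3L)
    stop("insufficient data: need at least 3 valid steps to fit the exponential model")
  if (length(unique(u)) < 2L)
    stop("insufficient data: need at least 2 distinct speeds")
  if (any(y <= 0))
    stop("nonpositive MO2 among valid steps; cannot fit on the log scale")
  lfit <- stats::lm(log(y) ~ u)
  a <- unname(exp(stats::coef(lfit)[1L]))
  b <- unname(stats::coef(lfit)[2L])
  r2 <- if (stats::var(log(y)) == 0) NA_real_ else
    1 - sum(stats::residuals(lfit)^2) / sum((log(y) - mean(log(y)))^2)
  if (method == "nls" && sum(stats::residuals(lfit)^2) > 1e-20) {
    # skip refinement on an exact fit: nls cannot iterate from a
    # zero-residual optimum
    nfit <- stats::nls(y ~ a * exp(b * u), start = list(a = a, b = b),
                       control = stats::nls.control(maxiter = 200))
    a <- unname(stats::coef(nfit)["a"])
    b <- unname(stats::coef(nfit)["b"])
  }
  structure(list(
    coefficients = c(a = a, b = b), smr = a, r2 = r2,
    sigma_log = stats::sigma(lfit), n = length(y),
    data = data.frame(speed = u, mo2 = y), method = method,
    logfit = lfit, call = match.call()
  ), class = "mo2_fit")
}

#' @export
print.mo2_fit <- function(x, digits = 4, ...) {
  cat("Exponential MO2-speed fit: MO2(U) = a * exp(b * U)\n")
  print(signif(x$coefficients, digits))
  cat(sprintf("SMR (MO2 at U = 0): %s mg O2 kg^-1 h^-1; n = %d steps; R^2(log) = %s\n",
              format(signif(x$smr, digits)), x$n,
              if (is.na(x$r2)) "NA" else format(signif(x$r2, digits))))
  invisible(x)
}

#' @export
coef.mo2_fit <- function(object, ...) object$coefficients

#' @export
predict.mo2_fit <- function(object, newdata = NULL, speed = NULL, ...) {
  if (is.null(speed)) {
    speed <- if (is.null(newdata)) object$data$speed else newdata$speed
  }
  a <- object$coefficients[["a"]]; b <- object$coefficients[["b"]]
  a * exp(b * speed)
}

#' @export
fitted.mo2_fit <- function(object, ...) predict(object)

#' @export
residuals.mo2_fit <- function(object, type = c("log", "response"), ...) {
  type <- match.arg(type)
  if (type == "log") log(object$data$mo2) - log(fitted(object))
  else object$data$mo2 - fitted(object)
}

#' @export
summary.mo2_fit <- function(object, ...) {
  out <- list(fit = object,
              coef_table = suppressWarnings(summary(object$logfit)$coefficients))
  class(out) <- "summary.mo2_fit"
  out
}

#' @export
print.summary.mo2_fit <- function(x, ...) {
  print(x$fit)
  cat("\nLog-scale regression coefficients:\n")
  stats::printCoefmat(x$coef_table)
  invisible(x)
}

#' @export
plot.mo2_fit <- function(x, ...) {
  u <- x$data$speed
  graphics::plot(u, x$data$mo2, xlab = "Swimming speed (BL/s)",
                 ylab = expression(MO[2] ~ (mg ~ O[2] ~ kg^-1 ~ h^-1)),
                 xlim = c(0, max(u)), ylim = range(0, x$smr, x$data$mo2), ...)
  uu <- seq(0, max(u), length.out = 100)
  graphics::lines(uu, predict(x, speed = uu))
  graphics::points(0, x$smr, pch = 4)
  invisible(x)
}

#' @export
simulate.mo2_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  as.data.frame(replicate(nsim, mu * exp(stats::rnorm(length(mu), 0, object$sigma_log))))
}

#' Maximum metabolic rate
#'
#' The maximum metabolic rate (MMR) is the highest mass-standardized MO2
#' recorded over the valid steps of the incremental swim test. Because the
#' allometric scale factor is a per-fish constant, the arg-max step is the
#' same whether taken on scaled or unscaled values.
#'
#' @param records A \code{mo2_records} data frame (or any frame with
#'   \code{scaled_mo2} and optionally \code{valid}, \code{step_index}).
#' @return MMR, mg O2 kg^-1 h^-1, with attribute \code{"step_index"} of the
#'   first step attaining it.
#' @export
compute_mmr <- function(records) {
  if ("valid" %in% names(records)) records <- records[records$valid, , drop = FALSE]
  if (nrow(records) == 0L) stop("insufficient data: no valid steps for MMR")
  i <- which.max(records$scaled_mo2)  # first occurrence on ties
  structure(records$scaled_mo2[i],
            step_index = if ("step_index" %in% names(records)) records$step_index[i] else i)
}

#' Aerobic scope
#'
#' Aerobic scope (AS) is the difference between maximum and standard
#' metabolic rate, the oxygen budget available beyond maintenance. A
#' negative scope is returned (with a warning) rather than suppressed, as
#' it signals a failed SMR extrapolation.
#'
#' @param smr,mmr Standard and maximum metabolic rates, mg O2 kg^-1 h^-1.
#' @return AS = MMR - SMR.
#' @export
compute_as <- function(smr, mmr) {
  stopifnot(is.finite(smr), is.finite(mmr))
  as <- mmr - smr
  if (as < 0) warning("negative aerobic scope (MMR < SMR): likely SMR fit failure")
  as
}

#' Critical swimming speed
#'
#' \deqn{U_{crit} = U_t + (t_1 / t) \, U_1} where \eqn{U_t} is the highest
#' velocity maintained for a complete step, \eqn{t_1} the time swum at the
#' fatigue step, \eqn{t} the full step duration and \eqn{U_1} the velocity
#' increment.
#'
#' @param u_t Last fully completed step speed, BL/s.
#' @param t1 Time swum at the fatigue step, minutes.
#' @param t Full step duration, minutes (default 14).
#' @param u1 Velocity increment, BL/s (default 0.3).
#' @return Ucrit in BL/s (vectorized).
#' @examples
#' compute_ucrit(2.1, 7) # 2.25
#' @export
compute_ucrit <- function(u_t, t1, t = 14, u1 = 0.3) {
  if (any(t <= 0)) stop("configuration error: step duration t must be positive")
  if (any(t1 < 0 | t1 > t)) stop("t1 must lie in [0, t]")
  if (any(u_t < 0)) stop("u_t must be nonnegative")
  u_t + (t1 / t) * u1
}

#' Assemble per-fish metabolic traits
#'
#' Combines the exponential fit (SMR), the observed maximum (MMR), their
#' difference (AS) and the critical swimming speed into one trait record.
#'
#' @param records Per-step MO2 records from \code{\link{process_trial}}.
#' @param ucrit_inputs List with \code{u_t}, \code{t1} and optionally
#'   \code{t}, \code{u1} (defaults from \code{cfg}).
#' @param fish_id Identifier carried into the output.
#' @param cfg A \code{\link{respirometry_config}}.
#' @param method Estimator passed to \code{\link{fit_mo2}}.
#' @return One-row data frame: \code{fish_id}, \code{smr}, \code{mmr},
#'   \code{as}, \code{ucrit}, \code{fit_a}, \code{fit_b}, \code{fit_r2},
#'   \code{n_valid_steps}, \code{flags}.
#' @export
metabolic_traits <- function(records, ucrit_inputs, fish_id = NA_character_,
                             cfg = respirometry_config(), method = "loglinear") {
  fit <- fit_mo2(scaled_mo2 ~ speed, records, method = method)
  mmr <- compute_mmr(records)
  flags <- character(0)
  as <- withCallingHandlers(
    compute_as(fit$smr, as.numeric(mmr)),
    warning = function(w) {
      flags <<- c(flags, "negative_AS")
      invokeRestart("muffleWarning")
    })
  t_ <- if (!is.null(ucrit_inputs$t)) ucrit_inputs$t else cfg$step_duration
  u1 <- if (!is.null(ucrit_inputs$u1)) ucrit_inputs$u1 else cfg$step_increment
  ucrit <- compute_ucrit(ucrit_inputs$u_t, ucrit_inputs$t1, t_, u1)
  if (any(records$flag_negative)) flags <- c(flags, "negative_MO2_step")
  data.frame(fish_id = fish_id, smr = fit$smr, mmr = as.numeric(mmr), as = as,
             ucrit = ucrit, fit_a = fit$coefficients[["a"]],
             fit_b = fit$coefficients[["b"]], fit_r2 = fit$r2,
             n_valid_steps = fit$n,
             flags = paste(flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Write a traits table to CSV
#'
#' @param traits Data frame of per-fish traits.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_traits <- function(traits, path) {
  utils::write.csv(traits, path, row.names = FALSE)
  invisible(path)
}
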
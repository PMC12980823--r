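## Somatic indices, egg-production metrics and mortality rates.

#' Somatic index
#'
#' Organ weight as a percentage of body weight (hepatosomatic index for
#' liver, gonadosomatic index for gonad):
#' \deqn{\mathrm{index}(\%) = 100 \times \mathrm{organ\ weight} /
#'   \mathrm{body\ weight}.}
#'
#' @param organ_weight,body_weight Weights in grams; \code{body_weight}
#'   must be positive. Vectorized.
#' @return Index in percent.
#' @examples
#' somatic_index(0.05, 2.5) # 2
#' @export
somatic_index <- function(organ_weight, body_weight) {
  if (any(body_weight <= 0)) stop("data error: body weight must be positive")
  if (any(organ_weight < 0)) stop("data error: organ weight must be nonnegative")
  100 * organ_weight / body_weight
}

validate_egg_series <- function(series) {
  need <- c("day", "egg_count", "n_females")
  miss <- setdiff(need, names(series))
  if (length(miss)) stop("egg series missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(series$day) || is.unsorted(series$day))
    stop("day must be unique and increasing")
  if (any(series$egg_count < 0) || any(series$egg_count != floor(series$egg_count)))
    stop("egg counts must be nonnegative integers")
  if (any(series$n_females <= 0)) stop("n_females must be positive on every day")
  series
}

#' Daily per-female egg production
#'
#' Each day's egg count normalized by the number of females present that
#' day; a day-varying female count (from a mortality log) is supported via
#' the \code{n_females} column.
#'
#' @param series Data frame with columns \code{day}, \code{egg_count},
#'   \code{n_females} (one row per day, one aquarium).
#' @return Data frame \code{day}, \code{daily} (eggs female^-1 day^-1).
#' @export
daily_egg_production <- function(series) {
  series <- validate_egg_series(series)
  data.frame(day = series$day, daily = series$egg_count / series$n_females)
}

#' Cumulative per-female egg production
#'
#' Running sum of the daily per-female values, so the cumulative series is
#' exactly the prefix-sum of the daily one.
#'
#' @inheritParams daily_egg_production
#' @return Data frame \code{day}, \code{cumulative} (eggs female^-1).
#' @export
cumulative_egg_production <- function(series) {
  d <- daily_egg_production(series)
  data.frame(day = d$day, cumulative = cumsum(d$daily))
}

#' Rate of change of egg production over time
#'
#' Ordinary least-squares slope of the daily or cumulative per-female egg
#' production on day index, summarizing the reproductive trend over the
#' exposure window.
#'
#' @inheritParams daily_egg_production
#' @param mode \code{"daily"} or \code{"cumulative"}.
#' @return Named vector \code{slope}, \code{se}, \code{p}.
#' @export
production_slope <- function(series, mode = c("daily", "cumulative")) {
  mode <- match.arg(mode)
  d <- if (mode == "daily") daily_egg_production(series)
       else cumulative_egg_production(series)
  y <- d[[2L]]
  if (nrow(d) < 3L) stop("need at least 3 days to estimate a slope")
  fit <- stats::lm(y ~ d$day)
  sm <- summary(fit)$coefficients
  c(slope = sm[2L, 1L], se = sm[2L, 2L], p = sm[2L, 4L])
}

#' Mortality rate
#'
#' @param deaths,total Nonnegative integer counts, \code{deaths <= total},
#'   \code{total > 0}.
#' @return List with \code{percent} (exact) and \code{rounded} (nearest
#'   integer percent, half-up) as used in reporting.
#' @examples
#' mortality_rate(41, 684)$rounded # 6
#' @export
mortality_rate <- function(deaths, total) {
  if (total <= 0) stop("total must be positive")
  if (deaths < 0 || deaths > total) stop("deaths must lie in [0, total]")
  pct <- 100 * deaths / total
  list(percent = pct, rounded = round_half_up(pct))
}

#' Read an egg-count table
#'
#' CSV dialect: \code{aquarium_id, day, egg_count, n_females, period}.
#'
#' @param path CSV path.
#' @return List of per-aquarium egg series data frames, named by aquarium.
#' @export
read_egg_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("aquarium_id", "day", "egg_count", "n_females")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("egg table missing columns: ", paste(miss, collapse = ", "))
  lapply(split(raw, raw$aquarium_id), validate_egg_series)
}

#' Read a somatic-index table
#'
#' CSV dialect: \code{fish_id, organ, organ_weight_g, body_weight_g};
#' computes the index on read.
#'
#' @param path CSV path.
#' @return Data frame with an added \code{index_pct} column.
#' @export
read_somatic_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fish_id", "organ", "organ_weight_g", "body_weight_g")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("somatic table missing columns: ", paste(miss, collapse = ", "))
  if (!all(raw$organ %in% c("liver", "gonad")))
    stop("organ must be 'liver' or 'gonad'")
  raw$index_pct <- somatic_index(raw$organ_weight_g, raw$body_weight_g)
  raw
}
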
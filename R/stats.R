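## Concentration-by-temperature inferential layer: linear (mixed) models
## with a PFAS x temperature interaction, per-temperature simple slopes,
## AIC/BIC/LRT-guided model selection, and distribution-aware two-sample
## tests.

#' Log-transform tissue concentrations
#'
#' Natural log of a concentration vector. When zeros are present (left-
#' censored values set to zero), a constant equal to half the smallest
#' method reporting limit is added to every value before taking logs, and
#' the offset used is recorded in the \code{"offset"} attribute.
#'
#' @param x Nonnegative concentrations.
#' @param offset Offset added when zeros are present (default half the
#'   smallest tissue MRL).
#' @return \code{log(x)} or \code{log(x + offset)}, with attribute
#'   \code{"offset"} (0 when no shift was needed).
#' @export
log_conc <- function(x, offset = min(mrl_tissue) / 2) {
  if (any(x < 0, na.rm = TRUE)) stop("concentrations must be nonnegative")
  used <- if (any(x == 0, na.rm = TRUE)) offset else 0
  structure(log(x + used), offset = used)
}

#' Fit a concentration-by-temperature interaction model
#'
#' Fits \code{response ~ log(conc) * temperature}, as a linear model or,
#' when a grouping factor (aquarium identity) with at least two levels is
#' supplied, as a linear mixed model with a random intercept per group.
#' The interaction is tested with a Type III Wald test; per-temperature
#' simple slopes are attached only when that test is significant at the
#' 0.05 level, mirroring the convention of plotting within-temperature
#' regression lines only under a significant interaction.
#'
#' @param data Data frame with the response, concentration, temperature
#'   and (optionally) grouping columns.
#' @param response,pfas Column names of the response trait and the raw
#'   concentration (log-transformed internally via \code{\link{log_conc}}
#'   unless \code{log_pfas = FALSE}).
#' @param temperature Column name of the temperature variable.
#' @param temp_factor Model temperature as a categorical factor
#'   (\code{TRUE}, default) or as a continuous covariate.
#' @param random Optional column name of the grouping factor (random
#'   intercept). With fewer than two observed levels the model falls back
#'   to ordinary least squares (noted in the result).
#' @param transform_response \code{"none"} (default) or \code{"log"}
#'   (refit convention when residual diagnostics fail).
#' @param log_pfas Log-transform the concentration (default TRUE).
#' @param alpha Significance level gating the simple-slope report
#'   (default 0.05).
#' @return Object of class \code{"pfas_fit"}: the fitted \code{model}, the
#'   \code{spec} used, \code{coefficients} table, \code{interaction_p},
#'   \code{simple_slopes} (data frame or NULL), \code{aic}, \code{bic},
#'   \code{logLik}, \code{shapiro_p} (residual normality), and
#'   \code{provenance} (log offset, fallback notes).
#' @export
fit_interaction_model <- function(data, response, pfas,
                                  temperature = "temp",
                                  temp_factor = TRUE,
                                  random = NULL,
                                  transform_response = c("none", "log"),
                                  log_pfas = TRUE,
                                  alpha = 0.05) {
  transform_response <- match.arg(transform_response)
  d <- as.data.frame(data)
  for (col in c(response, pfas, temperature))
    if (!col %in% names(d)) stop("column not found: ", col)
  if (temp_factor) {
    d$.temp <- factor(d[[temperature]])
    if (nlevels(d$.temp) < 2L)
      stop("singular design: only one temperature level; fit a slope-only model instead")
    tab <- table(d$.temp)
    if (any(tab < 3L))
      stop("need at least 3 observations per temperature level")
  } else {
    d$.temp <- d[[temperature]]
    if (length(unique(d$.temp)) < 2L)
      stop("singular design: only one temperature level; fit a slope-only model instead")
  }
  offset_used <- 0
  if (log_pfas) {
    lx <- log_conc(d[[pfas]])
    offset_used <- attr(lx, "offset")
    d$.x <- as.numeric(lx)
  } else d$.x <- d[[pfas]]
  d$.y <- if (transform_response == "log") log(d[[response]]) else d[[response]]

  notes <- character(0)
  use_mixed <- FALSE
  if (!is.null(random)) {
    if (!random %in% names(d)) stop("column not found: ", random)
    if (length(unique(d[[random]])) >= 2L) use_mixed <- TRUE
    else notes <- c(notes, "single grouping level: fell back to ordinary least squares")
  }
  if (use_mixed) {
    d$.g <- factor(d[[random]])
    mod <- lme4::lmer(.y ~ .x * .temp + (1 | .g), data = d, REML = TRUE)
    coefs <- as.data.frame(summary(mod)$coefficients)
  } else {
    mod <- stats::lm(.y ~ .x * .temp, data = d)
    coefs <- as.data.frame(suppressWarnings(summary(mod)$coefficients))
  }
  an <- tryCatch(car::Anova(mod, type = 3), error = function(e) e)
  if (inherits(an, "error")) {
    # an exactly deterministic relationship saturates the Wald test;
    # report p = 0 rather than failing the batch
    if (!use_mixed && sum(stats::residuals(mod)^2) < 1e-12) {
      interaction_p <- 0
      notes <- c(notes, "zero residual variance: interaction p set to 0")
    } else stop(an)
  } else {
    ia_row <- grep(".x:.temp", rownames(an), fixed = TRUE)
    pcol <- grep("^Pr", colnames(an))
    interaction_p <- an[ia_row, pcol]
  }

  slopes <- NULL
  if (is.finite(interaction_p) && interaction_p < alpha && temp_factor) {
    slopes <- do.call(rbind, lapply(levels(d$.temp), function(lv) {
      ss <- simple_slopes(d[d$.temp == lv, , drop = FALSE], ".y", ".x",
                          log_pfas = FALSE)
      cbind(data.frame(level = lv), as.data.frame(as.list(ss)))
    }))
  }
  res <- try(stats::residuals(mod), silent = TRUE)
  shapiro_p <- if (!inherits(res, "try-error") && length(res) >= 3 &&
                   length(res) <= 5000 && stats::var(res) > 0)
    tryCatch(stats::shapiro.test(res)$p.value, error = function(e) NA_real_)
  else NA_real_

  structure(list(
    model = mod,
    spec = list(response = response, pfas = pfas, temperature = temperature,
                temp_factor = temp_factor, random = if (use_mixed) random else NULL,
                transform_response = transform_response, log_pfas = log_pfas),
    coefficients = coefs,
    interaction_p = interaction_p,
    simple_slopes = slopes,
    aic = stats::AIC(mod), bic = stats::BIC(mod),
    logLik = as.numeric(stats::logLik(mod)),
    shapiro_p = shapiro_p,
    provenance = list(log_offset = offset_used, notes = notes)
  ), class = "pfas_fit")
}

#' @export
print.pfas_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Concentration-by-temperature model: %s ~ %s%s * %s%s\n",
              x$spec$response, if (x$spec$log_pfas) "log " else "", x$spec$pfas,
              x$spec$temperature,
              if (!is.null(x$spec$random)) paste0(" + (1|", x$spec$random, ")") else ""))
  cat(sprintf("Interaction p = %s; AIC = %.1f; BIC = %.1f\n",
              format.pval(x$interaction_p, digits), x$aic, x$bic))
  if (!is.null(x$simple_slopes)) {
    cat("Per-temperature simple slopes:\n")
    print(x$simple_slopes, digits = digits)
  } else cat("Interaction not significant at 0.05: no simple slopes reported.\n")
  invisible(x)
}

#' Per-temperature simple slope
#'
#' Ordinary least-squares regression of a trait on (log-) concentration
#' within one temperature level.
#'
#' @param data Data frame (already subset to one level, or pass
#'   \code{level}/\code{temperature} to subset here).
#' @param response,pfas Column names.
#' @param temperature,level Optional: subset \code{data} to rows where
#'   \code{data[[temperature]] == level} first.
#' @param log_pfas Log-transform the concentration (default TRUE).
#' @return Named vector \code{slope}, \code{se}, \code{p}, \code{r2}.
#' @export
simple_slopes <- function(data, response, pfas, temperature = NULL, level = NULL,
                          log_pfas = TRUE) {
  d <- as.data.frame(data)
  if (!is.null(temperature) && !is.null(level))
    d <- d[d[[temperature]] == level, , drop = FALSE]
  if (nrow(d) < 3L)
    stop("degenerate level: need at least 3 observations for a simple slope")
  x <- if (log_pfas) as.numeric(log_conc(d[[pfas]])) else d[[pfas]]
  y <- d[[response]]
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  c(slope = sm$coefficients[2L, 1L], se = sm$coefficients[2L, 2L],
    p = sm$coefficients[2L, 4L], r2 = sm$r.squared)
}

#' Select among candidate model formulas
#'
#' Fits each candidate formula by OLS (or a mixed model when \code{random}
#' is given) and returns the one preferred by AIC, reporting BIC and, for
#' nested candidates, the likelihood-ratio test p-value. When the AIC-best
#' model contains sex terms and a candidate identical but for those terms
#' is present, the simpler sexless model is retained unless the LRT is
#' significant (the drop-sex convention).
#'
#' @param formulas Named or unnamed list of model formulas on \code{data}.
#' @param data Data frame.
#' @param random Optional grouping column name (random intercept added to
#'   every candidate).
#' @param alpha LRT significance level for the drop-sex rule (default 0.05).
#' @return List: \code{best} (index), \code{formula}, \code{table}
#'   (AIC/BIC/logLik per candidate), \code{lrt_p} (sex-term LRT when
#'   applied, else NA).
#' @export
model_select <- function(formulas, data, random = NULL, alpha = 0.05) {
  fit1 <- function(f) {
    if (is.null(random)) stats::lm(f, data = data)
    else {
      rhs <- paste(deparse(f[[3L]]), collapse = " ")
      f2 <- stats::as.formula(paste(deparse(f[[2L]]), "~", rhs,
                                    "+ (1 |", random, ")"))
      lme4::lmer(f2, data = data, REML = FALSE)
    }
  }
  fits <- lapply(formulas, fit1)
  tab <- data.frame(
    formula = vapply(formulas, function(f) paste(deparse(f), collapse = ""), character(1)),
    AIC = vapply(fits, stats::AIC, numeric(1)),
    BIC = vapply(fits, stats::BIC, numeric(1)),
    logLik = vapply(fits, function(m) as.numeric(stats::logLik(m)), numeric(1))
  )
  best <- which.min(tab$AIC)  # ties: first candidate retained
  lrt_p <- NA_real_
  has_sex <- grepl("\\bsex\\b", tab$formula)
  if (has_sex[best]) {
    stripped <- gsub("\\s", "", gsub("\\*", ":", tab$formula[best]))
    cand <- which(!has_sex & vapply(seq_along(fits), function(i) {
      t1 <- unlist(strsplit(gsub("\\s", "", gsub("\\*", ":", tab$formula[i])), "[~+]"))
      t2 <- unlist(strsplit(stripped, "[~+]"))
      all(t1 %in% t2)
    }, logical(1)))
    if (length(cand)) {
      simpler <- cand[which.min(tab$AIC[cand])]
      a <- stats::anova(fits[[simpler]], fits[[best]])
      pc <- grep("^Pr", colnames(a))
      lrt_p <- a[nrow(a), pc]
      if (!is.finite(lrt_p) || lrt_p >= alpha) best <- simpler
    }
  }
  list(best = best, formula = formulas[[best]], table = tab, lrt_p = lrt_p)
}

#' Two-sample location test with distribution-guided choice
#'
#' Welch's t test or the Wilcoxon rank-sum test; with \code{method =
#' "auto"} the Wilcoxon test is chosen whenever a Shapiro-Wilk normality
#' check (alpha = 0.05) fails in either sample (constant samples count as
#' failing).
#'
#' @param x,y Numeric samples.
#' @param method \code{"auto"}, \code{"welch_t"} or \code{"wilcoxon"}.
#' @return List \code{statistic}, \code{p}, \code{method}. Degenerate
#'   input (both samples constant and equal) returns \code{NA}s with a
#'   warning.
#' @export
two_sample_test <- function(x, y, method = c("auto", "welch_t", "wilcoxon")) {
  method <- match.arg(method)
  const <- function(v) stats::var(v) == 0
  if (const(x) && const(y) && x[1L] == y[1L]) {
    warning("degenerate samples: both constant and equal; test undefined")
    return(list(statistic = NA_real_, p = NA_real_, method = "degenerate"))
  }
  if (method == "auto") {
    normal <- function(v) {
      if (length(v) < 3L || const(v)) return(FALSE)
      stats::shapiro.test(v)$p.value >= 0.05
    }
    method <- if (normal(x) && normal(y)) "welch_t" else "wilcoxon"
  }
  if (method == "welch_t") {
    tt <- stats::t.test(x, y)
    list(statistic = unname(tt$statistic), p = tt$p.value, method = "welch_t")
  } else {
    wt <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
    list(statistic = unname(wt$statistic), p = wt$p.value, method = "wilcoxon")
  }
}
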
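## Tissue-residue distribution metrics for PFOS/PFOA: censoring at the
## method reporting limit, compound sums, PFOS fraction, tissue percent
## shares, organ:blood ratios and fold-change ranges.

#' Method reporting limits
#'
#' Default method reporting limits (MRLs) for the two compounds, below
#' which a measurement is censored to zero prior to analysis.
#'
#' @format Named numeric vectors: \code{mrl_tissue} in ng g^-1 wet weight
#'   (PFOS 0.35, PFOA 0.49), \code{mrl_water} in ng L^-1 (PFOS 2.3,
#'   PFOA 1.8).
#' @name mrl
NULL

#' @rdname mrl
#' @export
mrl_tissue <- c(PFOS = 0.35, PFOA = 0.49)

#' @rdname mrl
#' @export
mrl_water <- c(PFOS = 2.3, PFOA = 1.8)

TISSUES <- c("muscle", "liver", "blood", "ovary", "egg", "whole_body")
SHARE_TISSUES <- c("blood", "liver", "muscle", "ovary")

## round half away from zero, the reporting convention for integer folds
## and percentages (base round() is half-to-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Left-censor a concentration at its reporting limit
#'
#' Values below the method reporting limit are considered zero prior to
#' analysis; values at or above it are kept as reported. Idempotent.
#'
#' @param conc Raw concentration(s), same units as \code{mrl}; must be
#'   nonnegative.
#' @param mrl Reporting limit(s), recycled against \code{conc}.
#' @return Censored concentration(s), with attribute \code{"below_mrl"}
#'   (logical vector).
#' @examples
#' censor_conc(0.20, 0.35) # 0, flagged
#' censor_conc(0.35, 0.35) # kept
#' @export
censor_conc <- function(conc, mrl) {
  if (any(conc < 0, na.rm = TRUE)) stop("data error: negative concentration")
  below <- conc < mrl
  out <- ifelse(below, 0, conc)
  attr(out, "below_mrl") <- below
  out
}

#' Apply MRL censoring to a long residue table
#'
#' @param panel Long data frame with at least \code{compound} and
#'   \code{conc} columns; an \code{mrl} column is used when present,
#'   otherwise looked up from \code{\link{mrl_tissue}} by compound.
#' @return The panel with \code{conc} censored and a \code{below_mrl}
#'   logical column.
#' @export
apply_censoring <- function(panel) {
  mrl <- if ("mrl" %in% names(panel)) panel$mrl else unname(mrl_tissue[panel$compound])
  if (anyNA(mrl)) stop("unknown compound(s): no reporting limit available")
  cc <- censor_conc(panel$conc, mrl)
  panel$conc <- as.numeric(cc)
  panel$below_mrl <- attr(cc, "below_mrl")
  panel
}

## pull one (fish, tissue, compound) concentration from a long panel
panel_conc <- function(panel, fish_id, tissue, compound) {
  r <- panel[panel$fish_id == fish_id & panel$tissue == tissue &
               panel$compound == compound, "conc"]
  if (length(r) == 0L) return(NA_real_)
  if (length(r) > 1L) stop("duplicate (fish, tissue, compound) entry: ",
                           fish_id, "/", tissue, "/", compound)
  r
}

#' Summed PFAS concentration in a tissue
#'
#' ΣPFAS = PFOS + PFOA for one fish and tissue (censored zeros count as
#' zero; no substitution at MRL/2).
#'
#' @param panel Long residue data frame (\code{fish_id}, \code{tissue},
#'   \code{compound}, \code{conc}).
#' @param fish_id,tissue Which panel cell to sum.
#' @return ΣPFAS in ng g^-1 wet weight.
#' @export
sum_pfas <- function(panel, fish_id, tissue) {
  pfos <- panel_conc(panel, fish_id, tissue, "PFOS")
  pfoa <- panel_conc(panel, fish_id, tissue, "PFOA")
  if (is.na(pfos) || is.na(pfoa))
    stop("missing data: both PFOS and PFOA are required for ΣPFAS (",
         fish_id, "/", tissue, ")")
  pfos + pfoa
}

#' PFOS fraction of the summed PFAS concentration
#'
#' @inheritParams sum_pfas
#' @return 100 x PFOS / (PFOS + PFOA), in percent; \code{NA} when the sum
#'   is zero (undefined, not zero).
#' @export
pfos_fraction <- function(panel, fish_id, tissue) {
  pfos <- panel_conc(panel, fish_id, tissue, "PFOS")
  total <- sum_pfas(panel, fish_id, tissue)
  if (total == 0) return(NA_real_)
  100 * pfos / total
}

#' Percent share of a compound across the four core tissues
#'
#' The percent share of a tissue is its concentration divided by the sum of
#' concentrations in blood, liver, muscle and ovary from the same fish. All
#' four tissues must be present; incomplete panels are an error (the fish
#' is excluded upstream and logged).
#'
#' @param panel Long residue data frame.
#' @param fish_id Fish to evaluate.
#' @param compound \code{"PFOS"}, \code{"PFOA"} or \code{"total"} (ΣPFAS).
#' @return Named numeric vector of shares (percent) over blood, liver,
#'   muscle, ovary; sums to 100 when the denominator is positive, all
#'   \code{NA} when it is zero.
#' @export
tissue_percent_share <- function(panel, fish_id, compound = c("PFOS", "PFOA", "total")) {
  compound <- match.arg(compound)
  conc <- vapply(SHARE_TISSUES, function(ti) {
    if (compound == "total") {
      tryCatch(sum_pfas(panel, fish_id, ti), error = function(e) NA_real_)
    } else panel_conc(panel, fish_id, ti, compound)
  }, numeric(1))
  if (anyNA(conc))
    stop("incomplete panel for fish ", fish_id, ": missing ",
         paste(SHARE_TISSUES[is.na(conc)], collapse = ", "))
  total <- sum(conc)
  if (total == 0) return(stats::setNames(rep(NA_real_, 4L), SHARE_TISSUES))
  100 * conc / total
}

#' Organ-to-blood concentration ratio
#'
#' Partitioning descriptor: concentration in muscle, liver or ovary
#' relative to the blood concentration of the same fish.
#'
#' @inheritParams tissue_percent_share
#' @param organ One of \code{"muscle"}, \code{"liver"}, \code{"ovary"}.
#' @return Dimensionless ratio; \code{NA} when blood concentration is zero
#'   (excluded, logged by callers).
#' @export
organ_blood_ratio <- function(panel, fish_id, organ = c("muscle", "liver", "ovary"),
                              compound = c("PFOS", "PFOA", "total")) {
  organ <- match.arg(organ)
  compound <- match.arg(compound)
  get1 <- function(ti) {
    if (compound == "total") sum_pfas(panel, fish_id, ti)
    else panel_conc(panel, fish_id, ti, compound)
  }
  blood <- get1("blood")
  org <- get1(organ)
  if (is.na(blood) || is.na(org))
    stop("missing data for ", fish_id, ": need ", organ, " and blood")
  if (blood == 0) return(NA_real_)
  org / blood
}

#' Fold-change range between two concentration ranges
#'
#' Range-wise fold change of an exposed group over a control group: the
#' minimum fold is the exposed low bound over the control high bound, the
#' maximum fold the exposed high over the control low. Integer folds use
#' half-up rounding, as in reporting conventions.
#'
#' @param control,exposed Length-2 numeric vectors \code{c(lo, hi)} of
#'   strictly positive concentrations.
#' @return List with \code{fold} (exact \code{c(min, max)}) and
#'   \code{rounded} (nearest integers, half-up).
#' @examples
#' fold_change_range(c(25.8, 56.5), c(1470, 1530))$rounded # 26 59
#' @export
fold_change_range <- function(control, exposed) {
  stopifnot(length(control) == 2L, length(exposed) == 2L)
  if (any(control <= 0) || any(exposed <= 0))
    stop("undefined fold: all range bounds must be positive")
  control <- sort(control); exposed <- sort(exposed)
  fold <- c(min = exposed[1L] / control[2L], max = exposed[2L] / control[1L])
  list(fold = fold, rounded = round_half_up(fold))
}

#' Exposure-to-criterion concentration ratio
#'
#' How far an exposure concentration sits above (ratio > 1) or below
#' (ratio < 1) a water-quality criterion, both in the same units.
#'
#' @param exposure,criterion Concentrations in identical units.
#' @return \code{exposure / criterion}.
#' @export
criterion_ratio <- function(exposure, criterion) {
  if (any(criterion <= 0)) stop("criterion must be positive")
  exposure / criterion
}

#' Read a long-format residue table
#'
#' CSV dialect: \code{fish_id, tissue, compound, conc_ng_g, mrl_ng_g}.
#'
#' @param path CSV path.
#' @param censor Apply \code{\link{apply_censoring}} on read (default TRUE).
#' @return Long residue data frame with canonical column names.
#' @export
read_residue_table <- function(path, censor = TRUE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fish_id", "tissue", "compound", "conc_ng_g")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("residue table missing columns: ", paste(miss, collapse = ", "))
  if (!all(raw$tissue %in% TISSUES))
    stop("unknown tissue(s): ", paste(setdiff(unique(raw$tissue), TISSUES), collapse = ", "))
  if (!all(raw$compound %in% c("PFOS", "PFOA")))
    stop("unknown compound(s): ",
         paste(setdiff(unique(raw$compound), c("PFOS", "PFOA")), collapse = ", "))
  df <- data.frame(fish_id = as.character(raw$fish_id), tissue = raw$tissue,
                   compound = raw$compound, conc = raw$conc_ng_g,
                   stringsAsFactors = FALSE)
  if ("mrl_ng_g" %in% names(raw)) df$mrl <- raw$mrl_ng_g
  if (censor) df <- apply_censoring(df)
  df
}
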
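## Pipeline entry points binding the stages into experiment-shaped runs:
## trace -> traits, residues -> distribution metrics, merged data -> model
## reports. File dialects are CSV (RFC 4180); units at file boundaries are
## grams, millimetres, seconds, mg/L and ng/g, converted in the readers.

#' Write oxygen traces in the file dialect
#'
#' Inverse of \code{\link{read_oxygen_traces}} (time back in seconds).
#'
#' @param traces One oxygen trace data frame or a list of them.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_trace_csv <- function(traces, path) {
  if (is.data.frame(traces)) traces <- list(traces)
  df <- do.call(rbind, lapply(traces, as.data.frame))
  out <- data.frame(trial_id = df$trial_id, time_s = df$time_h * 3600,
                    o2_mgL = df$o2, phase = df$phase, step_index = df$step_index,
                    speed_bls = df$speed, temp_C = df$temp)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a fish biometrics table
#'
#' CSV dialect \code{fish_id, mass_g, length_mm, sex, temp_C, pfas_group,
#' aquarium_id}; mass is converted to kg in the \code{mass_kg} column.
#'
#' @param path CSV path.
#' @return Data frame with an added \code{mass_kg} column.
#' @export
read_fish_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fish_id", "mass_g")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("fish table missing columns: ", paste(miss, collapse = ", "))
  if (any(raw$mass_g <= 0)) stop("fish mass must be positive")
  raw$fish_id <- as.character(raw$fish_id)
  raw$mass_kg <- raw$mass_g / 1000
  raw
}

#' Respirometry pipeline: traces to per-fish metabolic traits
#'
#' Processes every trial in a trace table through slope extraction,
#' background correction, mass standardization and trait fitting. Trials
#' are matched to fish by \code{trial_id == fish_id}. A trial that fails
#' its preconditions is reported in the QC table with a reason and the run
#' continues.
#'
#' @param traces A list of oxygen traces (as from
#'   \code{\link{read_oxygen_traces}}) or a path to a trace CSV.
#' @param fish A fish table data frame (see \code{\link{read_fish_table}})
#'   or a path to one.
#' @param ucrit_log Data frame \code{fish_id, u_t, t1_min} (or a CSV path):
#'   the behavioural fatigue log.
#' @param cfg A \code{\link{respirometry_config}}.
#' @param out_dir Optional directory; when given, writes
#'   \code{traits.csv} and \code{qc_report.csv} there.
#' @return List: \code{traits} (one row per successful trial), \code{qc}
#'   (per-trial status, invalid-slope counts, flags, reasons).
#' @export
pipeline_respirometry <- function(traces, fish, ucrit_log,
                                  cfg = respirometry_config(), out_dir = NULL) {
  if (is.character(traces)) traces <- read_oxygen_traces(traces)
  if (is.character(fish)) fish <- read_fish_table(fish)
  if (is.character(ucrit_log)) ucrit_log <- utils::read.csv(ucrit_log, stringsAsFactors = FALSE)
  if (length(traces) == 0L) stop("no trials found in input")
  traits <- list(); qc <- list()
  for (id in names(traces)) {
    row <- fish[fish$fish_id == id, , drop = FALSE]
    ul <- ucrit_log[ucrit_log$fish_id == id, , drop = FALSE]
    status <- tryCatch({
      if (nrow(row) != 1L) stop("no unique fish record for trial ", id)
      if (nrow(ul) != 1L) stop("no unique fatigue-log record for trial ", id)
      recs <- process_trial(traces[[id]], row$mass_kg, cfg)
      tr <- metabolic_traits(recs, list(u_t = ul$u_t, t1 = ul$t1_min), id, cfg)
      traits[[id]] <- tr
      data.frame(fish_id = id, status = "ok",
                 n_steps = nrow(recs), n_invalid = sum(!recs$valid),
                 flags = tr$flags, reason = "", stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(fish_id = id, status = "failed", n_steps = NA_integer_,
                 n_invalid = NA_integer_, flags = "",
                 reason = conditionMessage(e), stringsAsFactors = FALSE)
    })
    qc[[id]] <- status
  }
  out <- list(traits = if (length(traits)) do.call(rbind, traits) else NULL,
              qc = do.call(rbind, qc))
  rownames(out$qc) <- NULL
  if (!is.null(out$traits)) rownames(out$traits) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(out$traits)) write_traits(out$traits, file.path(out_dir, "traits.csv"))
    utils::write.csv(out$qc, file.path(out_dir, "qc_report.csv"), row.names = FALSE)
  }
  out
}

group_mean_se <- function(x) {
  x <- x[is.finite(x)]
  c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)), n = length(x))
}

#' Toxicokinetics pipeline: residues to distribution metrics
#'
#' Computes per-fish compound sums, PFOS fractions, tissue percent shares
#' and organ:blood ratios from a censored long residue table, then
#' summarizes them per treatment group (mean and standard error). Fish
#' with incomplete four-tissue panels or zero blood concentration are
#' excluded from the affected metric and logged with a reason code.
#'
#' @param residues Long residue data frame (or CSV path; censoring applied
#'   on read).
#' @param fish Fish table data frame or CSV path (treatment labels).
#' @param out_dir Optional output directory for the metric CSVs.
#' @return List of data frames: \code{sums} (per fish x tissue: ΣPFAS and
#'   PFOS fraction), \code{shares}, \code{ratios}, \code{group_summary},
#'   \code{exclusions}.
#' @export
pipeline_toxicokinetics <- function(residues, fish = NULL, out_dir = NULL) {
  if (is.character(residues)) residues <- read_residue_table(residues)
  if (is.character(fish)) fish <- read_fish_table(fish)
  ids <- unique(residues$fish_id)
  excl <- list()
  note <- function(id, metric, reason)
    excl[[length(excl) + 1L]] <<- data.frame(fish_id = id, metric = metric,
                                             reason = reason, stringsAsFactors = FALSE)
  sums <- do.call(rbind, lapply(ids, function(id) {
    tis <- unique(residues$tissue[residues$fish_id == id])
    do.call(rbind, lapply(tis, function(ti) {
      data.frame(fish_id = id, tissue = ti,
                 sum_pfas = sum_pfas(residues, id, ti),
                 pfos_fraction = pfos_fraction(residues, id, ti),
                 stringsAsFactors = FALSE)
    }))
  }))
  shares <- do.call(rbind, lapply(ids, function(id) {
    do.call(rbind, lapply(c("PFOS", "PFOA", "total"), function(cmp) {
      s <- tryCatch(tissue_percent_share(residues, id, cmp),
                    error = function(e) { note(id, paste0("share_", cmp),
                                               conditionMessage(e)); NULL })
      if (is.null(s)) return(NULL)
      data.frame(fish_id = id, compound = cmp, tissue = names(s),
                 share_pct = unname(s), stringsAsFactors = FALSE)
    }))
  }))
  ratios <- do.call(rbind, lapply(ids, function(id) {
    do.call(rbind, lapply(c("PFOS", "PFOA", "total"), function(cmp) {
      do.call(rbind, lapply(c("muscle", "liver", "ovary"), function(org) {
        r <- tryCatch(organ_blood_ratio(residues, id, org, cmp),
                      error = function(e) { note(id, paste0("ratio_", org, "_", cmp),
                                                 conditionMessage(e)); NA_real_ })
        if (is.na(r)) { note(id, paste0("ratio_", org, "_", cmp),
                            "blood concentration zero or missing"); return(NULL) }
        data.frame(fish_id = id, compound = cmp, organ = org, ratio = r,
                   stringsAsFactors = FALSE)
      }))
    }))
  }))
  group_summary <- NULL
  if (!is.null(fish)) {
    m <- merge(sums, fish[, c("fish_id", "temp_C", "pfas_group")], by = "fish_id")
    group_summary <- do.call(rbind, lapply(
      split(m, list(m$tissue, m$temp_C, m$pfas_group), drop = TRUE),
      function(g) {
        ms <- group_mean_se(g$sum_pfas)
        data.frame(tissue = g$tissue[1L], temp_C = g$temp_C[1L],
                   pfas_group = g$pfas_group[1L],
                   mean_sum_pfas = ms[["mean"]], se_sum_pfas = ms[["se"]],
                   n = ms[["n"]], stringsAsFactors = FALSE)
      }))
    rownames(group_summary) <- NULL
  }
  exclusions <- if (length(excl)) unique(do.call(rbind, excl)) else
    data.frame(fish_id = character(), metric = character(), reason = character())
  out <- list(sums = sums, shares = shares, ratios = ratios,
              group_summary = group_summary, exclusions = exclusions)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out)) if (!is.null(out[[nm]]))
      utils::write.csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  out
}

#' Statistics pipeline: model reports per response and compound
#'
#' Fits the concentration-by-temperature interaction model for each
#' requested response x compound combination and writes one JSON report
#' per fit plus a tidy CSV of all significant simple slopes.
#'
#' @param data Data frame holding responses, per-compound concentration
#'   columns, a temperature column and (optionally) a grouping column.
#' @param responses Character vector of response column names.
#' @param compounds Character vector of concentration column names.
#' @param temperature Temperature column name.
#' @param random Optional grouping column name.
#' @param out_dir Optional output directory (JSON per fit +
#'   \code{simple_slopes.csv}).
#' @return Named list of \code{pfas_fit} objects
#'   (\code{"<response>__<compound>"}).
#' @export
pipeline_stats <- function(data, responses, compounds, temperature = "temp_C",
                           random = NULL, out_dir = NULL) {
  fits <- list()
  for (resp in responses) for (cmp in compounds) {
    key <- paste(resp, cmp, sep = "__")
    fits[[key]] <- fit_interaction_model(data, resp, cmp,
                                         temperature = temperature,
                                         random = random)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    slope_rows <- list()
    for (key in names(fits)) {
      f <- fits[[key]]
      rep <- list(spec = f$spec,
                  coefficients = cbind(term = rownames(f$coefficients),
                                       as.data.frame(f$coefficients)),
                  interaction_p = f$interaction_p,
                  aic = f$aic, bic = f$bic, logLik = f$logLik,
                  shapiro_p = f$shapiro_p, provenance = f$provenance)
      jsonlite::write_json(rep, file.path(out_dir, paste0(key, ".json")),
                           auto_unbox = TRUE, digits = NA, null = "null")
      if (!is.null(f$simple_slopes))
        slope_rows[[key]] <- cbind(fit = key, f$simple_slopes)
    }
    slopes <- if (length(slope_rows)) do.call(rbind, slope_rows) else
      data.frame(fit = character(), level = character(), slope = numeric(),
                 se = numeric(), p = numeric(), r2 = numeric())
    utils::write.csv(slopes, file.path(out_dir, "simple_slopes.csv"),
                     row.names = FALSE)
  }
  fits
}
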
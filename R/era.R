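# Risk-quotient ecological risk assessment: per-site acute/chronic
# quotients against derived criteria, risk classification, and
# province/basin-level aggregation.

#' Read an exposure-record table from CSV
#'
#' Expected columns: `site_id`, `province`, `basin`, `mean`, and optionally
#' `reach`, `sd`, `min`, `max`, `unit` (`ug/L` or `mg/L`), `year_range`,
#' `source_id`, `flags` (semicolon-separated, e.g.
#' `near_contaminated_site;season_split`). Concentrations are converted to
#' ug/L on read.
#'
#' @param path Path to a CSV file.
#' @return Exposure-record data frame with numeric `mean`, `sd`, `min`,
#'   `max` in ug/L.
#' @export
read_exposure <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("site_id", "province", "basin")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("read_exposure(): missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("reach", "sd", "min", "max", "mean", "year_range", "source_id", "flags")) {
    if (!col %in% names(raw)) raw[[col]] <- NA
  }
  scale <- if ("unit" %in% names(raw)) ifelse(trimws(raw$unit) == "mg/L", 1000, 1) else 1
  for (col in c("mean", "sd", "min", "max")) {
    raw[[col]] <- suppressWarnings(as.numeric(raw[[col]])) * scale
  }
  raw$flags <- ifelse(is.na(raw$flags), "", as.character(raw$flags))
  ok <- !is.na(raw$mean) | !is.na(raw$min) | !is.na(raw$max)
  if (!all(ok)) {
    warning(sprintf("read_exposure(): %d record(s) carry no concentration at all",
                    sum(!ok)), call. = FALSE)
  }
  raw
}

#' Risk quotient
#'
#' QR = MEC / PNEC: the measured environmental concentration divided by the
#' predicted no-effect concentration (here, a derived water-quality
#' criterion). QR > 1 flags a significant risk.
#'
#' @param mec Measured environmental concentration(s), ug/L (>= 0).
#' @param pnec Predicted no-effect concentration, ug/L (> 0).
#' @return Dimensionless quotient(s).
#' @export
risk_quotient <- function(mec, pnec) {
  if (any(!is.finite(pnec) | pnec <= 0)) {
    stop("risk_quotient(): pnec must be positive", call. = FALSE)
  }
  if (any(mec < 0, na.rm = TRUE)) {
    stop("risk_quotient(): mec must be nonnegative", call. = FALSE)
  }
  mec / pnec
}

#' Classify a risk quotient
#'
#' Low for QR < 0.1, medium for 0.1 <= QR <= 1 (both boundary values assigned
#' to medium so the classes partition the line), high for QR > 1. Missing
#' quotients are `not_computable`.
#'
#' @param q Risk quotient(s) (>= 0 or NA).
#' @return Character vector over `low`, `medium`, `high`, `not_computable`.
#' @export
classify_risk <- function(q) {
  ifelse(is.na(q), "not_computable",
         ifelse(q < 0.1, "low", ifelse(q <= 1, "medium", "high")))
}

#' Assess exposure records against derived criteria
#'
#' Computes the acute quotient SQR = mean/SWQC and chronic quotient
#' LQR = mean/LWQC per record, plus interval quotients from mean +/- SD when
#' an SD is present (the lower bound is clipped at zero before division).
#' Records without a mean concentration are classed `not_computable`. With
#' `screen = TRUE`, records flagged `near_contaminated_site` or
#' `emergency_event` are dropped before assessment, with a log attribute.
#'
#' @param exposures Exposure-record data frame (see [read_exposure()]).
#' @param swqc,lwqc Short- and long-term criteria, ug/L (> 0).
#' @param screen Apply the exposure-selection flag screen (default TRUE).
#' @return Data frame of class `risk_results`: one row per assessed record
#'   with `sqr`, `lqr`, interval bounds, and `risk_class_s` / `risk_class_l`.
#'   Screened-out records are recorded in attribute `"screen_log"`.
#' @export
assess_risk <- function(exposures, swqc, lwqc, screen = TRUE) {
  stopifnot(swqc > 0, lwqc > 0)
  screen_log <- character()
  if (screen && "flags" %in% names(exposures)) {
    flagged <- grepl("near_contaminated_site|emergency_event", exposures$flags)
    if (any(flagged)) {
      screen_log <- sprintf("site %s excluded by flag(s): %s",
                            exposures$site_id[flagged], exposures$flags[flagged])
      exposures <- exposures[!flagged, , drop = FALSE]
    }
  }
  for (col in c("mean", "sd")) {
    if (!col %in% names(exposures)) exposures[[col]] <- NA_real_
  }
  for (col in c("province", "basin")) {
    if (!col %in% names(exposures)) exposures[[col]] <- NA_character_
  }
  mec <- exposures$mean
  has_sd <- !is.na(exposures$sd) & !is.na(mec)
  lo <- ifelse(has_sd, pmax(mec - exposures$sd, 0), NA_real_)
  hi <- ifelse(has_sd, mec + exposures$sd, NA_real_)
  out <- data.frame(
    site_id = exposures$site_id,
    province = exposures$province,
    basin = exposures$basin,
    mec = mec,
    sqr = risk_quotient(ifelse(is.na(mec), NA_real_, mec), swqc),
    lqr = risk_quotient(ifelse(is.na(mec), NA_real_, mec), lwqc),
    sqr_lo = lo / swqc, sqr_hi = hi / swqc,
    lqr_lo = lo / lwqc, lqr_hi = hi / lwqc,
    stringsAsFactors = FALSE
  )
  out$risk_class_s <- classify_risk(out$sqr)
  out$risk_class_l <- classify_risk(out$lqr)
  class(out) <- c("risk_results", "data.frame")
  attr(out, "criteria") <- c(swqc = swqc, lwqc = lwqc)
  attr(out, "screen_log") <- screen_log
  out
}

#' Tally risk classes
#'
#' Counts and proportions of computable quotients per risk class, with the
#' arithmetic mean quotient, for the acute and chronic assessments.
#'
#' @param results A `risk_results` data frame from [assess_risk()].
#' @return Data frame with one row per assessment (`sqr`, `lqr`) and columns
#'   `n`, `low`, `medium`, `high`, proportions, and `mean`.
#' @export
risk_tally <- function(results) {
  tally_one <- function(q, cls) {
    comp <- !is.na(q)
    n <- sum(comp)
    counts <- vapply(c("low", "medium", "high"),
                     function(k) sum(cls[comp] == k), integer(1))
    data.frame(
      n = n,
      low = counts[["low"]], medium = counts[["medium"]], high = counts[["high"]],
      prop_low = counts[["low"]] / n,
      prop_medium = counts[["medium"]] / n,
      prop_high = counts[["high"]] / n,
      mean = mean(q[comp]),
      not_computable = sum(!comp)
    )
  }
  out <- rbind(tally_one(results$sqr, results$risk_class_s),
               tally_one(results$lqr, results$risk_class_l))
  rownames(out) <- c("sqr", "lqr")
  out
}

#' Summarize risk quotients by group
#'
#' Arithmetic means of the computable acute and chronic quotients per basin
#' or province, with per-class counts of the acute classification.
#'
#' @param results A `risk_results` data frame from [assess_risk()].
#' @param by Grouping column: `"basin"` (default) or `"province"`.
#' @return Data frame with one row per group: `n_sites`, `mean_sqr`,
#'   `mean_lqr`, and acute class counts.
#' @export
summarize_risk <- function(results, by = c("basin", "province")) {
  by <- match.arg(by)
  comp <- results[!is.na(results$sqr), , drop = FALSE]
  if (nrow(comp) == 0L) stop("summarize_risk(): no computable quotients", call. = FALSE)
  groups <- split(comp, comp[[by]])
  out <- do.call(rbind, lapply(groups, function(d) {
    data.frame(
      group = d[[by]][1L],
      n_sites = nrow(d),
      mean_sqr = mean(d$sqr),
      mean_lqr = mean(d$lqr),
      n_low = sum(d$risk_class_s == "low"),
      n_medium = sum(d$risk_class_s == "medium"),
      n_high = sum(d$risk_class_s == "high"),
      stringsAsFactors = FALSE
    )
  }))
  names(out)[1L] <- by
  rownames(out) <- NULL
  out[order(-out$mean_sqr), , drop = FALSE]
}

#' Province-to-basin helper map
#'
#' An editable lookup shipped as data (not code) assigning each Chinese
#' province to a major river basin, following the eight-basin grouping in
#' which the Haihe and Huaihe basins are merged. Basin assignment in exposure
#' tables is an input column; this map is a convenience for filling it.
#'
#' @return Data frame with columns `province` and `basin`.
#' @export
province_basins <- function() {
  utils::read.csv(system.file("extdata", "province_basins.csv",
                              package = "fewqc", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
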
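# Pipeline orchestration and report plumbing: one call from a toxicity table
# to criteria by all three methods, one call from an exposure table to the
# risk assessment, with JSON reports and a reproducibility manifest.

#' Derive water-quality criteria from a toxicity table
#'
#' Runs the full derivation: screening, species- and genus-level
#' aggregation, acute-to-chronic ratio estimation, and the selected criteria
#' methods. With `output_dir` set, writes one JSON report per method, a
#' method-comparison CSV, the screening rejection report, and a run manifest.
#'
#' @param toxicity Toxicity records: a data frame (see [read_toxicity()]) or
#'   a path to a CSV file.
#' @param methods Subset of `c("AF", "TPR", "SSD")`.
#' @param acr_pairing Pairing policy for [acr_estimate()].
#' @param saf,laf,min_chronic_n,models Passed to [ssd_method()].
#' @param output_dir Optional directory for reports.
#' @return Object of class `wqc_derivation`: list with `results` (named list
#'   of `criteria_result`), `comparison` (data frame), `species`, `genera`,
#'   `acr`, `screen`.
#' @export
derive_wqc <- function(toxicity, methods = c("AF", "TPR", "SSD"),
                       acr_pairing = "same_source",
                       saf = 2, laf = 2, min_chronic_n = 8,
                       models = c("log_logistic", "log_normal"),
                       output_dir = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  records <- if (is.character(toxicity)) read_toxicity(toxicity) else toxicity
  if (is.null(records) || nrow(records) == 0L) {
    stop("derive_wqc(): no records", call. = FALSE)
  }
  screen <- screen_records(records)
  acc <- screen$accepted
  if (nrow(acc) == 0L) stop("derive_wqc(): no records survive screening", call. = FALSE)
  sv_acute <- species_values(acc, "acute")
  sv_chronic <- species_values(acc, "chronic")
  gv_acute <- genus_values(sv_acute)
  gv_chronic <- genus_values(sv_chronic)
  acr <- acr_estimate(acc, pairing = acr_pairing)

  results <- list()
  if ("AF" %in% methods) {
    results$AF <- af_method(sv_acute, acr$overall)
  }
  if ("TPR" %in% methods) {
    results$TPR <- tpr_method(gv_acute, acr = acr$overall)
  }
  if ("SSD" %in% methods) {
    results$SSD <- ssd_method(sv_acute, sv_chronic, acr = acr$overall,
                              saf = saf, laf = laf,
                              min_chronic_n = min_chronic_n, models = models)
  }
  comparison <- do.call(rbind, lapply(results, function(r) {
    data.frame(method = r$method,
               swqc = if (is.null(r$swqc)) NA_real_ else r$swqc,
               lwqc = if (is.null(r$lwqc)) NA_real_ else r$lwqc,
               stringsAsFactors = FALSE)
  }))
  rownames(comparison) <- NULL
  out <- list(results = results, comparison = comparison,
              species = rbind(sv_acute, sv_chronic),
              genera = rbind(gv_acute, gv_chronic),
              acr = acr, screen = screen,
              config = list(methods = methods, acr_pairing = acr_pairing,
                            saf = saf, laf = laf, min_chronic_n = min_chronic_n,
                            models = models))
  class(out) <- "wqc_derivation"
  if (!is.null(output_dir)) {
    write_derivation_reports(out, output_dir)
  }
  out
}

#' @export
print.wqc_derivation <- function(x, ...) {
  cat("Water-quality criteria derivation\n")
  cat(sprintf("  records: %d accepted, %d rejected; ACR = %s (%s pairing)\n",
              nrow(x$screen$accepted), nrow(x$screen$rejected),
              format(signif(x$acr$overall, 3)), x$acr$pairing))
  cmp <- transform(x$comparison, swqc = signif(swqc, 3), lwqc = signif(lwqc, 3))
  print(cmp)
  invisible(x)
}

write_derivation_reports <- function(derivation, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  for (m in names(derivation$results)) {
    r <- derivation$results[[m]]
    inter <- Filter(function(v) is.numeric(v) || is.character(v), r$intermediates)
    jsonlite::write_json(
      list(method = r$method, swqc = r$swqc, lwqc = r$lwqc,
           intermediates = inter, provenance = r$provenance),
      file.path(output_dir, paste0("criteria_", tolower(m), ".json")),
      auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
    if (m == "SSD") {
      write_ssd_report(r$intermediates$acute_fit,
                       file.path(output_dir, "ssd_acute_fit.json"))
    }
  }
  utils::write.csv(derivation$comparison,
                   file.path(output_dir, "criteria_comparison.csv"),
                   row.names = FALSE)
  write_rejection_report(derivation$screen,
                         file.path(output_dir, "screening_rejections.csv"))
  write_manifest(file.path(output_dir, "manifest.json"),
                 config = derivation$config)
  invisible(output_dir)
}

#' Assess an exposure table and write reports
#'
#' File-level wrapper around [assess_risk()]: reads the exposure CSV (or
#' takes a data frame), computes per-site quotients and classes against the
#' supplied criteria, and with `output_dir` writes the per-site CSV, the
#' basin summary CSV, the class tally JSON, and a manifest.
#'
#' @param exposure Exposure table (data frame or CSV path).
#' @param swqc,lwqc Criteria in ug/L (e.g. from [derive_wqc()]).
#' @param screen Passed to [assess_risk()].
#' @param output_dir Optional directory for reports.
#' @return The `risk_results` data frame, with the tally and basin summary
#'   attached as attributes `"tally"` and `"basins"`.
#' @export
run_risk_assessment <- function(exposure, swqc, lwqc, screen = TRUE,
                                output_dir = NULL) {
  exposures <- if (is.character(exposure)) read_exposure(exposure) else exposure
  results <- assess_risk(exposures, swqc = swqc, lwqc = lwqc, screen = screen)
  tally <- risk_tally(results)
  basins <- summarize_risk(results, by = "basin")
  attr(results, "tally") <- tally
  attr(results, "basins") <- basins
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(results),
                     file.path(output_dir, "risk_per_site.csv"), row.names = FALSE)
    utils::write.csv(basins, file.path(output_dir, "risk_by_basin.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(criteria = as.list(attr(results, "criteria")),
           tally = cbind(assessment = rownames(tally), tally),
           screen_log = attr(results, "screen_log")),
      file.path(output_dir, "risk_tally.json"),
      auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
    write_manifest(file.path(output_dir, "manifest.json"),
                   config = list(swqc = swqc, lwqc = lwqc, screen = screen))
  }
  results
}

#' Write synthetic datasets to CSV with a manifest
#'
#' @param output_dir Directory to write into.
#' @param exposure_config Optional list of arguments for
#'   [simulate_exposure()].
#' @param toxicity_config Optional list of arguments for
#'   [simulate_toxicity()].
#' @param seed Master seed applied to both generators (overrides any seed in
#'   the config lists).
#' @return Invisibly, the paths written.
#' @export
run_simulation <- function(output_dir, exposure_config = list(),
                           toxicity_config = NULL, seed = 1) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  if (!is.null(exposure_config)) {
    exposure_config$seed <- seed
    exp_table <- do.call(simulate_exposure, exposure_config)
    p <- file.path(output_dir, "synthetic_exposure.csv")
    utils::write.csv(exp_table, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(toxicity_config)) {
    toxicity_config$seed <- seed
    tox_table <- do.call(simulate_toxicity, toxicity_config)
    p <- file.path(output_dir, "synthetic_toxicity.csv")
    write_toxicity(tox_table, p)
    paths <- c(paths, p)
  }
  write_manifest(file.path(output_dir, "manifest.json"),
                 config = list(seed = seed,
                               exposure_config = exposure_config,
                               toxicity_config = toxicity_config))
  invisible(paths)
}

#' Read a run configuration from JSON or YAML
#'
#' @param path Path to a `.json`, `.yml` or `.yaml` file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("read_run_config(): the 'yaml' package is required for YAML configs",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    stop("read_run_config(): unsupported config format: ", ext, call. = FALSE)
  }
}

write_manifest <- function(path, config) {
  jsonlite::write_json(
    list(package = "fewqc",
         version = as.character(utils::packageVersion("fewqc")),
         r_version = paste(R.version$major, R.version$minor, sep = "."),
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         config = config),
    path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' Round for display
#'
#' Three significant figures, the package's reporting convention. All
#' internal computation keeps full precision.
#'
#' @param x Numeric.
#' @return `signif(x, 3)`.
#' @export
signif3 <- function(x) signif(x, 3)
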
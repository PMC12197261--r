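# Seeded generators: synthetic exposure tables with the statistical
# structure the risk assessment consumes, and toxicity datasets drawn from a
# known sensitivity distribution for parameter-recovery studies.

# Deterministic substream seed from a master seed and string/index context,
# so that adding a basin or site does not perturb the draws of the others.
# Kept below 2^31 - 1.
substream_seed <- function(seed, name, index) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  (as.numeric(seed) * 48271 + h * 1009 + index * 7919) %% 2147483647
}

#' Default basin configuration for the exposure generator
#'
#' Eight river-basin groups spanning the surveyed provinces with site counts
#' proportional to the published per-basin data volumes, scaled to 68 sites
#' in total. Log10 mean concentrations encode the observed north-south
#' contamination contrast (northern basins roughly half an order of magnitude
#' higher); the within-basin log10 SD of 0.4 reflects typical between-site
#' spread of riverine iron.
#'
#' @return Data frame with columns `name`, `n_sites`, `log10_mean`,
#'   `log10_sd`.
#' @export
default_exposure_basins <- function() {
  data.frame(
    name = c("Yangtze River Basin (middle and upper reaches)",
             "Yangtze River Basin (lower reaches)",
             "Southwest Basin",
             "Pearl River Basin",
             "Southeast Basin",
             "Yellow River and Huaihe River Basin",
             "Songhua and Liaohe River Basin",
             "Continental Basin"),
    n_sites = c(11L, 9L, 20L, 8L, 3L, 9L, 2L, 6L),
    log10_mean = c(2.20, 2.40, 2.20, 2.35, 2.30, 2.70, 2.70, 2.25),
    log10_sd = rep(0.4, 8),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic exposure table
#'
#' Per site, `n_replicates` concentrations are drawn lognormally (base-10
#' location/scale per basin) and summarized into the mean/SD/min/max schema
#' the risk assessment consumes. Fully reproducible: per-site substreams are
#' derived from the master seed and the basin name, so extending the
#' configuration leaves existing sites' draws unchanged.
#'
#' @param basins Basin configuration data frame (columns `name`, `n_sites`,
#'   `log10_mean`, `log10_sd`); default [default_exposure_basins()].
#' @param n_replicates Concentration draws per site (default 12). With one
#'   replicate the SD is reported missing.
#' @param n_missing_mean Number of sites (seeded choice) whose mean and SD
#'   are blanked, leaving only min/max — emulating literature records that
#'   report ranges only. Default 0.
#' @param seed Master integer seed.
#' @return Exposure-record data frame (schema of [read_exposure()]).
#' @export
simulate_exposure <- function(basins = default_exposure_basins(),
                              n_replicates = 12, n_missing_mean = 0,
                              seed = 1) {
  if (!is.data.frame(basins) || nrow(basins) == 0L) {
    stop("simulate_exposure(): at least one basin is required", call. = FALSE)
  }
  required <- c("name", "n_sites", "log10_mean", "log10_sd")
  if (!all(required %in% names(basins))) {
    stop("simulate_exposure(): basins need columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  if (any(basins$n_sites < 1L) || any(basins$log10_sd <= 0)) {
    stop("simulate_exposure(): n_sites must be >= 1 and log10_sd > 0",
         call. = FALSE)
  }
  stopifnot(n_replicates >= 1)
  rows <- list()
  for (b in seq_len(nrow(basins))) {
    for (s in seq_len(basins$n_sites[b])) {
      old <- .Random.seed_save()
      set.seed(substream_seed(seed, basins$name[b], s))
      draws <- 10^stats::rnorm(n_replicates, basins$log10_mean[b], basins$log10_sd[b])
      .Random.seed_restore(old)
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = sprintf("%s_site%02d", gsub("[^A-Za-z]+", "", basins$name[b]), s),
        province = basins$name[b],
        basin = basins$name[b],
        reach = NA_character_,
        mean = mean(draws),
        sd = if (n_replicates > 1L) stats::sd(draws) else NA_real_,
        min = min(draws),
        max = max(draws),
        year_range = "2009-2024",
        source_id = "synthetic",
        flags = "",
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (n_missing_mean > 0L) {
    old <- .Random.seed_save()
    set.seed(substream_seed(seed, "missing-mean", 0L))
    drop_idx <- sample(nrow(out), min(n_missing_mean, nrow(out)))
    .Random.seed_restore(old)
    out$mean[drop_idx] <- NA_real_
    out$sd[drop_idx] <- NA_real_
  }
  rownames(out) <- NULL
  out
}

#' Generate a synthetic toxicity dataset from a known SSD
#'
#' Species sensitivities are drawn from the configured sensitivity
#' distribution; each species then receives `records_per_species` endpoint
#' records jittered around its sensitivity by a mean-zero log-scale noise
#' with coefficient of variation `within_species_cv` (cv = 0 makes each
#' species' geometric mean equal its drawn sensitivity exactly). The output
#' is schema-identical to the packaged reference table, so the whole
#' derivation pipeline runs on it unchanged.
#'
#' @param n_species Number of species (>= 3). Default 18, the size of the
#'   packaged acute dataset.
#' @param model Sensitivity distribution: `"log_logistic"` (default) or
#'   `"log_normal"`.
#' @param location,scale Distribution parameters on the log10 ug/L scale.
#'   Defaults (4.3, 0.5) mirror the fitted acute SSD of the reference data.
#' @param records_per_species Endpoint records per species (default 3).
#' @param within_species_cv Within-species coefficient of variation of the
#'   record noise (default 0.2).
#' @param test_type `"acute"` or `"chronic"` labels for the records.
#' @param seed Master integer seed.
#' @return Toxicity-record data frame; the true species sensitivities are
#'   attached as attribute `"sensitivities"`.
#' @export
simulate_toxicity <- function(n_species = 18, model = c("log_logistic", "log_normal"),
                              location = 4.3, scale = 0.5,
                              records_per_species = 3, within_species_cv = 0.2,
                              test_type = "acute", seed = 1) {
  model <- match.arg(model)
  if (n_species < 3L) stop("simulate_toxicity(): n_species must be >= 3", call. = FALSE)
  if (scale <= 0) stop("simulate_toxicity(): scale must be > 0", call. = FALSE)
  if (within_species_cv < 0) stop("simulate_toxicity(): within_species_cv must be >= 0",
                                  call. = FALSE)
  old <- .Random.seed_save()
  set.seed(substream_seed(seed, paste0("toxicity-", model), n_species))
  qfun <- if (model == "log_logistic") stats::rlogis else stats::rnorm
  sens <- 10^qfun(n_species, location, scale)
  sdlog <- sqrt(log(1 + within_species_cv^2))
  rows <- lapply(seq_len(n_species), function(i) {
    noise <- if (within_species_cv > 0) {
      exp(stats::rnorm(records_per_species, 0, sdlog))
    } else {
      rep(1, records_per_species)
    }
    data.frame(
      species = sprintf("Species %02d", i),
      genus = sprintf("Genus %02d", i),
      test_type = test_type,
      endpoint = if (test_type == "acute") "LC50" else "NOEC",
      value = sens[i] * noise,
      source_id = "synthetic",
      exclude = FALSE,
      notes = "",
      stringsAsFactors = FALSE
    )
  })
  .Random.seed_restore(old)
  out <- do.call(rbind, rows)
  attr(out, "sensitivities") <- stats::setNames(sens, sprintf("Species %02d", seq_len(n_species)))
  out
}

# Save/restore the global RNG state so generators are self-contained.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
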
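# Toxicity-record handling: validation/screening and geometric-mean
# aggregation to species- and genus-level values (SMAV/GMAV, AVE/CVE),
# plus acute-to-chronic ratio estimation.

#' Endpoint whitelists by test type
#'
#' Acute tests report median-effect endpoints (LC50/EC50/IC50); chronic tests
#' additionally admit threshold endpoints (NOEC/LOEC/MATC) and, for chronic
#' exposure designs, EC50/LC50.
#'
#' @format Character vectors of endpoint codes.
#' @name endpoints
NULL

#' @rdname endpoints
#' @export
acute_endpoints <- c("LC50", "EC50", "IC50")

#' @rdname endpoints
#' @export
chronic_endpoints <- c("NOEC", "LOEC", "MATC", "EC50", "LC50")

#' Geometric mean of positive concentrations
#'
#' Scale-equivariant, permutation-invariant aggregate used throughout the
#' criteria derivation (species values, genus values, acute-to-chronic
#' ratios). Computed as `exp(mean(log(x)))`.
#'
#' @param x Numeric vector of positive, finite values.
#' @return A single numeric value between `min(x)` and `max(x)`.
#' @examples
#' geometric_mean(c(100, 10)) # 31.6
#' @export
geometric_mean <- function(x) {
  if (length(x) == 0L) {
    stop("geometric_mean(): empty input", call. = FALSE)
  }
  bad <- which(!is.finite(x) | x <= 0)
  if (length(bad) > 0L) {
    stop(sprintf(
      "geometric_mean(): nonpositive or non-finite value at position %d (value = %s)",
      bad[1L], format(x[bad[1L]])
    ), call. = FALSE)
  }
  exp(mean(log(x)))
}

#' Read a toxicity-record table from CSV
#'
#' Expected columns: `species`, `genus`, `test_type` (`acute`/`chronic`),
#' `endpoint`, `value`, `unit` (`ug/L` or `mg/L`; mg/L converted on read),
#' `source_id`, and optionally `exclude` (logical) and `notes`. Values with
#' thousands separators are rejected. Concentrations are stored internally in
#' ug/L.
#'
#' @param path Path to a UTF-8 CSV file.
#' @return A data frame of toxicity records with a `line` column giving the
#'   file line of each record.
#' @export
read_toxicity <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("species", "genus", "test_type", "endpoint", "value", "unit", "source_id")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("read_toxicity(): missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    stop("read_toxicity(): no records in ", path, call. = FALSE)
  }
  if (any(grepl(",", raw$value, fixed = TRUE))) {
    stop("read_toxicity(): thousands separators are not allowed in 'value'",
         call. = FALSE)
  }
  value <- suppressWarnings(as.numeric(raw$value))
  unit <- trimws(raw$unit)
  known <- c("ug/L", "µg/L", "μg/L", "mg/L")
  if (any(!unit %in% known)) {
    stop("read_toxicity(): unknown unit(s): ",
         paste(unique(unit[!unit %in% known]), collapse = ", "), call. = FALSE)
  }
  value <- ifelse(unit == "mg/L", value * 1000, value)
  exclude <- if ("exclude" %in% names(raw)) {
    tolower(trimws(raw$exclude)) %in% c("true", "t", "1", "yes")
  } else {
    rep(FALSE, nrow(raw))
  }
  data.frame(
    line = seq_len(nrow(raw)) + 1L, # header is line 1
    species = trimws(raw$species),
    genus = trimws(raw$genus),
    test_type = trimws(raw$test_type),
    endpoint = trimws(raw$endpoint),
    value = value,
    source_id = trimws(raw$source_id),
    exclude = exclude,
    notes = if ("notes" %in% names(raw)) raw$notes else "",
    stringsAsFactors = FALSE
  )
}

#' Write toxicity records to CSV
#'
#' Inverse of [read_toxicity()]: emits the on-disk schema with an explicit
#' `unit` column (always ug/L).
#'
#' @param records Toxicity-record data frame.
#' @param path Output CSV path.
#' @export
write_toxicity <- function(records, path) {
  out <- data.frame(
    species = records$species,
    genus = records$genus,
    test_type = records$test_type,
    endpoint = records$endpoint,
    value = records$value,
    unit = "ug/L",
    source_id = records$source_id,
    exclude = if ("exclude" %in% names(records)) records$exclude else FALSE,
    notes = if ("notes" %in% names(records)) records$notes else "",
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The packaged ferric-iron toxicity reference table
#'
#' 47 curated records (31 acute over 18 species in 17 genera; 16 chronic over
#' 4 species in 4 genera) of ferric-iron toxicity to freshwater organisms,
#' with literature source keys.
#'
#' @return A toxicity-record data frame (see [read_toxicity()]).
#' @export
ferric_toxicity <- function() {
  read_toxicity(system.file("extdata", "ferric_toxicity.csv", package = "fewqc",
                            mustWork = TRUE))
}

#' Screening rule set for toxicity records
#'
#' @param acute_endpoints,chronic_endpoints Endpoint whitelists per test type.
#' @param drop_excluded Drop records whose `exclude` flag is set (explicit,
#'   logged curation; no automatic outlier elimination is performed).
#' @return A named list of rules consumed by [screen_records()].
#' @export
screening_rules <- function(acute_endpoints = fewqc::acute_endpoints,
                            chronic_endpoints = fewqc::chronic_endpoints,
                            drop_excluded = TRUE) {
  list(
    acute_endpoints = acute_endpoints,
    chronic_endpoints = chronic_endpoints,
    drop_excluded = drop_excluded
  )
}

#' Screen toxicity records
#'
#' Applies required-field, endpoint-whitelist and positivity checks. Failing
#' records are not dropped silently: each rejection is reported with the rule
#' it violated, and `accepted` plus `rejected` partition the input.
#'
#' @param records Toxicity-record data frame.
#' @param rules A rule set from [screening_rules()].
#' @return A list of class `tox_screen` with elements `accepted` (records) and
#'   `rejected` (data frame with `line`, `species` and `rule`).
#' @export
screen_records <- function(records, rules = screening_rules()) {
  if (!"line" %in% names(records)) {
    records$line <- seq_len(nrow(records))
  }
  if (!"exclude" %in% names(records)) {
    records$exclude <- FALSE
  }
  rule_of <- function(i) {
    r <- records[i, ]
    if (is.na(r$species) || !nzchar(r$species)) return("missing species")
    if (is.na(r$genus) || !nzchar(r$genus)) return("missing genus")
    if (!r$test_type %in% c("acute", "chronic")) return("unknown test_type")
    if (is.na(r$value) || !is.finite(r$value) || r$value <= 0) {
      return("nonpositive concentration")
    }
    if (r$test_type == "acute" && !r$endpoint %in% rules$acute_endpoints) {
      return("endpoint not allowed for acute")
    }
    if (r$test_type == "chronic" && !r$endpoint %in% rules$chronic_endpoints) {
      return("endpoint not allowed for chronic")
    }
    if (isTRUE(rules$drop_excluded) && isTRUE(r$exclude)) {
      return("excluded by curation flag")
    }
    NA_character_
  }
  rule <- vapply(seq_len(nrow(records)), rule_of, character(1))
  ok <- is.na(rule)
  out <- list(
    accepted = records[ok, , drop = FALSE],
    rejected = data.frame(
      line = records$line[!ok],
      species = records$species[!ok],
      rule = rule[!ok],
      stringsAsFactors = FALSE
    )
  )
  class(out) <- "tox_screen"
  out
}

#' @export
print.tox_screen <- function(x, ...) {
  cat(sprintf("Toxicity screening: %d accepted, %d rejected\n",
              nrow(x$accepted), nrow(x$rejected)))
  if (nrow(x$rejected) > 0L) {
    print(x$rejected)
  }
  invisible(x)
}

#' Write a screening rejection report
#'
#' @param screen A `tox_screen` object from [screen_records()].
#' @param path Output CSV path (columns: line, species, rule).
#' @export
write_rejection_report <- function(screen, path) {
  utils::write.csv(screen$rejected, path, row.names = FALSE)
  invisible(path)
}

#' Species-level toxicity values (SMAV / AVE / CVE)
#'
#' One value per species: the geometric mean of that species' surviving record
#' concentrations of the requested test type. No outlier elimination is
#' applied; curated exclusions must be flagged in the input and are handled by
#' [screen_records()].
#'
#' @param records Screened toxicity records.
#' @param test_type `"acute"` or `"chronic"`.
#' @return Data frame with `species`, `genus`, `test_type`, `n_records`,
#'   `value` (ug/L), sorted by `value`.
#' @export
species_values <- function(records, test_type = c("acute", "chronic")) {
  test_type <- match.arg(test_type)
  rec <- records[records$test_type == test_type, , drop = FALSE]
  if (nrow(rec) == 0L) {
    return(data.frame(species = character(), genus = character(),
                      test_type = character(), n_records = integer(),
                      value = numeric(), stringsAsFactors = FALSE))
  }
  split_rec <- split(rec, rec$species)
  out <- do.call(rbind, lapply(split_rec, function(d) {
    data.frame(
      species = d$species[1L],
      genus = d$genus[1L],
      test_type = test_type,
      n_records = nrow(d),
      value = geometric_mean(d$value),
      stringsAsFactors = FALSE
    )
  }))
  out <- out[order(out$value), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genus-level toxicity values (GMAV)
#'
#' One value per genus: the geometric mean of its member species values. A
#' single-species genus inherits that species' value.
#'
#' @param sv Species values from [species_values()].
#' @return Data frame with `genus`, `test_type`, `n_species`, `value` (ug/L),
#'   sorted by `value`.
#' @export
genus_values <- function(sv) {
  if (nrow(sv) == 0L) {
    return(data.frame(genus = character(), test_type = character(),
                      n_species = integer(), value = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(split(sv, sv$genus), function(d) {
    data.frame(
      genus = d$genus[1L],
      test_type = d$test_type[1L],
      n_species = nrow(d),
      value = geometric_mean(d$value),
      stringsAsFactors = FALSE
    )
  }))
  out <- out[order(out$value), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Acute-to-chronic ratio (ACR)
#'
#' For each species with both acute and chronic records, the per-species ratio
#' is gm(matched acute records) / gm(all chronic records); the overall ACR is
#' the geometric mean of per-species ratios. Under the default `same_source`
#' pairing, the acute side is restricted to records sharing a literature
#' source with the species' chronic records, so numerator and denominator come
#' from comparable experimental conditions; species with no shared source are
#' excluded and logged. `all_records` uses every acute record and is intended
#' for sensitivity analysis.
#'
#' @param records Screened toxicity records containing both test types.
#' @param pairing `"same_source"` (default) or `"all_records"`.
#' @return An object of class `acr_estimate`: list with `per_species` (data
#'   frame of species, matched acute value, chronic value, ratio), `overall`
#'   (geometric mean of ratios), `pairing`, and `log` (character vector of
#'   exclusions).
#' @export
acr_estimate <- function(records, pairing = c("same_source", "all_records")) {
  pairing <- match.arg(pairing)
  ac <- records[records$test_type == "acute", , drop = FALSE]
  ch <- records[records$test_type == "chronic", , drop = FALSE]
  candidates <- intersect(unique(ac$species), unique(ch$species))
  log_lines <- character()
  rows <- list()
  for (sp in candidates) {
    a <- ac[ac$species == sp, , drop = FALSE]
    c_ <- ch[ch$species == sp, , drop = FALSE]
    if (pairing == "same_source") {
      shared <- intersect(unique(a$source_id), unique(c_$source_id))
      if (length(shared) == 0L) {
        log_lines <- c(log_lines, sprintf(
          "%s: no acute/chronic records share a source; excluded from ACR", sp))
        next
      }
      a <- a[a$source_id %in% shared, , drop = FALSE]
    }
    acute_val <- geometric_mean(a$value)
    chronic_val <- geometric_mean(c_$value)
    rows[[sp]] <- data.frame(
      species = sp,
      acute_value_matched = acute_val,
      chronic_value = chronic_val,
      ratio = acute_val / chronic_val,
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) {
    stop("ACR not computable: no species has paired acute and chronic records",
         call. = FALSE)
  }
  per_species <- do.call(rbind, rows)
  rownames(per_species) <- NULL
  out <- list(
    per_species = per_species,
    overall = geometric_mean(per_species$ratio),
    pairing = pairing,
    log = log_lines
  )
  class(out) <- "acr_estimate"
  out
}

#' @export
print.acr_estimate <- function(x, ...) {
  cat(sprintf("Acute-to-chronic ratio (pairing = %s)\n", x$pairing))
  print(transform(x$per_species,
                  acute_value_matched = signif(acute_value_matched, 3),
                  chronic_value = signif(chronic_value, 3),
                  ratio = signif(ratio, 3)))
  cat(sprintf("Overall ACR (geometric mean): %s\n", format(signif(x$overall, 3))))
  for (l in x$log) cat("note: ", l, "\n", sep = "")
  invisible(x)
}
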
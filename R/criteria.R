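# Water-quality criteria assembly by three derivation routes: assessment
# factor, toxicity percentage ranking (US EPA 1985 final acute value), and
# species sensitivity distribution.

new_criteria_result <- function(method, swqc = NULL, lwqc = NULL,
                                intermediates = list(),
                                provenance = character()) {
  out <- list(method = method, swqc = swqc, lwqc = lwqc,
              intermediates = intermediates, provenance = provenance)
  for (v in c(swqc, lwqc)) {
    if (!is.null(v) && (!is.finite(v) || v <= 0)) {
      stop("criteria_result: criteria must be positive", call. = FALSE)
    }
  }
  class(out) <- "criteria_result"
  out
}

#' @export
print.criteria_result <- function(x, ...) {
  cat(sprintf("Water-quality criteria (%s method)\n", x$method))
  if (!is.null(x$swqc)) cat(sprintf("  SWQC: %s ug/L\n", format(signif(x$swqc, 3))))
  if (!is.null(x$lwqc)) cat(sprintf("  LWQC: %s ug/L\n", format(signif(x$lwqc, 3))))
  nums <- Filter(is.numeric, x$intermediates)
  if (length(nums) > 0L) {
    cat("  intermediates:",
        paste(sprintf("%s = %s", names(nums), vapply(nums, function(v)
          format(signif(v, 3)), character(1))), collapse = ", "), "\n")
  }
  for (l in x$provenance) cat("  - ", l, "\n", sep = "")
  invisible(x)
}

#' Assessment-factor method
#'
#' The criterion is the most sensitive species' acute toxicity value (ATV,
#' the minimum species-level value) divided by the overall acute-to-chronic
#' ratio, i.e. a chronic-protective single value.
#'
#' @param acute_species Species values data frame from [species_values()] (or
#'   a numeric vector of species values, ug/L).
#' @param acr Overall acute-to-chronic ratio (> 0), e.g.
#'   `acr_estimate(...)$overall`.
#' @return A `criteria_result` with the derived value in `lwqc` and
#'   intermediates `atv` and `acr`.
#' @export
af_method <- function(acute_species, acr) {
  vals <- if (is.data.frame(acute_species)) acute_species$value else acute_species
  if (length(vals) == 0L) stop("af_method(): no acute species values", call. = FALSE)
  stopifnot(acr > 0)
  atv <- min(vals)
  sensitive <- if (is.data.frame(acute_species)) {
    acute_species$species[which.min(acute_species$value)]
  } else {
    NA_character_
  }
  new_criteria_result(
    method = "AF",
    lwqc = atv / acr,
    intermediates = list(atv = atv, acr = acr, most_sensitive = sensitive),
    provenance = sprintf("WQC = ATV (%s ug/L, most sensitive species) / ACR (%s)",
                         format(signif(atv, 3)), format(signif(acr, 3)))
  )
}

#' Final acute value by toxicity percentage ranking
#'
#' Implements the US EPA (1985) final acute value computation. Genus mean
#' acute values are ranked ascending; the cumulative probability of rank R
#' among N genera is P = R/(N + 1); the four genera whose P is nearest 0.05
#' (ties toward the lower rank) enter
#' \deqn{S^2 = \frac{\sum (\ln G)^2 - (\sum \ln G)^2 / 4}
#'                  {\sum P - (\sum \sqrt P)^2 / 4},\quad
#'       L = \frac{\sum \ln G - S \sum \sqrt P}{4},\quad
#'       FAV = e^{S\sqrt{0.05} + L}.}
#'
#' @param genus_acute Genus values data frame from [genus_values()] (or a
#'   numeric vector of genus values, ug/L).
#' @return List with `fav` (ug/L) and `diagnostics` (chosen genera with P, S,
#'   L, N).
#' @export
tpr_fav <- function(genus_acute) {
  vals <- if (is.data.frame(genus_acute)) genus_acute$value else genus_acute
  labs <- if (is.data.frame(genus_acute)) genus_acute$genus else
    as.character(seq_along(vals))
  if (length(vals) < 4L) {
    stop("tpr_fav(): at least 4 genera are required", call. = FALSE)
  }
  o <- order(vals)
  vals <- vals[o]
  labs <- labs[o]
  n <- length(vals)
  P_all <- seq_len(n) / (n + 1)
  sel <- order(abs(P_all - 0.05), seq_len(n))[1:4]
  sel <- sort(sel)
  G <- vals[sel]
  P <- P_all[sel]
  lnG <- log(G)
  num <- sum(lnG^2) - sum(lnG)^2 / 4
  den <- sum(P) - sum(sqrt(P))^2 / 4
  S <- sqrt(max(num, 0) / den)
  L <- (sum(lnG) - S * sum(sqrt(P))) / 4
  fav <- exp(S * sqrt(0.05) + L)
  list(
    fav = fav,
    diagnostics = list(
      genera = labs[sel],
      gmav = G,
      P = P,
      S = S,
      L = L,
      n_genera = n
    )
  )
}

#' Toxicity-percentage-ranking criteria (CMC and CCC)
#'
#' CMC = FAV/2; FCV = FAV/ACR; CCC is the minimum over the populated final
#' values (FCV, and the final plant and residue values when available; both
#' are typically absent for ferric iron and are skipped with a log line).
#'
#' @param genus_acute Genus acute values (see [tpr_fav()]). Ignored when
#'   `fav` is supplied directly.
#' @param acr Overall acute-to-chronic ratio (> 0).
#' @param fpv,frv Optional final plant / final residue values (ug/L).
#' @param fav Optional externally supplied final acute value (ug/L); when
#'   given, the ranking step is bypassed.
#' @return A `criteria_result` with `swqc = CMC`, `lwqc = CCC` and
#'   intermediates `fav`, `cmc`, `fcv`, `ccc` (plus `fpv`/`frv` if given).
#' @export
tpr_method <- function(genus_acute = NULL, acr, fpv = NULL, frv = NULL,
                       fav = NULL) {
  stopifnot(acr > 0)
  provenance <- character()
  diagnostics <- NULL
  if (is.null(fav)) {
    res <- tpr_fav(genus_acute)
    fav <- res$fav
    diagnostics <- res$diagnostics
    provenance <- c(provenance, sprintf(
      "FAV = %s ug/L from genera %s (P = %s)",
      format(signif(fav, 3)), paste(diagnostics$genera, collapse = ", "),
      paste(signif(diagnostics$P, 3), collapse = ", ")))
  } else {
    provenance <- c(provenance, sprintf("FAV = %s ug/L (supplied)",
                                        format(signif(fav, 3))))
  }
  cmc <- fav / 2
  fcv <- fav / acr
  finals <- c(fcv = fcv, fpv = fpv, frv = frv)
  if (is.null(fpv)) provenance <- c(provenance, "FPV unavailable; skipped in CCC")
  if (is.null(frv)) provenance <- c(provenance, "FRV unavailable; skipped in CCC")
  ccc <- min(finals)
  inter <- list(fav = fav, cmc = cmc, fcv = fcv, ccc = ccc, acr = acr,
                tpr_diagnostics = diagnostics)
  if (!is.null(fpv)) inter$fpv <- fpv
  if (!is.null(frv)) inter$frv <- frv
  new_criteria_result(
    method = "TPR", swqc = cmc, lwqc = ccc,
    intermediates = inter,
    provenance = c(provenance,
                   sprintf("CMC = FAV/2; CCC = min(%s)",
                           paste(names(finals), collapse = ", ")))
  )
}

#' Species-sensitivity-distribution criteria (SWQC and LWQC)
#'
#' Fits candidate SSD models to the acute species values, selects the best by
#' goodness of fit, and sets SWQC = acute HC5 / SAF. When at least
#' `min_chronic_n` chronic species values are available a chronic SSD is
#' fitted and LWQC = chronic HC5 / LAF; otherwise LWQC falls back to acute
#' HC5 / ACR, with the fallback logged.
#'
#' @param acute_species Species acute values (data frame from
#'   [species_values()] or numeric vector, ug/L).
#' @param chronic_species Optional species chronic values.
#' @param acr Overall acute-to-chronic ratio; required for the fallback.
#' @param saf,laf Short-/long-term assessment factors (default 2).
#' @param min_chronic_n Minimum chronic species count for direct chronic
#'   fitting (default 8).
#' @param models Candidate model names for [ssd_fit_candidates()].
#' @param method Fitting method passed through to [ssd_fit()].
#' @return A `criteria_result` with `swqc`, `lwqc`, intermediates
#'   `hc5_acute`, `hc5_chronic` (if fitted), `saf`, `laf`, `acr`, and the
#'   fitted `acute_fit` / `chronic_fit` objects.
#' @export
ssd_method <- function(acute_species, chronic_species = NULL, acr = NULL,
                       saf = 2, laf = 2, min_chronic_n = 8,
                       models = c("log_logistic", "log_normal"),
                       method = "ls") {
  stopifnot(saf > 0, laf > 0)
  avals <- if (is.data.frame(acute_species)) {
    stats::setNames(acute_species$value, acute_species$species)
  } else {
    acute_species
  }
  if (length(avals) < 3L) {
    stop("ssd_method(): insufficient acute data for SSD fitting", call. = FALSE)
  }
  acute_fit <- select_best_model(ssd_fit_candidates(ssd_ranks(avals),
                                                    models = models,
                                                    method = method))
  hc5_acute <- acute_fit$hc5
  swqc <- hc5_acute / saf
  provenance <- sprintf("acute SSD: %s selected (r2 = %.3f); HC5 = %s ug/L; SWQC = HC5/SAF(%s)",
                        acute_fit$model, acute_fit$r2,
                        format(signif(hc5_acute, 3)), format(saf))

  cvals <- if (is.data.frame(chronic_species)) chronic_species$value else chronic_species
  chronic_fit <- NULL
  if (!is.null(cvals) && length(cvals) >= min_chronic_n) {
    chronic_fit <- select_best_model(ssd_fit_candidates(ssd_ranks(cvals),
                                                        models = models,
                                                        method = method))
    lwqc <- chronic_fit$hc5 / laf
    provenance <- c(provenance, sprintf(
      "chronic SSD: %s selected; HC5 = %s ug/L; LWQC = HC5/LAF(%s)",
      chronic_fit$model, format(signif(chronic_fit$hc5, 3)), format(laf)))
  } else {
    if (is.null(acr)) {
      stop("ssd_method(): chronic data insufficient and no ACR supplied for fallback",
           call. = FALSE)
    }
    lwqc <- hc5_acute / acr
    provenance <- c(provenance, sprintf(
      "chronic data insufficient (%d < %d species): LWQC = acute HC5 / ACR(%s)",
      length(cvals), min_chronic_n, format(signif(acr, 3))))
  }
  inter <- list(hc5_acute = hc5_acute, saf = saf, laf = laf,
                acute_fit = acute_fit)
  if (!is.null(chronic_fit)) inter$hc5_chronic <- chronic_fit$hc5
  if (!is.null(chronic_fit)) inter$chronic_fit <- chronic_fit
  if (!is.null(acr)) inter$acr <- acr
  new_criteria_result(method = "SSD", swqc = swqc, lwqc = lwqc,
                      intermediates = inter, provenance = provenance)
}
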
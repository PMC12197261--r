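# Species sensitivity distributions: rank/cumulative-frequency construction,
# candidate CDF fitting on log10 toxicity values, goodness of fit and model
# selection, and hazard-concentration (HCp) inversion.

ssd_models <- c("log_logistic", "log_normal", "logistic_raw", "normal_raw")

model_is_log <- function(model) model %in% c("log_logistic", "log_normal")
model_is_logistic <- function(model) model %in% c("log_logistic", "logistic_raw")

model_cdf <- function(model) {
  if (model_is_logistic(model)) stats::plogis else stats::pnorm
}

model_quantile <- function(model) {
  if (model_is_logistic(model)) stats::qlogis else stats::qnorm
}

#' Rank species values and compute cumulative frequencies
#'
#' Species toxicity values are ranked ascending on the log10 scale. Tied
#' values share one rank whose frequency `f` is the tie count, and the
#' cumulative frequency of rank R is
#' \deqn{F_R = \frac{\sum_{r \le R} f_r}{\sum f + 1},}
#' which keeps every plotting position strictly inside (0, 1). With n
#' distinct values this reduces to R/(n + 1).
#'
#' @param values Positive concentrations (ug/L), one per species.
#' @param labels Optional labels (species names); defaults to names of
#'   `values` or an index.
#' @return Data frame of class `ssd_points`: one row per input value with
#'   `label`, `value`, `x` (log10 value), `rank`, `f`, `cum_freq`, ordered by
#'   `x`.
#' @export
ssd_ranks <- function(values, labels = NULL) {
  if (length(values) == 0L) stop("ssd_ranks(): no values", call. = FALSE)
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad) > 0L) {
    stop(sprintf("ssd_ranks(): nonpositive value at position %d", bad[1L]),
         call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- if (!is.null(names(values))) names(values) else as.character(seq_along(values))
  }
  o <- order(values)
  values <- values[o]
  labels <- labels[o]
  distinct <- unique(values)
  rank_of <- match(values, distinct)
  f_per_rank <- tabulate(rank_of)
  cum_per_rank <- cumsum(f_per_rank) / (sum(f_per_rank) + 1)
  out <- data.frame(
    label = labels,
    value = values,
    x = log10(values),
    rank = rank_of,
    f = f_per_rank[rank_of],
    cum_freq = cum_per_rank[rank_of],
    stringsAsFactors = FALSE
  )
  class(out) <- c("ssd_points", "data.frame")
  out
}

#' Anderson-Darling statistic of a sample against a fitted CDF
#'
#' @param x Numeric sample.
#' @param cdf A vectorized CDF function.
#' @return The A-squared statistic.
#' @keywords internal
ad_statistic <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  u <- pmin(pmax(cdf(x), 1e-12), 1 - 1e-12)
  i <- seq_len(n)
  -n - mean((2 * i - 1) * (log(u) + log(1 - rev(u))))
}

# Asymptotic p-value for the A-D normality statistic with estimated
# parameters (D'Agostino & Stephens case 3). Only valid for normal-family
# models; the logistic case has no implemented approximation and reports NA.
ad_p_normal <- function(a2, n) {
  a <- a2 * (1 + 0.75 / n + 2.25 / n^2)
  if (a >= 0.6) {
    exp(1.2937 - 5.709 * a + 0.0186 * a^2)
  } else if (a > 0.34) {
    exp(0.9177 - 4.279 * a - 1.38 * a^2)
  } else if (a > 0.2) {
    1 - exp(-8.318 + 42.796 * a - 59.938 * a^2)
  } else {
    1 - exp(-13.436 + 101.14 * a - 223.73 * a^2)
  }
}

#' Fit one sensitivity-distribution model
#'
#' Fits the chosen CDF to the empirical cumulative frequencies by nonlinear
#' least squares: the curve y(x; location, scale) is regressed on the
#' per-rank points (x, cum_freq), where x is the log10 toxicity value for the
#' log-domain models and the raw concentration otherwise. Starting values are
#' location = median(x) and scale = IQR(x)/2, with up to five deterministic
#' perturbation restarts on failure. `method = "mle"` instead estimates
#' location and scale by maximum likelihood on the x sample; goodness-of-fit
#' statistics are still evaluated against the empirical frequencies so that
#' both routes are comparable.
#'
#' @param points An `ssd_points` table from [ssd_ranks()], or a numeric vector
#'   of concentrations.
#' @param model One of `"log_logistic"`, `"log_normal"`, `"logistic_raw"`,
#'   `"normal_raw"`.
#' @param method `"ls"` (nonlinear least squares on the CDF; default) or
#'   `"mle"`.
#' @return Object of class `ssd_fit`: model, location, scale, `r2`
#'   (1 - SSres/SStot about the mean empirical frequency), `rmse`
#'   (sqrt(SSres/n)), `ad_stat`, `ad_p` (NA for logistic models), `hc5`
#'   (ug/L), `n_points`, and the per-rank table with fitted values.
#' @export
ssd_fit <- function(points, model = c("log_logistic", "log_normal",
                                      "logistic_raw", "normal_raw"),
                    method = c("ls", "mle")) {
  model <- match.arg(model)
  method <- match.arg(method)
  if (is.numeric(points)) points <- ssd_ranks(points)
  # one point per rank: tied species share a single plotting position
  pts <- points[!duplicated(points$rank), , drop = FALSE]
  x <- if (model_is_log(model)) pts$x else pts$value
  y <- pts$cum_freq
  if (length(unique(x)) < 3L) {
    stop("ssd_fit(): need at least 3 distinct values", call. = FALSE)
  }
  cdf <- model_cdf(model)
  start <- list(location = stats::median(x),
                scale = max(stats::IQR(x) / 2, 1e-3 * max(abs(x), 1)))

  if (method == "ls") {
    fit <- NULL
    # deterministic restart ladder: scale the start values, no RNG involved
    perturb <- rbind(c(1, 1), c(1, 0.5), c(1, 2), c(0.9, 1), c(1.1, 1.5), c(1, 0.25))
    for (k in seq_len(nrow(perturb))) {
      st <- list(location = start$location * perturb[k, 1],
                 scale = start$scale * perturb[k, 2])
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ cdf(x, location, scale), start = st,
                          lower = c(-Inf, 1e-12),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL
      )
      if (!is.null(fit)) break
    }
    if (is.null(fit)) {
      stop(sprintf("ssd_fit(): %s fit did not converge after restarts", model),
           call. = FALSE)
    }
    location <- stats::coef(fit)[["location"]]
    scale <- stats::coef(fit)[["scale"]]
  } else {
    dens <- if (model_is_logistic(model)) stats::dlogis else stats::dnorm
    nll <- function(p) -sum(dens(x, p[1], exp(p[2]), log = TRUE))
    opt <- stats::optim(c(start$location, log(start$scale)), nll, method = "BFGS")
    location <- opt$par[1]
    scale <- exp(opt$par[2])
  }

  fitted_y <- cdf(x, location, scale)
  ss_res <- sum((y - fitted_y)^2)
  ss_tot <- sum((y - mean(y))^2)
  a2 <- ad_statistic(x, function(z) cdf(z, location, scale))
  ad_p <- if (model_is_logistic(model)) NA_real_ else ad_p_normal(a2, length(x))
  out <- list(
    model = model,
    method = method,
    location = location,
    scale = scale,
    r2 = 1 - ss_res / ss_tot,
    rmse = sqrt(ss_res / length(y)),
    ad_stat = a2,
    ad_p = ad_p,
    n_points = length(y),
    points = transform(pts, fitted = fitted_y)
  )
  class(out) <- "ssd_fit"
  out$hc5 <- ssd_hcp(out, 0.05)
  out
}

#' Hazard concentration HCp
#'
#' Inverts the fitted CDF at fraction `p` and back-transforms to a
#' concentration: for log-domain models HCp = 10^(location +
#' scale * Q(p)) with Q the standard logistic or normal quantile. At p = 0.5
#' this is the model median; for the logistic family at p = 0.05 it equals
#' 10^(location - scale * ln 19).
#'
#' @param fit An `ssd_fit` object.
#' @param p Fraction of species affected, in (0, 1). Default 0.05.
#' @return Concentration in ug/L (log-domain models), or on the raw modelled
#'   scale otherwise.
#' @export
ssd_hcp <- function(fit, p = 0.05) {
  stopifnot(inherits(fit, "ssd_fit"), all(p > 0), all(p < 1))
  q <- fit$location + fit$scale * model_quantile(fit$model)(p)
  if (model_is_log(fit$model)) 10^q else q
}

#' Fit all candidate SSD models
#'
#' @param points `ssd_points` table or numeric concentrations.
#' @param models Candidate model names; defaults to the two log-domain
#'   families.
#' @param method Passed to [ssd_fit()].
#' @return Named list of `ssd_fit` objects (non-converged candidates are
#'   dropped with a warning).
#' @export
ssd_fit_candidates <- function(points,
                               models = c("log_logistic", "log_normal"),
                               method = "ls") {
  fits <- list()
  for (m in models) {
    f <- tryCatch(ssd_fit(points, model = m, method = method),
                  error = function(e) {
                    warning(sprintf("candidate %s dropped: %s", m, conditionMessage(e)),
                            call. = FALSE)
                    NULL
                  })
    if (!is.null(f)) fits[[m]] <- f
  }
  if (length(fits) == 0L) stop("ssd_fit_candidates(): no candidate converged",
                               call. = FALSE)
  fits
}

#' Select the best-fitting SSD model
#'
#' Maximizes r2; ties broken by lower RMSE, then lower Anderson-Darling
#' statistic. The selection trace (one row per candidate) is attached as
#' attribute `"trace"`.
#'
#' @param fits List of `ssd_fit` objects.
#' @return The selected `ssd_fit`.
#' @export
select_best_model <- function(fits) {
  if (length(fits) == 0L) stop("select_best_model(): no fits", call. = FALSE)
  trace <- data.frame(
    model = vapply(fits, `[[`, character(1), "model"),
    r2 = vapply(fits, `[[`, numeric(1), "r2"),
    rmse = vapply(fits, `[[`, numeric(1), "rmse"),
    ad_stat = vapply(fits, `[[`, numeric(1), "ad_stat"),
    stringsAsFactors = FALSE
  )
  o <- order(-trace$r2, trace$rmse, trace$ad_stat)
  best <- fits[[o[1L]]]
  attr(best, "trace") <- trace[o, , drop = FALSE]
  best
}

#' @export
print.ssd_fit <- function(x, ...) {
  cat(sprintf("SSD fit: %s (%s)\n", x$model,
              if (x$method == "ls") "least squares on CDF" else "maximum likelihood"))
  cat(sprintf("  location = %.4f, scale = %.4f (n = %d ranks)\n",
              x$location, x$scale, x$n_points))
  cat(sprintf("  r2 = %.4f, rmse = %.4f, A-D = %.4f%s\n",
              x$r2, x$rmse, x$ad_stat,
              if (is.na(x$ad_p)) "" else sprintf(" (p = %.3f)", x$ad_p)))
  cat(sprintf("  HC5 = %s ug/L\n", format(signif(x$hc5, 3))))
  invisible(x)
}

#' Plot an SSD fit
#'
#' Empirical plotting positions with the fitted CDF and the HC5 marker.
#'
#' @param x An `ssd_fit` object (log-domain models).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ssd_fit <- function(x, ...) {
  if (!model_is_log(x$model)) {
    stop("plot.ssd_fit(): only log-domain models are plotted", call. = FALSE)
  }
  pts <- x$points
  xx <- seq(min(pts$x) - 0.5, max(pts$x) + 0.5, length.out = 200)
  cdf <- model_cdf(x$model)
  graphics::plot(pts$x, pts$cum_freq, xlab = "log10 concentration (ug/L)",
                 ylab = "fraction of species affected",
                 main = sprintf("SSD (%s)", x$model), ...)
  graphics::lines(xx, cdf(xx, x$location, x$scale))
  graphics::abline(h = 0.05, lty = 3)
  graphics::abline(v = log10(x$hc5), lty = 3)
  invisible(x)
}

#' Export an SSD fit report as JSON
#'
#' @param fit An `ssd_fit` object.
#' @param path Output path.
#' @export
write_ssd_report <- function(fit, path) {
  report <- list(
    model = fit$model,
    method = fit$method,
    location = fit$location,
    scale = fit$scale,
    r2 = fit$r2,
    rmse = fit$rmse,
    ad_stat = fit$ad_stat,
    ad_p = fit$ad_p,
    hc5 = fit$hc5,
    n_points = fit$n_points,
    points = fit$points[, c("label", "x", "cum_freq", "fitted")]
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
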
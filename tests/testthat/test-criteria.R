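test_that("assessment-factor method divides the most sensitive value by the ACR", {
  rec <- screen_records(tox_fixture())$accepted
  sv <- species_values(rec, "acute")
  acr <- acr_estimate(rec)$overall
  res <- af_method(sv, acr)
  expect_equal(res$intermediates$atv, 123)
  expect_equal(res$intermediates$most_sensitive, "Nais elinguis")
  expect_equal(signif(res$lwqc, 3), 4.98)

  expect_equal(af_method(100, 10)$lwqc, 10)
  expect_equal(af_method(c(50, 100, 20), 1)$lwqc, 20)
  expect_error(af_method(numeric(0), 2), "no acute")
  # never exceeds the minimum value when acr >= 1
  set.seed(3)
  for (i in 1:5) {
    v <- rlnorm(6, 4, 1)
    a <- runif(1, 1, 50)
    expect_lte(af_method(v, a)$lwqc, min(v))
  }
})

test_that("final acute value matches closed-form constructions", {
  # four identical genus values: S = 0 and FAV equals that value
  expect_equal(tpr_fav(rep(250, 4))$fav, 250)

  # genus values built log-linearly in sqrt(P): lnG = a + b*sqrt(P) makes the
  # EPA regression exact, so S = b, L = a, FAV = exp(a + b*sqrt(0.05)).
  a <- log(80)
  b <- 2.3
  n <- 17
  P <- (1:4) / (n + 1)
  low4 <- exp(a + b * sqrt(P))
  rest <- seq(from = max(low4) * 5, by = 1000, length.out = n - 4)
  res <- tpr_fav(c(low4, rest))
  expect_equal(res$diagnostics$S, b, tolerance = 1e-9)
  expect_equal(res$diagnostics$L, a, tolerance = 1e-9)
  expect_equal(res$fav, exp(a + b * sqrt(0.05)), tolerance = 1e-9)
  expect_equal(res$diagnostics$P, P)

  # invariant to supply order
  shuffled <- tpr_fav(sample(c(low4, rest)))
  expect_equal(shuffled$fav, res$fav, tolerance = 1e-12)

  expect_error(tpr_fav(c(1, 2, 3)), "at least 4")
})

test_that("ranking on the reference genera picks the four lowest (frozen FAV)", {
  rec <- screen_records(tox_fixture())$accepted
  gv <- genus_values(species_values(rec, "acute"))
  res <- tpr_fav(gv)
  expect_equal(res$diagnostics$n_genera, 17L)
  expect_equal(sort(signif(res$diagnostics$gmav, 3)), c(123, 279, 400, 1650))
  expect_equal(res$diagnostics$P, (1:4) / 18)
  # regression constant: independent spreadsheet-style evaluation of the
  # EPA formula on these four genera
  lnG <- log(res$diagnostics$gmav)
  P <- res$diagnostics$P
  S <- sqrt((sum(lnG^2) - sum(lnG)^2 / 4) / (sum(P) - sum(sqrt(P))^2 / 4))
  expect_equal(res$fav, exp(S * sqrt(0.05) + (sum(lnG) - S * sum(sqrt(P))) / 4))
  expect_equal(res$fav, 88.27498, tolerance = 1e-6)
})

test_that("TPR criteria combine FAV, ACR and the final-value minimum rule", {
  # consistency with the published intermediate: a supplied FAV of 222 and
  # ACR 24.7 give CMC 111 and CCC 9.0
  res <- tpr_method(acr = 24.69049, fav = 222)
  expect_equal(res$swqc, 111)
  expect_equal(res$lwqc, 9.0, tolerance = 0.005)
  expect_equal(res$intermediates$ccc, res$intermediates$fcv)

  res2 <- tpr_method(acr = 2, fav = 200, fpv = 40)
  expect_equal(res2$swqc, 100)
  expect_equal(res2$lwqc, 40) # min(fcv = 100, fpv = 40)

  res3 <- tpr_method(acr = 1, fav = 100)
  expect_equal(res3$swqc, 50)
  expect_equal(res3$lwqc, 100)
  expect_match(paste(res3$provenance, collapse = "; "), "FPV unavailable")
})

test_that("SSD criteria divide HC5 by the assessment factors with ACR fallback", {
  rec <- screen_records(tox_fixture())$accepted
  sv_a <- species_values(rec, "acute")
  sv_c <- species_values(rec, "chronic")
  acr <- acr_estimate(rec)$overall

  res <- ssd_method(sv_a, sv_c, acr = acr, saf = 2, laf = 2, min_chronic_n = 8)
  hc5 <- res$intermediates$hc5_acute
  expect_equal(res$swqc * 2, hc5)        # swqc * saf = hc5 exactly
  expect_equal(res$lwqc * acr, hc5)      # fallback: lwqc * acr = hc5 exactly
  expect_match(paste(res$provenance, collapse = "; "), "insufficient")
  expect_null(res$intermediates$hc5_chronic)

  # identity factors pass the HC5 straight through
  res1 <- ssd_method(sv_a, sv_c, acr = 1, saf = 1, laf = 1)
  expect_equal(res1$swqc, res1$lwqc)
  expect_equal(res1$swqc, res1$intermediates$hc5_acute)

  # a sufficient chronic set is fitted directly
  set.seed(21)
  chron <- 10^rnorm(10, 2.5, 0.4)
  res2 <- ssd_method(sv_a, chron, acr = acr, min_chronic_n = 8)
  expect_false(is.null(res2$intermediates$hc5_chronic))
  expect_equal(res2$lwqc * 2, res2$intermediates$hc5_chronic)

  expect_error(ssd_method(c(10, 20), acr = 2), "insufficient acute")
  expect_error(ssd_method(sv_a, sv_c, acr = NULL), "no ACR")
})

test_that("criteria scale linearly with a global rescaling of the inputs", {
  rec <- screen_records(tox_fixture())$accepted
  sv <- species_values(rec, "acute")
  gv <- genus_values(sv)
  acr <- acr_estimate(rec)$overall
  cc <- 7.3
  expect_equal(af_method(sv$value * cc, acr)$lwqc,
               cc * af_method(sv$value, acr)$lwqc)
  expect_equal(tpr_fav(gv$value * cc)$fav, cc * tpr_fav(gv$value)$fav,
               tolerance = 1e-9)
  s1 <- ssd_method(sv$value, acr = acr)
  s2 <- ssd_method(sv$value * cc, acr = acr)
  expect_equal(s2$swqc, cc * s1$swqc, tolerance = 1e-4)
})
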
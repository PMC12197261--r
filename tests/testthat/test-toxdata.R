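test_that("geometric mean matches hand aggregates and basic algebra", {
  expect_equal(signif(geometric_mean(c(100, 10)), 3), 31.6)
  expect_equal(signif(geometric_mean(c(6000, 3000)), 3), 4240)
  expect_equal(geometric_mean(42), 42)
  # scale equivariance and permutation invariance
  set.seed(7)
  for (i in 1:10) {
    v <- rlnorm(5, 3, 1)
    cc <- runif(1, 0.01, 100)
    expect_equal(geometric_mean(cc * v), cc * geometric_mean(v))
    expect_equal(geometric_mean(sample(v)), geometric_mean(v))
  }
  expect_true(geometric_mean(c(1, 100)) >= 1 && geometric_mean(c(1, 100)) <= 100)
})

test_that("geometric mean rejects empty or nonpositive input, naming the entry", {
  expect_error(geometric_mean(numeric(0)), "empty")
  expect_error(geometric_mean(c(10, 0, 5)), "position 2")
  expect_error(geometric_mean(c(10, -1)), "nonpositive")
  expect_error(geometric_mean(c(1, Inf)), "non-finite")
})

test_that("screening accepts the reference table and reports rule violations", {
  scr <- screen_records(tox_fixture())
  expect_equal(nrow(scr$accepted), 47L)
  expect_equal(nrow(scr$rejected), 0L)

  bad <- rbind(
    make_records("A a", 0),                               # nonpositive
    make_records("B b", 10, test_type = "acute", endpoint = "NOEC"), # whitelist
    make_records("C c", 10, test_type = "chronic", endpoint = "IC50"),
    make_records("", 10),                                 # missing species
    make_records("D d", 10)                               # fine
  )
  scr2 <- screen_records(bad)
  expect_equal(nrow(scr2$accepted) + nrow(scr2$rejected), nrow(bad))
  expect_equal(scr2$rejected$rule,
               c("nonpositive concentration", "endpoint not allowed for acute",
                 "endpoint not allowed for chronic", "missing species"))
  expect_equal(scr2$accepted$species, "D d")

  # curated exclusion flag is honoured and logged, not silent
  flagged <- make_records("E e", 10)
  flagged$exclude <- TRUE
  scr3 <- screen_records(flagged)
  expect_equal(scr3$rejected$rule, "excluded by curation flag")
})

test_that("species and genus aggregation reproduce the reference table", {
  rec <- screen_records(tox_fixture())$accepted
  sva <- species_values(rec, "acute")
  svc <- species_values(rec, "chronic")
  gva <- genus_values(sva)
  gvc <- genus_values(svc)

  expect_equal(nrow(sva), 18L)
  expect_equal(nrow(gva), 17L)
  expect_equal(nrow(svc), 4L)
  expect_equal(nrow(gvc), 4L)
  expect_equal(sum(sva$n_records), 31L)
  expect_equal(sum(svc$n_records), 16L)

  expect_equal(signif(sva$value[sva$species == "Daphnia magna"], 3), 24800)
  expect_equal(sva$value[sva$species == "Nais elinguis"], 123)
  expect_equal(signif(svc$value[svc$species == "Pimephales promelas"], 3), 569)

  # every genus value printed in the source table, to 3 significant figures
  expect_equal(signif(gva$value[match(names(printed_genus_values), gva$genus)], 3),
               unname(printed_genus_values))
  expect_equal(signif(gvc$value[match(names(printed_genus_chronic), gvc$genus)], 3),
               unname(printed_genus_chronic))

  # invariants: aggregate between min and max; single-species genus identity
  for (sp in sva$species) {
    v <- rec$value[rec$species == sp & rec$test_type == "acute"]
    expect_true(sva$value[sva$species == sp] >= min(v) - 1e-9)
    expect_true(sva$value[sva$species == sp] <= max(v) + 1e-9)
  }
  singles <- gva$genus[gva$n_species == 1L]
  for (g in singles) {
    expect_equal(gva$value[gva$genus == g],
                 sva$value[sva$genus == g])
  }
})

test_that("acute-to-chronic ratio uses source-matched pairs", {
  rec <- screen_records(tox_fixture())$accepted
  acr <- acr_estimate(rec, pairing = "same_source")
  expect_setequal(acr$per_species$species,
                  c("Daphnia pulex", "Pimephales promelas"))
  # per-species ratios from matched sources
  dp <- acr$per_species[acr$per_species$species == "Daphnia pulex", ]
  expect_equal(dp$ratio, geometric_mean(c(12900, 15800, 17400)) /
                 geometric_mean(c(1310, 1310, 1310, 960, 960, 960, 700, 700, 700)))
  expect_equal(signif(acr$overall, 3), 24.7)
  # overall lies between per-species ratios
  expect_true(acr$overall >= min(acr$per_species$ratio))
  expect_true(acr$overall <= max(acr$per_species$ratio))

  # all-records pairing is the documented sensitivity variant
  acr_all <- acr_estimate(rec, pairing = "all_records")
  expect_equal(acr_all$overall, 19.77046, tolerance = 1e-6)

  # trivial algebra: identical acute and chronic sets give ratio 1
  same <- rbind(make_records("X x", c(10, 40), test_type = "acute"),
                make_records("X x", c(10, 40), test_type = "chronic"))
  expect_equal(acr_estimate(same)$overall, 1)
  two <- rbind(make_records("X x", 100, test_type = "acute"),
               make_records("X x", 10, test_type = "chronic"),
               make_records("Y y", 400, test_type = "acute"),
               make_records("Y y", 10, test_type = "chronic"))
  expect_equal(acr_estimate(two)$overall, 20)

  expect_error(acr_estimate(make_records("Z z", 5)), "not computable")
  # same_source requested but sources disjoint: species excluded and logged
  disjoint <- rbind(make_records("X x", 100, source_id = "A"),
                    make_records("X x", 10, test_type = "chronic", source_id = "B"),
                    make_records("Y y", 400, source_id = "C"),
                    make_records("Y y", 10, test_type = "chronic", source_id = "C"))
  est <- acr_estimate(disjoint, "same_source")
  expect_equal(est$per_species$species, "Y y")
  expect_match(est$log, "X x")
})

test_that("reading converts units, rejects separators, and round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,genus,test_type,endpoint,value,unit,source_id",
               "A a,A,acute,LC50,1.5,mg/L,S1",
               "B b,B,acute,EC50,250,ug/L,S2"), path)
  rec <- read_toxicity(path)
  expect_equal(rec$value, c(1500, 250))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,genus,test_type,endpoint,value,unit,source_id",
               "A a,A,acute,LC50,\"1,500\",ug/L,S1"), bad)
  expect_error(read_toxicity(bad), "separators")

  out <- withr::local_tempfile(fileext = ".csv")
  write_toxicity(tox_fixture(), out)
  again <- read_toxicity(out)
  cols <- c("species", "genus", "test_type", "endpoint", "value", "source_id")
  expect_identical(again[cols], tox_fixture()[cols])
})
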
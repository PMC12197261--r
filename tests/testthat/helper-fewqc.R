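# Shared fixtures, built in code.

tox_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- ferric_toxicity()
    cache
  }
})

# Minimal in-memory toxicity records (already in ug/L).
make_records <- function(species, value, test_type = "acute",
                         endpoint = if (test_type == "acute") "LC50" else "NOEC",
                         genus = species, source_id = "S1") {
  data.frame(species = species, genus = genus, test_type = test_type,
             endpoint = endpoint, value = value, source_id = source_id,
             exclude = FALSE, notes = "", stringsAsFactors = FALSE)
}

make_exposure <- function(mean, sd = NA_real_, min = NA_real_, max = NA_real_,
                          basin = "Basin A", province = basin, flags = "") {
  n <- length(mean)
  data.frame(site_id = sprintf("site%02d", seq_len(n)),
             province = rep_len(province, n), basin = rep_len(basin, n),
             mean = mean, sd = rep_len(sd, n),
             min = rep_len(min, n), max = rep_len(max, n),
             flags = rep_len(flags, n), stringsAsFactors = FALSE)
}

# Genus values printed in the reference table, for aggregation checks.
printed_genus_values <- c(
  Asellus = 124000, Ceriodaphnia = 33200, Chironomus = 1650, Daphnia = 15600,
  Duttaphrynus = 400, Gambusia = 99200, Lepomis = 20300, Melanoides = 8490,
  Nais = 123, Orconectes = 32000, Physa = 12100, Pimephales = 21800,
  Ptychocheilus = 54800, Salmo = 36300, Stenocypris = 279, Tubifex = 94300,
  Xenopus = 1000000
)
printed_genus_chronic <- c(Chlorella = 4240, Daphnia = 958, Lecane = 31.6,
                           Pimephales = 569)
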
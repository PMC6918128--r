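# Shared fixtures. Expensive objects are computed once per session and
# cached so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

tis_ref_table <- function(tis = example_tis()) {
  tibble::tibble(name = tis$name, formula = tis$formula,
                 adduct = vapply(tis$adducts, function(a) names(a)[1], ""),
                 rt = tis$rt)
}

# full-size characterization campaign under the study's acquisition design
# (5 compounds, 5 tIS, 7 x 4-fold dilutions + blank, 15 min gradient)
full_campaign <- function() {
  cached("full_campaign", {
    simulate_characterization_campaign(example_compounds(), example_tis(),
                                       seed = 20240901)
  })
}

full_campaign_library <- function() {
  cached("full_campaign_library", {
    characterize_campaign(full_campaign(), example_compounds(), example_tis(),
                          default_config())
  })
}

# small fast run: short gradient, one compound + two tIS
small_run <- function(amount = 400, seed = 11, drift = NULL) {
  cmp <- example_compounds()[1, ]
  cmp$rt <- 1.5
  tis <- example_tis()[1:2, ]
  tis$rt <- c(0.6, 2.4)
  sim <- simulate_run(dplyr::bind_rows(cmp, tis), c(amount, 200, 200),
                      drift = drift, seed = seed, gradient_min = 3)
  sim$compound <- cmp
  sim$tis <- tis
  sim
}

# a tiny deterministic library for I/O tests
toy_library <- function() {
  s1 <- ms_spectrum(c(94.0651, 138.055), c(999, 250),
                    annotation = c("C6H8N+; fragment", NA),
                    precursor_mz = 138.055, collision_energy = 30,
                    rt = 7.46, ion_mode = "positive")
  s2 <- ms_spectrum(c(76.0393, 118.0863), c(500, 1000),
                    precursor_mz = 118.0863, collision_energy = 10,
                    rt = 7.2, ion_mode = "positive")
  ms_library(
    name = c("trigonelline-like", "betaine-like"),
    formula = c("C7H7NO2", "C5H11NO2"),
    adduct = c("[M+H]+", "[M+H]+"),
    inchikey = c(synthetic_inchikey("trigonelline-like"),
                 synthetic_inchikey("betaine-like")),
    smiles = c(NA, NA),
    precursor_mz = c(138.055, 118.0863),
    experimental_mz = c(138.0561, NA),
    rt = c(7.46, 7.2),
    collision_energy = c(30, 10),
    spectrum = list(s1, s2),
    provenance = list(c(INSTRUMENT = "synthetic Q-TOF", COMMENT = "toy record"),
                      character()))
}

random_spectrum <- function(n = NULL) {
  if (is.null(n)) n <- sample(1:12, 1)
  ms_spectrum(sort(runif(n, 50, 500)) + seq_len(n) * 0.5,  # well separated
              runif(n, 1, 1000),
              precursor_mz = 500, collision_energy = 30, rt = 5)
}
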
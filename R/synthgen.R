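# Ground-truthed synthetic AIF data: dilution series for library
# construction and query datasets for identification. The generator emits
# scan data and a manifest from one source, so the manifest is exact truth.
#
# Emulated acquisition design: 15 min gradient, cycles of three alternating
# collision-energy channels (full scan, 10, 30 eV) at 6 scans/s, m/z range
# 40-1200, Gaussian elution peaks (sigma 3 s), saturating detector response
# (hard ceiling), adducts with carbon-13 isotope partners, a constant
# contaminant ion, uniform chemical noise, and smooth monotone RT drift.

#' Define a synthetic compound
#'
#' @param name Compound name (also seeds the synthetic InChIKey).
#' @param formula Elemental formula string, or `NA` for an "unknown" ion
#'   specified directly by `ion_mz` (used for decoys).
#' @param rt True retention time, minutes.
#' @param response_factor Detector response, AU per fmol (apex height
#'   before saturation).
#' @param adducts Named numeric vector of adduct name -> relative fraction
#'   (fractions must sum to at most 1; the first entry is the base adduct).
#' @param fragments Named list keyed by collision energy (`"10"`, `"30"`):
#'   each a data frame with columns `formula` (ion formula, `NA` allowed),
#'   `mz` (used when `formula` is `NA`) and `rel_intensity` (percent of the
#'   base fragment, in (0, 100]).
#' @param ion_mz Explicit precursor ion m/z when `formula` is `NA`.
#' @param inchikey Optional InChIKey; defaults to a synthetic (structurally
#'   valid but unresolvable) key derived from `name`.
#' @return One-row tibble with list-columns, ready to `rbind` into a
#'   compound set.
#' @export
synthetic_compound <- function(name, formula = NA, rt,
                               response_factor = 1000,
                               adducts = c("[M+H]+" = 1),
                               fragments = list(),
                               ion_mz = NULL,
                               inchikey = NULL) {
  if (any(unlist(lapply(fragments, function(f) f$rel_intensity)) <= 0) ||
      any(unlist(lapply(fragments, function(f) f$rel_intensity)) > 100)) {
    stop("fragment relative intensities must be in (0, 100]", call. = FALSE)
  }
  if (sum(adducts) > 1 + 1e-9) {
    stop("adduct fractions must sum to at most 1", call. = FALSE)
  }
  tibble::tibble(
    name = name,
    formula = as.character(formula),
    rt = rt,
    response_factor = response_factor,
    adducts = list(adducts),
    fragments = list(lapply(fragments, tibble::as_tibble)),
    ion_mz = if (is.null(ion_mz)) NA_real_ else ion_mz,
    inchikey = if (is.null(inchikey)) synthetic_inchikey(name) else inchikey)
}

#' Deterministic synthetic InChIKey
#'
#' Produces a structurally valid 27-character key (14-10-1 uppercase
#' blocks) hashed from a name. The keys are synthetic: they have the right
#' shape for grouping and round-trips but do not correspond to real
#' structures and must not be resolved against chemical databases.
#'
#' @param name Any string.
#' @return A synthetic InChIKey.
#' @export
synthetic_inchikey <- function(name) {
  codes <- utf8ToInt(name)
  h <- cumsum(codes * seq_along(codes) * 31)
  pick <- function(i) LETTERS[(h[(i - 1) %% length(h) + 1] + i * 17) %% 26 + 1]
  first <- paste0(vapply(1:14, pick, ""), collapse = "")
  second <- paste0(vapply(15:24, pick, ""), collapse = "")
  paste0(first, "-", second, "-N")
}

#' Dilution series design
#'
#' Serial dilution levels `c_k = top_conc / fold^k`, `k = 0..level_count-1`,
#' and the injected amount per level (`concentration x volume`; 1 uM x 1 uL
#' = 1000 fmol). The defaults reproduce a 7-level 4-fold series from 4.0 to
#' ~0.001 uM; 2 uL at the top level injects 8000 fmol.
#'
#' @param level_count Number of dilution levels (`>= 2`).
#' @param fold Dilution factor between levels (`> 1`).
#' @param top_conc Top concentration, uM.
#' @param volume_ul Injection volume, uL.
#' @return Tibble with columns `level`, `concentration_um`, `amount_fmol`.
#' @examples
#' make_dilution_series()
#' @export
make_dilution_series <- function(level_count = 7, fold = 4, top_conc = 4.0,
                                 volume_ul = 2) {
  stopifnot(level_count >= 2, fold > 1)
  k <- 0:(level_count - 1)
  conc <- top_conc / fold^k
  tibble::tibble(level = k + 1L, concentration_um = conc,
                 amount_fmol = conc * volume_ul * 1000)
}

#' Smooth monotone retention-time drift
#'
#' Returns `f(rt) = rt + shift + amplitude * sin(pi * rt / gradient_min)`,
#' a smooth perturbation that is monotone for `|amplitude| <
#' gradient_min / pi`.
#'
#' @param shift Constant offset, minutes.
#' @param amplitude Half-sine amplitude, minutes.
#' @param gradient_min Gradient length, minutes.
#' @return A function of retention time.
#' @export
make_drift <- function(shift = 0, amplitude = 0, gradient_min = 15) {
  if (abs(amplitude) >= gradient_min / pi) {
    stop("amplitude too large for a monotone drift", call. = FALSE)
  }
  function(rt) rt + shift + amplitude * sin(pi * rt / gradient_min)
}

# resolve a compound's ions per channel into a table of
# (mz, apex_height, kind, label) given its full-scan base height h0
.compound_ions <- function(cmp, h0, channel_energies, sat_ceiling,
                           survival = c("10" = 0.5, "30" = 0.1),
                           frag_scale = c("10" = 0.6, "30" = 0.4),
                           isotope_ratio_per_c = 0.011) {
  adducts <- cmp$adducts[[1]]
  known <- !is.na(cmp$formula)
  rows <- list()
  for (ch in channel_energies) {
    chkey <- as.character(ch)
    is_full <- ch == channel_energies[1]
    att <- if (is_full) 1 else unname(survival[chkey])
    if (is.na(att)) att <- 0.3
    has_frag_table <- !is_full &&
      !is.null(cmp$fragments[[1]][[chkey]]) &&
      nrow(cmp$fragments[[1]][[chkey]]) > 0
    for (ai in seq_along(adducts)) {
      # when a fragment table fully specifies this channel's base-adduct
      # pattern (it may itself list the surviving precursor ion), do not
      # also emit an attenuated precursor for the base adduct
      if (ai == 1 && has_frag_table) next
      aname <- names(adducts)[ai]
      frac <- adducts[[ai]]
      mz <- if (known) adduct_mz(cmp$formula, aname) else cmp$ion_mz
      h <- h0 * frac * att
      if (h <= 0) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        channel = ch, mz = mz, apex_height = h,
        kind = if (ai == 1) "precursor" else "adduct", label = aname,
        rel_intensity = NA_real_)
      if (is_full && known) {
        nC <- formula_counts(cmp$formula)[["C"]]
        if (nC > 0) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            channel = ch, mz = isotope_mz(mz, 1),
            apex_height = h * isotope_ratio_per_c * nC,
            kind = "isotope", label = paste0(aname, " isotope M+1"),
            rel_intensity = NA_real_)
        }
      }
    }
    if (!is_full) {
      frs <- cmp$fragments[[1]][[chkey]]
      if (!is.null(frs) && nrow(frs) > 0) {
        fmz <- vapply(seq_len(nrow(frs)), function(i) {
          if (!is.na(frs$formula[i])) {
            # fragment given as a singly charged cation formula
            (monoisotopic_mass(frs$formula[i]) - .electron_mass)
          } else frs$mz[i]
        }, 0)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          channel = ch, mz = fmz,
          apex_height = h0 * unname(frag_scale[chkey]) *
            frs$rel_intensity / 100,
          kind = "fragment",
          label = ifelse(is.na(frs$formula), sprintf("m/z %.4f", fmz),
                         paste0(frs$formula, "+")),
          rel_intensity = frs$rel_intensity)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out$apex_height <- pmin(out$apex_height, sat_ceiling)
  out
}

#' Simulate one AIF run
#'
#' Emits centroided scan cycles for a set of compounds at given injected
#' amounts, plus the exact ground-truth manifest. Full-scan channel carries
#' precursor adducts and their M+1 isotopes; collision-energy channels
#' carry the energy-specific fragment tables plus the attenuated precursor
#' ions. A constant contaminant ion and uniform chemical noise are added to
#' every channel; peak heights clip at the saturation ceiling; centroid
#' m/z jitter stays within 2 mDa.
#'
#' @param compounds Compound set (rows from [synthetic_compound()]).
#' @param amounts Injected amount per compound, fmol (recycled; 0 = absent).
#' @param drift Monotone RT perturbation function (see [make_drift()]).
#' @param noise_floor Chemical-noise intensity scale, AU.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param gradient_min Gradient length, minutes.
#' @param scan_rate Scans per second across all channels.
#' @param channel_energies Collision-energy channels, eV (first = full scan).
#' @param mass_range Acquired m/z range, Th.
#' @param sat_ceiling Detector saturation ceiling, AU.
#' @param sigma_min Gaussian elution peak sigma, minutes.
#' @param contaminant_mz,contaminant_height Constant background ion.
#' @param noise_peaks_per_scan Mean number of random noise centroids per
#'   scan.
#' @return List with elements `run` (an `aif_run`) and `manifest` (tibble:
#'   one row per emitted ion with compound, channel, kind, label, m/z,
#'   apex height after clipping, drifted RT, relative intensity for
#'   fragments, amount and noise floor).
#' @export
simulate_run <- function(compounds, amounts, drift = NULL,
                         noise_floor = 500, seed = NULL,
                         gradient_min = 15, scan_rate = 6,
                         channel_energies = c(0, 10, 30),
                         mass_range = c(40, 1200),
                         sat_ceiling = 5e6, sigma_min = 0.05,
                         contaminant_mz = 149.0233,
                         contaminant_height = 2000,
                         noise_peaks_per_scan = 3) {
  gen <- function() {
    .simulate_run_impl(compounds, amounts, drift, noise_floor, gradient_min,
                       scan_rate, channel_energies, mass_range, sat_ceiling,
                       sigma_min, contaminant_mz, contaminant_height,
                       noise_peaks_per_scan)
  }
  if (!is.null(seed)) withr::with_seed(seed, gen()) else gen()
}

.simulate_run_impl <- function(compounds, amounts, drift, noise_floor,
                               gradient_min, scan_rate, channel_energies,
                               mass_range, sat_ceiling, sigma_min,
                               contaminant_mz, contaminant_height,
                               noise_peaks_per_scan) {
  if (is.null(drift)) drift <- identity
  n_ch <- length(channel_energies)
  n_cycles <- floor(gradient_min * 60 * scan_rate / n_ch)
  scan_period_min <- 1 / scan_rate / 60
  cycles <- tibble::tibble(
    cycle = rep(seq_len(n_cycles), each = n_ch),
    channel = rep(channel_energies, n_cycles),
    time_min = ((rep(seq_len(n_cycles), each = n_ch) - 1) * n_ch +
                  rep(seq_len(n_ch), n_cycles) - 1) * scan_period_min)
  amounts <- rep_len(amounts, nrow(compounds))
  jitter_mz <- function(mz) {
    mz + pmax(pmin(stats::rnorm(length(mz), 0, 0.0007), 0.002), -0.002)
  }
  manifest <- list()
  points <- list()
  for (ci in seq_len(nrow(compounds))) {
    cmp <- compounds[ci, ]
    amt <- amounts[ci]
    if (amt <= 0) next
    rt_d <- drift(cmp$rt)
    if (rt_d < 0 || rt_d > gradient_min) {
      stop("compound '", cmp$name, "' RT ", round(rt_d, 2),
           " outside the gradient", call. = FALSE)
    }
    h0 <- min(cmp$response_factor * amt, sat_ceiling)
    ions <- .compound_ions(cmp, h0, channel_energies, sat_ceiling)
    manifest[[length(manifest) + 1L]] <- dplyr::mutate(
      ions, compound = cmp$name, rt = rt_d, amount_fmol = amt,
      noise_floor = noise_floor)
    for (k in seq_len(nrow(ions))) {
      grid <- cycles[cycles$channel == ions$channel[k], ]
      y <- ions$apex_height[k] *
        exp(-0.5 * ((grid$time_min - rt_d) / sigma_min)^2)
      y <- pmin(y, sat_ceiling)
      keep <- y > pmax(1, 0.001 * ions$apex_height[k])
      if (!any(keep)) next
      y <- y[keep] * exp(stats::rnorm(sum(keep), 0, 0.03))
      points[[length(points) + 1L]] <- tibble::tibble(
        cycle = grid$cycle[keep], channel = grid$channel[keep],
        time_min = grid$time_min[keep],
        mz = jitter_mz(rep(ions$mz[k], sum(keep))),
        intensity = pmin(y, sat_ceiling))
    }
  }
  # constant contaminant in every scan of every channel
  points[[length(points) + 1L]] <- tibble::tibble(
    cycle = cycles$cycle, channel = cycles$channel,
    time_min = cycles$time_min,
    mz = jitter_mz(rep(contaminant_mz, nrow(cycles))),
    intensity = contaminant_height * exp(stats::rnorm(nrow(cycles), 0, 0.03)))
  # uniform chemical noise
  n_noise <- stats::rpois(nrow(cycles), noise_peaks_per_scan)
  if (sum(n_noise) > 0) {
    idx <- rep(seq_len(nrow(cycles)), n_noise)
    points[[length(points) + 1L]] <- tibble::tibble(
      cycle = cycles$cycle[idx], channel = cycles$channel[idx],
      time_min = cycles$time_min[idx],
      mz = stats::runif(length(idx), mass_range[1], mass_range[2]),
      intensity = noise_floor * (0.3 + stats::rexp(length(idx))))
  }
  pts <- dplyr::bind_rows(points)
  pts <- pts[pts$mz >= mass_range[1] & pts$mz <= mass_range[2], ]
  run <- aif_run(pts, cycles = cycles, channel_energies = channel_energies,
                 mass_range = mass_range)
  man <- dplyr::bind_rows(manifest)
  if (is.null(man) || nrow(man) == 0) {
    man <- tibble::tibble(channel = numeric(), mz = numeric(),
                          apex_height = numeric(), kind = character(),
                          label = character(), rel_intensity = numeric(),
                          compound = character(), rt = numeric(),
                          amount_fmol = numeric(), noise_floor = numeric())
  }
  list(run = run, manifest = man)
}

#' Simulate a full characterization campaign
#'
#' One dilution series per compound (default 7 levels of 4-fold dilution
#' plus a blank), with all tIS spiked at a constant amount into every run
#' and an independent smooth monotone RT drift per run. Optionally, a tIS
#' coeluting with the characterized compound suffers ion suppression
#' (halved height) in the runs where the compound is present.
#'
#' @param compounds Compound set (rows from [synthetic_compound()]).
#' @param tis tIS set (rows from [synthetic_compound()]; `>= 2`, spanning
#'   the gradient).
#' @param seed Integer seed driving all randomness.
#' @param dilution Dilution design from [make_dilution_series()].
#' @param tis_amount_fmol Constant tIS amount per run.
#' @param max_shift,max_amplitude Per-run drift parameter ranges, minutes.
#' @param suppression Enable coelution ion suppression of tIS.
#' @param suppression_window Coelution window, minutes.
#' @param ... Passed to [simulate_run()].
#' @return List with `series` (named by compound: list of `runs`,
#'   `manifests`, `amounts` — the last run is the blank), `tis`,
#'   `dilution`, `drifts` (per compound: tibble of shift/amplitude).
#' @export
simulate_characterization_campaign <- function(
    compounds, tis, seed = 1L,
    dilution = make_dilution_series(),
    tis_amount_fmol = 200,
    max_shift = 0.25, max_amplitude = 0.2,
    suppression = FALSE, suppression_window = 0.3, ...) {
  stopifnot(nrow(tis) >= 2)
  withr::with_seed(seed, {
    series <- list()
    drifts <- list()
    for (ci in seq_len(nrow(compounds))) {
      cmp <- compounds[ci, ]
      amounts <- c(dilution$amount_fmol, 0)  # last run is the blank
      runs <- list()
      manifests <- list()
      dr <- tibble::tibble(shift = stats::runif(length(amounts), -max_shift,
                                                max_shift),
                           amplitude = stats::runif(length(amounts),
                                                    -max_amplitude,
                                                    max_amplitude))
      for (ri in seq_along(amounts)) {
        tis_run <- tis
        if (suppression && amounts[ri] > 0) {
          hit <- abs(tis$rt - cmp$rt) <= suppression_window
          tis_run$response_factor[hit] <- tis_run$response_factor[hit] * 0.5
        }
        all_cmp <- dplyr::bind_rows(cmp, tis_run)
        all_amt <- c(amounts[ri], rep(tis_amount_fmol, nrow(tis)))
        sim <- simulate_run(all_cmp, all_amt,
                            drift = make_drift(dr$shift[ri], dr$amplitude[ri]),
                            ...)
        runs[[ri]] <- sim$run
        manifests[[ri]] <- sim$manifest
      }
      series[[cmp$name]] <- list(runs = runs, manifests = manifests,
                                 amounts = amounts)
      drifts[[cmp$name]] <- dr
    }
    list(series = series, tis = tis, dilution = dilution, drifts = drifts)
  })
}

#' Simulate a query dataset with decoys
#'
#' One run containing a true library compound plus decoy features sharing
#' its nominal precursor m/z but eluting at other retention times with
#' disjoint fragment sets — the identification test bed: AMRT alone cannot
#' separate them, MS2 can.
#'
#' @param true_compound One row from [synthetic_compound()].
#' @param decoys Compound rows (typically `formula = NA` with `ion_mz`
#'   equal to the true precursor m/z and unrelated fragments).
#' @param tis Optional tIS set spiked into the run.
#' @param seed Integer seed.
#' @param amount_fmol Injected amount of the true compound (and decoys).
#' @param tis_amount_fmol tIS amount.
#' @param drift Drift function for the run.
#' @param ... Passed to [simulate_run()].
#' @return List with `run`, `manifest`, and `truth` (tibble: name, m/z,
#'   drifted RT, `is_true`).
#' @export
simulate_query_dataset <- function(true_compound, decoys, tis = NULL,
                                   seed = 1L, amount_fmol = 500,
                                   tis_amount_fmol = 200,
                                   drift = make_drift(0.1, 0.1), ...) {
  all_cmp <- dplyr::bind_rows(true_compound, decoys,
                              if (!is.null(tis)) tis)
  n_t <- if (is.null(tis)) 0 else nrow(tis)
  amounts <- c(rep(amount_fmol, nrow(true_compound) + nrow(decoys)),
               rep(tis_amount_fmol, n_t))
  sim <- simulate_run(all_cmp, amounts, drift = drift, seed = seed, ...)
  prec_mz <- function(cmp) {
    if (!is.na(cmp$formula)) adduct_mz(cmp$formula, names(cmp$adducts[[1]])[1])
    else cmp$ion_mz
  }
  truth <- tibble::tibble(
    name = c(true_compound$name, decoys$name),
    mz = c(prec_mz(true_compound),
           vapply(seq_len(nrow(decoys)), function(i) prec_mz(decoys[i, ]), 0)),
    rt = drift(c(true_compound$rt, decoys$rt)),
    is_true = c(rep(TRUE, nrow(true_compound)), rep(FALSE, nrow(decoys))))
  c(sim, list(truth = truth))
}

#' Built-in example compound and tIS sets
#'
#' Five characterized compounds with known formulas, adduct patterns and
#' energy-specific fragment tables (all fragments are chemically valid
#' subformula ions of the protonated molecule, so annotation retains
#' them), and five tIS spanning the 15 min gradient. `example_decoys()`
#' returns two unknown ions at the nominal m/z of the first example
#' compound but different RTs and unrelated fragments.
#'
#' @return Compound-set tibbles.
#' @export
example_compounds <- function() {
  dplyr::bind_rows(
    synthetic_compound(
      "trigonelline-like", "C7H7NO2", rt = 7.46, response_factor = 2000,
      adducts = c("[M+H]+" = 0.8, "[M+Na]+" = 0.1, "[M+K]+" = 0.05),
      fragments = list(
        "10" = data.frame(formula = c("C7H8NO2", "C6H8N"),
                          mz = NA, rel_intensity = c(100, 35)),
        "30" = data.frame(formula = c("C6H8N", "C6H6N", "C5H4N", "C7H8NO2"),
                          mz = NA, rel_intensity = c(100, 20, 12, 25)))),
    # two positional isomers of the first compound: same formula and
    # precursor m/z, distinct RTs and fragmentation (the classic
    # isobaric-isomer ambiguity AMRT alone cannot resolve)
    synthetic_compound(
      "aminobenzoate-like", "C7H7NO2", rt = 5.10, response_factor = 1500,
      adducts = c("[M+H]+" = 0.85, "[M+Na]+" = 0.05),
      fragments = list(
        "10" = data.frame(formula = c("C7H8NO2", "C7H6NO"),
                          mz = NA, rel_intensity = c(100, 45)),
        "30" = data.frame(formula = c("C7H6NO", "C6H6N", "C5H6N"),
                          mz = NA, rel_intensity = c(100, 30, 40)))),
    synthetic_compound(
      "methylnicotinate-like", "C7H7NO2", rt = 6.70, response_factor = 1200,
      adducts = c("[M+H]+" = 0.9, "[M+K]+" = 0.05),
      fragments = list(
        "10" = data.frame(formula = c("C7H8NO2", "C6H8N"),
                          mz = NA, rel_intensity = c(100, 20)),
        "30" = data.frame(formula = c("C6H8N", "C5H5", "C3H4N"),
                          mz = NA, rel_intensity = c(100, 35, 15)))),
    synthetic_compound(
      "glutamate-like", "C5H9NO4", rt = 11.00, response_factor = 900,
      adducts = c("[M+H]+" = 0.9),
      fragments = list(
        "10" = data.frame(formula = c("C5H10NO4", "C5H8NO3", "C4H8NO2"),
                          mz = NA, rel_intensity = c(100, 55, 20)),
        "30" = data.frame(formula = c("C4H8NO2", "C4H6NO", "C3H6N"),
                          mz = NA, rel_intensity = c(100, 40, 30)))),
    synthetic_compound(
      "caffeine-like", "C8H10N4O2", rt = 3.80, response_factor = 1800,
      adducts = c("[M+H]+" = 0.95),
      fragments = list(
        "10" = data.frame(formula = c("C8H11N4O2", "C7H11N4O"),
                          mz = NA, rel_intensity = c(100, 18)),
        "30" = data.frame(formula = c("C6H8N3O", "C5H8N3", "C8H11N4O2"),
                          mz = NA, rel_intensity = c(100, 35, 40)))))
}

#' @rdname example_compounds
#' @export
example_tis <- function() {
  dplyr::bind_rows(
    synthetic_compound("tis-A", "C5H5N5", rt = 1.50, response_factor = 1500),
    synthetic_compound("tis-B", "C4H9NO3", rt = 4.50, response_factor = 1500),
    synthetic_compound("tis-C", "C6H6N2O", rt = 7.50, response_factor = 1500),
    synthetic_compound("tis-D", "C3H7NO2S", rt = 10.50, response_factor = 1500),
    synthetic_compound("tis-E", "C7H14N2O3", rt = 13.50, response_factor = 1500))
}

#' @rdname example_compounds
#' @export
example_decoys <- function() {
  mz <- adduct_mz("C7H7NO2", "[M+H]+")
  dplyr::bind_rows(
    synthetic_compound(
      "decoy-early", formula = NA, rt = 4.99, response_factor = 2500,
      ion_mz = mz,
      fragments = list(
        "10" = data.frame(formula = NA, mz = c(53.25, 71.92),
                          rel_intensity = c(100, 60)),
        "30" = data.frame(formula = NA, mz = c(45.37, 58.81, 83.64),
                          rel_intensity = c(100, 70, 30)))),
    synthetic_compound(
      "decoy-late", formula = NA, rt = 6.58, response_factor = 2200,
      ion_mz = mz,
      fragments = list(
        "10" = data.frame(formula = NA, mz = c(61.44, 97.23),
                          rel_intensity = c(100, 40)),
        "30" = data.frame(formula = NA, mz = c(49.56, 76.18, 104.72),
                          rel_intensity = c(100, 55, 25)))))
}

#' Read / write compound specification files
#'
#' Human-editable YAML: a list of compounds, each with name, formula (or
#' ion_mz), rt, response_factor, adducts (name: fraction) and fragments
#' (energy: list of \{formula or mz, rel_intensity\}).
#'
#' @param path YAML file.
#' @param compounds Compound-set tibble (for writing).
#' @return `read_compound_specs`: a compound-set tibble.
#' @export
read_compound_specs <- function(path) {
  spec <- yaml::read_yaml(path)
  dplyr::bind_rows(lapply(spec, function(s) {
    frs <- lapply(s$fragments %||% list(), function(fl) {
      data.frame(
        formula = vapply(fl, function(x) as.character(x$formula %||% NA), ""),
        mz = vapply(fl, function(x) as.numeric(x$mz %||% NA), 0),
        rel_intensity = vapply(fl, function(x) as.numeric(x$rel_intensity), 0))
    })
    synthetic_compound(
      name = s$name, formula = s$formula %||% NA, rt = s$rt,
      response_factor = s$response_factor %||% 1000,
      adducts = unlist(s$adducts %||% list("[M+H]+" = 1)),
      fragments = frs,
      ion_mz = s$ion_mz, inchikey = s$inchikey)
  }))
}

#' @rdname read_compound_specs
#' @export
write_compound_specs <- function(compounds, path) {
  lst <- lapply(seq_len(nrow(compounds)), function(i) {
    cmp <- compounds[i, ]
    frs <- lapply(cmp$fragments[[1]], function(f) {
      lapply(seq_len(nrow(f)), function(j) {
        out <- list(rel_intensity = f$rel_intensity[j])
        if (!is.na(f$formula[j])) out$formula <- f$formula[j]
        else out$mz <- f$mz[j]
        out
      })
    })
    out <- list(name = cmp$name, rt = cmp$rt,
                response_factor = cmp$response_factor,
                adducts = as.list(cmp$adducts[[1]]),
                inchikey = cmp$inchikey)
    if (!is.na(cmp$formula)) out$formula <- cmp$formula
    if (!is.na(cmp$ion_mz)) out$ion_mz <- cmp$ion_mz
    if (length(frs)) out$fragments <- frs
    out
  })
  yaml::write_yaml(lst, path)
  invisible(path)
}
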
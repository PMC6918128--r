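# Pipeline orchestration: the library-construction chain (tIS RT alignment
# -> dual deconvolution -> 1% intensity filter -> annotation -> strip ->
# curation) and AMRT+MS2 identification of query runs. These functions are
# what the command-line wrapper (inst/cli/aif.R) calls.

#' Default pipeline configuration
#'
#' All tunables in one named list: tolerances (`mz_tol`, `bin_tol`,
#' `frag_tol` in Th; `rt_tol` in minutes), the tIS anchor search window,
#' the relative-intensity filter, CorrDec settings (`noise_level`,
#' `min_samples`, `r_threshold`), the MS2 acceptance threshold (percent),
#' the RT-spread group check window, the saturation ceiling used to pick a
#' representative (nonsaturated) dilution run, and the seed.
#'
#' @param ... Overrides merged over the defaults.
#' @return Named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    mz_tol = 0.01,              # Th, AMRT and EIC window
    rt_tol = 0.7,               # min, AMRT window
    bin_tol = 0.01,             # Th, spectral match binning
    frag_tol = 0.01,            # Th, deconvolution fragment binning
    tis_search_window = 1.5,    # min, anchor search around reference RT
    intensity_threshold_pct = 1.0,
    noise_level = 1000,         # AU, CorrDec above-noise criterion
    min_samples = 4,            # CorrDec minimum above-noise runs
    r_threshold = 0.90,         # CorrDec Pearson threshold
    ms2_threshold = 70,         # %, identification acceptance
    rt_group_window = 1.0,      # min, group RT-spread flag
    sat_ceiling = 5e6,          # AU, saturation ceiling
    min_peak_height = 500,      # AU, feature/peak detection floor
    annotation_tol = 0.01,      # Th
    seed = 1L
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Read a pipeline configuration file
#'
#' YAML file of overrides, merged over [default_config()].
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return Named list.
#' @export
read_config <- function(path = NULL) {
  if (is.null(path)) return(default_config())
  do.call(default_config, yaml::read_yaml(path))
}

.log_row <- function(stage, compound, detail, n) {
  tibble::tibble(stage = stage, compound = compound, detail = detail, n = n)
}

#' Build library records from one compound's dilution series
#'
#' The full characterization chain for one chemical standard: locate tIS
#' anchors and build per-run RT maps; pick a representative nonsaturated
#' run; deconvolve each detectable adduct at each collision energy with
#' both the least-squares and the correlation method; filter peaks below
#' the relative-intensity threshold; annotate fragments/adducts/isotopes;
#' strip unannotated peaks; emit one record per adduct x energy (the
#' correlation spectrum when available, otherwise the least-squares one),
#' with the corrected RT and the theoretical precursor m/z (the measured
#' value retained in `experimental_mz`).
#'
#' @param runs List of `aif_run` (the dilution series; blanks allowed).
#' @param compound One compound row: `name`, `formula`, `adducts` (named
#'   fractions or names; first = base), `inchikey`, optional `rt` (expected,
#'   minutes).
#' @param tis_ref tIS reference table: `name`, `formula`, `adduct`, `rt`.
#' @param config From [default_config()].
#' @return List: `library` (an [ms_library]), `log` (stage/count tibble).
#' @export
characterize_series <- function(runs, compound, tis_ref,
                                config = default_config()) {
  stopifnot(length(runs) >= 1)
  log <- list()
  cname <- compound$name
  # 1. RT maps per run
  maps <- lapply(runs, function(run) {
    obs <- locate_tis_anchors(run, tis_ref, mz_tol = config$mz_tol,
                              search_window = config$tis_search_window,
                              min_height = config$min_peak_height)
    tryCatch(build_rt_map(tis_ref[, c("name", "rt")], obs),
             error = function(e) NULL)
  })
  log[[length(log) + 1L]] <- .log_row("rt_maps", cname, "built",
                                      sum(!vapply(maps, is.null, TRUE)))
  adducts <- compound$adducts[[1]]
  adduct_names <- if (is.null(names(adducts))) adducts else names(adducts)
  full_ch <- runs[[1]]$channel_energies[1]
  frag_channels <- setdiff(runs[[1]]$channel_energies, full_ch)
  expected_rt <- if ("rt" %in% names(compound)) compound$rt else NULL

  # 2. precursor detection per run at the base adduct
  base_mz <- adduct_mz(compound$formula, adduct_names[1])
  prec <- lapply(runs, function(run) {
    eic <- extract_eic(run, full_ch, base_mz, tol = config$mz_tol)
    pk <- detect_peaks(eic, min_height = config$min_peak_height)
    if (!is.null(expected_rt) && nrow(pk) > 0) {
      pk <- pk[abs(pk$apex_rt - expected_rt) <= config$tis_search_window, ]
    }
    if (nrow(pk) == 0) return(NULL)
    pk[which.max(pk$height), ]
  })
  h <- vapply(prec, function(p) if (is.null(p)) 0 else p$height, 0)
  if (all(h == 0)) stop("no detectable precursor for '", cname, "'",
                        call. = FALSE)
  nonsat <- which(h > 0 & h < 0.98 * config$sat_ceiling)
  rep_i <- if (length(nonsat) > 0) nonsat[which.max(h[nonsat])] else which.max(h)
  log[[length(log) + 1L]] <- .log_row("representative_run", cname,
                                      paste0("height=", round(h[rep_i])), rep_i)
  rep_run <- runs[[rep_i]]
  rep_map <- maps[[rep_i]]
  rt_corr <- if (!is.null(rep_map)) {
    correct_rt(rep_map, prec[[rep_i]]$apex_rt)
  } else prec[[rep_i]]$apex_rt

  # measured precursor m/z near the apex (kept as the experimental value)
  measure_mz <- function(run, pk, mz) {
    pts <- run$points[run$points$channel == full_ch &
                        abs(run$points$mz - mz) <= config$mz_tol &
                        abs(run$points$time_min - pk$apex_rt) <= 0.05, ]
    if (nrow(pts) == 0) return(NA_real_)
    sum(pts$mz * pts$intensity) / sum(pts$intensity)
  }

  records <- list()
  for (ad in adduct_names) {
    ad_mz <- adduct_mz(compound$formula, ad)
    eic <- extract_eic(rep_run, full_ch, ad_mz, tol = config$mz_tol)
    pk <- detect_peaks(eic, min_height = config$min_peak_height)
    pk <- pk[abs(pk$apex_rt - prec[[rep_i]]$apex_rt) <= 0.1, ]
    if (nrow(pk) == 0) {
      log[[length(log) + 1L]] <- .log_row("adduct_not_detected", cname, ad, 0)
      next
    }
    pk <- pk[which.max(pk$height), ]
    exp_mz <- measure_mz(rep_run, pk, ad_mz)
    for (ch in frag_channels) {
      dec_ls <- ms2dec(rep_run, pk, channel = ch, precursor_mz = ad_mz,
                       frag_tol = config$frag_tol,
                       saturation_ceiling = config$sat_ceiling)
      dec_corr <- corrdec(runs, precursor_mz = ad_mz, channel = ch,
                          noise_level = config$noise_level,
                          min_samples = config$min_samples,
                          r_threshold = config$r_threshold,
                          mz_tol = config$mz_tol,
                          frag_tol = config$frag_tol,
                          expected_rt = pk$apex_rt, rt_window = 0.5)
      if (is.null(dec_corr)) {
        log[[length(log) + 1L]] <- .log_row(
          "corrdec_declined", cname,
          paste0(ad, " @", ch, "eV: <", config$min_samples,
                 " runs above noise"), sum(h > config$noise_level))
      }
      spec <- if (!is.null(dec_corr) && nrow(dec_corr) > 0) dec_corr else dec_ls
      method <- attr(spec, "method")
      n_raw <- nrow(spec)
      spec <- filter_relative_intensity(spec, config$intensity_threshold_pct)
      spec <- annotate_fragments(spec, compound$formula, ad,
                                 tol = config$annotation_tol)
      n_ann <- sum(!is.na(spec$annotation))
      spec <- strip_unannotated(spec)
      spec <- normalize_spectrum(spec)
      log[[length(log) + 1L]] <- .log_row(
        "spectrum", cname,
        paste0(ad, " @", ch, "eV ", method, ": raw=", n_raw,
               " annotated=", n_ann), nrow(spec))
      if (nrow(spec) == 0) next
      attr(spec, "precursor_mz") <- ad_mz
      attr(spec, "collision_energy") <- ch
      attr(spec, "rt") <- rt_corr
      records[[length(records) + 1L]] <- ms_library(
        name = cname, formula = compound$formula, adduct = ad,
        inchikey = compound$inchikey, smiles = NA,
        precursor_mz = if (is.na(exp_mz)) ad_mz else exp_mz,
        experimental_mz = NA, rt = rt_corr, ion_mode = "positive",
        collision_energy = ch, spectrum = list(spec),
        provenance = list(c(COMMENT = paste0("deconvolution=", method))))
    }
  }
  lib <- if (length(records)) {
    as_ms_library(dplyr::bind_rows(records))
  } else ms_library()
  if (nrow(lib) > 0) lib <- replace_precursor_mz(lib)
  list(library = lib, log = dplyr::bind_rows(log))
}

#' Characterize a whole campaign
#'
#' Runs [characterize_series()] for every compound of a simulated (or
#' assembled) campaign and concatenates the resulting records.
#'
#' @param campaign Output of [simulate_characterization_campaign()], or any
#'   list with `series[[name]]$runs` per compound.
#' @param compounds Compound table (rows as in [synthetic_compound()]).
#' @param tis tIS table (rows as in [synthetic_compound()]); reference RTs
#'   are taken from its `rt` column and the first adduct of each tIS.
#' @param config From [default_config()].
#' @return List: `library`, `log`.
#' @export
characterize_campaign <- function(campaign, compounds, tis,
                                  config = default_config()) {
  tis_ref <- tibble::tibble(
    name = tis$name, formula = tis$formula,
    adduct = vapply(tis$adducts, function(a) names(a)[1], ""),
    rt = tis$rt)
  libs <- list()
  logs <- list()
  for (ci in seq_len(nrow(compounds))) {
    cmp <- compounds[ci, ]
    runs <- campaign$series[[cmp$name]]$runs
    res <- characterize_series(runs, cmp, tis_ref, config)
    libs[[ci]] <- res$library
    logs[[ci]] <- res$log
  }
  lib <- as_ms_library(dplyr::bind_rows(libs))
  list(library = lib, log = dplyr::bind_rows(logs))
}

#' Curate a spectral library
#'
#' Batch curation of an existing library: relative-intensity filtering,
#' re-annotation against each record's formula and adduct, removal of
#' unannotated peaks, replacement of the experimental precursor m/z by the
#' theoretical value (the measurement moves to `experimental_mz`), and
#' group consistency checks. Idempotent: curating a curated library
#' changes nothing.
#'
#' @param lib An [ms_library].
#' @param config From [default_config()].
#' @param annotate Re-annotate and strip peaks (requires formula + adduct
#'   on every record).
#' @return List: `library` (curated), `groups` (from [group_records()]).
#' @export
curate_library <- function(lib, config = default_config(), annotate = TRUE) {
  if (nrow(lib) > 0) {
    lib$spectrum <- lapply(seq_len(nrow(lib)), function(i) {
      s <- filter_relative_intensity(lib$spectrum[[i]],
                                     config$intensity_threshold_pct)
      if (annotate && !is.na(lib$formula[i]) && !is.na(lib$adduct[i])) {
        s <- annotate_fragments(s, lib$formula[i], lib$adduct[i],
                                tol = config$annotation_tol)
        s <- strip_unannotated(s)
      }
      normalize_spectrum(s)
    })
    lib <- replace_precursor_mz(lib)
  }
  groups <- group_records(lib, rt_window = config$rt_group_window)
  list(library = lib, groups = groups)
}

#' Detect library-targeted features in a query run
#'
#' For every distinct precursor m/z in the library, extracts the full-scan
#' EIC, detects chromatographic peaks, measures each peak's m/z from the
#' centroids at its apex, corrects its RT through the run's tIS map (when
#' given) and attaches least-squares-deconvoluted MS2 spectra per
#' collision-energy channel.
#'
#' @param run An `aif_run`.
#' @param lib An [ms_library] providing the target m/z values.
#' @param rt_map Optional `rt_map` for RT correction.
#' @param config From [default_config()].
#' @return Feature tibble: `feature_id`, `mz`, `rt`, `height`, `ms2`
#'   (list-column of per-energy spectra).
#' @export
detect_query_features <- function(run, lib, rt_map = NULL,
                                  config = default_config()) {
  full_ch <- run$channel_energies[1]
  frag_channels <- setdiff(run$channel_energies, full_ch)
  targets <- unique(round(lib$precursor_mz, 4))
  rows <- list()
  for (tmz in targets) {
    eic <- extract_eic(run, full_ch, tmz, tol = config$mz_tol)
    pks <- detect_peaks(eic, min_height = config$min_peak_height)
    for (k in seq_len(nrow(pks))) {
      pk <- pks[k, ]
      pts <- run$points[run$points$channel == full_ch &
                          abs(run$points$mz - tmz) <= config$mz_tol &
                          abs(run$points$time_min - pk$apex_rt) <= 0.05, ]
      meas_mz <- if (nrow(pts) > 0) {
        sum(pts$mz * pts$intensity) / sum(pts$intensity)
      } else tmz
      ms2 <- lapply(frag_channels, function(ch) {
        s <- ms2dec(run, pk, channel = ch, precursor_mz = tmz,
                    frag_tol = config$frag_tol,
                    saturation_ceiling = config$sat_ceiling)
        filter_relative_intensity(s, config$intensity_threshold_pct)
      })
      names(ms2) <- as.character(frag_channels)
      rt <- if (!is.null(rt_map)) correct_rt(rt_map, pk$apex_rt) else pk$apex_rt
      rows[[length(rows) + 1L]] <- tibble::tibble(
        feature_id = sprintf("F%.4f@%.2f", tmz, pk$apex_rt),
        mz = meas_mz, rt = rt, height = pk$height, ms2 = list(ms2))
    }
  }
  out <- dplyr::bind_rows(rows)
  if (is.null(out) || nrow(out) == 0) {
    out <- tibble::tibble(feature_id = character(), mz = numeric(),
                          rt = numeric(), height = numeric(), ms2 = list())
  }
  out
}

#' Identify features in a query run against a library
#'
#' AMRT candidate search, MS2 dot-product scoring and confidence-level
#' assignment in one call.
#'
#' @param run An `aif_run`.
#' @param lib A curated [ms_library].
#' @param tis_ref Optional tIS reference table (`name`, `formula`,
#'   `adduct`, `rt`) for RT correction of the query run.
#' @param config From [default_config()].
#' @param same_batch Passed to [assign_level()].
#' @return List: `features`, `matches` (scored, leveled), `rt_map`.
#' @export
identify_run <- function(run, lib, tis_ref = NULL,
                         config = default_config(), same_batch = FALSE) {
  rt_map <- NULL
  if (!is.null(tis_ref)) {
    obs <- locate_tis_anchors(run, tis_ref, mz_tol = config$mz_tol,
                              search_window = config$tis_search_window,
                              min_height = config$min_peak_height)
    rt_map <- tryCatch(build_rt_map(tis_ref[, c("name", "rt")], obs),
                       error = function(e) NULL)
  }
  features <- detect_query_features(run, lib, rt_map = rt_map, config = config)
  cand <- find_amrt_matches(features, lib, mz_tol = config$mz_tol,
                            rt_tol = config$rt_tol)
  scored <- score_matches(cand, features, lib, bin_tol = config$bin_tol,
                          ms2_threshold = config$ms2_threshold)
  scored <- assign_level(scored, same_batch = same_batch)
  list(features = features, matches = scored, rt_map = rt_map)
}
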
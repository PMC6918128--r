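# Library curation engine: spectral dot product, InChIKey grouping and
# consistency checks, precursor m/z replacement, consensus spectra,
# product-ion frequencies and library comparison.

#' Dot-product similarity of two spectra
#'
#' Peaks are matched greedily by nearest m/z within `bin_tol` (each peak
#' used at most once, ties to the lower m/z); the similarity is the squared
#' cosine of the matched-plus-unmatched intensity vectors, in percent.
#' Symmetric, in \[0, 100\].
#'
#' @param a,b [ms_spectrum] objects (or peak tables with `mz`, `intensity`).
#' @param bin_tol Match tolerance, Th.
#' @return Similarity in percent; 0 (with a warning) if either spectrum is
#'   empty.
#' @examples
#' a <- ms_spectrum(c(100, 110), c(100, 50))
#' b <- ms_spectrum(c(100, 110), c(50, 100))
#' dot_product(a, b)  # 64
#' @export
dot_product <- function(a, b, bin_tol = 0.01) {
  if (bin_tol <= 0) stop("bin_tol must be > 0", call. = FALSE)
  if (nrow(a) == 0 || nrow(b) == 0) {
    warning("empty spectrum in dot_product; similarity is 0", call. = FALSE)
    return(0)
  }
  pairs <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
  pairs$dmz <- abs(a$mz[pairs$i] - b$mz[pairs$j])
  pairs <- pairs[pairs$dmz <= bin_tol, ]
  pairs <- pairs[order(pairs$dmz, a$mz[pairs$i]), ]
  used_a <- logical(nrow(a))
  used_b <- logical(nrow(b))
  x <- numeric(0)
  y <- numeric(0)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE
    used_b[j] <- TRUE
    x <- c(x, a$intensity[i])
    y <- c(y, b$intensity[j])
  }
  x <- c(x, a$intensity[!used_a], rep(0, sum(!used_b)))
  y <- c(y, rep(0, sum(!used_a)), b$intensity[!used_b])
  if (sum(x^2) == 0 || sum(y^2) == 0) return(0)
  100 * sum(x * y)^2 / (sum(x^2) * sum(y^2))
}

#' Group library records by InChIKey
#'
#' Partitions a library by the full InChIKey or (default) its first 14
#' characters, which hash the molecular skeleton, so that stereoisomer and
#' salt-form records of one compound fall in one group. Records without a
#' valid InChIKey become flagged singleton groups.
#'
#' @param lib An [ms_library].
#' @param by `"first_block"` (default) or `"full"`.
#' @param rt_window RT spread threshold (minutes) forwarded to
#'   [check_group_consistency()].
#' @return Tibble with one row per group: `key`, `n_records`, `records`
#'   (list of [ms_library] subsets), `missing_key`, plus the consistency
#'   columns of [check_group_consistency()].
#' @export
group_records <- function(lib, by = c("first_block", "full"),
                          rt_window = 1.0) {
  by <- match.arg(by)
  valid <- is_inchikey(lib$inchikey) & !is.na(lib$inchikey)
  key <- rep(NA_character_, nrow(lib))
  key[valid] <- if (by == "full") lib$inchikey[valid] else
    inchikey_first_block(lib$inchikey[valid])
  key[!valid] <- paste0(".singleton-", which(!valid))
  idx <- split(seq_len(nrow(lib)), key)
  rows <- lapply(names(idx), function(k) {
    sub <- as_ms_library(lib[idx[[k]], ])
    flags <- check_group_consistency(sub, rt_window = rt_window)
    tibble::tibble(key = k, n_records = nrow(sub), records = list(sub),
                   missing_key = grepl("^\\.singleton-", k),
                   formula_mismatch = flags$formula_mismatch,
                   rt_spread_exceeded = flags$rt_spread_exceeded,
                   rt_spread = flags$rt_spread)
  })
  dplyr::bind_rows(rows)
}

#' Consistency flags for one compound group
#'
#' Records of the same compound should share one elemental formula and
#' elute at similar retention times; a spread of `rt_window` (default 1
#' minute) or more suggests records from different chromatographic methods.
#'
#' @param records An [ms_library] holding the group's records.
#' @param rt_window RT spread threshold, minutes.
#' @return One-row tibble: `formula_mismatch`, `rt_spread_exceeded`,
#'   `rt_spread`.
#' @export
check_group_consistency <- function(records, rt_window = 1.0) {
  stopifnot(nrow(records) >= 1)
  forms <- unique(records$formula[!is.na(records$formula)])
  rts <- records$rt[!is.na(records$rt)]
  spread <- if (length(rts) >= 2) max(rts) - min(rts) else 0
  tibble::tibble(formula_mismatch = length(forms) > 1,
                 rt_spread_exceeded = spread >= rt_window,
                 rt_spread = spread)
}

#' Replace experimental precursor m/z by the theoretical value
#'
#' For characterized compounds the identity is known, so the library should
#' carry the exact theoretical precursor m/z; the measured value is moved
#' to the `experimental_mz` column (and serialized into COMMENT by
#' [write_msp()]) because it documents the record's mass accuracy.
#' Idempotent.
#'
#' @param lib An [ms_library] (all rows must have formula and adduct).
#' @return The curated library.
#' @export
replace_precursor_mz <- function(lib) {
  if (any(is.na(lib$formula)) || any(is.na(lib$adduct))) {
    stop("replace_precursor_mz requires formula and adduct on every record",
         call. = FALSE)
  }
  theo <- vapply(seq_len(nrow(lib)),
                 function(i) adduct_mz(lib$formula[i], lib$adduct[i]), 0)
  changed <- is.na(lib$precursor_mz) | abs(lib$precursor_mz - theo) > 1e-9
  lib$experimental_mz <- ifelse(changed & is.na(lib$experimental_mz),
                                lib$precursor_mz, lib$experimental_mz)
  lib$precursor_mz <- theo
  lib$spectrum <- lapply(seq_len(nrow(lib)), function(i) {
    s <- lib$spectrum[[i]]
    attr(s, "precursor_mz") <- theo[i]
    s
  })
  lib
}

#' Consensus spectrum across replicate spectra
#'
#' Peaks are normalized to base 100 per spectrum, clustered across spectra
#' within `bin_tol`, and clusters present in at least `min_fraction` of the
#' spectra are kept with intensity-weighted mean m/z and the median of the
#' normalized intensities. The result is renormalized to base 100.
#'
#' @param spectra List of [ms_spectrum], all at the same collision energy.
#' @param bin_tol Cluster tolerance, Th.
#' @param min_fraction Minimum fraction of spectra a peak must appear in.
#' @return An [ms_spectrum].
#' @export
consensus_spectrum <- function(spectra, bin_tol = 0.01, min_fraction = 0.5) {
  stopifnot(length(spectra) >= 1)
  ces <- unique(vapply(spectra, function(s) collision_energy(s) %||% NA_real_,
                       0))
  if (length(ces[!is.na(ces)]) > 1) {
    stop("consensus requires spectra at one collision energy, got: ",
         paste(ces, collapse = ", "), call. = FALSE)
  }
  pool <- dplyr::bind_rows(lapply(seq_along(spectra), function(i) {
    s <- normalize_spectrum(spectra[[i]])
    if (nrow(s) == 0) return(NULL)
    tibble::tibble(spec = i, mz = s$mz, intensity = s$intensity)
  }))
  template <- spectra[[1]]
  if (is.null(pool) || nrow(pool) == 0) return(template[0, ])
  pool$bin <- .bin_mz(pool$mz, bin_tol)
  agg <- dplyr::summarise(
    dplyr::group_by(pool, .data$bin),
    mz = sum(.data$mz * .data$intensity) / sum(.data$intensity),
    intensity = stats::median(.data$intensity),
    n_spec = dplyr::n_distinct(.data$spec), .groups = "drop")
  agg <- agg[agg$n_spec >= min_fraction * length(spectra), ]
  out <- ms_spectrum(agg$mz, agg$intensity,
                     precursor_mz = precursor_mz(template),
                     collision_energy = collision_energy(template),
                     rt = spectrum_rt(template),
                     ion_mode = ion_mode(template))
  normalize_spectrum(out)
}

#' Product-ion frequency across a library
#'
#' Counts, per m/z bin, how many records contain a peak in that bin (each
#' record at most once per bin) — a screen for compound-specific versus
#' ubiquitous product ions.
#'
#' @param lib An [ms_library].
#' @param bin_tol Bin tolerance, Th.
#' @return Tibble with columns `mz` (bin center), `n_records`, sorted by
#'   descending count.
#' @export
product_ion_frequency <- function(lib, bin_tol = 0.01) {
  pool <- dplyr::bind_rows(lapply(seq_len(nrow(lib)), function(i) {
    s <- lib$spectrum[[i]]
    if (nrow(s) == 0) return(NULL)
    tibble::tibble(record = i, mz = s$mz, intensity = s$intensity)
  }))
  if (is.null(pool) || nrow(pool) == 0) {
    return(tibble::tibble(mz = numeric(), n_records = integer()))
  }
  pool$bin <- .bin_mz(pool$mz, bin_tol)
  agg <- dplyr::summarise(
    dplyr::group_by(pool, .data$bin),
    mz = sum(.data$mz * .data$intensity) / sum(.data$intensity),
    n_records = dplyr::n_distinct(.data$record), .groups = "drop")
  dplyr::arrange(agg[, c("mz", "n_records")], dplyr::desc(.data$n_records),
                 .data$mz)
}

#' Compare two libraries record by record
#'
#' Records are paired by InChIKey first block; for every pair sharing a
#' collision energy the spectral dot product and the RT difference are
#' reported.
#'
#' @param a,b [ms_library] objects.
#' @param bin_tol Dot-product match tolerance, Th.
#' @return Tibble: `key`, `name_a`, `name_b`, `collision_energy`,
#'   `similarity`, `rt_diff`.
#' @export
compare_libraries <- function(a, b, bin_tol = 0.01) {
  key_of <- function(lib) {
    ifelse(is_inchikey(lib$inchikey) & !is.na(lib$inchikey),
           substr(lib$inchikey, 1, 14), NA_character_)
  }
  ka <- key_of(a)
  kb <- key_of(b)
  shared <- intersect(ka[!is.na(ka)], kb[!is.na(kb)])
  rows <- lapply(shared, function(k) {
    ia <- which(ka == k)
    ib <- which(kb == k)
    grid <- expand.grid(i = ia, j = ib)
    grid <- grid[!is.na(a$collision_energy[grid$i]) &
                   a$collision_energy[grid$i] == b$collision_energy[grid$j], ]
    if (nrow(grid) == 0) return(NULL)
    tibble::tibble(
      key = k,
      name_a = a$name[grid$i],
      name_b = b$name[grid$j],
      collision_energy = a$collision_energy[grid$i],
      similarity = vapply(seq_len(nrow(grid)), function(r) {
        dot_product(a$spectrum[[grid$i[r]]], b$spectrum[[grid$j[r]]],
                    bin_tol = bin_tol)
      }, 0),
      rt_diff = a$rt[grid$i] - b$rt[grid$j])
  })
  out <- dplyr::bind_rows(rows)
  if (is.null(out) || nrow(out) == 0) {
    return(tibble::tibble(key = character(), name_a = character(),
                          name_b = character(), collision_energy = numeric(),
                          similarity = numeric(), rt_diff = numeric()))
  }
  out
}
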
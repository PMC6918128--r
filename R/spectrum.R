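# Spectrum and library-record containers. A spectrum is a tibble of peaks
# (mz, intensity, annotation) carrying acquisition metadata as attributes;
# a library is a tibble with one row per record and a spectrum list-column.

#' Construct an MS2 spectrum
#'
#' A spectrum is a peak table (tibble with columns `mz`, `intensity` and
#' optional `annotation`) plus precursor m/z, collision energy, retention
#' time and ion mode carried as attributes. Peaks are sorted ascending by
#' m/z on construction.
#'
#' @param mz Peak m/z values (Th), all `> 0`.
#' @param intensity Peak intensities (detector units), all `>= 0`.
#' @param annotation Optional character vector of per-peak annotation labels
#'   (`NA` = unannotated).
#' @param precursor_mz Precursor m/z in Th (`NA` if unknown).
#' @param collision_energy Collision energy in eV.
#' @param rt Retention time in minutes.
#' @param ion_mode `"positive"` or `"negative"`.
#' @return A tibble of class `ms_spectrum`.
#' @examples
#' ms_spectrum(c(94.0651, 138.0550), c(999, 400), precursor_mz = 138.0550)
#' @export
ms_spectrum <- function(mz = numeric(), intensity = numeric(),
                        annotation = NULL,
                        precursor_mz = NA_real_,
                        collision_energy = NA_real_,
                        rt = NA_real_,
                        ion_mode = "positive") {
  stopifnot(length(mz) == length(intensity))
  if (length(mz) > 0 && (any(mz <= 0) || any(intensity < 0))) {
    stop("peaks require mz > 0 and intensity >= 0", call. = FALSE)
  }
  if (is.null(annotation)) annotation <- rep(NA_character_, length(mz))
  stopifnot(length(annotation) == length(mz))
  ord <- order(mz)
  out <- tibble::tibble(mz = as.numeric(mz)[ord],
                        intensity = as.numeric(intensity)[ord],
                        annotation = as.character(annotation)[ord])
  structure(out,
            class = c("ms_spectrum", class(out)),
            precursor_mz = precursor_mz,
            collision_energy = collision_energy,
            rt = rt,
            ion_mode = ion_mode)
}

#' Spectrum metadata accessors
#'
#' @param s An `ms_spectrum`.
#' @return The stored precursor m/z, collision energy (eV), retention time
#'   (minutes) or ion mode.
#' @export
precursor_mz <- function(s) attr(s, "precursor_mz")

#' @rdname precursor_mz
#' @export
collision_energy <- function(s) attr(s, "collision_energy")

#' @rdname precursor_mz
#' @export
spectrum_rt <- function(s) attr(s, "rt")

#' @rdname precursor_mz
#' @export
ion_mode <- function(s) attr(s, "ion_mode")

# rebuild a spectrum from a plain peak table, keeping metadata of `template`
rebuild_spectrum <- function(peaks, template) {
  ms_spectrum(peaks$mz, peaks$intensity,
              annotation = if ("annotation" %in% names(peaks)) peaks$annotation,
              precursor_mz = precursor_mz(template),
              collision_energy = collision_energy(template),
              rt = spectrum_rt(template),
              ion_mode = ion_mode(template))
}

#' @export
print.ms_spectrum <- function(x, ...) {
  cat(sprintf("<ms_spectrum> %d peaks | precursor %.4f | CE %s eV | RT %s min\n",
              nrow(x), precursor_mz(x) %||% NA,
              format(collision_energy(x)), format(spectrum_rt(x))))
  NextMethod()
}

#' Normalize a spectrum to base peak 100
#'
#' Rescales intensities so the most intense peak is 100. Explicit by design:
#' I/O never rescales.
#'
#' @param s An `ms_spectrum`.
#' @return The rescaled spectrum (empty spectra pass through).
#' @export
normalize_spectrum <- function(s) {
  if (nrow(s) == 0) return(s)
  rebuild_spectrum(
    tibble::tibble(mz = s$mz, intensity = 100 * s$intensity / max(s$intensity),
                   annotation = s$annotation),
    s)
}

#' Assemble a spectral-library tibble
#'
#' One row per library record: compound metadata, AMRT coordinates and the
#' peak list as a `spectrum` list-column. This is the in-memory form of an
#' MSP/MGF library.
#'
#' @param name Compound name.
#' @param formula Elemental formula string (may be `NA`).
#' @param adduct Adduct name string (precursor type).
#' @param inchikey InChIKey (may be `NA`).
#' @param smiles SMILES string (may be `NA`).
#' @param precursor_mz Precursor m/z in Th.
#' @param experimental_mz Original experimental precursor m/z retained after
#'   curation (`NA` before curation).
#' @param rt Retention time, minutes.
#' @param ion_mode `"positive"` or `"negative"`.
#' @param collision_energy Collision energy, eV.
#' @param spectrum List of `ms_spectrum` objects.
#' @param provenance List of named character vectors of free-form metadata
#'   (instrument, chromatography, author, license, comment, ...).
#' @return Tibble of class `ms_library`.
#' @export
ms_library <- function(name = character(), formula = NA, adduct = NA,
                       inchikey = NA, smiles = NA,
                       precursor_mz = NA, experimental_mz = NA,
                       rt = NA, ion_mode = "positive",
                       collision_energy = NA, spectrum = list(),
                       provenance = NULL) {
  n <- length(name)
  if (is.null(provenance)) provenance <- rep(list(character()), n)
  out <- tibble::tibble(
    name = as.character(name),
    formula = rep_len(as.character(formula), n),
    adduct = rep_len(as.character(adduct), n),
    inchikey = rep_len(as.character(inchikey), n),
    smiles = rep_len(as.character(smiles), n),
    precursor_mz = rep_len(as.numeric(precursor_mz), n),
    experimental_mz = rep_len(as.numeric(experimental_mz), n),
    rt = rep_len(as.numeric(rt), n),
    ion_mode = rep_len(as.character(ion_mode), n),
    collision_energy = rep_len(as.numeric(collision_energy), n),
    spectrum = spectrum,
    provenance = provenance
  )
  class(out) <- c("ms_library", class(out))
  out
}

as_ms_library <- function(df) {
  class(df) <- unique(c("ms_library", class(df)))
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
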
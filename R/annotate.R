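# Formula-based annotation of deconvoluted MS2 peaks: bounded subformula
# search for fragments, plus adduct and carbon-13 isotope candidates of the
# known compound. Unannotated peaks can then be stripped from the spectrum.

#' Enumerate adduct / water-loss / isotope candidate ions
#'
#' Cross product of the supplied adducts, 0..`max_water_losses` neutral
#' water losses and 0..`max_isotope` carbon-13 substitutions, with
#' theoretical m/z from the exact-mass table. Infeasible losses (more water
#' than the ion holds) are skipped silently.
#'
#' @param f Neutral elemental formula (object or string).
#' @param adducts Character vector of adduct names.
#' @param max_water_losses Maximum number of neutral H2O losses.
#' @param max_isotope Maximum carbon-13 isotope index.
#' @return Tibble with columns `label`, `adduct`, `n_water_loss`, `isotope`,
#'   `mz`, deduplicated by label.
#' @examples
#' enumerate_candidate_ions("C7H7NO2", c("[M+H]+", "[M+Na]+", "[M+K]+"))
#' @export
enumerate_candidate_ions <- function(f, adducts = c("[M+H]+", "[M+Na]+", "[M+K]+"),
                                     max_water_losses = 0, max_isotope = 0) {
  stopifnot(length(adducts) >= 1)
  grid <- expand.grid(adduct = adducts, w = 0:max_water_losses,
                      iso = 0:max_isotope, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    base <- grid$adduct[i]
    w <- grid$w[i]
    name <- if (w > 0) {
      sub("\\]", paste0("-", if (w > 1) w else "", "H2O]"), base)
    } else base
    a <- tryCatch(parse_adduct(name), error = function(e) NULL)
    if (is.null(a)) return(NULL)
    mz0 <- tryCatch(adduct_mz(f, a), error = function(e) NULL)
    if (is.null(mz0)) return(NULL)  # loss infeasible for this formula
    iso <- grid$iso[i]
    label <- if (iso > 0) paste0(a$name, " isotope M+", iso) else a$name
    tibble::tibble(label = label, adduct = a$name, n_water_loss = w,
                   isotope = iso, mz = isotope_mz(mz0, iso, abs(a$charge)))
  })
  out <- dplyr::bind_rows(rows)
  out[!duplicated(out$label), ]
}

# all subformula ions of the precursor ion's atom multiset, with chemical
# constraints: ring-plus-double-bond equivalents >= 0 and H <= 2C + N + 2
.subformula_ions <- function(ion_counts, charge) {
  sym <- names(ion_counts)
  combos <- do.call(expand.grid, c(lapply(ion_counts, function(n) 0:n),
                                   list(KEEP.OUT.ATTRS = FALSE)))
  names(combos) <- sym
  combos <- combos[rowSums(combos) >= 1, , drop = FALSE]
  cnt <- function(e) if (e %in% sym) combos[[e]] else 0
  rdbe <- cnt("C") - cnt("H") / 2 + cnt("N") / 2 + 1
  hmax <- cnt("H") <= 2 * cnt("C") + cnt("N") + 2
  ok <- rdbe >= 0 & hmax
  combos <- combos[ok, , drop = FALSE]
  rdbe <- rdbe[ok]
  mass <- as.matrix(combos) %*% .atomic_masses[sym]
  mz <- (as.numeric(mass) - sign(charge) * abs(charge) * .electron_mass) /
    abs(charge)
  labels <- apply(combos, 1, function(row) {
    format(new_formula(stats::setNames(as.integer(row), sym)))
  })
  tibble::tibble(formula = paste0(labels, if (charge > 0) "+" else "-"),
                 mz = mz, rdbe = rdbe,
                 even_electron = rdbe %% 1 != 0,
                 n_atoms = rowSums(combos))
}

#' Annotate MS2 peaks of a known compound
#'
#' For each peak, searches (a) all subformulas of the ionized precursor's
#' atom multiset whose ion m/z lies within `tol`, subject to chemical
#' constraints (ring-plus-double-bond equivalents >= 0; H <= 2C + N + 2),
#' and (b) adduct / water-loss / carbon-13 isotope candidates of the intact
#' molecule. The lowest-|mass error| candidate wins; ties prefer
#' even-electron ions, then fewer atoms. Peaks with no candidate within
#' `tol` stay unannotated.
#'
#' @param s An [ms_spectrum].
#' @param f Neutral formula of the compound (object or string).
#' @param adduct The precursor adduct (object or name).
#' @param tol Annotation tolerance, Th.
#' @param adducts Adduct names tried for co-detected adduct ions.
#' @param max_water_losses,max_isotope Candidate-ion bounds passed to
#'   [enumerate_candidate_ions()].
#' @return The spectrum with its `annotation` column filled
#'   (`"<ion>; <kind>"`) and a `peak_annotations` attribute: a tibble with
#'   columns `mz`, `kind` (fragment / adduct / isotope / precursor),
#'   `ion`, `theoretical_mz`, `mass_error_mda`, `even_electron`.
#' @export
annotate_fragments <- function(s, f, adduct, tol = 0.01,
                               adducts = c("[M+H]+", "[M+Na]+", "[M+K]+"),
                               max_water_losses = 3, max_isotope = 2) {
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  a <- as_adduct(adduct)
  ion_cnt <- ion_formula(f, a)
  frag_cand <- .subformula_ions(stats::setNames(as.integer(ion_cnt),
                                                names(ion_cnt)), a$charge)
  full_label <- paste0(format(ion_cnt), if (a$charge > 0) "+" else "-")
  ion_cand <- enumerate_candidate_ions(f, adducts = unique(c(a$name, adducts)),
                                       max_water_losses = max_water_losses,
                                       max_isotope = max_isotope)
  ann <- lapply(s$mz, function(pmz) {
    fr <- frag_cand[abs(frag_cand$mz - pmz) <= tol, ]
    if (nrow(fr) > 0) {
      fr <- tibble::tibble(
        kind = ifelse(fr$formula == full_label, "precursor", "fragment"),
        ion = fr$formula, theoretical_mz = fr$mz,
        even_electron = fr$even_electron, n_atoms = fr$n_atoms)
    }
    io <- ion_cand[abs(ion_cand$mz - pmz) <= tol, ]
    if (nrow(io) > 0) {
      io <- tibble::tibble(
        kind = ifelse(io$isotope > 0, "isotope",
                      ifelse(io$label == a$name, "precursor", "adduct")),
        ion = io$label, theoretical_mz = io$mz,
        even_electron = TRUE, n_atoms = Inf)
    }
    cand <- dplyr::bind_rows(if (nrow(fr)) fr, if (nrow(io)) io)
    if (is.null(cand) || nrow(cand) == 0) return(NULL)
    cand$err <- abs(cand$theoretical_mz - pmz)
    # precursor/adduct/isotope identities of the intact molecule outrank a
    # coincidental subformula at the same m/z
    cand$rank_kind <- match(cand$kind, c("precursor", "isotope", "adduct",
                                         "fragment"))
    cand <- cand[order(round(cand$err, 9), cand$rank_kind,
                       !cand$even_electron, cand$n_atoms), ]
    best <- cand[1, ]
    tibble::tibble(mz = pmz, kind = best$kind, ion = best$ion,
                   theoretical_mz = best$theoretical_mz,
                   mass_error_mda = 1000 * (pmz - best$theoretical_mz),
                   even_electron = best$even_electron)
  })
  tab <- dplyr::bind_rows(ann)
  labels <- rep(NA_character_, nrow(s))
  if (!is.null(tab) && nrow(tab) > 0) {
    hit <- !vapply(ann, is.null, logical(1))
    labels[hit] <- paste0(tab$ion, "; ", tab$kind)
  }
  out <- s
  out$annotation <- labels
  attr(out, "peak_annotations") <- tab %||% tibble::tibble()
  out
}

#' Per-peak annotation table of an annotated spectrum
#'
#' @param s A spectrum returned by [annotate_fragments()].
#' @return The `peak_annotations` tibble.
#' @export
peak_annotations <- function(s) attr(s, "peak_annotations")

#' Remove unannotated peaks
#'
#' Keeps exactly the peaks that carry an annotation, order preserved.
#'
#' @param s An annotated [ms_spectrum].
#' @return The stripped spectrum.
#' @export
strip_unannotated <- function(s) {
  keep <- !is.na(s$annotation)
  out <- rebuild_spectrum(s[keep, c("mz", "intensity", "annotation")], s)
  if ("quality" %in% names(s)) out$quality <- s$quality[keep]
  attr(out, "method") <- attr(s, "method")
  pa <- attr(s, "peak_annotations")
  if (!is.null(pa) && nrow(pa) > 0) {
    attr(out, "peak_annotations") <- pa[pa$mz %in% out$mz, ]
  }
  class(out) <- class(s)
  out
}
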
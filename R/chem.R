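# Exact-mass chemistry primitives: elemental formulas, adducts, isotopes,
# InChIKey handling. All downstream theoretical m/z values come from here.

# Monoisotopic atomic masses (IUPAC); carbon-12 is exact by definition.
.atomic_masses <- c(
  C  = 12,
  H  = 1.0078250319,
  N  = 14.0030740052,
  O  = 15.9949146221,
  P  = 30.97376151,
  S  = 31.97207069,
  Na = 22.98976928,
  K  = 38.9637064864,
  Cl = 34.96885271
)

.electron_mass <- 0.00054858
.c13_delta <- 1.003355  # mass difference carbon-13 minus carbon-12

#' Supported elements
#'
#' @return Character vector of element symbols the formula parser accepts.
#' @export
supported_elements <- function() names(.atomic_masses)

#' Parse an elemental formula
#'
#' Parses a Hill-notation style formula string (e.g. `"C7H7NO2"`) into a
#' named integer vector of atom counts, the package's elemental-formula
#' representation.
#'
#' @param text Formula string. Element symbols must be in
#'   [supported_elements()]; counts default to 1.
#' @return Named integer vector of class `elemental_formula`, one entry per
#'   element present, in Hill order (C, H, then alphabetical).
#' @examples
#' parse_formula("C7H7NO2")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) {
    stop("empty formula string", call. = FALSE)
  }
  text <- trimws(text)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text, perl = TRUE)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    stop("cannot parse formula: '", text, "'", call. = FALSE)
  }
  sym <- sub("[0-9]*$", "", tokens)
  cnt <- sub("^[A-Za-z]+", "", tokens)
  cnt <- ifelse(cnt == "", 1L, suppressWarnings(as.integer(cnt)))
  bad <- setdiff(sym, supported_elements())
  if (length(bad) > 0) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  counts <- tapply(cnt, factor(sym, levels = supported_elements()), sum)
  counts <- counts[!is.na(counts) & counts > 0]
  if (length(counts) == 0 || sum(counts) < 1) {
    stop("formula must contain at least one atom", call. = FALSE)
  }
  new_formula(stats::setNames(as.integer(counts), names(counts)))
}

new_formula <- function(counts) {
  counts <- counts[counts != 0]
  if (any(counts < 0)) stop("negative atom count", call. = FALSE)
  structure(counts[.hill_order(names(counts))], class = "elemental_formula")
}

.hill_order <- function(sym) {
  rest <- sort(setdiff(sym, c("C", "H")))
  intersect(c("C", "H", rest), sym)
}

#' Format an elemental formula as a Hill-notation string
#'
#' @param x An `elemental_formula` (or named count vector).
#' @param ... Ignored.
#' @return Single string, e.g. `"C7H7NO2"`.
#' @export
format.elemental_formula <- function(x, ...) {
  x <- x[.hill_order(names(x))]
  paste0(names(x), ifelse(x == 1, "", x), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<formula> ", format(x), "  (", round(monoisotopic_mass(x), 4),
      " Da)\n", sep = "")
  invisible(x)
}

#' @export
`==.elemental_formula` <- function(e1, e2) {
  identical(formula_counts(e1), formula_counts(e2))
}

formula_counts <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  v <- stats::setNames(rep(0L, length(.atomic_masses)), supported_elements())
  v[names(f)] <- as.integer(f)
  v
}

#' Combine or subtract formulas
#'
#' `formula_add()` returns the element-wise sum of two formulas;
#' `formula_subtract()` the difference, erroring if any count would go
#' negative (a neutral loss cannot exceed the available atoms).
#'
#' @param a,b Formulas (objects or strings).
#' @return An `elemental_formula`; subtracting a formula from itself gives an
#'   empty formula (zero atoms), accepted only as an intermediate.
#' @export
formula_add <- function(a, b) {
  new_formula(formula_counts(a) + formula_counts(b))
}

#' @rdname formula_add
#' @export
formula_subtract <- function(a, b) {
  d <- formula_counts(a) - formula_counts(b)
  if (any(d < 0)) {
    neg <- names(d)[d < 0]
    stop("loss exceeds available atoms of: ", paste(neg, collapse = ", "),
         call. = FALSE)
  }
  new_formula(d)
}

#' Monoisotopic mass of a formula
#'
#' Sum of monoisotopic atomic masses over the atom counts.
#'
#' @param f An `elemental_formula` or formula string.
#' @return Mass in Da (full precision; round for display).
#' @examples
#' monoisotopic_mass("C7H7NO2")  # 137.0477
#' @export
monoisotopic_mass <- function(f) {
  cnt <- formula_counts(f)
  sum(cnt * .atomic_masses[names(cnt)])
}

# ---- adducts -----------------------------------------------------------

#' Parse an adduct descriptor
#'
#' Parses electrospray adduct names like `"[M+H]+"`, `"[M+Na]+"`,
#' `"[M+H-2H2O]+"` into gained/lost formulas and a charge. Multipliers
#' expand (`2H2O` is two waters); both the ASCII hyphen and the Unicode
#' minus sign are accepted.
#'
#' @param name Adduct name string.
#' @return A list of class `adduct` with elements `name` (canonical form),
#'   `charge`, `gained`, `lost` (named count vectors, possibly empty).
#' @examples
#' parse_adduct("[M+H]+")
#' parse_adduct("[M+H-2H2O]+")
#' @export
parse_adduct <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  txt <- gsub("−", "-", trimws(name))
  m <- regmatches(txt, regexec("^\\[M((?:[+-][^+\\]-]+)*)\\]([0-9]*)([+-])$",
                               txt, perl = TRUE))[[1]]
  if (length(m) == 0) {
    stop("malformed adduct name: '", name, "'", call. = FALSE)
  }
  groups_txt <- m[2]
  zmag <- if (nzchar(m[3])) as.integer(m[3]) else 1L
  charge <- if (m[4] == "+") zmag else -zmag
  gained <- stats::setNames(integer(0), character(0))
  lost <- gained
  if (nzchar(groups_txt)) {
    gm <- gregexpr("([+-])([0-9]*)([A-Za-z][A-Za-z0-9]*)", groups_txt,
                   perl = TRUE)[[1]]
    toks <- regmatches(groups_txt, list(gm))[[1]]
    if (sum(attr(gm, "match.length")) != nchar(groups_txt)) {
      stop("malformed adduct group in '", name, "'", call. = FALSE)
    }
    for (tok in toks) {
      sign <- substr(tok, 1, 1)
      body <- substring(tok, 2)
      mult <- as.integer(sub("^([0-9]*).*$", "\\1", body))
      if (is.na(mult)) mult <- 1L
      fstr <- sub("^[0-9]*", "", body)
      cnt <- formula_counts(parse_formula(fstr)) * mult
      cnt <- cnt[cnt > 0]
      tgt <- if (sign == "+") "gained" else "lost"
      cur <- if (sign == "+") gained else lost
      all_sym <- union(names(cur), names(cnt))
      merged <- stats::setNames(rep(0L, length(all_sym)), all_sym)
      merged[names(cur)] <- merged[names(cur)] + cur
      merged[names(cnt)] <- merged[names(cnt)] + as.integer(cnt)
      if (sign == "+") gained <- merged else lost <- merged
    }
  }
  out <- structure(
    list(name = NA_character_, charge = charge,
         gained = gained[.hill_order(names(gained))],
         lost = lost[.hill_order(names(lost))]),
    class = "adduct"
  )
  out$name <- format(out)
  out
}

#' Format an adduct in canonical form
#'
#' @param x An `adduct`.
#' @param ... Ignored.
#' @return Canonical name, e.g. `"[M+H-2H2O]+"` (losses collapsed with
#'   multipliers; gains before losses; ASCII hyphen).
#' @export
format.adduct <- function(x, ...) {
  part <- function(cnt, sign) {
    if (length(cnt) == 0) return("")
    # express water losses with a multiplier, other elements inline
    if (sign == "-" && setequal(names(cnt), c("H", "O")) &&
        cnt[["H"]] == 2 * cnt[["O"]]) {
      n <- cnt[["O"]]
      return(paste0("-", if (n > 1) n else "", "H2O"))
    }
    paste0(sign, format(new_formula(cnt)))
  }
  zmag <- abs(x$charge)
  paste0("[M", part(x$gained, "+"), part(x$lost, "-"), "]",
         if (zmag > 1) zmag else "", if (x$charge > 0) "+" else "-")
}

#' @export
print.adduct <- function(x, ...) {
  cat("<adduct> ", x$name, "\n", sep = "")
  invisible(x)
}

as_adduct <- function(a) {
  if (inherits(a, "adduct")) a else parse_adduct(a)
}

#' Theoretical m/z of an adduct ion
#'
#' `m/z = (M + gained - lost - charge * m_e) / |charge|` where `M` is the
#' monoisotopic mass of the neutral formula and `m_e` the electron mass.
#'
#' @param f Neutral formula (object or string).
#' @param adduct An `adduct` or adduct name string.
#' @return m/z in Th.
#' @examples
#' adduct_mz("C7H7NO2", "[M+H]+")   # 138.0550
#' adduct_mz("C7H7NO2", "[M+Na]+")  # 160.0369
#' @export
adduct_mz <- function(f, adduct) {
  a <- as_adduct(adduct)
  ion <- ion_formula(f, a)  # validates losses
  mass <- monoisotopic_mass(ion)
  (mass - a$charge * .electron_mass) / abs(a$charge)
}

# the ion's atom multiset: neutral + gained - lost
ion_formula <- function(f, adduct) {
  a <- as_adduct(adduct)
  cnt <- formula_counts(f)
  if (length(a$gained)) cnt[names(a$gained)] <- cnt[names(a$gained)] + a$gained
  if (length(a$lost)) {
    cnt[names(a$lost)] <- cnt[names(a$lost)] - a$lost
    if (any(cnt < 0)) {
      stop("adduct loss exceeds available atoms in ", format(new_formula(formula_counts(f))),
           call. = FALSE)
    }
  }
  if (sum(cnt) < 1) stop("resulting ion has no atoms", call. = FALSE)
  new_formula(cnt)
}

#' m/z of a carbon-13 isotopologue
#'
#' @param mz Monoisotopic m/z in Th.
#' @param n Isotope index (number of 13C substitutions), `n = 0` is identity.
#' @param charge Absolute charge (default 1).
#' @return m/z shifted by `n * 1.003355 / charge`.
#' @examples
#' isotope_mz(138.0550, 1)  # 139.0584
#' @export
isotope_mz <- function(mz, n, charge = 1L) {
  if (any(n < 0)) stop("isotope index must be >= 0", call. = FALSE)
  mz + n * .c13_delta / abs(charge)
}

# ---- InChIKey ----------------------------------------------------------

#' Validate an InChIKey
#'
#' Checks the 27-character three-block structure (14-10-1, uppercase
#' letters, dash-separated).
#'
#' @param key Candidate InChIKey string(s).
#' @return Logical vector.
#' @export
is_inchikey <- function(key) {
  grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", key)
}

#' First block of an InChIKey
#'
#' The first 14 characters hash the molecular skeleton; records sharing them
#' are grouped as one compound during curation.
#'
#' @param key InChIKey string(s); invalid keys are an error.
#' @return 14-character string(s).
#' @examples
#' inchikey_first_block("YDHWWBZFRZWVHO-UHFFFAOYSA-N")
#' @export
inchikey_first_block <- function(key) {
  bad <- !is_inchikey(key)
  if (any(bad)) {
    stop("invalid InChIKey: ", paste(key[bad], collapse = ", "), call. = FALSE)
  }
  substr(key, 1, 14)
}

proton_mass <- function() .atomic_masses[["H"]] - .electron_mass
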
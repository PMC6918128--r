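# Spectral-library I/O: NIST MSP dialect (read/write), MGF (read/write),
# MassBank records (read-only), plus the AIF scan container and its
# tabular on-disk format. All text I/O is UTF-8.

.msp_known_keys <- c("NAME", "PRECURSORMZ", "PRECURSORTYPE", "FORMULA",
                     "INCHIKEY", "SMILES", "RETENTIONTIME",
                     "COLLISIONENERGY", "IONMODE", "COMMENT", "NUM PEAKS")

#' Read a NIST MSP spectral library
#'
#' Parses one `LibraryRecord` per `NAME:` block. Header keys are matched
#' case-insensitively; keys outside the canonical dialect are preserved
#' verbatim in the `provenance` list-column. Peak lines are
#' `mz<TAB>intensity<TAB>"annotation"` with whitespace also accepted as a
#' separator and the quoted annotation optional. An `experimental_mz=<x>`
#' token inside COMMENT populates the `experimental_mz` column.
#'
#' @param path File path, or a character vector of lines.
#' @return An [ms_library] tibble.
#' @export
read_msp <- function(path) {
  lines <- .as_lines(path)
  blocks <- .split_blocks(lines, function(l) grepl("^name\\s*:", l, ignore.case = TRUE))
  recs <- lapply(blocks, .parse_msp_block)
  .bind_library(recs)
}

.as_lines <- function(path) {
  if (length(path) == 1 && !grepl("\n", path) && file.exists(path)) {
    readLines(path, encoding = "UTF-8", warn = FALSE)
  } else {
    unlist(strsplit(path, "\n", fixed = TRUE), use.names = FALSE)
  }
}

# split file lines into records, each starting at a line matching `is_start`
.split_blocks <- function(lines, is_start) {
  starts <- which(vapply(lines, is_start, logical(1), USE.NAMES = FALSE))
  if (length(starts) == 0) return(list())
  ends <- c(starts[-1] - 1L, length(lines))
  Map(function(s, e) lines[s:e], starts, ends)
}

.parse_msp_block <- function(block) {
  block <- block[nzchar(trimws(block))]
  is_hdr <- grepl("^[A-Za-z][A-Za-z0-9 _$/-]*\\s*:", block)
  # peak lines start after the Num Peaks header
  np_idx <- grep("^num\\s*peaks\\s*:", block, ignore.case = TRUE)
  if (length(np_idx) == 0) stop("MSP record without 'Num Peaks' line", call. = FALSE)
  hdr <- block[seq_len(np_idx)]
  hdr <- hdr[grepl(":", hdr, fixed = TRUE)]
  keys <- toupper(trimws(sub(":.*$", "", hdr)))
  vals <- trimws(sub("^[^:]*:", "", hdr))
  names(vals) <- keys
  get <- function(k) if (k %in% keys) vals[[k]] else NA_character_
  num_peaks <- as.integer(get("NUM PEAKS"))
  peak_lines <- if (np_idx < length(block)) block[(np_idx + 1):length(block)] else character()
  peaks <- .parse_peak_lines(peak_lines)
  nm <- get("NAME")
  if (!is.na(num_peaks) && nrow(peaks) != num_peaks) {
    stop("record '", nm, "': Num Peaks declares ", num_peaks,
         " but ", nrow(peaks), " peak lines found", call. = FALSE)
  }
  comment <- get("COMMENT")
  exp_mz <- NA_real_
  if (!is.na(comment)) {
    m <- regmatches(comment, regexec("experimental_mz=([0-9.eE+-]+)", comment))[[1]]
    if (length(m) == 2) exp_mz <- as.numeric(m[2])
  }
  extra_keys <- setdiff(keys, .msp_known_keys)
  prov <- vals[keys %in% extra_keys]
  if (!is.na(comment)) prov <- c(prov, COMMENT = comment)
  rt <- as.numeric(get("RETENTIONTIME"))
  ce <- as.numeric(get("COLLISIONENERGY"))
  pmz <- as.numeric(get("PRECURSORMZ"))
  imode <- get("IONMODE")
  spec <- ms_spectrum(peaks$mz, peaks$intensity, annotation = peaks$annotation,
                      precursor_mz = pmz, collision_energy = ce, rt = rt,
                      ion_mode = if (is.na(imode)) "positive" else tolower(imode))
  list(name = nm, formula = get("FORMULA"), adduct = get("PRECURSORTYPE"),
       inchikey = get("INCHIKEY"), smiles = get("SMILES"),
       precursor_mz = pmz, experimental_mz = exp_mz, rt = rt,
       ion_mode = if (is.na(imode)) "positive" else tolower(imode),
       collision_energy = ce, spectrum = spec, provenance = prov)
}

.parse_peak_lines <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(mz = numeric(), intensity = numeric(),
                          annotation = character()))
  }
  m <- regmatches(lines, regexec(
    '^\\s*([0-9.eE+-]+)\\s+([0-9.eE+-]+)(?:\\s+"([^"]*)")?\\s*$', lines,
    perl = TRUE))
  bad <- vapply(m, length, integer(1)) == 0
  if (any(bad)) {
    stop("unparseable peak line: '", lines[which(bad)[1]], "'", call. = FALSE)
  }
  mz <- as.numeric(vapply(m, `[`, "", 2))
  intensity <- as.numeric(vapply(m, `[`, "", 3))
  ann <- vapply(m, `[`, "", 4)
  ann[ann == ""] <- NA_character_
  if (anyNA(mz) || anyNA(intensity)) {
    stop("unparseable peak values", call. = FALSE)
  }
  tibble::tibble(mz = mz, intensity = intensity, annotation = ann)
}

.bind_library <- function(recs) {
  if (length(recs) == 0) return(ms_library())
  ms_library(
    name = vapply(recs, `[[`, "", "name"),
    formula = vapply(recs, `[[`, "", "formula"),
    adduct = vapply(recs, `[[`, "", "adduct"),
    inchikey = vapply(recs, `[[`, "", "inchikey"),
    smiles = vapply(recs, `[[`, "", "smiles"),
    precursor_mz = vapply(recs, `[[`, 0, "precursor_mz"),
    experimental_mz = vapply(recs, `[[`, 0, "experimental_mz"),
    rt = vapply(recs, `[[`, 0, "rt"),
    ion_mode = vapply(recs, `[[`, "", "ion_mode"),
    collision_energy = vapply(recs, `[[`, 0, "collision_energy"),
    spectrum = lapply(recs, `[[`, "spectrum"),
    provenance = lapply(recs, `[[`, "provenance")
  )
}

.fmt_mz <- function(x) {
  s <- sub("0+$", "", sprintf("%.8f", x))
  sub("\\.$", "", s)
}
.fmt_num <- function(x) format(x, digits = 10, scientific = FALSE, trim = TRUE)

#' Write a library in the canonical MSP dialect
#'
#' Field order: NAME, PRECURSORMZ, PRECURSORTYPE, FORMULA, INCHIKEY, SMILES,
#' RETENTIONTIME (minutes), COLLISIONENERGY (eV), IONMODE, any preserved
#' provenance keys, COMMENT, Num Peaks, then tab-separated peak lines with
#' the annotation quoted. `NA` fields are omitted. Output is deterministic
#' for identical input. A non-`NA` `experimental_mz` is serialized into
#' COMMENT as `experimental_mz=<value>` if not already present.
#'
#' @param lib An [ms_library].
#' @param path Output file path, or `NULL` to return the lines invisibly.
#' @return Character vector of lines (invisibly when written to a file).
#' @export
write_msp <- function(lib, path = NULL) {
  out <- unlist(lapply(seq_len(nrow(lib)), function(i) {
    r <- lib[i, ]
    spec <- r$spectrum[[1]]
    if (is.na(r$name) || !nzchar(r$name)) stop("record without name", call. = FALSE)
    prov <- r$provenance[[1]]
    comment <- if ("COMMENT" %in% names(prov)) prov[["COMMENT"]] else NA_character_
    if (!is.na(r$experimental_mz) &&
        (is.na(comment) || !grepl("experimental_mz=", comment))) {
      tok <- paste0("experimental_mz=", .fmt_mz(r$experimental_mz))
      comment <- if (is.na(comment) || !nzchar(comment)) tok else paste0(comment, "; ", tok)
    }
    extras <- prov[setdiff(names(prov), "COMMENT")]
    hdr <- c(
      paste0("NAME: ", r$name),
      if (!is.na(r$precursor_mz)) paste0("PRECURSORMZ: ", .fmt_mz(r$precursor_mz)),
      if (!is.na(r$adduct)) paste0("PRECURSORTYPE: ", r$adduct),
      if (!is.na(r$formula)) paste0("FORMULA: ", r$formula),
      if (!is.na(r$inchikey)) paste0("INCHIKEY: ", r$inchikey),
      if (!is.na(r$smiles)) paste0("SMILES: ", r$smiles),
      if (!is.na(r$rt)) paste0("RETENTIONTIME: ", .fmt_num(r$rt)),
      if (!is.na(r$collision_energy)) paste0("COLLISIONENERGY: ", .fmt_num(r$collision_energy)),
      if (!is.na(r$ion_mode)) paste0("IONMODE: ", r$ion_mode),
      if (length(extras)) paste0(names(extras), ": ", unname(extras)),
      if (!is.na(comment)) paste0("COMMENT: ", comment),
      paste0("Num Peaks: ", nrow(spec))
    )
    pk <- paste0(.fmt_mz(spec$mz), "\t", .fmt_num(spec$intensity),
                 ifelse(is.na(spec$annotation), "",
                        paste0("\t\"", spec$annotation, "\"")))
    c(hdr, pk, "")
  }))
  if (!is.null(path)) {
    writeLines(out, path, useBytes = TRUE)
    return(invisible(out))
  }
  out
}

# ---- MGF ---------------------------------------------------------------

#' Read / write MGF spectral files
#'
#' Minimal `BEGIN IONS`/`END IONS` dialect: `PEPMASS` maps to precursor m/z,
#' `RTINSECONDS` to retention time (converted to minutes at the boundary),
#' `TITLE` to the record name. Compound metadata travels in additional
#' `KEY=VALUE` lines (FORMULA, PRECURSORTYPE, INCHIKEY, SMILES,
#' COLLISIONENERGY, IONMODE) so MSP round-trips survive the format change.
#'
#' @param path File path or character vector of lines (`read_mgf`); an
#'   [ms_library] (`write_mgf`).
#' @return `read_mgf`: an [ms_library]; `write_mgf`: the lines, invisibly
#'   when written to a file.
#' @export
read_mgf <- function(path) {
  lines <- .as_lines(path)
  begins <- grep("^BEGIN IONS\\s*$", lines)
  ends <- grep("^END IONS\\s*$", lines)
  if (length(begins) != length(ends) || any(ends < begins)) {
    stop("unterminated BEGIN IONS block", call. = FALSE)
  }
  recs <- Map(function(b, e) .parse_mgf_block(lines[(b + 1):(e - 1)]), begins, ends)
  .bind_library(recs)
}

.mgf_known_keys <- c("TITLE", "PEPMASS", "RTINSECONDS", "CHARGE", "FORMULA",
                     "PRECURSORTYPE", "INCHIKEY", "SMILES",
                     "COLLISIONENERGY", "IONMODE")

.parse_mgf_block <- function(block) {
  block <- block[nzchar(trimws(block))]
  is_kv <- grepl("^[A-Za-z][A-Za-z0-9_]*=", block)
  kv <- block[is_kv]
  keys <- toupper(sub("=.*$", "", kv))
  vals <- sub("^[^=]*=", "", kv)
  names(vals) <- keys
  get <- function(k) if (k %in% keys) vals[[k]] else NA_character_
  peaks <- .parse_peak_lines(block[!is_kv])
  rt <- as.numeric(get("RTINSECONDS")) / 60
  pmz <- as.numeric(sub("\\s.*$", "", get("PEPMASS")))  # PEPMASS may carry intensity
  ce <- as.numeric(get("COLLISIONENERGY"))
  imode <- get("IONMODE")
  prov <- vals[!(keys %in% .mgf_known_keys)]
  spec <- ms_spectrum(peaks$mz, peaks$intensity, annotation = peaks$annotation,
                      precursor_mz = pmz, collision_energy = ce, rt = rt,
                      ion_mode = if (is.na(imode)) "positive" else tolower(imode))
  list(name = get("TITLE"), formula = get("FORMULA"),
       adduct = get("PRECURSORTYPE"), inchikey = get("INCHIKEY"),
       smiles = get("SMILES"), precursor_mz = pmz,
       experimental_mz = NA_real_, rt = rt,
       ion_mode = if (is.na(imode)) "positive" else tolower(imode),
       collision_energy = ce, spectrum = spec, provenance = prov)
}

#' @rdname read_mgf
#' @param lib An [ms_library] to serialize.
#' @export
write_mgf <- function(lib, path = NULL) {
  out <- unlist(lapply(seq_len(nrow(lib)), function(i) {
    r <- lib[i, ]
    spec <- r$spectrum[[1]]
    prov <- r$provenance[[1]]
    c("BEGIN IONS",
      paste0("TITLE=", r$name),
      if (!is.na(r$precursor_mz)) paste0("PEPMASS=", .fmt_mz(r$precursor_mz)),
      if (!is.na(r$rt)) paste0("RTINSECONDS=", .fmt_num(r$rt * 60)),
      if (!is.na(r$adduct)) paste0("PRECURSORTYPE=", r$adduct),
      if (!is.na(r$formula)) paste0("FORMULA=", r$formula),
      if (!is.na(r$inchikey)) paste0("INCHIKEY=", r$inchikey),
      if (!is.na(r$smiles)) paste0("SMILES=", r$smiles),
      if (!is.na(r$collision_energy)) paste0("COLLISIONENERGY=", .fmt_num(r$collision_energy)),
      if (!is.na(r$ion_mode)) paste0("IONMODE=", r$ion_mode),
      if (length(prov)) paste0(names(prov), "=", unname(prov)),
      paste0(.fmt_mz(spec$mz), " ", .fmt_num(spec$intensity),
             ifelse(is.na(spec$annotation), "",
                    paste0(" \"", spec$annotation, "\""))),
      "END IONS", "")
  }))
  if (!is.null(path)) {
    writeLines(out, path, useBytes = TRUE)
    return(invisible(out))
  }
  out
}

# ---- MassBank records (read-only) --------------------------------------

#' Read MassBank-format records
#'
#' Read-only support for the flat-file MassBank record format (one record
#' per `ACCESSION:` block, `//` terminated). Extracts name, formula, SMILES,
#' InChIKey, precursor m/z and type, retention time and the `PK$PEAK` list.
#'
#' @param path File path or character vector of lines.
#' @return An [ms_library].
#' @export
read_massbank <- function(path) {
  lines <- .as_lines(path)
  blocks <- .split_blocks(lines, function(l) grepl("^ACCESSION:", l))
  recs <- lapply(blocks, .parse_massbank_block)
  .bind_library(recs)
}

.parse_massbank_block <- function(block) {
  val <- function(pat) {
    hit <- grep(pat, block, value = TRUE)
    if (length(hit) == 0) return(NA_character_)
    trimws(sub(pat, "", hit[1]))
  }
  nm <- val("^CH\\$NAME:\\s*")
  formula <- val("^CH\\$FORMULA:\\s*")
  smiles <- val("^CH\\$SMILES:\\s*")
  inchikey <- val("^CH\\$LINK:\\s*INCHIKEY\\s*")
  pmz <- as.numeric(val("^MS\\$FOCUSED_ION:\\s*PRECURSOR_M/Z\\s*"))
  ptype <- val("^MS\\$FOCUSED_ION:\\s*PRECURSOR_TYPE\\s*")
  ce <- as.numeric(gsub("[^0-9.]", "", val("^AC\\$MASS_SPECTROMETRY:\\s*COLLISION_ENERGY\\s*")))
  imode <- tolower(val("^AC\\$MASS_SPECTROMETRY:\\s*ION_MODE\\s*"))
  rt_txt <- val("^AC\\$CHROMATOGRAPHY:\\s*RETENTION_TIME\\s*")
  rt <- as.numeric(gsub("[^0-9.]", "", rt_txt))
  if (!is.na(rt_txt) && grepl("\\bs(ec)?\\b", rt_txt) && !grepl("min", rt_txt)) {
    rt <- rt / 60
  }
  pk_start <- grep("^PK\\$PEAK:", block)
  peaks <- tibble::tibble(mz = numeric(), intensity = numeric(),
                          annotation = character())
  if (length(pk_start) == 1 && pk_start < length(block)) {
    pls <- block[(pk_start + 1):length(block)]
    pls <- pls[!grepl("^//", pls)]
    pls <- trimws(pls)
    pls <- pls[nzchar(pls)]
    if (length(pls)) {
      fields <- strsplit(pls, "\\s+")
      peaks <- tibble::tibble(
        mz = vapply(fields, function(f) as.numeric(f[1]), 0),
        intensity = vapply(fields, function(f) as.numeric(f[2]), 0),
        annotation = NA_character_)
    }
  }
  imod <- if (is.na(imode)) "positive" else imode
  spec <- ms_spectrum(peaks$mz, peaks$intensity,
                      precursor_mz = pmz, collision_energy = ce, rt = rt,
                      ion_mode = imod)
  list(name = nm, formula = formula, adduct = ptype, inchikey = inchikey,
       smiles = smiles, precursor_mz = pmz, experimental_mz = NA_real_,
       rt = rt, ion_mode = imod, collision_energy = ce,
       spectrum = spec, provenance = character())
}

# ---- AIF runs ----------------------------------------------------------

#' Construct an AIF run
#'
#' An AIF run holds centroided scan data for cycles of alternating
#' collision-energy channels (default full scan 0 eV, then 10 and 30 eV).
#'
#' @param points Tibble with columns `cycle` (integer), `channel` (collision
#'   energy, eV), `time_min`, `mz`, `intensity` — one row per centroid.
#' @param cycles Tibble with columns `cycle`, `channel`, `time_min` listing
#'   every acquired scan (including scans that produced no centroids). If
#'   `NULL`, derived from `points`.
#' @param channel_energies Collision-energy channels in acquisition order.
#' @param mass_range Acquired m/z interval, Th.
#' @return Object of class `aif_run`.
#' @export
aif_run <- function(points, cycles = NULL, channel_energies = c(0, 10, 30),
                    mass_range = c(40, 1200)) {
  if (is.null(cycles)) {
    cycles <- dplyr::distinct(points[, c("cycle", "channel", "time_min")])
  }
  cycles <- dplyr::arrange(cycles, .data$time_min)
  if (any(diff(cycles$time_min) <= 0)) {
    stop("scan times must be strictly increasing", call. = FALSE)
  }
  per_cycle <- tapply(cycles$channel, cycles$cycle,
                      function(ch) length(unique(ch)))
  if (any(per_cycle != length(channel_energies))) {
    bad <- names(per_cycle)[per_cycle != length(channel_energies)][1]
    stop("cycle ", bad, " does not contain all channels (",
         paste(channel_energies, collapse = ", "), " eV)", call. = FALSE)
  }
  structure(list(points = tibble::as_tibble(points),
                 cycles = tibble::as_tibble(cycles),
                 channel_energies = channel_energies,
                 mass_range = mass_range),
            class = "aif_run")
}

#' @export
print.aif_run <- function(x, ...) {
  cat(sprintf("<aif_run> %d cycles x %d channels (%s eV) | %d centroids | m/z %g-%g\n",
              length(unique(x$cycles$cycle)), length(x$channel_energies),
              paste(x$channel_energies, collapse = "/"),
              nrow(x$points), x$mass_range[1], x$mass_range[2]))
  invisible(x)
}

#' Read / write AIF scan data in the internal tabular format
#'
#' The internal format is a UTF-8 TSV with comment headers
#' `# channel_energies:` and `# mass_range:` followed by columns `cycle`,
#' `channel`, `time_min`, `mz`, `intensity` (one row per centroid; scans
#' with no centroids appear once with `NA` m/z). `read_aif_run` also accepts
#' an mzML file (extension `.mzML`, requires the mzR package), grouping
#' scans into cycles by arrival order of their collision-energy labels.
#'
#' @param path File to read or write.
#' @param run An `aif_run` (for `write_aif_run`).
#' @return `read_aif_run`: an `aif_run`; `write_aif_run`: `path`, invisibly.
#' @export
read_aif_run <- function(path) {
  if (grepl("\\.mzml$", path, ignore.case = TRUE)) {
    return(.read_mzml_run(path))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  geth <- function(key) {
    hit <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (length(hit) == 0) return(NULL)
    as.numeric(strsplit(sub("^[^:]*:", "", hit[1]), ",")[[1]])
  }
  energies <- geth("channel_energies") %||% c(0, 10, 30)
  mass_range <- geth("mass_range") %||% c(40, 1200)
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t")
  cycles <- dplyr::distinct(df[, c("cycle", "channel", "time_min")])
  points <- tibble::as_tibble(df[!is.na(df$mz), ])
  aif_run(points, cycles = cycles, channel_energies = energies,
          mass_range = mass_range)
}

#' @rdname read_aif_run
#' @export
write_aif_run <- function(run, path) {
  empty <- dplyr::anti_join(run$cycles,
                            run$points[, c("cycle", "channel")],
                            by = c("cycle", "channel"))
  df <- dplyr::bind_rows(
    run$points[, c("cycle", "channel", "time_min", "mz", "intensity")],
    if (nrow(empty)) tibble::tibble(cycle = empty$cycle, channel = empty$channel,
                                    time_min = empty$time_min,
                                    mz = NA_real_, intensity = NA_real_)
  )
  df <- dplyr::arrange(df, .data$time_min, .data$mz)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    paste0("# channel_energies: ", paste(run$channel_energies, collapse = ",")),
    paste0("# mass_range: ", paste(run$mass_range, collapse = ","))), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_mzml_run <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the mzR package", call. = FALSE)
  }
  h <- NULL
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms))
  h <- mzR::header(ms)
  ce <- h$collisionEnergy
  ce[is.na(ce)] <- 0
  # group scans into cycles: a new cycle starts whenever the first channel
  # label (in arrival order) recurs
  first_label <- ce[1]
  cycle <- cumsum(ce == first_label)
  pts <- lapply(seq_len(nrow(h)), function(i) {
    pk <- mzR::peaks(ms, i)
    if (nrow(pk) == 0) return(NULL)
    tibble::tibble(cycle = cycle[i], channel = ce[i],
                   time_min = h$retentionTime[i] / 60,
                   mz = pk[, 1], intensity = pk[, 2])
  })
  cycles <- tibble::tibble(cycle = cycle, channel = ce,
                           time_min = h$retentionTime / 60)
  aif_run(dplyr::bind_rows(pts), cycles = cycles,
          channel_energies = unique(ce),
          mass_range = c(min(h$lowMZ, na.rm = TRUE), max(h$highMZ, na.rm = TRUE)))
}
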
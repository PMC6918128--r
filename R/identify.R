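# AMRT+MS2 identification: accurate-mass + retention-time candidate search
# against a curated library, MS2 dot-product scoring, and assignment of a
# reporting confidence level.

#' Find accurate-mass + retention-time candidate matches
#'
#' Returns every (feature, record) pair whose m/z and corrected RT both
#' fall within the tolerances. No bijection is forced: one feature may
#' match several records and one record several features.
#'
#' @param features Data frame of query features with columns `feature_id`,
#'   `mz`, `rt` (corrected, minutes), `height`, and optionally `ms2` (list
#'   of named lists of [ms_spectrum] per collision energy).
#' @param lib An [ms_library].
#' @param mz_tol m/z tolerance, Th.
#' @param rt_tol RT tolerance, minutes.
#' @return Tibble of class `amrt_matches`: feature columns plus `record`
#'   (library row index), `compound`, `adduct`, `mass_error_mda`,
#'   `rt_error_min`.
#' @export
find_amrt_matches <- function(features, lib, mz_tol = 0.01, rt_tol = 0.7) {
  if (mz_tol <= 0 || rt_tol <= 0) stop("tolerances must be > 0", call. = FALSE)
  rows <- lapply(seq_len(nrow(features)), function(i) {
    dm <- features$mz[i] - lib$precursor_mz
    dr <- features$rt[i] - lib$rt
    hit <- which(abs(dm) <= mz_tol & abs(dr) <= rt_tol)
    if (length(hit) == 0) return(NULL)
    tibble::tibble(feature_id = features$feature_id[i],
                   feature_mz = features$mz[i],
                   feature_rt = features$rt[i],
                   height = features$height[i],
                   record = hit,
                   compound = lib$name[hit],
                   adduct = lib$adduct[hit],
                   mass_error_mda = 1000 * dm[hit],
                   rt_error_min = dr[hit])
  })
  out <- dplyr::bind_rows(rows)
  if (is.null(out) || nrow(out) == 0) {
    out <- tibble::tibble(feature_id = character(), feature_mz = numeric(),
                          feature_rt = numeric(), height = numeric(),
                          record = integer(), compound = character(),
                          adduct = character(), mass_error_mda = numeric(),
                          rt_error_min = numeric())
  }
  class(out) <- c("amrt_matches", class(out))
  out
}

#' Score AMRT candidates by MS2 similarity
#'
#' Computes the spectral dot product between the feature's deconvoluted MS2
#' and the library record at every shared collision energy; a candidate is
#' accepted when its best similarity reaches `ms2_threshold`. Candidates
#' without that support are retained with status `"AMRT-only"` — never
#' silently dropped, since an AMRT-only hit is still a (weaker) annotation.
#'
#' @param candidates An `amrt_matches` tibble from [find_amrt_matches()].
#' @param features The query feature table (provides the `ms2` list-column:
#'   per feature, a named list of [ms_spectrum] keyed by collision energy).
#' @param lib The [ms_library] used for the search.
#' @param bin_tol Dot-product match tolerance, Th.
#' @param ms2_threshold Acceptance threshold, percent similarity.
#' @return The candidates with added columns `similarity` (best over shared
#'   energies, `NA` when no spectra could be compared), `energy` (of the
#'   best similarity), `accepted`, `status` (`"AMRT+MS2"` or `"AMRT-only"`).
#' @export
score_matches <- function(candidates, features, lib, bin_tol = 0.01,
                          ms2_threshold = 70) {
  ms2_of <- function(fid) {
    i <- match(fid, features$feature_id)
    if ("ms2" %in% names(features)) features$ms2[[i]] else NULL
  }
  sim <- lapply(seq_len(nrow(candidates)), function(k) {
    qs <- ms2_of(candidates$feature_id[k])
    rec <- lib[candidates$record[k], ]
    if (is.null(qs) || length(qs) == 0) {
      return(list(similarity = NA_real_, energy = NA_real_))
    }
    energies <- suppressWarnings(as.numeric(names(qs)))
    shared <- which(energies == rec$collision_energy)
    if (is.na(rec$collision_energy) || length(shared) == 0) {
      return(list(similarity = NA_real_, energy = NA_real_))
    }
    sims <- vapply(shared, function(j) {
      q <- qs[[j]]
      if (is.null(q) || nrow(q) == 0) return(NA_real_)
      dot_product(q, rec$spectrum[[1]], bin_tol = bin_tol)
    }, 0)
    if (all(is.na(sims))) return(list(similarity = NA_real_, energy = NA_real_))
    best <- which.max(sims)
    list(similarity = sims[best], energy = energies[shared][best])
  })
  candidates$similarity <- vapply(sim, `[[`, 0, "similarity")
  candidates$energy <- vapply(sim, `[[`, 0, "energy")
  candidates$accepted <- !is.na(candidates$similarity) &
    candidates$similarity >= ms2_threshold
  candidates$status <- ifelse(candidates$accepted, "AMRT+MS2", "AMRT-only")
  # rank multiple accepted records per feature: similarity, then RT error,
  # then mass error; best flagged
  candidates <- dplyr::arrange(
    candidates, .data$feature_id,
    dplyr::desc(dplyr::coalesce(.data$similarity, -1)),
    abs(.data$rt_error_min), abs(.data$mass_error_mda))
  candidates$best <- !duplicated(candidates$feature_id) & candidates$accepted
  class(candidates) <- unique(c("amrt_matches", class(candidates)))
  candidates
}

#' Assign a reporting confidence level
#'
#' Identification-confidence policy: an AMRT+MS2-accepted match against
#' standards run in the same analytical batch earns level 1; the same match
#' against a library from another batch earns level 2 (AMRT+MS2), because
#' retention times are only fully trustworthy within a batch; an AMRT-only
#' match earns level 2 (AMRT). The mapping is overridable.
#'
#' @param matches Scored matches from [score_matches()].
#' @param same_batch Were the library standards analyzed in the same
#'   analytical batch as the query data?
#' @param policy Named character vector mapping the three cases
#'   `accepted_same_batch`, `accepted_other_batch`, `amrt_only` to labels.
#' @return The matches with a `level` column.
#' @export
assign_level <- function(matches, same_batch = FALSE,
                         policy = c(accepted_same_batch = "level-1",
                                    accepted_other_batch = "level-2 (AMRT+MS2)",
                                    amrt_only = "level-2 (AMRT)")) {
  matches$level <- ifelse(
    matches$accepted,
    if (same_batch) policy[["accepted_same_batch"]] else policy[["accepted_other_batch"]],
    policy[["amrt_only"]])
  matches
}

#' @exportS3Method generics::tidy
tidy.amrt_matches <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @exportS3Method generics::glance
glance.amrt_matches <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x),
    n_features = dplyr::n_distinct(x$feature_id),
    n_accepted = if ("accepted" %in% names(x)) sum(x$accepted) else NA_integer_,
    median_abs_mass_error_mda = stats::median(abs(x$mass_error_mda)),
    median_abs_rt_error_min = stats::median(abs(x$rt_error_min)))
}

#' Plot identification candidates
#'
#' @param object An `amrt_matches` tibble (scored).
#' @param ... Ignored.
#' @return A ggplot of RT error vs mass error, colored by status.
#' @exportS3Method ggplot2::autoplot
autoplot.amrt_matches <- function(object, ...) {
  df <- tibble::as_tibble(object)
  if (!"status" %in% names(df)) df$status <- "candidate"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rt_error_min,
                                   y = .data$mass_error_mda,
                                   colour = .data$status)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "RT error (min)", y = "mass error (mDa)",
                  colour = NULL, title = "AMRT+MS2 candidates")
}
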
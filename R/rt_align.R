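# Retention-time correction anchored on technical internal standards (tIS):
# piecewise-linear mapping between observed and reference anchor RTs, with
# constant-offset extrapolation beyond the anchor span.

#' Build a tIS retention-time map
#'
#' Matches observed tIS anchors to their reference counterparts by compound
#' name and assembles the piecewise-linear correction. Anchors present in
#' the reference but not detected in the run (e.g. lost to ion suppression)
#' are dropped with a warning.
#'
#' @param reference Data frame with columns `name` and `rt` (reference
#'   retention times from an authentic representative analysis, minutes).
#' @param observed Data frame with columns `name` and `rt` (the same tIS as
#'   detected in the run to be corrected). Missing compounds are allowed.
#' @return Tibble of class `rt_map` with columns `name`, `observed`,
#'   `reference`, sorted by observed RT.
#' @examples
#' ref <- data.frame(name = c("a", "b"), rt = c(2, 10))
#' obs <- data.frame(name = c("a", "b"), rt = c(2.5, 10.5))
#' build_rt_map(ref, obs)
#' @export
build_rt_map <- function(reference, observed) {
  stopifnot(all(c("name", "rt") %in% names(reference)),
            all(c("name", "rt") %in% names(observed)))
  if (any(reference$rt <= 0)) stop("reference RTs must be positive", call. = FALSE)
  if (anyDuplicated(reference$rt)) {
    stop("reference anchors must have distinct RTs", call. = FALSE)
  }
  obs <- observed[!is.na(observed$rt), ]
  matched <- merge(data.frame(name = reference$name, reference = reference$rt),
                   data.frame(name = obs$name, observed = obs$rt),
                   by = "name")
  dropped <- setdiff(reference$name, matched$name)
  if (length(dropped) > 0) {
    warning("tIS anchor(s) not detected, dropped from RT map: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (nrow(matched) < 2) {
    stop("need at least 2 matched tIS anchors to build an RT map (got ",
         nrow(matched), ")", call. = FALSE)
  }
  matched <- matched[order(matched$observed), ]
  if (any(diff(matched$observed) <= 0) || any(diff(matched$reference) <= 0)) {
    ord <- matched[order(matched$reference), ]
    off <- ord$name[c(diff(ord$observed) <= 0, FALSE) |
                      c(FALSE, diff(ord$observed) <= 0)]
    stop("observed anchor RTs are not monotone in reference order (",
         paste(unique(off), collapse = ", "), ")", call. = FALSE)
  }
  out <- tibble::tibble(name = matched$name, observed = matched$observed,
                        reference = matched$reference)
  class(out) <- c("rt_map", class(out))
  out
}

#' Apply a retention-time map
#'
#' Linear interpolation between anchors; at an observed anchor the reference
#' RT is returned exactly; outside the anchor span the offset of the nearest
#' anchor is applied as a constant (no slope extrapolation).
#'
#' @param map An `rt_map` from [build_rt_map()].
#' @param rt Retention time(s) to correct, minutes, `>= 0`.
#' @return Corrected retention time(s), minutes.
#' @examples
#' m <- build_rt_map(data.frame(name = c("a", "b"), rt = c(2, 10)),
#'                   data.frame(name = c("a", "b"), rt = c(2.5, 10.5)))
#' correct_rt(m, c(2.5, 6.5, 12.0))  # 2.0 6.0 11.5
#' @export
correct_rt <- function(map, rt) {
  stopifnot(inherits(map, "rt_map"))
  if (any(rt < 0, na.rm = TRUE)) stop("rt must be non-negative", call. = FALSE)
  inner <- stats::approx(map$observed, map$reference, xout = rt,
                         rule = 1, ties = "ordered")$y
  lo <- rt < map$observed[1]
  hi <- rt > map$observed[nrow(map)]
  inner[lo] <- rt[lo] + (map$reference[1] - map$observed[1])
  inner[hi] <- rt[hi] + (map$reference[nrow(map)] - map$observed[nrow(map)])
  inner
}

#' Retention-time deviation statistics across runs
#'
#' Summarizes the repeatability of one compound's RT over repeated
#' injections: mean, maximum absolute deviation from the mean, and the
#' coefficient of variation (sample standard deviation over mean, percent).
#'
#' @param rts Numeric vector of retention times (minutes), length `>= 2`.
#' @return One-row tibble with columns `n`, `mean`, `max_dev`, `cv_percent`.
#' @examples
#' rt_deviation_stats(c(7.0, 7.2, 7.4))
#' @export
rt_deviation_stats <- function(rts) {
  rts <- rts[!is.na(rts)]
  if (length(rts) < 2) {
    stop("need at least 2 retention times", call. = FALSE)
  }
  m <- mean(rts)
  tibble::tibble(n = length(rts), mean = m,
                 max_dev = max(abs(rts - m)),
                 cv_percent = 100 * stats::sd(rts) / m)
}

#' Locate tIS anchors in a run
#'
#' For each tIS, extracts the full-scan EIC at its adduct m/z and takes the
#' apex of the most intense chromatographic peak within a search window
#' around the reference RT as the observed anchor.
#'
#' @param run An `aif_run`.
#' @param tis Data frame with columns `name`, `formula`, `adduct`, `rt`
#'   (reference RT, minutes).
#' @param mz_tol EIC extraction tolerance, Th.
#' @param search_window Half-width of the RT window around the reference RT
#'   in which the anchor is sought, minutes.
#' @param min_height Minimum peak height for a detection.
#' @return Tibble with columns `name`, `rt` (observed apex, `NA` when not
#'   detected), `height`.
#' @export
locate_tis_anchors <- function(run, tis, mz_tol = 0.01, search_window = 1.5,
                               min_height = 0) {
  stopifnot(inherits(run, "aif_run"))
  rows <- lapply(seq_len(nrow(tis)), function(i) {
    mz <- adduct_mz(tis$formula[i], tis$adduct[i])
    eic <- extract_eic(run, channel = run$channel_energies[1], mz = mz,
                       tol = mz_tol)
    pk <- detect_peaks(eic, min_height = min_height)
    pk <- pk[abs(pk$apex_rt - tis$rt[i]) <= search_window, ]
    if (nrow(pk) == 0) {
      tibble::tibble(name = tis$name[i], rt = NA_real_, height = NA_real_)
    } else {
      best <- pk[which.max(pk$height), ]
      tibble::tibble(name = tis$name[i], rt = best$apex_rt, height = best$height)
    }
  })
  dplyr::bind_rows(rows)
}

#' @exportS3Method generics::tidy
tidy.rt_map <- function(x, ...) {
  tibble::tibble(name = x$name, observed = x$observed, reference = x$reference,
                 offset = x$reference - x$observed)
}

#' @exportS3Method generics::glance
glance.rt_map <- function(x, ...) {
  off <- x$reference - x$observed
  tibble::tibble(n_anchors = nrow(x), mean_offset = mean(off),
                 max_abs_offset = max(abs(off)),
                 span_observed = diff(range(x$observed)))
}

#' Plot a retention-time map
#'
#' @param object An `rt_map`.
#' @param ... Ignored.
#' @return A ggplot showing the observed-to-reference offset per anchor.
#' @exportS3Method ggplot2::autoplot
autoplot.rt_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$offset)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "observed RT (min)", y = "reference - observed (min)",
                  title = "tIS retention-time correction")
}
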
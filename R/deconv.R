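# EIC extraction, chromatographic peak detection, and MS2 deconvolution of
# AIF data by two complementary strategies: within-run non-negative
# least-squares fitting of elution profiles, and cross-dilution-series
# correlation of fragment intensities with the precursor.

#' Extract an ion chromatogram
#'
#' Per scan of the requested collision-energy channel, sums the centroid
#' intensities within `mz +/- tol`; scans with no centroid in the window
#' contribute zero.
#'
#' @param run An `aif_run`.
#' @param channel Collision energy of the channel to extract from, eV.
#' @param mz Target m/z, Th.
#' @param tol Extraction half-window, Th (`> 0`).
#' @return Tibble of class `eic` with columns `time_min`, `intensity` and
#'   attributes `target_mz`, `tol`, `channel`.
#' @export
extract_eic <- function(run, channel, mz, tol = 0.01) {
  stopifnot(inherits(run, "aif_run"))
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  if (!channel %in% run$channel_energies) {
    stop("channel ", channel, " eV not present in run", call. = FALSE)
  }
  grid <- run$cycles[run$cycles$channel == channel, ]
  grid <- grid[order(grid$time_min), ]
  pts <- run$points[run$points$channel == channel &
                      abs(run$points$mz - mz) <= tol, ]
  ints <- stats::setNames(rep(0, nrow(grid)), as.character(grid$cycle))
  if (nrow(pts) > 0) {
    agg <- tapply(pts$intensity, pts$cycle, sum)
    ints[names(agg)] <- agg
  }
  out <- tibble::tibble(time_min = grid$time_min, intensity = unname(ints))
  structure(out, class = c("eic", class(out)),
            target_mz = mz, tol = tol, channel = channel)
}

#' Detect chromatographic peaks in an EIC
#'
#' Local maxima of the 3-point moving-average-smoothed trace; boundaries
#' extend from the apex to the nearest valley or baseline crossing. The
#' apex retention time is refined by parabolic interpolation through the
#' three scans around the maximum. Peaks narrower than `min_width` scans or
#' lower than `min_height` are discarded.
#'
#' @param eic An `eic`.
#' @param min_height Minimum raw apex height, detector units.
#' @param min_width Minimum number of scans between the boundaries.
#' @return Tibble with columns `apex_rt`, `height`, `area`, `left`, `right`
#'   (boundaries in minutes).
#' @export
detect_peaks <- function(eic, min_height = 0, min_width = 3) {
  y <- eic$intensity
  t <- eic$time_min
  n <- length(y)
  if (n < 3 || all(y == 0)) {
    return(tibble::tibble(apex_rt = numeric(), height = numeric(),
                          area = numeric(), left = numeric(), right = numeric()))
  }
  s <- stats::filter(y, rep(1 / 3, 3), sides = 2)
  s[is.na(s)] <- y[is.na(s)]
  s <- as.numeric(s)
  apexes <- which(s[2:(n - 1)] >= s[1:(n - 2)] & s[2:(n - 1)] >= s[3:n] &
                    (s[2:(n - 1)] > s[1:(n - 2)] | s[2:(n - 1)] > s[3:n]) &
                    s[2:(n - 1)] > 0) + 1L
  rows <- lapply(apexes, function(i) {
    l <- i
    while (l > 1 && s[l - 1] < s[l] && s[l - 1] > 0) l <- l - 1L
    r <- i
    while (r < n && s[r + 1] < s[r] && s[r + 1] > 0) r <- r + 1L
    if (r - l + 1 < min_width) return(NULL)
    height <- max(y[l:r])
    if (height < min_height || height <= 0) return(NULL)
    im <- l - 1L + which.max(y[l:r])
    apex_rt <- t[im]
    if (im > 1 && im < n) {
      y1 <- y[im - 1]; y2 <- y[im]; y3 <- y[im + 1]
      den <- y1 - 2 * y2 + y3
      if (den < 0) {
        delta <- 0.5 * (y1 - y3) / den
        if (abs(delta) <= 0.5) {
          apex_rt <- t[im] + delta * mean(diff(t[max(1, im - 1):min(n, im + 1)]))
        }
      }
    }
    tibble::tibble(apex_rt = apex_rt, height = height,
                   area = sum(diff(t[l:r]) * (y[l:(r - 1)] + y[(l + 1):r]) / 2),
                   left = t[l], right = t[r])
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(apex_rt = numeric(), height = numeric(),
                          area = numeric(), left = numeric(), right = numeric()))
  }
  # merge duplicate apexes that smoothing can produce on plateaus
  out <- out[!duplicated(round(out$apex_rt, 6)), ]
  dplyr::arrange(out, .data$apex_rt)
}

# non-negative least squares by iterative clamping: drop columns whose
# unconstrained coefficient goes negative and refit (fallback for the rare
# designs where the active-set solver fails to converge)
.nnls_clamp <- function(X, y) {
  active <- seq_len(ncol(X))
  coefs <- rep(0, ncol(X))
  for (it in seq_len(ncol(X))) {
    b <- tryCatch(stats::coef(stats::lm.fit(X[, active, drop = FALSE], y)),
                  error = function(e) rep(0, length(active)))
    b[is.na(b)] <- 0
    if (all(b >= 0)) {
      coefs[active] <- b
      return(coefs)
    }
    active <- active[b >= 0]
    if (length(active) == 0) return(coefs)
  }
  coefs[active] <- pmax(b, 0)
  coefs
}

# cluster sorted m/z values into bins separated by gaps > tol;
# returns an integer bin id per input value (original order)
.bin_mz <- function(mz, tol) {
  ord <- order(mz)
  gaps <- c(0, diff(mz[ord]))
  bin_sorted <- cumsum(gaps > tol) + 1L
  bins <- integer(length(mz))
  bins[ord] <- bin_sorted
  bins
}

.deconv_spectrum <- function(mz, intensity, quality, method, precursor_mz,
                             apex_rt, channel) {
  ord <- order(mz)
  s <- ms_spectrum(mz[ord], intensity[ord],
                   precursor_mz = precursor_mz, collision_energy = channel,
                   rt = apex_rt, ion_mode = "positive")
  s$quality <- quality[ord]
  attr(s, "method") <- method
  class(s) <- unique(c("deconvoluted_spectrum", class(s)))
  s
}

#' MS2 deconvolution by within-run least squares
#'
#' For every fragment m/z bin with signal inside the precursor peak's
#' boundaries in the chosen collision-energy channel, fits the bin's EIC
#' segment as a non-negative linear combination of (i) the precursor's
#' normalized full-scan elution profile, (ii) normalized profiles of other
#' peaks detected in that bin's own EIC whose apexes differ from the
#' precursor apex, and (iii) a constant baseline. The deconvoluted
#' intensity of the bin is the precursor component's fitted apex height;
#' zero-coefficient bins are omitted.
#'
#' @param run An `aif_run`.
#' @param precursor One row of [detect_peaks()] output for the precursor in
#'   the full-scan channel.
#' @param channel Fragment channel collision energy, eV.
#' @param precursor_mz Precursor m/z, Th.
#' @param frag_tol Fragment binning tolerance, Th.
#' @param apex_tol Minimum apex separation (minutes) for a bin-EIC peak to
#'   count as an interferent rather than the precursor itself.
#' @param saturation_ceiling Intensity above which the precursor profile is
#'   considered clipped; a Gaussian profile fitted to the peak width is then
#'   used instead of the raw profile shape.
#' @param min_share Minimum fraction of a bin's maximum signal that the
#'   precursor component must explain for the bin to be reported.
#' @return A `deconvoluted_spectrum` (an [ms_spectrum] with a `quality`
#'   column holding the fit R^2 per bin and attribute `method =
#'   "least-squares"`), or an empty spectrum when the window has no signal.
#' @export
ms2dec <- function(run, precursor, channel, precursor_mz,
                   frag_tol = 0.01, apex_tol = 0.05,
                   saturation_ceiling = Inf, min_share = 0.05) {
  stopifnot(inherits(run, "aif_run"), nrow(precursor) == 1)
  full_ch <- run$channel_energies[1]
  prec_eic <- extract_eic(run, full_ch, precursor_mz, tol = frag_tol)
  in_win <- prec_eic$time_min >= precursor$left &
    prec_eic$time_min <= precursor$right
  if (!any(in_win)) stop("precursor boundaries contain no scans", call. = FALSE)
  prof_t <- prec_eic$time_min[in_win]
  prof <- prec_eic$intensity[in_win]
  clipped <- max(prof) >= saturation_ceiling
  if (clipped) {
    # Gaussian fallback: sigma from full width at half maximum
    half <- prof >= max(prof) / 2
    fwhm <- diff(range(prof_t[half]))
    sigma <- max(fwhm / 2.3548, mean(diff(prof_t)))
    prof <- exp(-0.5 * ((prof_t - precursor$apex_rt) / sigma)^2)
  }
  if (max(prof) <= 0) stop("precursor profile is empty", call. = FALSE)
  prof <- prof / max(prof)
  # chromatographic width shared by coeluting components: Gaussian fit to
  # the precursor profile, falling back to full width at half maximum
  halfp <- prof >= 0.5
  sigma_chrom <- max(diff(range(prof_t[halfp])) / 2.3548, mean(diff(prof_t)))
  gfit <- tryCatch(
    stats::nls(prof ~ a * exp(-0.5 * ((prof_t - mu) / sig)^2),
               start = list(a = 1, mu = precursor$apex_rt, sig = sigma_chrom),
               control = stats::nls.control(warnOnly = TRUE)),
    error = function(e) NULL)
  if (!is.null(gfit)) {
    sg <- abs(stats::coef(gfit)[["sig"]])
    if (is.finite(sg) && sg > 0.2 * sigma_chrom && sg < 5 * sigma_chrom) {
      sigma_chrom <- sg
    }
  }

  pts_ch <- run$points[run$points$channel == channel, ]
  pts <- pts_ch[pts_ch$time_min >= precursor$left &
                  pts_ch$time_min <= precursor$right, ]
  if (nrow(pts) == 0) {
    return(.deconv_spectrum(numeric(), numeric(), numeric(), "least-squares",
                            precursor_mz, precursor$apex_rt, channel))
  }
  bins <- .bin_mz(pts$mz, frag_tol)
  frag_grid <- run$cycles[run$cycles$channel == channel, ]
  frag_grid <- frag_grid[order(frag_grid$time_min), ]
  win_scans <- frag_grid$time_min >= precursor$left &
    frag_grid$time_min <= precursor$right
  win_times <- frag_grid$time_min[win_scans]
  # resample the (full-scan-channel) precursor profile onto the fragment
  # channel's scan times
  prof_w <- stats::approx(prof_t, prof, xout = win_times, rule = 2)$y

  # bin EIC over the whole run, built from the channel's points directly
  # (avoids re-scanning the full point table per bin)
  cyc_index <- match(pts_ch$cycle, frag_grid$cycle)
  bin_eic_of <- function(bin_mz) {
    ints <- rep(0, nrow(frag_grid))
    sel <- which(abs(pts_ch$mz - bin_mz) <= frag_tol)
    if (length(sel) > 0) {
      agg <- tapply(pts_ch$intensity[sel], cyc_index[sel], sum)
      ints[as.integer(names(agg))] <- agg
    }
    structure(tibble::tibble(time_min = frag_grid$time_min, intensity = ints),
              class = c("eic", "tbl_df", "tbl", "data.frame"),
              target_mz = bin_mz, tol = frag_tol, channel = channel)
  }
  res <- lapply(split(seq_len(nrow(pts)), bins), function(idx) {
    sub <- pts[idx, ]
    bin_mz <- sum(sub$mz * sub$intensity) / sum(sub$intensity)
    bin_eic <- bin_eic_of(bin_mz)
    yw <- bin_eic$intensity[win_scans]
    if (all(yw == 0)) return(NULL)
    interf <- detect_peaks(bin_eic, min_height = 0)
    interf <- interf[abs(interf$apex_rt - precursor$apex_rt) > apex_tol &
                       interf$right > precursor$left &
                       interf$left < precursor$right, ]
    X <- matrix(prof_w, ncol = 1)
    if (nrow(interf) > 0) {
      for (j in seq_len(nrow(interf))) {
        # interferent elution modeled as a Gaussian at its detected apex
        # with the shared chromatographic width (using the mixed bin trace
        # itself would let the interferent absorb the precursor's share)
        p <- exp(-0.5 * ((win_times - interf$apex_rt[j]) / sigma_chrom)^2)
        if (max(p) > 1e-6) X <- cbind(X, p / max(p))
      }
    }
    X <- cbind(X, 1)  # constant baseline
    fit <- tryCatch(pracma::lsqnonneg(X, yw), error = function(e) NULL)
    if (is.null(fit)) fit <- list(x = .nnls_clamp(X, yw))
    coef_prec <- fit$x[1]
    if (coef_prec <= 0) return(NULL)
    # a bin dominated by other components is not attributed to the
    # precursor: its fitted share must clear min_share of the bin signal
    if (coef_prec < min_share * max(yw)) return(NULL)
    fitted <- as.numeric(X %*% fit$x)
    ss_res <- sum((yw - fitted)^2)
    ss_tot <- sum((yw - mean(yw))^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
    tibble::tibble(mz = bin_mz, intensity = coef_prec,
                   quality = max(min(r2, 1), 0))
  })
  res <- dplyr::bind_rows(res)
  if (nrow(res) == 0) {
    return(.deconv_spectrum(numeric(), numeric(), numeric(), "least-squares",
                            precursor_mz, precursor$apex_rt, channel))
  }
  .deconv_spectrum(res$mz, res$intensity, res$quality, "least-squares",
                   precursor_mz, precursor$apex_rt, channel)
}

#' MS2 deconvolution by cross-sample correlation
#'
#' Uses a dilution series: fragment bins whose apex heights across runs
#' correlate with the precursor's apex heights (Pearson r at least
#' `r_threshold`, computed over the runs where the precursor is above
#' `noise_level`) are attributed to the precursor. The method declines
#' (returns `NULL`) unless at least `min_samples` runs have the precursor
#' above the noise level. Reported intensities are the through-origin
#' regression slopes of fragment on precursor height, rescaled so the base
#' peak is 100. Constant (zero-variance) fragment vectors — chemical noise
#' present at every dilution — fail the correlation test by definition.
#'
#' @param series List of `aif_run` (the dilution series, any order).
#' @param precursor_mz Precursor m/z, Th.
#' @param channel Fragment channel collision energy, eV.
#' @param noise_level Precursor height threshold for a run to count as
#'   above-noise (detector units).
#' @param min_samples Minimum number of above-noise runs required.
#' @param r_threshold Minimum Pearson correlation for a fragment bin.
#' @param mz_tol Precursor EIC tolerance, Th.
#' @param frag_tol Fragment binning tolerance, Th.
#' @param expected_rt Optional RT (minutes) to disambiguate the precursor
#'   peak; the most intense peak within `rt_window` of it is used.
#' @param rt_window Half-width of the `expected_rt` search window, minutes.
#' @return A `deconvoluted_spectrum` with `quality` = Pearson r and
#'   attribute `method = "correlation"`, or `NULL` when declined.
#' @export
corrdec <- function(series, precursor_mz, channel, noise_level,
                    min_samples = 4, r_threshold = 0.90,
                    mz_tol = 0.01, frag_tol = 0.01,
                    expected_rt = NULL, rt_window = 0.5) {
  stopifnot(length(series) >= 2)
  ch_struct <- lapply(series, function(r) r$channel_energies)
  if (length(unique(vapply(ch_struct, paste, "", collapse = ","))) != 1) {
    stop("runs have unequal channel structure", call. = FALSE)
  }
  full_ch <- series[[1]]$channel_energies[1]
  prec <- lapply(series, function(run) {
    eic <- extract_eic(run, full_ch, precursor_mz, tol = mz_tol)
    pk <- detect_peaks(eic)
    if (!is.null(expected_rt)) {
      pk <- pk[abs(pk$apex_rt - expected_rt) <= rt_window, ]
    }
    if (nrow(pk) == 0) return(NULL)
    pk[which.max(pk$height), ]
  })
  h <- vapply(prec, function(p) if (is.null(p)) 0 else p$height, 0)
  above <- which(h > noise_level)
  if (length(above) < min_samples) return(NULL)

  # pool fragment centroids from each above-noise run's own precursor window
  pooled <- dplyr::bind_rows(lapply(above, function(i) {
    run <- series[[i]]
    w <- prec[[i]]
    pts <- run$points[run$points$channel == channel &
                        run$points$time_min >= w$left &
                        run$points$time_min <= w$right, ]
    if (nrow(pts) == 0) return(NULL)
    tibble::tibble(run = i, mz = pts$mz, intensity = pts$intensity,
                   time_min = pts$time_min)
  }))
  if (is.null(pooled) || nrow(pooled) == 0) {
    ref <- prec[[above[which.max(h[above])]]]
    return(.deconv_spectrum(numeric(), numeric(), numeric(), "correlation",
                            precursor_mz, ref$apex_rt, channel))
  }
  pooled$bin <- .bin_mz(pooled$mz, frag_tol)
  hh <- h[above]
  res <- lapply(split(seq_len(nrow(pooled)), pooled$bin), function(idx) {
    sub <- pooled[idx, ]
    bin_mz <- sum(sub$mz * sub$intensity) / sum(sub$intensity)
    v <- vapply(above, function(i) {
      x <- sub$intensity[sub$run == i]
      if (length(x) == 0) 0 else max(x)
    }, 0)
    if (stats::sd(v) == 0 || stats::sd(hh) == 0) return(NULL)
    r <- stats::cor(v, hh)
    if (!is.finite(r) || r < r_threshold) return(NULL)
    slope <- sum(v * hh) / sum(hh^2)
    tibble::tibble(mz = bin_mz, intensity = slope, quality = r)
  })
  res <- dplyr::bind_rows(res)
  ref <- prec[[above[which.max(h[above])]]]
  if (nrow(res) == 0) {
    return(.deconv_spectrum(numeric(), numeric(), numeric(), "correlation",
                            precursor_mz, ref$apex_rt, channel))
  }
  res$intensity <- 100 * res$intensity / max(res$intensity)
  .deconv_spectrum(res$mz, res$intensity, res$quality, "correlation",
                   precursor_mz, ref$apex_rt, channel)
}

#' Average raw MS2 scans around an apex
#'
#' Mean centroid spectrum over the scans of a channel within `apex +/-
#' window`; centroids from different scans are merged within `mz_tol`
#' (intensity-weighted mean m/z, intensity averaged over the number of
#' scans, absent scans counting zero).
#'
#' @param run An `aif_run`.
#' @param channel Collision energy, eV.
#' @param apex Center of the averaging window, minutes.
#' @param window Half-width of the window, minutes (`> 0`).
#' @param mz_tol Merge tolerance, Th.
#' @return An [ms_spectrum].
#' @export
average_raw_ms2 <- function(run, channel, apex, window, mz_tol = 0.01) {
  if (window <= 0) stop("window must be > 0", call. = FALSE)
  grid <- run$cycles[run$cycles$channel == channel &
                       abs(run$cycles$time_min - apex) <= window, ]
  n_scans <- nrow(grid)
  if (n_scans == 0) stop("averaging window contains no scans", call. = FALSE)
  pts <- run$points[run$points$channel == channel &
                      abs(run$points$time_min - apex) <= window, ]
  if (nrow(pts) == 0) {
    return(ms_spectrum(precursor_mz = NA_real_, collision_energy = channel,
                       rt = apex))
  }
  bins <- .bin_mz(pts$mz, mz_tol)
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(bin = bins, mz = pts$mz,
                                   intensity = pts$intensity), .data$bin),
    mz = sum(.data$mz * .data$intensity) / sum(.data$intensity),
    intensity = sum(.data$intensity) / n_scans, .groups = "drop")
  ms_spectrum(agg$mz, agg$intensity, precursor_mz = NA_real_,
              collision_energy = channel, rt = apex)
}

#' Remove low-relative-intensity peaks
#'
#' Keeps exactly the peaks whose intensity is at least `threshold_percent`
#' of the base peak (the boundary is kept; removal applies to peaks
#' strictly below it).
#'
#' @param s An [ms_spectrum].
#' @param threshold_percent Relative-intensity cutoff, percent of base peak.
#' @return The filtered spectrum (empty in, empty out).
#' @examples
#' s <- ms_spectrum(c(50, 60, 70), c(1000, 50, 9))
#' filter_relative_intensity(s)  # drops the 9-unit peak
#' @export
filter_relative_intensity <- function(s, threshold_percent = 1.0) {
  if (nrow(s) == 0) return(s)
  keep <- s$intensity >= threshold_percent / 100 * max(s$intensity)
  out <- rebuild_spectrum(s[keep, c("mz", "intensity", "annotation")], s)
  if ("quality" %in% names(s)) out$quality <- s$quality[keep]
  for (a in c("method")) attr(out, a) <- attr(s, a)
  class(out) <- class(s)
  out
}

#' Plot an extracted ion chromatogram
#'
#' @param object An `eic`.
#' @param peaks Optional [detect_peaks()] output to mark apexes.
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.eic <- function(object, peaks = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$time_min, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "retention time (min)", y = "intensity",
      title = sprintf("EIC m/z %.4f ± %.3g (%g eV)",
                      attr(object, "target_mz"), attr(object, "tol"),
                      attr(object, "channel")))
  if (!is.null(peaks) && nrow(peaks) > 0) {
    p <- p + ggplot2::geom_point(data = peaks,
                                 ggplot2::aes(x = .data$apex_rt, y = .data$height),
                                 colour = "red")
  }
  p
}

#' Mirror plot of two spectra
#'
#' Head-to-tail comparison, each spectrum normalized to base peak 100.
#'
#' @param a,b [ms_spectrum] objects (b drawn downwards).
#' @param labels Character vector of length 2 for the legend.
#' @return A ggplot.
#' @export
plot_mirror <- function(a, b, labels = c("a", "b")) {
  na <- normalize_spectrum(a)
  nb <- normalize_spectrum(b)
  df <- dplyr::bind_rows(
    tibble::tibble(mz = na$mz, intensity = na$intensity, which = labels[1]),
    tibble::tibble(mz = nb$mz, intensity = -nb$intensity, which = labels[2]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mz, ymin = 0,
                                   ymax = .data$intensity,
                                   colour = .data$which)) +
    ggplot2::geom_linerange() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::labs(x = "m/z", y = "relative intensity", colour = NULL)
}
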
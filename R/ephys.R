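#' MEA recording container
#'
#' A multi-electrode recording: an electrodes x samples voltage matrix
#' (arbitrary amplitude calibration), its sampling rate, 0-based electrode
#' ids, an optional condition label and the recording start time.
#'
#' @param data numeric matrix, electrodes in rows, samples in columns.
#' @param fs sampling rate in Hz.
#' @param electrode_ids integer ids, unique, 0-based by convention.
#' @param condition optional condition label.
#' @param t0 recording start time in seconds.
#' @return an object of class `mea_recording`.
#' @export
new_recording <- function(data, fs, electrode_ids = NULL, condition = NULL,
                          t0 = 0) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop_bad_arg("data", "must be a numeric electrodes x samples matrix")
  }
  if (anyNA(data)) stop_bad_arg("data", "contains NA/NaN samples")
  check_finite_scalar(fs, "fs", min = 0, strict_min = TRUE)
  if (is.null(electrode_ids)) electrode_ids <- 0:(nrow(data) - 1L)
  electrode_ids <- as.integer(electrode_ids)
  if (length(electrode_ids) != nrow(data) || anyDuplicated(electrode_ids)) {
    stop_bad_arg("electrode_ids", "must be unique, one per data row")
  }
  structure(list(data = data, fs = fs, electrode_ids = electrode_ids,
                 condition = condition, t0 = t0),
            class = "mea_recording")
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf(
    "MEA recording: %d electrodes x %d samples (%.1f s at %g Hz)%s\n",
    nrow(x$data), ncol(x$data), ncol(x$data) / x$fs, x$fs,
    if (is.null(x$condition)) "" else paste0(", condition ", x$condition)))
  invisible(x)
}

#' Threshold spike detection
#'
#' Detects spikes per electrode as excursions of the absolute voltage beyond
#' `threshold_sd` standard deviations, the SD being estimated on the full
#' trace of that electrode. Candidate crossings falling within one
#' `window_ms` rolling window of an already accepted event are merged into
#' it, so detected events are at least one window apart; the event time is
#' the first threshold crossing.
#'
#' @param rec an [new_recording()] object.
#' @param window_ms merge/refractory window in ms.
#' @param threshold_sd detection threshold in SD units.
#' @return an object of class `spike_train`: per-electrode spike times (s,
#'   relative to `t0`), the detection parameters and per-electrode SD
#'   estimates.
#' @export
#' @examples
#' v <- matrix(rnorm(20000), nrow = 1)
#' v[1, 5000] <- 50 # inject one large event
#' detect_spikes(new_recording(v, fs = 2000))
detect_spikes <- function(rec, window_ms = 10, threshold_sd = 5.5) {
  stopifnot(inherits(rec, "mea_recording"))
  check_finite_scalar(window_ms, "window_ms", min = 0, strict_min = TRUE)
  check_finite_scalar(threshold_sd, "threshold_sd", min = 0, strict_min = TRUE)
  win <- window_ms / 1000 * rec$fs
  if (ncol(rec$data) < win) {
    stop_bad_arg("rec", "recording is shorter than one detection window")
  }
  sds <- apply(rec$data, 1, sd)
  times <- vector("list", nrow(rec$data))
  for (e in seq_len(nrow(rec$data))) {
    if (sds[e] == 0) {
      warning(sprintf(
        "electrode %d has zero variance; no spikes detectable",
        rec$electrode_ids[e]), call. = FALSE)
      times[[e]] <- numeric(0)
      next
    }
    cand <- which(abs(rec$data[e, ]) > threshold_sd * sds[e])
    if (!length(cand)) {
      times[[e]] <- numeric(0)
      next
    }
    accepted <- cand[1]
    last <- cand[1]
    for (i in cand[-1]) {
      if (i - last > win) {
        accepted <- c(accepted, i)
        last <- i
      }
    }
    times[[e]] <- (accepted - 1L) / rec$fs
  }
  names(times) <- as.character(rec$electrode_ids)
  structure(list(times = times, electrode_ids = rec$electrode_ids,
                 sd_estimate = stats::setNames(sds,
                                               as.character(rec$electrode_ids)),
                 window_ms = window_ms, threshold_sd = threshold_sd,
                 fs = rec$fs, duration_s = ncol(rec$data) / rec$fs),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  n <- vapply(x$times, length, 0L)
  cat(sprintf(
    "Spike train: %d electrodes, %d spikes total (%.1f s, %.1f SD, %g ms window)\n",
    length(n), sum(n), x$duration_s, x$threshold_sd, x$window_ms))
  invisible(x)
}

#' Per-electrode spike counts
#'
#' @param train a [detect_spikes()] result.
#' @return a list with `per_electrode` (named counts), `total`, and the
#'   across-electrode `mean` and `sd` of the counts.
#' @export
spike_counts <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  n <- vapply(train$times, length, 0L)
  list(per_electrode = n, total = sum(n), mean = mean(n), sd = sd(n))
}

#' Fragment-wise power spectral densities
#'
#' Splits each electrode trace into consecutive non-overlapping fragments
#' (10 s by default, discarding an incomplete tail), removes each fragment's
#' mean, and computes a one-sided rectangular-window periodogram normalized
#' as a density (power per Hz, `2 |X_k|^2 / (fs N)`, factor 1 at Nyquist), so
#' that the density integrates to the fragment variance. A 10-s fragment has
#' a native resolution of exactly 0.1 Hz, so the requested 0.2-300 Hz by
#' 0.1 Hz grid maps one-to-one onto periodogram bins.
#'
#' @param rec an [new_recording()] object.
#' @param fragment_s fragment length in seconds.
#' @param fmin,fmax frequency range in Hz (inclusive); `fmax <= fs/2`.
#' @param df frequency step in Hz; must equal the native `1/fragment_s`
#'   resolution.
#' @param electrodes optional electrode ids to restrict to.
#' @return an object of class `power_spectrogram`: per-electrode
#'   fragments x frequency-bins matrices, the frequency grid, fragment start
#'   times and the condition label.
#' @export
#' @examples
#' rec <- new_recording(matrix(sin(2 * pi * 10 * (0:24999) / 2500),
#'                             nrow = 1), fs = 2500)
#' ps <- compute_power_density(rec)
#' ps$freqs[which.max(ps$power[[1]][1, ])] # 10 Hz
compute_power_density <- function(rec, fragment_s = 10, fmin = 0.2,
                                  fmax = 300, df = 0.1, electrodes = NULL) {
  stopifnot(inherits(rec, "mea_recording"))
  check_finite_scalar(fragment_s, "fragment_s", min = 0, strict_min = TRUE)
  n_fs <- rec$fs * fragment_s
  if (abs(n_fs - round(n_fs)) > 1e-9) {
    stop_bad_arg("fragment_s", "fs * fragment_s must be an integer")
  }
  n_fs <- as.integer(round(n_fs))
  if (fmax > rec$fs / 2) stop_bad_arg("fmax", "exceeds the Nyquist frequency")
  if (abs(df - 1 / fragment_s) > 1e-9) {
    stop_bad_arg("df", "must equal the native resolution 1/fragment_s")
  }
  n_frag <- ncol(rec$data) %/% n_fs
  if (n_frag < 1) {
    stop_bad_arg("rec", "recording is shorter than one fragment")
  }
  if (is.null(electrodes)) electrodes <- rec$electrode_ids
  rows <- match(electrodes, rec$electrode_ids)
  if (anyNA(rows)) stop_bad_arg("electrodes", "unknown electrode id")
  k <- seq.int(round(fmin / df), round(fmax / df))
  if (min(k) < 1) stop_bad_arg("fmin", "must be at least one bin above DC")
  freqs <- k * df
  half <- n_fs %/% 2L
  scale <- ifelse(k == half, 1, 2) / (rec$fs * n_fs)
  power <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    mat <- matrix(NA_real_, nrow = n_frag, ncol = length(k))
    for (j in seq_len(n_frag)) {
      v <- rec$data[rows[i], ((j - 1L) * n_fs + 1L):(j * n_fs)]
      X <- fft(v - mean(v))
      mat[j, ] <- scale * Mod(X[k + 1L])^2
    }
    power[[i]] <- mat
  }
  names(power) <- as.character(electrodes)
  structure(list(power = power, freqs = freqs,
                 fragment_starts = rec$t0 + (seq_len(n_frag) - 1L) * fragment_s,
                 electrode_ids = as.integer(electrodes),
                 fs = rec$fs, fragment_s = fragment_s,
                 condition = rec$condition),
            class = "power_spectrogram")
}

#' @export
print.power_spectrogram <- function(x, ...) {
  cat(sprintf(
    "Power spectrogram: %d electrodes, %d fragments of %g s, %.1f-%.1f Hz by %.1f Hz%s\n",
    length(x$power), length(x$fragment_starts), x$fragment_s, min(x$freqs),
    max(x$freqs), x$freqs[2] - x$freqs[1],
    if (is.null(x$condition)) "" else paste0(", condition ", x$condition)))
  invisible(x)
}

#' Canonical EEG-style frequency bands
#'
#' Delta (0.5-4), theta (4-8), alpha (8-13), beta (13-30), gamma (30-80) and
#' high-frequency oscillations (HFO, 80-600 Hz). Band membership is half-open
#' `[lo, hi)`.
#'
#' @return a data frame with columns `band`, `lo`, `hi`.
#' @export
default_bands <- function() {
  data.frame(band = c("delta", "theta", "alpha", "beta", "gamma", "HFO"),
             lo = c(0.5, 4, 8, 13, 30, 80),
             hi = c(4, 8, 13, 30, 80, 600))
}

#' Mean band power per fragment
#'
#' Averages the power density over frequency bands, per fragment and
#' electrode. The HFO band extends to 600 Hz, beyond the 300 Hz spectrogram
#' cap, so when a band exceeds the grid of a precomputed spectrogram the
#' function must be given the raw recording and computes a second spectral
#' pass internally up to the highest band edge.
#'
#' @param x a `power_spectrogram` or an `mea_recording`.
#' @param bands a data frame with columns `band`, `lo`, `hi` (Hz);
#'   membership is `[lo, hi)`.
#' @param ... passed on to [compute_power_density()] for the recording
#'   method.
#' @return an object of class `band_summary`: per-electrode
#'   fragments x bands matrices of mean power density, plus the band table.
#' @export
band_power <- function(x, bands = default_bands(), ...) {
  UseMethod("band_power")
}

#' @export
band_power.power_spectrogram <- function(x, bands = default_bands(), ...) {
  stopifnot(is.data.frame(bands), all(c("band", "lo", "hi") %in% names(bands)))
  if (max(bands$hi) > x$fs / 2) {
    stop_bad_arg("bands", "band edge exceeds the Nyquist frequency")
  }
  if (max(bands$lo) >= max(x$freqs) + (x$freqs[2] - x$freqs[1])) {
    stop_bad_arg("bands", "band lies beyond the spectrogram frequency grid")
  }
  out <- lapply(x$power, function(mat) {
    bp <- sapply(seq_len(nrow(bands)), function(b) {
      sel <- x$freqs >= bands$lo[b] & x$freqs < bands$hi[b]
      if (!any(sel)) return(rep(NA_real_, nrow(mat)))
      rowMeans(mat[, sel, drop = FALSE])
    })
    bp <- matrix(bp, nrow = nrow(mat))
    colnames(bp) <- bands$band
    bp
  })
  structure(list(power = out, bands = bands,
                 electrode_ids = x$electrode_ids,
                 fragment_starts = x$fragment_starts,
                 condition = x$condition),
            class = "band_summary")
}

#' @export
band_power.mea_recording <- function(x, bands = default_bands(), ...) {
  if (max(bands$hi) > x$fs / 2) {
    stop_bad_arg("bands", "band edge exceeds the Nyquist frequency")
  }
  ps <- compute_power_density(x, fmax = min(max(bands$hi), x$fs / 2), ...)
  band_power(ps, bands = bands)
}

#' @export
print.band_summary <- function(x, ...) {
  cat(sprintf("Band summary: %d electrodes, %d fragments, bands %s\n",
              length(x$power), length(x$fragment_starts),
              paste(x$bands$band, collapse = ", ")))
  invisible(x)
}

#' Select the most active electrodes
#'
#' Activity is measured as the full-trace standard deviation per electrode;
#' the `n` highest-SD electrodes are returned in descending order of SD, ties
#' broken by the lower electrode id. Given a list of recordings sharing an
#' electrode layout, per-electrode SDs are averaged across recordings first.
#'
#' @param rec an `mea_recording` or a list of them.
#' @param n number of electrodes to select.
#' @return an integer vector of electrode ids.
#' @export
select_active_electrodes <- function(rec, n = 20) {
  if (inherits(rec, "mea_recording")) rec <- list(rec)
  stopifnot(length(rec) >= 1L,
            all(vapply(rec, inherits, TRUE, "mea_recording")))
  ids <- rec[[1]]$electrode_ids
  for (r in rec) {
    if (!identical(r$electrode_ids, ids)) {
      stop_bad_arg("rec", "recordings have differing electrode layouts")
    }
  }
  if (n > length(ids)) stop_bad_arg("n", "exceeds the number of electrodes")
  sds <- rowMeans(vapply(rec, function(r) apply(r$data, 1, sd),
                         numeric(length(ids))))
  ids[order(-sds, ids)][seq_len(n)]
}
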
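#' Condition signal profile
#'
#' Describes the LFP signature of an experimental condition as generated by
#' [generate_recording()]: mean spontaneous firing rate of the active
#' electrodes, spike peak amplitude in units of the background SD, and
#' multiplicative gains applied to the background power in chosen frequency
#' bands. Composite conditions carry mixture weights over base profiles
#' instead of a signature of their own.
#'
#' Built-in presets model the directions reported for brain-derived
#' extracellular vesicle (BDEV) experiments on organotypic cultures:
#' \describe{
#'   \item{CTL}{mock treatment: 2 Hz firing, flat band gains.}
#'   \item{GW}{exosome-secretion inhibitor: as CTL with a 1.3x amplitude gain
#'     on the beta band (13-30 Hz), a distinguishable mid-band signature.}
#'   \item{EV}{vesicle supplementation: firing rate halved (1 Hz) and high
#'     frequency oscillation (HFO, 80-600 Hz) amplitude gain 0.6, i.e.
#'     dampened firing and reduced HFO power.}
#'   \item{GW_EV}{co-treatment, a fragment-level mixture of the three base
#'     signatures with weights (CTL 0.32, GW 0.57, EV 0.11).}
#' }
#' Effect magnitudes are not measured quantities; they are fixed package
#' defaults chosen to make a three-class problem learnable but not
#' degenerate, and every field can be overridden.
#'
#' @param name condition name; one of `"CTL"`, `"GW"`, `"EV"`, `"GW_EV"`.
#' @param firing_rate_hz mean spike rate per active electrode (Hz).
#' @param spike_amplitude_sd spike peak in units of the background SD; must
#'   exceed the 5.5 SD detection threshold for a detectable class.
#' @param band_gains data frame with columns `lo`, `hi`, `gain`: amplitude
#'   multiplier applied to background components with frequency in
#'   `[lo, hi)` Hz (power scales as `gain^2`).
#' @param mixture_weights named numeric vector of proportions over base
#'   profile names (composite conditions only); must sum to 1.
#' @return an object of class `condition_profile`.
#' @export
#' @examples
#' condition_profile("EV")
#' condition_profile("CTL", firing_rate_hz = 4)
condition_profile <- function(name = c("CTL", "GW", "EV", "GW_EV"),
                              firing_rate_hz = NULL,
                              spike_amplitude_sd = NULL,
                              band_gains = NULL,
                              mixture_weights = NULL) {
  name <- match.arg(name)
  defaults <- switch(name,
    CTL = list(firing_rate_hz = 2, spike_amplitude_sd = 8,
               band_gains = empty_band_gains(), mixture_weights = NULL),
    GW = list(firing_rate_hz = 2, spike_amplitude_sd = 8,
              band_gains = data.frame(lo = 13, hi = 30, gain = 1.3),
              mixture_weights = NULL),
    EV = list(firing_rate_hz = 1, spike_amplitude_sd = 8,
              band_gains = data.frame(lo = 80, hi = 600, gain = 0.6),
              mixture_weights = NULL),
    GW_EV = list(firing_rate_hz = NA_real_, spike_amplitude_sd = NA_real_,
                 band_gains = empty_band_gains(),
                 mixture_weights = c(CTL = 0.32, GW = 0.57, EV = 0.11)))
  p <- defaults
  if (!is.null(firing_rate_hz)) p$firing_rate_hz <- firing_rate_hz
  if (!is.null(spike_amplitude_sd)) p$spike_amplitude_sd <- spike_amplitude_sd
  if (!is.null(band_gains)) p$band_gains <- band_gains
  if (!is.null(mixture_weights)) p$mixture_weights <- mixture_weights
  if (is.null(p$mixture_weights)) {
    check_finite_scalar(p$firing_rate_hz, "firing_rate_hz", min = 0)
    check_finite_scalar(p$spike_amplitude_sd, "spike_amplitude_sd", min = 0)
    stopifnot(is.data.frame(p$band_gains),
              all(c("lo", "hi", "gain") %in% names(p$band_gains)))
    if (any(p$band_gains$hi <= p$band_gains$lo) || any(p$band_gains$gain < 0)) {
      stop_bad_arg("band_gains", "bands need hi > lo and gain >= 0")
    }
  } else {
    if (abs(sum(p$mixture_weights) - 1) > 1e-8) {
      stop_bad_arg("mixture_weights", "must sum to 1")
    }
  }
  structure(c(list(name = name), p), class = "condition_profile")
}

empty_band_gains <- function() {
  data.frame(lo = numeric(0), hi = numeric(0), gain = numeric(0))
}

#' Synthetic recording specification
#'
#' Geometry and background statistics of a synthetic MEA session: electrode
#' count, sampling rate, duration (a whole number of 10-s analysis
#' fragments), how many electrodes carry spiking activity, the background
#' noise SD and its 1/f spectral slope, and the seed. Defaults mirror a
#' 60-electrode array sampled at 10 kHz for 2 min.
#'
#' @param n_electrodes number of electrodes.
#' @param fs sampling rate in Hz; must exceed 1200 Hz so the 80-600 Hz HFO
#'   band is below Nyquist.
#' @param duration_s duration in seconds; a multiple of the 10-s fragment.
#' @param n_active number of electrodes carrying spikes.
#' @param noise_sd background SD (arbitrary amplitude units).
#' @param one_over_f_exponent spectral slope of the 1/f background component.
#' @param seed integer seed; the generator is bit-reproducible given the seed.
#' @return an object of class `recording_spec`.
#' @export
recording_spec <- function(n_electrodes = 60, fs = 10000, duration_s = 120,
                           n_active = 30, noise_sd = 10,
                           one_over_f_exponent = 1, seed = 1L) {
  check_finite_scalar(n_electrodes, "n_electrodes", min = 1)
  check_finite_scalar(fs, "fs", min = 0, strict_min = TRUE)
  if (fs <= 1200) {
    stop_bad_arg("fs", "must exceed 1200 Hz (twice the 600 Hz HFO edge)")
  }
  check_finite_scalar(duration_s, "duration_s", min = 0, strict_min = TRUE)
  if (abs(duration_s %% 10) > 1e-9) {
    stop_bad_arg("duration_s", "must be a multiple of the 10 s fragment")
  }
  if ((fs * 10) %% 1 != 0) {
    stop_bad_arg("fs", "a 10 s fragment must hold an integer sample count")
  }
  check_finite_scalar(n_active, "n_active", min = 0)
  if (n_active > n_electrodes) {
    stop_bad_arg("n_active", "cannot exceed n_electrodes")
  }
  check_finite_scalar(noise_sd, "noise_sd", min = 0, strict_min = TRUE)
  check_finite_scalar(one_over_f_exponent, "one_over_f_exponent", min = 0)
  structure(list(n_electrodes = as.integer(n_electrodes), fs = fs,
                 duration_s = duration_s, n_active = as.integer(n_active),
                 noise_sd = noise_sd,
                 one_over_f_exponent = one_over_f_exponent,
                 seed = as.integer(seed)),
            class = "recording_spec")
}

# One 10-s fragment of band-shaped 1/f + white background for one electrode.
# The amplitude scale is calibrated analytically so the unshaped (all gains 1)
# background has SD = noise_sd; band gains then multiply band power by gain^2
# exactly, in expectation.
fragment_noise <- function(n, fs, noise_sd, alpha, band_gains) {
  m <- n %/% 2L - 1L
  f <- (1:m) * fs / n
  shape <- 1 + 1 / pmax(f, 0.2)^alpha # white floor + 1/f^alpha
  scale2 <- noise_sd^2 * n^2 / (4 * sum(shape))
  g <- rep(1, m)
  if (nrow(band_gains)) {
    for (i in seq_len(nrow(band_gains))) {
      sel <- f >= band_gains$lo[i] & f < band_gains$hi[i]
      g[sel] <- g[sel] * band_gains$gain[i]
    }
  }
  amp <- sqrt(shape * scale2) * g
  xk <- complex(real = rnorm(m), imaginary = rnorm(m)) * amp
  spec <- c(0, xk, 0, Conj(rev(xk)))
  Re(fft(spec, inverse = TRUE)) / n
}

# Biphasic extracellular spike template (~1.5 ms): sharp negative peak then a
# smaller positive rebound; peak |amplitude| normalized to 1.
spike_template <- function(fs) {
  t_ms <- (0:ceiling(1.5e-3 * fs)) / fs * 1000
  w <- -exp(-0.5 * ((t_ms - 0.4) / 0.15)^2) +
    0.35 * exp(-0.5 * ((t_ms - 1.0) / 0.25)^2)
  w / max(abs(w))
}

# Shared engine: every fragment draws its profile from `profiles` with
# `weights`; spikes are Poisson-placed on the active electrodes.
generate_engine <- function(spec, profiles, weights) {
  stopifnot(inherits(spec, "recording_spec"))
  lapply(profiles, function(p) stopifnot(inherits(p, "condition_profile")))
  nm <- vapply(profiles, `[[`, "", "name")
  names(profiles) <- nm
  n_frag <- as.integer(spec$duration_s / 10)
  n_fs <- as.integer(spec$fs * 10)
  tmpl <- spike_template(spec$fs)
  with_seed(spec$seed, {
    active <- sort(sample.int(spec$n_electrodes, spec$n_active))
    frag_idx <- sample.int(length(profiles), n_frag, replace = TRUE,
                           prob = weights)
    data <- matrix(0, nrow = spec$n_electrodes, ncol = n_frag * n_fs)
    spikes <- vector("list", spec$n_electrodes)
    for (e in seq_len(spec$n_electrodes)) spikes[[e]] <- numeric(0)
    for (j in seq_len(n_frag)) {
      p <- profiles[[frag_idx[j]]]
      cols <- ((j - 1L) * n_fs + 1L):(j * n_fs)
      for (e in seq_len(spec$n_electrodes)) {
        v <- fragment_noise(n_fs, spec$fs, spec$noise_sd,
                            spec$one_over_f_exponent, p$band_gains)
        if (e %in% active && p$firing_rate_hz > 0) {
          n_spk <- rpois(1, p$firing_rate_hz * 10)
          if (n_spk > 0) {
            pos <- sort(sample.int(n_fs - length(tmpl), n_spk, replace = TRUE))
            for (s in pos) {
              seg <- s:(s + length(tmpl) - 1L)
              v[seg] <- v[seg] +
                tmpl * p$spike_amplitude_sd * spec$noise_sd
            }
            spikes[[e]] <- c(spikes[[e]], (j - 1) * 10 + (pos - 1L) / spec$fs)
          }
        }
        data[e, cols] <- v
      }
    }
    rec <- new_recording(data, fs = spec$fs,
                         electrode_ids = 0:(spec$n_electrodes - 1L),
                         condition = if (length(profiles) == 1L) nm else
                           paste(nm, collapse = "+"))
    attr(rec, "fragment_labels") <- nm[frag_idx]
    attr(rec, "active_electrodes") <- rec$electrode_ids[active]
    attr(rec, "spike_times") <- spikes
    attr(rec, "seed") <- spec$seed
    rec
  })
}

#' Generate a synthetic MEA recording
#'
#' Produces one multi-electrode recording under a condition profile: each
#' electrode carries 1/f-plus-white background noise with the profile's band
#' gains applied in the frequency domain, and the active electrodes
#' additionally carry Poisson-placed biphasic spike templates. The background
#' of each 10-s fragment is synthesized independently, matching the
#' fragment-wise downstream analysis. Ground truth (spike times, active
#' electrode ids, per-fragment labels) is attached as attributes for
#' recovery tests.
#'
#' @param spec a [recording_spec()].
#' @param profile a [condition_profile()] (not a mixture profile).
#' @return an object of class `mea_recording` (see [new_recording()]) with
#'   attributes `spike_times`, `active_electrodes`, `fragment_labels`.
#' @export
#' @examples
#' spec <- recording_spec(n_electrodes = 4, fs = 2500, duration_s = 20,
#'                        n_active = 2, seed = 7)
#' rec <- generate_recording(spec, condition_profile("CTL"))
#' dim(rec$data)
generate_recording <- function(spec, profile) {
  stopifnot(inherits(profile, "condition_profile"))
  if (!is.null(profile$mixture_weights)) {
    stop("`profile` is a mixture profile; use generate_mixture_recording()",
         call. = FALSE)
  }
  generate_engine(spec, list(profile), weights = 1)
}

#' Generate a fragment-level mixture recording
#'
#' Models a composite condition whose 10-s fragments each express one of
#' several base signatures: every fragment independently draws a base profile
#' with the given probabilities. Fragment-level ground-truth labels are
#' retained in the `fragment_labels` attribute so that classifier
#' repartition can be checked against the generating weights.
#'
#' @param spec a [recording_spec()].
#' @param base_profiles list of base [condition_profile()]s.
#' @param weights numeric mixing proportions, summing to 1. Defaults to the
#'   `mixture_weights` of the `GW_EV` preset when `base_profiles` has names
#'   matching it.
#' @return an `mea_recording`; `attr(, "fragment_labels")` gives each
#'   fragment's true base condition.
#' @export
generate_mixture_recording <- function(spec, base_profiles, weights) {
  if (length(base_profiles) == 0L) {
    stop_bad_arg("base_profiles", "must contain at least one profile")
  }
  if (length(weights) != length(base_profiles)) {
    stop_bad_arg("weights", "must match the number of base profiles")
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    stop_bad_arg("weights", "must be non-negative and sum to 1")
  }
  generate_engine(spec, base_profiles, weights)
}

#' Generate a synthetic protein abundance table
#'
#' Emulates a label-free proteomics quantitation matrix: log-normal protein
#' abundances, a per-sample multiplicative loading factor (unequal sample
#' loading is what the rank-based comparison is designed to survive), an
#' enriched protein subset shifted by a fold-change in one condition, and
#' intensity-dependent missingness (each sample's lowest abundances are
#' censored below the sample's `missing_rate` detection quantile).
#'
#' @param n_proteins number of proteins.
#' @param n_samples_per_condition samples per condition.
#' @param conditions character vector of condition names.
#' @param loading_factors positive per-sample loading multipliers, length
#'   `n_samples_per_condition * length(conditions)` (default all 1).
#' @param missing_rate fraction of each sample censored to missing, in
#'   `[0, 1)`.
#' @param enriched_set integer or character indices of enriched proteins.
#' @param effect multiplicative fold-change applied to the enriched set in
#'   `enriched_condition` (1 = null).
#' @param enriched_condition condition receiving the enrichment.
#' @param seed integer seed.
#' @return an [abundance_table()] with attributes `enriched_ids` and
#'   `loading_factors` (ground truth).
#' @export
#' @examples
#' tab <- generate_protein_table(n_proteins = 50, n_samples_per_condition = 3,
#'                               conditions = c("Stag", "uFlow"), seed = 1)
#' dim(tab$abundance)
generate_protein_table <- function(n_proteins = 2000,
                                   n_samples_per_condition = 5,
                                   conditions = c("Stag", "uFlow"),
                                   loading_factors = NULL,
                                   missing_rate = 0,
                                   enriched_set = integer(0),
                                   effect = 1,
                                   enriched_condition = conditions[length(conditions)],
                                   seed = 1L) {
  check_finite_scalar(n_proteins, "n_proteins", min = 1)
  check_finite_scalar(n_samples_per_condition, "n_samples_per_condition",
                      min = 1)
  if (!is.numeric(missing_rate) || missing_rate < 0 || missing_rate >= 1) {
    stop_bad_arg("missing_rate", "must lie in [0, 1)")
  }
  check_finite_scalar(effect, "effect", min = 0, strict_min = TRUE)
  n_samples <- n_samples_per_condition * length(conditions)
  if (is.null(loading_factors)) loading_factors <- rep(1, n_samples)
  if (length(loading_factors) != n_samples || any(loading_factors <= 0)) {
    stop_bad_arg("loading_factors",
                 "must be positive, one per sample")
  }
  ids <- sprintf("P%04d", seq_len(n_proteins))
  if (is.character(enriched_set)) {
    if (!all(enriched_set %in% ids)) {
      stop_bad_arg("enriched_set", "contains unknown protein ids")
    }
    enriched_idx <- match(enriched_set, ids)
  } else {
    enriched_idx <- as.integer(enriched_set)
    if (length(enriched_idx) && (min(enriched_idx) < 1 ||
                                 max(enriched_idx) > n_proteins)) {
      stop_bad_arg("enriched_set", "indices out of range")
    }
  }
  if (!enriched_condition %in% conditions) {
    stop_bad_arg("enriched_condition", "not one of `conditions`")
  }
  cond <- factor(rep(conditions, each = n_samples_per_condition),
                 levels = conditions)
  sample_ids <- paste0(rep(conditions, each = n_samples_per_condition), "_",
                       rep(seq_len(n_samples_per_condition),
                           times = length(conditions)))
  with_seed(seed, {
    base <- rnorm(n_proteins, mean = 20, sd = 2) # log2 baseline abundance
    logx <- matrix(base, nrow = n_proteins, ncol = n_samples) +
      matrix(rnorm(n_proteins * n_samples, sd = 0.7), n_proteins, n_samples)
    logx <- sweep(logx, 2, log2(loading_factors), `+`)
    if (length(enriched_idx) && effect != 1) {
      shift_cols <- which(cond == enriched_condition)
      logx[enriched_idx, shift_cols] <-
        logx[enriched_idx, shift_cols] + log2(effect)
    }
    x <- 2^logx
    if (missing_rate > 0) {
      for (s in seq_len(n_samples)) {
        thr <- quantile(x[, s], probs = missing_rate, names = FALSE)
        x[x[, s] < thr, s] <- NA_real_
      }
    }
    dimnames(x) <- list(ids, sample_ids)
    tab <- abundance_table(x, conditions = stats::setNames(cond, sample_ids))
    attr(tab, "enriched_ids") <- ids[enriched_idx]
    attr(tab, "loading_factors") <- stats::setNames(loading_factors, sample_ids)
    attr(tab, "seed") <- seed
    tab
  })
}
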
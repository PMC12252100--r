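# Seeded synthetic single-lead ECG: five morphologically distinct AAMI
# classes, each beat a sum of five Gaussian deflections (P, Q, R, S, T) plus
# baseline-wander, power-line and white noise. Not a physiological simulator;
# a controllable benchmark whose class separability is a single dial.

# MIT-BIH beat symbol inventory per AAMI class (15 source codes total)
AAMI_SYMBOLS <- list(
  N = c("N", "L", "R"),
  S = c("A", "a", "J", "S", "e", "j"),
  V = c("V", "E"),
  F = c("F"),
  Q = c("/", "Q", "f")
)

# Reference morphology, positions as fractions of the window, widths and
# amplitudes in samples (at 300) and mV. R sits at the window centre.
BASE_WAVES <- rbind(
  P = c(amp = 0.15,  centre = 0.320, width = 10 / 300),
  Q = c(amp = -0.10, centre = 0.467, width = 4 / 300),
  R = c(amp = 1.00,  centre = 0.500, width = 6 / 300),
  S = c(amp = -0.15, centre = 0.533, width = 5 / 300),
  T = c(amp = 0.30,  centre = 0.717, width = 22 / 300)
)

# Per-class morphology at full separability, expressed as the target wave
# table; templates interpolate linearly from the N morphology for
# separability in [0, 1] and saturate above 1.
class_target_waves <- function(class) {
  w <- BASE_WAVES
  switch(class,
    N = w,
    S = { # early, narrow, inverted P (ectopic atrial focus)
      w["P", "amp"] <- -0.12
      w["P", "centre"] <- w["P", "centre"] - 20 / 300
      w["P", "width"] <- w["P", "width"] * 0.6
      w
    },
    V = { # wide QRS, absent P, inverted T
      w["R", "width"] <- w["R", "width"] * 3
      w["R", "amp"] <- 0.85
      w["P", "amp"] <- 0.015
      w["T", "amp"] <- -0.35
      w
    },
    F = (class_target_waves("N") + class_target_waves("V")) / 2,
    Q = { # pacing spike before a widened QRS, flat P
      w["P", "amp"] <- 0
      w["Q", "amp"] <- 0.85
      w["Q", "width"] <- 2 / 300
      w["R", "width"] <- w["R", "width"] * 2
      w["T", "amp"] <- 0.15
      w
    },
    stopf("unknown AAMI class '%s'", class)
  )
}

#' Beat morphology template
#'
#' Describes one AAMI class as five Gaussian deflections (P, Q, R, S, T) with
#' amplitudes in mV, centres and widths in samples, plus the RR-interval
#' distribution used when beats are laid out into a record. Class differences
#' are offsets from the normal (N) morphology scaled by `separability`
#' (linear up to 1, saturating above), so `separability = 0` collapses all
#' classes onto one template and large values give well-separated classes.
#'
#' @param aami_class one of `"N"`, `"S"`, `"V"`, `"F"`, `"Q"`.
#' @param segment_len beat window length in samples.
#' @param fs sampling frequency, Hz.
#' @param separability unitless scale (>= 0) of between-class morphological
#'   difference.
#' @return an object of class `beat_template`.
#' @export
beat_template <- function(aami_class, segment_len = 300, fs = 360,
                          separability = 1) {
  aami_class <- match.arg(aami_class, AAMI_CLASSES)
  if (separability < 0) stopf("separability must be >= 0")
  g <- min(separability, 1)
  waves <- BASE_WAVES + g * (class_target_waves(aami_class) - BASE_WAVES)
  # to samples
  wp <- cbind(
    amp = waves[, "amp"],
    centre = round(waves[, "centre"] * segment_len),
    width = pmax(1, waves[, "width"] * segment_len)
  )
  rr_mean <- round(1.2 * segment_len)
  if (aami_class == "S") rr_mean <- round(rr_mean * (1 - 0.2 * g)) # shortened preceding RR
  tpl <- structure(
    list(aami_class = aami_class, wave_params = wp,
         rr_mean = rr_mean, rr_jitter_sd = round(0.05 * rr_mean),
         segment_len = segment_len, fs = fs),
    class = "beat_template"
  )
  validate_template(tpl)
  tpl
}

validate_template <- function(tpl) {
  wp <- tpl$wave_params
  if (any(diff(wp[, "centre"]) <= 0)) {
    stopf("wave centres must be strictly increasing P < Q < R < S < T")
  }
  if (any(wp[, "width"] <= 0)) stopf("wave widths must be > 0")
  if (wp["R", "amp"] <= 0) stopf("R amplitude must be > 0")
  invisible(tpl)
}

#' Default templates for all five AAMI classes
#' @inheritParams beat_template
#' @return named list of `beat_template`s.
#' @export
default_templates <- function(segment_len = 300, fs = 360, separability = 1) {
  stats::setNames(
    lapply(AAMI_CLASSES, beat_template, segment_len = segment_len, fs = fs,
           separability = separability),
    AAMI_CLASSES
  )
}

#' Additive noise specification
#'
#' Baseline wander and power-line interference are sinusoids with random
#' phase; white noise is Gaussian. Amplitudes in mV.
#'
#' @param baseline_amp,baseline_freq baseline-wander amplitude (mV) and
#'   frequency (Hz).
#' @param powerline_amp,powerline_freq power-line amplitude (mV) and mains
#'   frequency, 50 or 60 Hz.
#' @param white_sd white-noise standard deviation (mV).
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(baseline_amp = 0.05, baseline_freq = 0.3,
                       powerline_amp = 0.02, powerline_freq = 50,
                       white_sd = 0.02) {
  if (baseline_amp < 0 || powerline_amp < 0 || white_sd < 0) {
    stopf("noise amplitudes must be >= 0")
  }
  if (!powerline_freq %in% c(50, 60)) stopf("powerline_freq must be 50 or 60 Hz")
  structure(list(baseline_amp = baseline_amp, baseline_freq = baseline_freq,
                 powerline_amp = powerline_amp, powerline_freq = powerline_freq,
                 white_sd = white_sd),
            class = "noise_spec")
}

# clean Gaussian-sum waveform of one template on sample grid 0..L-1
template_waveform <- function(tpl, segment_len = tpl$segment_len,
                              r_shift = 0, amp_scale = 1) {
  wp <- tpl$wave_params
  t <- seq.int(0, segment_len - 1)
  y <- numeric(segment_len)
  for (w in rownames(wp)) {
    centre <- wp[w, "centre"] + r_shift
    if (centre < 0 || centre > segment_len - 1) {
      stopf("wave %s centre (%g) lies outside the %d-sample window",
            w, centre, segment_len)
    }
    y <- y + amp_scale * wp[w, "amp"] * exp(-0.5 * ((t - centre) / wp[w, "width"])^2)
  }
  y
}

# additive noise realisation for n samples starting at absolute sample t0
noise_realisation <- function(noise, n, fs, t0 = 0) {
  t <- (seq.int(t0, t0 + n - 1)) / fs
  ph <- stats::runif(2, 0, 2 * pi)
  noise$baseline_amp * sin(2 * pi * noise$baseline_freq * t + ph[1]) +
    noise$powerline_amp * sin(2 * pi * noise$powerline_freq * t + ph[2]) +
    stats::rnorm(n, 0, noise$white_sd)
}

#' Generate one synthetic beat
#'
#' Sum of the template's five Gaussian deflections plus a baseline-wander
#' sinusoid, a power-line sinusoid (both with seeded random phase) and white
#' noise. Identical `(template, noise, seed)` gives a bit-identical vector.
#'
#' @param template a [beat_template()].
#' @param noise a [noise_spec()].
#' @param seed integer seed.
#' @param components if `TRUE`, return `list(beat, clean)` instead of the
#'   noisy vector alone.
#' @return numeric vector of `segment_len` samples (mV), or a list when
#'   `components = TRUE`.
#' @export
synth_beat <- function(template, noise = noise_spec(), seed = 1,
                       components = FALSE) {
  clean <- template_waveform(template)
  nz <- with_seed(seed, noise_realisation(noise, template$segment_len, template$fs))
  beat <- clean + nz
  if (components) list(beat = beat, clean = clean) else beat
}

#' Synthetic dataset specification
#'
#' @param counts named integer vector, beats per AAMI class. The default
#'   follows the training-set proportions of the MIT-BIH intra-patient split
#'   (54,171 / 1,807 / 4,348 / 483 / 4,858) scaled to roughly 3,000 beats.
#' @param fs sampling frequency, Hz.
#' @param segment_len beat window length, samples.
#' @param separability unitless between-class morphology scale.
#' @param noise a [noise_spec()].
#' @param seed integer seed.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(counts = round(3000 * c(N = 54171, S = 1807, V = 4348,
                                               F = 483, Q = 4858) / 65667),
                       fs = 360, segment_len = 300, separability = 1,
                       noise = noise_spec(), seed = 1) {
  if (is.null(names(counts))) stopf("counts must be named by AAMI class")
  counts <- counts[AAMI_CLASSES]
  names(counts) <- AAMI_CLASSES
  counts[is.na(counts)] <- 0L
  if (any(counts < 0)) stopf("class counts must be >= 0")
  if (fs <= 0) stopf("fs must be > 0")
  if (separability < 0) stopf("separability must be >= 0")
  structure(list(counts = as.integer(counts), fs = fs,
                 segment_len = as.integer(segment_len),
                 separability = separability, noise = noise,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate an annotated synthetic ECG record
#'
#' Lays beats out along a record with RR intervals drawn per beat from a
#' truncated normal (+/- 3 sd, so R indices stay sorted), sums the Gaussian
#' deflections onto a common signal, adds record-level noise, and returns the
#' signal with beat annotations whose `r_index` is exactly each beat's
#' R-deflection centre. Annotation symbols are drawn from the MIT-BIH
#' inventory of the beat's class.
#'
#' @param spec a [synth_spec()]; `counts` gives the class mix of the record.
#' @param templates named list of [beat_template()]s (defaults derived from
#'   `spec`).
#' @param record_id record name.
#' @return an object of class `ecg_record`: `list(record_id, signal, fs,
#'   ann)` where `ann` is a data.frame with 0-based `r_index`, MIT-BIH
#'   `symbol`, and `aami` class.
#' @export
synth_record <- function(spec, templates = NULL, record_id = "synth") {
  if (!is.null(templates) && length(templates) == 0L) {
    stopf("at least one beat template is required")
  }
  if (is.null(templates)) {
    templates <- default_templates(spec$segment_len, spec$fs, spec$separability)
  }
  n <- sum(spec$counts)
  if (n == 0L) stopf("record must contain at least one beat")
  classes <- rep(AAMI_CLASSES, times = spec$counts)
  for (tpl in templates) {
    if (tpl$rr_mean <= spec$segment_len / 2) {
      stopf("rr_mean (%d) must exceed segment_len/2 (%g)", tpl$rr_mean,
            spec$segment_len / 2)
    }
  }
  with_seed(spec$seed, {
    classes <- sample(classes)
    symbols <- vapply(classes, function(cl) {
      inv <- AAMI_SYMBOLS[[cl]]
      inv[sample.int(length(inv), 1L)]
    }, character(1))
    rr <- vapply(classes, function(cl) {
      tpl <- templates[[cl]]
      if (tpl$rr_jitter_sd == 0) return(as.numeric(tpl$rr_mean))
      j <- stats::rnorm(1, 0, tpl$rr_jitter_sd)
      j <- clamp(j, -3 * tpl$rr_jitter_sd, 3 * tpl$rr_jitter_sd)
      tpl$rr_mean + j
    }, numeric(1))
    r_index <- round(cumsum(rr)) # 0-based R-peak positions
    len <- r_index[n] + round(templates[[classes[n]]]$rr_mean / 2)
    signal <- numeric(len)
    half <- round(spec$segment_len / 2)
    for (i in seq_len(n)) {
      tpl <- templates[[classes[i]]]
      lo <- r_index[i] - half        # 0-based window start
      beat <- template_waveform(tpl)
      idx <- seq.int(lo, lo + spec$segment_len - 1)
      keep <- idx >= 0 & idx < len
      signal[idx[keep] + 1L] <- signal[idx[keep] + 1L] + beat[keep]
    }
    signal <- signal + noise_realisation(spec$noise, len, spec$fs)
    structure(
      list(record_id = record_id, signal = signal, fs = spec$fs,
           ann = data.frame(r_index = as.integer(r_index), symbol = symbols,
                            aami = classes, stringsAsFactors = FALSE)),
      class = "ecg_record"
    )
  })
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> '%s': %d samples @ %g Hz, %d annotations\n",
              x$record_id, length(x$signal), x$fs, nrow(x$ann)))
  invisible(x)
}

#' Generate a labelled synthetic beat dataset
#'
#' Emits exactly the per-class counts requested in `spec`, each beat from the
#' class template with a small seeded multiplicative amplitude jitter (sd
#' 0.05) plus the additive noise model. Rows are grouped by class in AAMI
#' order; shuffling happens at split time.
#'
#' @param spec a [synth_spec()].
#' @return a [beat_dataset()] of raw (unnormalized) beats.
#' @export
synth_dataset <- function(spec) {
  n <- sum(spec$counts)
  if (n == 0L) stopf("total beat count must be > 0")
  templates <- default_templates(spec$segment_len, spec$fs, spec$separability)
  feats <- matrix(0, n, spec$segment_len)
  labels <- rep(AAMI_CLASSES, times = spec$counts)
  with_seed(spec$seed, {
    amp <- clamp(stats::rnorm(n, 1, 0.05), 0.7, 1.3)
    for (i in seq_len(n)) {
      tpl <- templates[[labels[i]]]
      feats[i, ] <- template_waveform(tpl, amp_scale = amp[i]) +
        noise_realisation(spec$noise, spec$segment_len, spec$fs)
    }
  })
  beat_dataset(feats, labels, fs = spec$fs,
               meta = list(generator = "synth_dataset", seed = spec$seed,
                           separability = spec$separability,
                           config_hash = config_hash(unclass(spec)[
                             c("counts", "fs", "segment_len", "separability", "seed")])))
}
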
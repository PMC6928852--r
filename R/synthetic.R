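#' Beat morphology template parameters
#'
#' Gaussian-sum beat model: each beat is a sum of five Gaussian waves (P, Q,
#' R, S, T) with per-wave amplitude (mV), center (seconds relative to the R
#' peak) and width (seconds). Class-specific modifiers emulate the AAMI
#' groups: V widens the QRS waves 2.5-fold and suppresses the P wave; S
#' shortens the beat's RR interval to 70% (premature timing) and halves and
#' advances the P wave; F is the average of the N and V waveforms; Q is a
#' narrow spike of random polarity with no P or T wave.
#'
#' @param p_amp,q_amp,r_amp,s_amp,t_amp Wave amplitudes in mV.
#' @param p_center,q_center,r_center,s_center,t_center Wave centers in
#'   seconds relative to R.
#' @param p_width,q_width,r_width,s_width,t_width Wave widths (Gaussian
#'   sigma) in seconds.
#' @param rr_mean Mean RR interval in seconds (> 0.3).
#' @param rr_jitter Standard deviation of the per-beat RR jitter in seconds.
#' @param v_qrs_widen QRS width multiplier for V beats.
#' @param s_rr_shorten RR multiplier for S beats.
#' @param q_spike_amp Spike amplitude magnitude for Q beats.
#' @param q_spike_width Spike width in seconds for Q beats.
#' @return A `beat_template_params` list.
#' @export
beat_template_params <- function(
    p_amp = 0.15, q_amp = -0.10, r_amp = 1.0, s_amp = -0.15, t_amp = 0.35,
    p_center = -0.20, q_center = -0.03, r_center = 0, s_center = 0.03,
    t_center = 0.25,
    p_width = 0.025, q_width = 0.010, r_width = 0.012, s_width = 0.010,
    t_width = 0.060,
    rr_mean = 0.8, rr_jitter = 0.04,
    v_qrs_widen = 2.5, s_rr_shorten = 0.7,
    q_spike_amp = 1.0, q_spike_width = 0.008) {
  stopifnot(rr_mean > 0.3, rr_jitter >= 0,
            all(c(p_width, q_width, r_width, s_width, t_width) > 0))
  structure(as.list(environment()), class = "beat_template_params")
}

#' Additive noise parameters for synthetic records
#'
#' Emulates the three artifact sources a denoiser must handle: slow
#' baseline wander (respiration-scale sinusoid), powerline interference
#' (60 Hz by default, 50 Hz in European settings) and broadband white
#' noise.
#'
#' @param baseline_amp,baseline_freq Baseline wander amplitude (mV) and
#'   frequency (Hz).
#' @param powerline_amp,powerline_freq Powerline amplitude (mV) and
#'   frequency (Hz).
#' @param white_sd White-noise standard deviation (mV).
#' @return A `noise_params` list.
#' @export
noise_params <- function(baseline_amp = 0.1, baseline_freq = 0.3,
                         powerline_amp = 0.05, powerline_freq = 60,
                         white_sd = 0.02) {
  stopifnot(baseline_amp >= 0, powerline_amp >= 0, white_sd >= 0)
  structure(as.list(environment()), class = "noise_params")
}

gauss_wave <- function(t, amp, center, width) {
  amp * exp(-0.5 * ((t - center) / width)^2)
}

# Noiseless waveform of one beat of class `cls` over time axis t (seconds,
# 0 at the R peak).
beat_waveform <- function(cls, params, t) {
  p <- params
  base <- function(p_amp, qrs_widen = 1) {
    gauss_wave(t, p_amp, p$p_center, p$p_width) +
      gauss_wave(t, p$q_amp, p$q_center, p$q_width * qrs_widen) +
      gauss_wave(t, p$r_amp, p$r_center, p$r_width * qrs_widen) +
      gauss_wave(t, p$s_amp, p$s_center, p$s_width * qrs_widen) +
      gauss_wave(t, p$t_amp, p$t_center, p$t_width)
  }
  switch(cls,
    N = base(p$p_amp),
    V = base(0, qrs_widen = p$v_qrs_widen),
    S = gauss_wave(t, p$p_amp * 0.5, p$p_center - 0.05, p$p_width) +
      base(0),  # altered, advanced P wave on a normal QRS-T
    F = 0.5 * (base(p$p_amp) + base(0, qrs_widen = p$v_qrs_widen)),
    Q = gauss_wave(t, (p$q_spike_polarity %||% 1) * p$q_spike_amp, 0,
                   p$q_spike_width),
    stop("invalid class: ", cls))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate one synthetic beat
#'
#' One beat of Gaussian-sum morphology for the given AAMI class, spanning
#' one (jittered) RR interval with the R peak at roughly a third of the
#' interval. Uses the R random number stream; seed it (or use
#' [generate_record()]) for reproducibility.
#'
#' @param cls One of `"N","S","V","F","Q"`.
#' @param params A [beat_template_params()].
#' @param fs Sampling rate in Hz.
#' @return List with `samples` (numeric), `r_offset` (0-based sample index
#'   of the annotated R position within the beat) and `class`.
#' @export
generate_beat <- function(cls, params = beat_template_params(), fs = 360) {
  rr <- params$rr_mean + stats::rnorm(1, 0, params$rr_jitter)
  rr <- max(rr, 0.4)
  if (cls == "S") rr <- rr * params$s_rr_shorten
  if (cls == "Q") params$q_spike_polarity <- sample(c(-1, 1), 1)
  n <- round(rr * fs)
  r_off <- round(0.35 * n)
  t <- (seq_len(n) - 1 - r_off) / fs
  list(samples = beat_waveform(cls, params, t), r_offset = r_off, class = cls)
}

class_symbols <- c(N = "N", S = "A", V = "V", F = "F", Q = "/")

# Concatenate beats of the given class sequence into an annotated record
# with additive noise; 0.5 s of quiet lead-in/out keeps every beat window
# segmentable.
assemble_record <- function(record_id, classes, params, noise, fs) {
  pad <- round(0.5 * fs)
  pieces <- vector("list", length(classes))
  idx <- integer(length(classes))
  offset <- pad
  for (i in seq_along(classes)) {
    b <- generate_beat(classes[i], params, fs)
    pieces[[i]] <- b$samples
    idx[i] <- offset + b$r_offset
    offset <- offset + length(b$samples)
  }
  x <- c(numeric(pad), unlist(pieces), numeric(pad))
  n <- length(x)
  t <- (seq_len(n) - 1) / fs
  if (noise$baseline_amp > 0)
    x <- x + noise$baseline_amp *
      sin(2 * pi * noise$baseline_freq * t + stats::runif(1, 0, 2 * pi))
  if (noise$powerline_amp > 0)
    x <- x + noise$powerline_amp *
      sin(2 * pi * noise$powerline_freq * t + stats::runif(1, 0, 2 * pi))
  if (noise$white_sd > 0)
    x <- x + stats::rnorm(n, 0, noise$white_sd)
  ecg_record(record_id, x, fs = fs, ann_indices = idx,
             ann_symbols = unname(class_symbols[classes]))
}

#' Generate a synthetic annotated ECG record
#'
#' Draws `n_beats` classes from `class_mix`, concatenates Gaussian-sum
#' beats, and adds baseline wander, powerline interference and white noise.
#' Annotations hold the true R sample indices and class-coded beat symbols
#' (`N, A, V, F, /`) that [map_aami_label()] maps back onto the AAMI
#' classes. Fully reproducible from `seed`.
#'
#' @param n_beats Number of beats.
#' @param class_mix Named per-class probabilities summing to 1 (order
#'   N, S, V, F, Q).
#' @param noise A [noise_params()].
#' @param params A [beat_template_params()].
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @param record_id Record identifier.
#' @return An [ecg_record()].
#' @export
generate_record <- function(n_beats,
                            class_mix = c(N = 0.9, S = 0.03, V = 0.06,
                                          F = 0.007, Q = 0.003),
                            noise = noise_params(),
                            params = beat_template_params(),
                            fs = 360, seed = 1, record_id = "synth") {
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  cls_names <- names(class_mix)
  with_local_seed(seed, {
    classes <- sample(cls_names, n_beats, replace = TRUE, prob = class_mix)
    assemble_record(record_id, classes, params, noise, fs)
  })
}

# Multiply amplitudes/widths/timing by modest random factors to emulate
# inter-patient morphology variation; one draw per record.
perturb_template <- function(params, sdlog = 0.08) {
  jitter_fields <- c("p_amp", "q_amp", "r_amp", "s_amp", "t_amp",
                     "p_width", "q_width", "r_width", "s_width", "t_width",
                     "rr_mean")
  for (f in jitter_fields)
    params[[f]] <- params[[f]] * exp(stats::rnorm(1, 0, sdlog))
  params
}

#' Generate an inter-patient style synthetic dataset
#'
#' Disjoint sets of training and testing records whose beat-template
#' parameters are drawn independently per record, the synthetic analogue of
#' the inter-patient constraint that no subject contributes beats to both
#' splits. The default class mix mirrors the heavy imbalance of ambulatory
#' arrhythmia data (about 90% N, 3% S, 6% V, 0.7% F, 0.3% Q). To keep the
#' rare classes trainable at small scale, each split is guaranteed at least
#' `min_per_class` beats of every class (excess N beats are reassigned,
#' deterministically under the seed, when a draw comes up short).
#'
#' @param n_train,n_test Total beats in each split.
#' @param mix Named class probabilities (order N, S, V, F, Q).
#' @param noise A [noise_params()].
#' @param seed Integer seed.
#' @param beats_per_record Beats per synthetic record.
#' @param min_per_class Minimum beats per class per split.
#' @param fs Sampling rate.
#' @return List with `train` and `test`, each a list of [ecg_record()]s,
#'   plus `template_log`, a data.frame of the per-record template draws.
#' @export
generate_imbalanced_dataset <- function(
    n_train = 2000, n_test = 1000,
    mix = c(N = 0.9, S = 0.03, V = 0.06, F = 0.007, Q = 0.003),
    noise = noise_params(), seed = 1, beats_per_record = 200,
    min_per_class = 5, fs = 360) {
  if (abs(sum(mix) - 1) > 1e-8) stop("class mix must sum to 1")
  cls_names <- names(mix)

  draw_split <- function(n_total, prefix, id0) {
    n_rec <- ceiling(n_total / beats_per_record)
    sizes <- rep(beats_per_record, n_rec)
    sizes[n_rec] <- n_total - beats_per_record * (n_rec - 1)
    classes <- sample(cls_names, n_total, replace = TRUE, prob = mix)
    for (k in cls_names) {         # top up rare classes from N beats
      short <- min(min_per_class, n_total) - sum(classes == k)
      if (short > 0) {
        pool <- which(classes == "N")
        classes[pool[seq_len(short)]] <- k
      }
    }
    stops <- cumsum(sizes)
    starts <- c(1, head(stops, -1) + 1)
    recs <- vector("list", n_rec)
    logs <- vector("list", n_rec)
    for (i in seq_len(n_rec)) {
      tpl <- perturb_template(beat_template_params())
      id <- sprintf("%s%03d", prefix, id0 + i)
      recs[[i]] <- assemble_record(id, classes[starts[i]:stops[i]],
                                   tpl, noise, fs)
      logs[[i]] <- data.frame(record_id = id, r_amp = tpl$r_amp,
                              rr_mean = tpl$rr_mean, t_amp = tpl$t_amp)
    }
    list(records = recs, log = do.call(rbind, logs))
  }

  with_local_seed(seed, {
    tr <- draw_split(n_train, "train", 0)
    te <- draw_split(n_test, "test", 100)
    list(train = tr$records, test = te$records,
         template_log = rbind(tr$log, te$log))
  })
}
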
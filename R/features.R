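#' Nonlinear entropy measures of a signal
#'
#' Additive cost-function entropies computed directly on the raw sample
#' values of a mode. All three satisfy `E(c(u, v)) = E(u) + E(v)` and
#' `E(0) = 0`.
#'
#' `shannon_entropy` returns `-sum(s^2 * log(s^2))` with the convention
#' `0 * log(0) = 0` (natural log; the leading minus is the usual toolbox
#' convention that makes small-amplitude signals score positive).
#' `log_energy_entropy` returns `sum(log(s^2))` with `log(0)` terms
#' contributing 0. `norm_entropy` returns `sum(abs(s)^p)`, the p-th power of
#' the lp norm, for `p >= 1`.
#'
#' @param s Numeric vector of samples.
#' @param p Norm exponent, `p >= 1` (default 1.1).
#' @return A single numeric value.
#' @export
shannon_entropy <- function(s) {
  s2 <- as.numeric(s)^2
  nz <- s2 > 0
  -sum(s2[nz] * log(s2[nz]))
}

#' @rdname shannon_entropy
#' @export
log_energy_entropy <- function(s) {
  s2 <- as.numeric(s)^2
  nz <- s2 > 0
  sum(log(s2[nz]))
}

#' @rdname shannon_entropy
#' @export
norm_entropy <- function(s, p = 1.1) {
  if (p < 1) stop("invalid parameter: p must be >= 1")
  sum(abs(as.numeric(s))^p)
}

#' Zero-lag higher-order cumulants
#'
#' Second-, third- and fourth-order sample cumulants of the mean-removed
#' sequence: with `m_k` the k-th central sample moment (denominator `n`),
#' `cum2 = m2`, `cum3 = m3`, `cum4 = m4 - 3 m2^2`. These capture the
#' variance, asymmetry and deviation from Gaussianity of a mode; all three
#' vanish for a constant sequence and `cum3`, `cum4` vanish in expectation
#' for Gaussian input.
#'
#' @param s Numeric vector, length at least 2.
#' @return Named numeric vector `c(cum2, cum3, cum4)`.
#' @export
hos_cumulants <- function(s) {
  s <- as.numeric(s)
  if (length(s) < 2) stop("need at least 2 samples for cumulants")
  d <- s - mean(s)
  m2 <- mean(d^2)
  m3 <- mean(d^3)
  m4 <- mean(d^4)
  c(cum2 = m2, cum3 = m3, cum4 = m4 - 3 * m2^2)
}

#' Column names of the 36-element beat feature vector
#'
#' Six features per mode, in the order CUM2, CUM3, CUM4, Shannon entropy,
#' log-energy entropy, norm entropy, for modes 1 through 6.
#'
#' @return Character vector of length 36.
#' @export
feature_names <- function() {
  as.vector(vapply(1:6, function(l)
    paste0(c("CUM2", "CUM3", "CUM4", "Shan", "log", "norm"), "_IMF", l),
    character(6)))
}

#' Assemble the 36-element feature vector of one beat
#'
#' Applies the three cumulants and three entropies to the first six modes of
#' a decomposition, giving 6 features x 6 modes = 36 values in
#' [feature_names()] order.
#'
#' @param imfs An `imf_set` with at least 6 modes.
#' @param p Norm-entropy exponent (default 1.1).
#' @return Named numeric vector of length 36.
#' @export
build_feature_vector <- function(imfs, p = 1.1) {
  stopifnot(inherits(imfs, "imf_set"))
  if (length(imfs$modes) < 6)
    stop("insufficient modes: need at least 6, have ", length(imfs$modes))
  out <- unlist(lapply(1:6, function(l) {
    m <- imfs$modes[[l]]
    c(hos_cumulants(m),
      shannon_entropy(m), log_energy_entropy(m), norm_entropy(m, p))
  }), use.names = FALSE)
  if (!all(is.finite(out))) stop("non-finite feature value computed")
  stats::setNames(out, feature_names())
}

#' Feature table for a set of beat segments
#'
#' Decomposes every segment with [iceemd()] and stacks the per-beat feature
#' vectors into a data.frame, with `record_id`, `r_index` and `label`
#' columns prepended. Each beat gets its own deterministic noise seed
#' derived from `seed` and the beat's position, so the table is reproducible
#' and independent of evaluation order.
#'
#' @param segments List of `beat_segment` objects (from [segment_beats()]).
#' @param J,eps0,L,config ICEEMD settings, see [iceemd()].
#' @param p Norm-entropy exponent.
#' @param seed Base seed for the per-beat noise realizations.
#' @return A data.frame with `3 + 36` columns and one row per segment.
#' @export
beat_feature_table <- function(segments, J = 50, eps0 = 0.2, L = 6,
                               p = 1.1, seed = 1, config = sift_config()) {
  rows <- lapply(seq_along(segments), function(i) {
    seg <- segments[[i]]
    dec <- iceemd(seg$samples, J = J, eps0 = eps0, L = L,
                  seed = (seed + 1000L * i) %% .Machine$integer.max,
                  config = config)
    build_feature_vector(dec, p = p)
  })
  feats <- as.data.frame(do.call(rbind, rows))
  meta <- data.frame(
    record_id = vapply(segments, `[[`, character(1), "record_id"),
    r_index = vapply(segments, `[[`, integer(1), "r_index"),
    label = vapply(segments, `[[`, character(1), "aami_class"),
    stringsAsFactors = FALSE)
  cbind(meta, feats)
}
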
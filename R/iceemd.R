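#' Sifting configuration for empirical mode decomposition
#'
#' Controls the inner sifting loop. Sifting stops when the classic SD
#' criterion — the sum over samples of the pointwise squared relative change
#' between consecutive sift iterates, `sum(((h_prev - h_new) / h_prev)^2)` —
#' drops below `sd_threshold`, or after `max_sift_iters` iterations.
#' Decomposition stops when the residue can no longer support both spline
#' envelopes (fewer than two maxima or two minima) or `max_modes` modes have
#' been extracted.
#'
#' @param max_sift_iters Maximum sifting iterations per mode.
#' @param sd_threshold Cauchy stopping threshold (dimensionless).
#' @param max_modes Cap on the number of extracted modes.
#' @param boundary Envelope end handling; only `"mirror"` (reflect two
#'   extrema beyond each end) is implemented.
#' @return A `sift_config` list.
#' @export
sift_config <- function(max_sift_iters = 100, sd_threshold = 0.2,
                        max_modes = 12, boundary = "mirror") {
  stopifnot(max_sift_iters >= 1, sd_threshold > 0, max_modes >= 1,
            identical(boundary, "mirror"))
  structure(list(max_sift_iters = as.integer(max_sift_iters),
                 sd_threshold = sd_threshold,
                 max_modes = as.integer(max_modes),
                 boundary = boundary),
            class = "sift_config")
}

#' Locate strict local extrema
#'
#' Interior strict maxima and minima of a sequence; a flat run (plateau)
#' that is higher or lower than both neighbours counts once, at its midpoint.
#'
#' @param x Numeric vector of length at least 3.
#' @return List with integer vectors `maxima` and `minima` (1-based indices).
#' @export
find_extrema <- function(x) {
  if (length(x) < 3) stop("too short: need at least 3 samples")
  find_extrema_cpp(as.numeric(x))
}

#' Local mean of a signal via spline envelopes
#'
#' The mean of the upper (through maxima) and lower (through minima) natural
#' cubic spline envelopes, with two extrema mirrored past each end to tame
#' end swings. When the signal has fewer than two maxima or two minima it is
#' treated as a trend and returned unchanged.
#'
#' @param x Numeric vector of length at least 3.
#' @param config A [sift_config()] (boundary policy).
#' @return Numeric vector of the same length as `x`.
#' @export
local_mean <- function(x, config = sift_config()) {
  if (length(x) < 3) stop("too short: need at least 3 samples")
  local_mean_cpp(as.numeric(x))
}

new_imf_set <- function(modes, residue, eps0 = NA_real_,
                        n_realizations = NA_integer_, seed = NA_integer_) {
  structure(list(modes = modes, residue = residue,
                 source_length = length(residue),
                 eps0 = eps0, n_realizations = n_realizations, seed = seed),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set: %d modes + residue, length %d>\n",
              length(x$modes), x$source_length))
  invisible(x)
}

#' Classic empirical mode decomposition
#'
#' Repeatedly sifts out the highest-frequency oscillatory component (an
#' intrinsic mode function) by subtracting the spline-envelope local mean,
#' then recurses on the remainder until it has fewer than three extrema.
#' The telescoping construction guarantees that the modes plus the residue
#' reproduce the input to rounding error.
#'
#' @param x Numeric vector, length at least 8.
#' @param config A [sift_config()].
#' @return An `imf_set`: list of modes `C_1..C_L` (decreasing frequency)
#'   plus `residue`.
#' @export
emd <- function(x, config = sift_config()) {
  x <- as.numeric(x)
  if (length(x) < 8) stop("input too short for decomposition")
  res <- emd_cpp(x, config$sd_threshold, config$max_sift_iters,
                 config$max_modes)
  L <- res$n_modes
  modes <- if (L > 0) lapply(seq_len(L), function(l) res$modes[, l]) else list()
  new_imf_set(modes, as.numeric(res$residue))
}

#' Improved complete ensemble empirical mode decomposition
#'
#' Noise-assisted EMD in which each residue is estimated as the average
#' local mean over `J` noise-perturbed copies of the previous residue:
#' `r_1 = <M(x + b_0 E_1(w_j))>`, `C_1 = x - r_1`, and for `l >= 2`
#' `r_l = <M(r_{l-1} + b_{l-1} E_l(w_j))>`, `C_l = r_{l-1} - r_l`, where
#' `E_l(w_j)` is the l-th EMD mode of the j-th white-noise realization,
#' `M(.)` the spline-envelope local mean, and `b_l = eps0 * sd(r_l)` scales
#' the injected noise to the residue amplitude. Averaging the *local means*
#' rather than the modes makes the reconstruction exact by construction and
#' keeps residual noise out of the modes. With `eps0 = 0` the procedure
#' degenerates to deterministic repeated local-mean peeling and the seed is
#' never consulted.
#'
#' @param x Numeric vector, length at least 8.
#' @param J Number of white-noise realizations (default 50).
#' @param eps0 Noise amplitude factor relative to the residue standard
#'   deviation (default 0.2).
#' @param L Number of modes to return.
#' @param seed Integer seed for the noise realizations; the same `(x, J,
#'   eps0, L, seed)` always yields the identical decomposition.
#' @param config A [sift_config()] used for all inner EMDs and local means.
#' @return An `imf_set` with modes `C_1..C_L`, residue `r_L`, and the noise
#'   settings recorded.
#' @export
iceemd <- function(x, J = 50, eps0 = 0.2, L = 6, seed = 1,
                   config = sift_config()) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8) stop("input too short for decomposition")
  stopifnot(J >= 1, eps0 >= 0, L >= 1)

  # Precompute the EMD modes of each noise realization once; E_l(w_j) at
  # level l is the l-th column. A short signal supports only a handful of
  # noise modes, so a realization whose decomposition ran out of modes
  # contributes the unperturbed local mean at deeper levels (zero noise),
  # as in reference ensemble-EMD implementations; only when no realization
  # at all reaches level l is the request unserviceable.
  noise_modes <- NULL
  if (eps0 > 0) {
    noise_modes <- with_local_seed(seed, {
      lapply(seq_len(J), function(j) {
        w <- rnorm(n)
        dec <- emd_cpp(w, config$sd_threshold, config$max_sift_iters,
                       max(config$max_modes, L))
        dec$modes[, seq_len(dec$n_modes), drop = FALSE]
      })
    })
    deepest <- max(vapply(noise_modes, ncol, integer(1)))
    if (deepest < L)
      stop("insufficient modes: no noise realization produced ", L,
           " modes (deepest: ", deepest,
           "); lower L or lengthen the signal")
  }

  modes <- vector("list", L)
  r_prev <- x
  for (l in seq_len(L)) {
    if (eps0 > 0) {
      beta <- eps0 * stats::sd(r_prev)
      acc <- numeric(n)
      for (j in seq_len(J)) {
        pert <- if (ncol(noise_modes[[j]]) >= l)
          r_prev + beta * noise_modes[[j]][, l] else r_prev
        acc <- acc + local_mean_cpp(pert)
      }
      r_l <- acc / J
    } else {
      r_l <- local_mean_cpp(r_prev)
    }
    modes[[l]] <- r_prev - r_l
    r_prev <- r_l
  }
  new_imf_set(modes, r_prev, eps0 = eps0, n_realizations = as.integer(J),
              seed = as.integer(seed))
}

#' Export a decomposition as a data frame
#'
#' One column per mode (`C1..CL`) plus `residue`; convenient for writing the
#' decomposition of a beat to CSV.
#'
#' @param imfs An `imf_set`.
#' @return A data.frame with `source_length` rows.
#' @export
imf_frame <- function(imfs) {
  stopifnot(inherits(imfs, "imf_set"))
  cols <- c(stats::setNames(imfs$modes,
                            paste0("C", seq_along(imfs$modes))),
            list(residue = imfs$residue))
  as.data.frame(cols)
}
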
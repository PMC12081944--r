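# Synthetic EEG generation: component bumps over 1/f background noise.
#
# Components are half-period raised-cosine bumps (cos^2) of stated width,
# scaled so that the component's designated measure recovers the table
# amplitude exactly on noiseless data: peak-measured components (P1/N1/P2)
# use the table value as the bump peak; FAL-measured components (MMN/P3b)
# divide by the closed-form 20-ms windowed-mean factor of the bump.

# Mean of a unit cos^2 bump of width `width` over a +/-halfwidth window
# around its centre.
deviance_window_factor <- function(width, halfwidth = 10) {
  0.5 + width / (4 * pi * halfwidth) * sin(2 * pi * halfwidth / width)
}

# Sample a raised-cosine bump at integer times; `center` may be fractional.
bump_trace <- function(times, center, width, peak = 1) {
  x <- times - center
  v <- numeric(length(times))
  inside <- abs(x) <= width / 2
  v[inside] <- peak * cos(pi * x[inside] / width)^2
  v
}

next_pow2 <- function(n) 2^ceiling(log2(n))

# Zero-phase compensated frequency response of a symmetric FIR kernel at all
# N DFT bins (real up to rounding; the real part is taken).
compensated_response <- function(kernel, N) {
  m <- (length(kernel) - 1L) / 2L
  K <- stats::fft(c(kernel, numeric(N - length(kernel))))
  Re(K * exp(2i * pi * m * (seq_len(N) - 1L) / N))
}

#' Generate 1/f-shaped Gaussian noise
#'
#' Draws the spectrum directly in the frequency domain (amplitude
#' proportional to f^(-exponent/2), DC removed) and inverse-transforms;
#' channel pairs share one complex FFT. `sd` is the theoretical per-sample
#' standard deviation of the broadband noise before any `response` shaping.
#'
#' @param n_samples Samples per channel.
#' @param n_channels Number of channels.
#' @param sd Broadband per-sample standard deviation (uV).
#' @param exponent Spectral exponent beta of the 1/f^beta power spectrum.
#' @param rate Sampling rate in Hz.
#' @param response Optional real frequency response (its length sets the
#'   FFT size, which must be at least `n_samples`; e.g. from
#'   [design_fir()] via a compensated response) folded into the spectrum,
#'   yielding noise identical in law to generating broadband noise and
#'   filtering it.
#' @param active_tol Spectrum bins where `abs(response)` falls below this
#'   are skipped (no random draws); ignored without `response`.
#' @return Matrix `n_channels` x `n_samples`.
#' @export
noise_1f <- function(n_samples, n_channels, sd = 10, exponent = 1,
                     rate = 1000, response = NULL, active_tol = 1e-5) {
  if (sd == 0) return(matrix(0, n_channels, n_samples))
  N <- if (is.null(response)) next_pow2(n_samples) else length(response)
  if (N < n_samples) stop("`response` shorter than the recording",
                          call. = FALSE)
  k <- seq_len(N - 1L)
  f <- pmin(k, N - k) * rate / N
  s <- numeric(N)
  s[k + 1L] <- f^(-exponent / 2)
  scale <- sd / sqrt(sum(s^2) / N^2)
  s <- s * scale
  if (!is.null(response)) {
    s <- s * response
    active <- which(abs(s) > active_tol * max(abs(s)) & seq_len(N) > 1L)
  } else {
    active <- k + 1L
  }
  out <- matrix(0, n_channels, n_samples)
  na <- length(active)
  i <- 1L
  while (i <= n_channels) {
    z <- complex(N)
    z[active] <- complex(real = stats::rnorm(na),
                         imaginary = stats::rnorm(na)) * s[active]
    x <- stats::fft(z, inverse = TRUE) / N
    out[i, ] <- Re(x)[seq_len(n_samples)]
    if (i + 1L <= n_channels) out[i + 1L, ] <- Im(x)[seq_len(n_samples)]
    i <- i + 2L
  }
  out
}

# Resolve the realized component parameters for one session (participant in
# one environment): table means + subject amplitude intercept + per-cell
# amplitude jitter + per-cell latency jitter. Consumes RNG draws in a fixed
# order (amplitude jitter, then latency jitter) so the literal and fast
# synthesis paths realize identical parameters under the same seed.
session_component_params <- function(truth, age, environment,
                                     amp_intercepts = NULL) {
  rows <- truth_for_cell(truth, age, environment)
  rows$amp_realized <- rows$amplitude +
    stats::rnorm(nrow(rows), 0, rows$cell_sd)
  if (!is.null(amp_intercepts)) {
    rows$amp_realized <- rows$amp_realized +
      unname(amp_intercepts[rows$component])
  }
  rows$lat_realized <- rows$latency + stats::rnorm(nrow(rows), 0,
                                                   rows$latency_sd)
  # deviance components keep their polarity: participant variation scales a
  # response but does not invert it (the rectified-area latency would be
  # undefined on an inverted bump)
  fal <- rows$component %in% c("MMN", "P3b")
  neg <- rows$polarity < 0
  rows$amp_realized[fal & neg] <- pmin(rows$amp_realized[fal & neg], 0)
  rows$amp_realized[fal & !neg] <- pmax(rows$amp_realized[fal & !neg], 0)
  # FAL-measured components: scale the bump peak so the 20-ms windowed mean
  # equals the table amplitude
  rows$peak <- rows$amp_realized
  rows$peak[fal] <- rows$amp_realized[fal] /
    deviance_window_factor(rows$width[fal])
  rows
}

# Onsets (ms, marker + injected technical offset) at which a component row's
# bump is placed.
component_onsets <- function(row, events, truth, environment) {
  if (row$dimension == "all") {
    ev <- events
  } else {
    pos <- dimension_positions(row$dimension)
    ev <- events[events$position %in% pos, , drop = FALSE]
  }
  ev$onset + truth_offset(truth, environment, ev$position)
}

#' Positions making up a target dimension
#'
#' @param dimension `"azimuth"` (left + right) or `"distance"` (near + far).
#' @return Character vector of positions.
#' @export
dimension_positions <- function(dimension) {
  switch(dimension,
         azimuth = c("left", "right"),
         distance = c("near", "far"),
         stop("unknown dimension: ", dimension, call. = FALSE))
}

#' Synthesize the raw EEG recording of one session
#'
#' Literal generator: for every trial, adds the grid-weighted component
#' bumps at the event onset plus the environment's injected technical onset
#' offset (MMN/P3b only on target trials, with dimension-specific
#' parameters), then adds 1/f background noise. Component topographies sum
#' to zero across the montage, so average re-referencing leaves grid
#' measurements unchanged. Intended for unit-scale work; the cohort runner
#' uses an equivalent pre-filtered path (see the methods vignette).
#'
#' @param events An [generate_sequence()] event table (marker onsets).
#' @param truth An [ground_truth_default()] table covering the cell.
#' @param age,environment Design cell of this session.
#' @param seed Optional integer seed.
#' @param montage Channel names (components need their grid channels plus at
#'   least one free channel for the zero-sum counterweight).
#' @param amp_intercepts Optional named numeric of per-component amplitude
#'   intercepts (participant random effects shared across environments).
#' @param duration_pad Silence after the last onset, ms.
#' @return List with `recording` ([oddball_recording()]) and `events`.
#' @export
synthesize_participant <- function(events, truth, age, environment,
                                   seed = NULL, montage = montage_64(),
                                   amp_intercepts = NULL,
                                   duration_pad = 4800) {
  if (!is.null(seed)) set.seed(seed)
  params <- session_component_params(truth, age, environment, amp_intercepts)
  ns <- as.integer(max(events$onset) + duration_pad)
  data <- noise_1f(ns, length(montage), truth$noise_sd, truth$noise_exponent)
  rownames(data) <- montage
  tt <- seq_len(ns)  # recording times, t0 = 1 ms
  for (i in seq_len(nrow(params))) {
    row <- params[i, ]
    w <- component_topography(row$component, montage)
    onsets <- component_onsets(row, events, truth, environment)
    half <- row$width / 2
    rel <- (ceiling(row$lat_realized - half)):(floor(row$lat_realized + half))
    y <- bump_trace(rel, row$lat_realized, row$width, row$peak)
    trace <- numeric(ns)
    for (o in onsets) {
      idx <- o + rel  # onset at time o means sample index o (t0 = 1)
      keep <- idx >= 1L & idx <= ns
      trace[idx[keep]] <- trace[idx[keep]] + y[keep]
    }
    ch <- which(w != 0)
    data[ch, ] <- data[ch, ] + w[ch] %o% trace
  }
  list(recording = oddball_recording(data, montage, srate = 1000, t0 = 1,
                                     reference = "raw"),
       events = events)
}

#' Simulate behavioral responses for one session
#'
#' Target trials are correct with the cell's accuracy probability (on the
#' logit scale, shifted by participant ability and per-dimension jitter);
#' standards are "correct" (no response) with probability 1 minus the
#' false-alarm rate.
#'
#' @param events Event table.
#' @param truth Ground truth with the accuracy table.
#' @param environment Session environment.
#' @param seed Optional integer seed.
#' @param ability Participant ability offset on the logit scale.
#' @return `events` with a logical `correct` column.
#' @export
simulate_behavior <- function(events, truth, environment, seed = NULL,
                              ability = 0) {
  if (!is.null(seed)) set.seed(seed)
  acc <- truth$accuracy[truth$accuracy$environment == environment, ]
  if (nrow(acc) == 0) stop("no accuracy entries for environment ",
                           environment, call. = FALSE)
  if (any(acc$p <= 0 | acc$p >= 1) ||
      truth$false_alarm < 0 || truth$false_alarm >= 1) {
    stop("response probabilities must lie in (0, 1)", call. = FALSE)
  }
  jit <- stats::rnorm(nrow(acc), 0, truth$behavior_cell_sd)
  p_dim <- stats::plogis(stats::qlogis(acc$p) + ability + jit)
  names(p_dim) <- acc$dimension
  correct <- rep(NA, nrow(events))
  std <- !events$is_target
  correct[std] <- stats::runif(sum(std)) > truth$false_alarm
  for (dim in names(p_dim)) {
    sel <- events$position %in% dimension_positions(dim)
    correct[sel] <- stats::runif(sum(sel)) < p_dim[dim]
  }
  events$correct <- correct
  events
}

# ---------------------------------------------------------------------------
# Fast cohort path: pre-filtered synthesis.
#
# Filtering is linear and time-invariant, so the filtered recording equals
# (a) the sum of pre-filtered component templates placed at the trial
# onsets, plus (b) 1/f noise drawn with the compensated filter response
# folded into its spectrum. The 41 montage channels outside the analysis
# grids carry no signal relevant after average referencing (topographies are
# zero-sum) and enter only through the reference mean; their noise is drawn
# as one aggregate trace with sd * sqrt(41). Equivalence with the literal
# path is asserted in the test suite.

# Precompute session-size-independent pieces for the fast path: the
# combined kernel, its compensated response at the padded FFT size, and
# (when noise parameters are given) the scaled, filter-shaped noise
# spectrum together with the indices of its non-negligible bins.
fast_precompute <- function(n_samples, filters, rate = 1000,
                            noise_sd = NULL, noise_exponent = 1,
                            active_tol = 1e-4) {
  kernels <- lapply(filters, design_fir, rate = rate)
  kernel <- Reduce(combine_kernels, kernels)
  N <- next_pow2(n_samples)
  response <- compensated_response(kernel, N)
  out <- list(kernel = kernel, N = N, response = response,
              m = (length(kernel) - 1L) %/% 2L)
  if (!is.null(noise_sd) && noise_sd > 0) {
    k <- seq_len(N - 1L)
    f <- pmin(k, N - k) * rate / N
    s <- numeric(N)
    s[k + 1L] <- f^(-noise_exponent / 2)
    s <- s * (noise_sd / sqrt(sum(s^2) / N^2))  # sd before shaping
    s <- s * response
    out$spectrum <- s
    out$active <- which(abs(s) > active_tol * max(abs(s)))
  }
  out
}

# Draw pairs of real noise channels from a precomputed complex spectrum:
# channel pairs are the real and imaginary parts of one inverse FFT of an
# (unsymmetrized) complex-Gaussian spectrum, which are independent because
# the spectrum magnitude is frequency-symmetric.
noise_from_spectrum <- function(n_samples, n_channels, spectrum, active) {
  out <- matrix(0, n_channels, n_samples)
  N <- length(spectrum)
  na <- length(active)
  sa <- spectrum[active]
  z <- complex(N)
  keep <- seq_len(n_samples)
  i <- 1L
  while (i <= n_channels) {
    z[active] <- complex(real = stats::rnorm(na) * sa,
                         imaginary = stats::rnorm(na) * sa)
    x <- stats::fft(z, inverse = TRUE) / N
    out[i, ] <- Re(x)[keep]
    if (i + 1L <= n_channels) out[i + 1L, ] <- Im(x)[keep]
    i <- i + 2L
  }
  out
}

# Filtered template of one component row: values plus the relative time of
# the first sample (can be negative: filter ringing precedes the bump).
filtered_template <- function(row, kernel) {
  half <- row$width / 2
  rel <- (ceiling(row$lat_realized - half)):(floor(row$lat_realized + half))
  y <- bump_trace(rel, row$lat_realized, row$width, row$peak)
  L <- length(kernel)
  m <- (L - 1L) %/% 2L
  n <- length(y) + L - 1L
  N <- stats::nextn(n)
  conv <- Re(stats::fft(stats::fft(c(y, numeric(N - length(y)))) *
                          stats::fft(c(kernel, numeric(N - L))),
                        inverse = TRUE))[seq_len(n)] / N
  list(values = conv, start = rel[1] - m)
}

# Place template values at each onset into a length-ns trace.
place_template <- function(ns, onsets, template) {
  trace <- numeric(ns)
  len <- length(template$values)
  for (o in onsets) {
    i1 <- o + template$start
    i2 <- i1 + len - 1L
    if (i1 < 1L || i2 > ns) {
      j <- max(1L, i1):min(ns, i2)
      trace[j] <- trace[j] + template$values[j - i1 + 1L]
    } else {
      trace[i1:i2] <- trace[i1:i2] + template$values
    }
  }
  trace
}

# Fast path: filtered, average-referenced recording restricted to
# `keep_channels`. Same RNG draw order for component parameters as the
# literal path, so noiseless outputs coincide exactly.
synthesize_session_filtered <- function(events, truth, age, environment,
                                        seed = NULL,
                                        montage = montage_64(),
                                        keep_channels = NULL,
                                        amp_intercepts = NULL,
                                        duration_pad = 4800,
                                        precomp = NULL,
                                        filters = default_filters()) {
  if (!is.null(seed)) set.seed(seed)
  grids <- erp_grids()
  if (is.null(keep_channels)) keep_channels <- unique(unlist(grids))
  params <- session_component_params(truth, age, environment, amp_intercepts)
  ns <- as.integer(max(events$onset) + duration_pad)
  if (is.null(precomp)) precomp <- fast_precompute(ns, filters)
  stopifnot(precomp$N >= ns)

  nk <- length(keep_channels)
  n_rest <- length(montage) - nk
  # kept-channel noise plus one aggregate trace for the remaining channels
  noise <- if (!is.null(precomp$spectrum)) {
    noise_from_spectrum(ns, nk + 1L, precomp$spectrum, precomp$active)
  } else {
    noise_1f(ns, nk + 1L, truth$noise_sd, truth$noise_exponent,
             response = precomp$response)
  }
  noise[nk + 1L, ] <- noise[nk + 1L, ] * sqrt(n_rest)
  ref_mean <- colSums(noise) / length(montage)
  data <- noise[seq_len(nk), , drop = FALSE] -
    rep(ref_mean, each = nk)
  rownames(data) <- keep_channels

  for (i in seq_len(nrow(params))) {
    row <- params[i, ]
    w <- component_topography(row$component, montage)[keep_channels]
    if (all(w == 0)) next
    onsets <- component_onsets(row, events, truth, environment)
    trace <- place_template(ns, onsets, filtered_template(row, precomp$kernel))
    ch <- which(w != 0)
    data[ch, ] <- data[ch, ] + w[ch] %o% trace
  }
  list(recording = oddball_recording(data, keep_channels, srate = 1000,
                                     t0 = 1, reference = "average"),
       events = events)
}
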
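# Preprocessing: windowed-sinc FIR filtering, average re-referencing,
# epoching with baseline correction, trial selection and artifact rejection.

#' Continuous multi-channel recording
#'
#' @param data Numeric matrix, channels x samples (uV).
#' @param channels Channel names.
#' @param srate Sampling rate in Hz (the pipeline assumes 1000).
#' @param t0 Time of the first sample in ms.
#' @param reference Reference description string.
#' @return An object of class `oddball_recording`.
#' @export
oddball_recording <- function(data, channels = rownames(data), srate = 1000,
                              t0 = 0, reference = "recording") {
  if (is.null(dim(data))) data <- matrix(data, nrow = 1)
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(data)))
  stopifnot(nrow(data) == length(channels))
  if (anyNA(data) || any(!is.finite(data))) {
    stop("recording contains non-finite samples", call. = FALSE)
  }
  rownames(data) <- channels
  structure(list(data = data, channels = channels, srate = srate, t0 = t0,
                 reference = reference),
            class = "oddball_recording")
}

#' @export
print.oddball_recording <- function(x, ...) {
  cat(sprintf("Recording: %d channels x %d samples @ %g Hz (%.1f s), ref: %s\n",
              nrow(x$data), ncol(x$data), x$srate,
              ncol(x$data) / x$srate, x$reference))
  invisible(x)
}

#' FIR filter specification
#'
#' Hamming-windowed sinc FIR filters. The defaults used by the pipeline are
#' a 0.25-Hz high-pass of length 6601 and a 33.75-Hz low-pass of length 441
#' (transition bandwidths 0.5 and 7.5 Hz at 1000 Hz, following the
#' window-method relation tb = 3.3 / length * rate).
#'
#' @param kind `"highpass"` or `"lowpass"`.
#' @param cutoff -6 dB cutoff frequency in Hz.
#' @param length Filter length in taps (odd, for integer group delay).
#' @param window Window function name (only `"hamming"` is implemented).
#' @return An object of class `fir_spec`.
#' @export
fir_spec <- function(kind = c("highpass", "lowpass"), cutoff, length,
                     window = "hamming") {
  kind <- match.arg(kind)
  length <- as.integer(length)
  if (length %% 2L == 0L) {
    stop("filter length must be odd for exact group-delay compensation",
         call. = FALSE)
  }
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  structure(list(kind = kind, cutoff = cutoff, length = length,
                 transition_bandwidth = 3.3 / length,  # x rate, in Hz
                 window = window),
            class = "fir_spec")
}

#' Design a windowed-sinc linear-phase FIR filter
#'
#' @param spec A [fir_spec()].
#' @param rate Sampling rate in Hz.
#' @return Numeric coefficient vector of length `spec$length` (symmetric,
#'   DC gain exactly 1 for low-pass / 0 for high-pass).
#' @export
design_fir <- function(spec, rate) {
  if (spec$cutoff >= rate / 2) {
    stop("cutoff must lie below the Nyquist frequency", call. = FALSE)
  }
  if (spec$window != "hamming") stop("only Hamming windows are implemented")
  L <- spec$length
  m <- (L - 1L) / 2L
  x <- seq_len(L) - 1L - m
  fc <- spec$cutoff / rate
  h <- ifelse(x == 0, 2 * fc, sin(2 * pi * fc * x) / (pi * x))
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(L) - 1L) / (L - 1L))
  h <- h * w
  h <- h / sum(h)  # unit DC gain
  if (spec$kind == "highpass") {
    h <- -h
    h[m + 1L] <- h[m + 1L] + 1  # spectral inversion
  }
  h
}

#' Frequency response of an FIR kernel
#'
#' @param kernel Coefficient vector.
#' @param freq Frequencies in Hz.
#' @param rate Sampling rate in Hz.
#' @return Complex response at `freq` (of the causal filter; take `Mod()`
#'   for the magnitude, which equals the zero-phase compensated gain).
#' @export
fir_response <- function(kernel, freq, rate) {
  n <- seq_along(kernel) - 1
  vapply(freq, function(f) {
    sum(kernel * exp(-2i * pi * f * n / rate))
  }, complex(1))
}

# Convolve two kernels (used to combine high-pass and low-pass into one
# linear-phase kernel; both odd-length, so the result is odd-length too).
combine_kernels <- function(k1, k2) {
  n <- length(k1) + length(k2) - 1L
  N <- stats::nextn(n)
  Re(stats::fft(stats::fft(c(k1, numeric(N - length(k1)))) *
                  stats::fft(c(k2, numeric(N - length(k2)))),
                inverse = TRUE))[seq_len(n)] / N
}

# FFT convolution of a channels x samples matrix with a symmetric FIR
# kernel, compensating the (L-1)/2 group delay so the output is zero-phase
# and the same length as the input. Channels are packed in pairs into one
# complex FFT. Edges are zero-padded; callers keep a lead-in/out margin of
# at least half the kernel length.
fft_filter_matrix <- function(data, kernel) {
  nch <- nrow(data)
  ns <- ncol(data)
  L <- length(kernel)
  m <- (L - 1L) %/% 2L
  N <- stats::nextn(ns + L - 1L)
  K <- stats::fft(c(kernel, numeric(N - L)))
  out <- matrix(0, nch, ns, dimnames = dimnames(data))
  i <- 1L
  while (i <= nch) {
    if (i < nch) {
      z <- complex(real = c(data[i, ], numeric(N - ns)),
                   imaginary = c(data[i + 1L, ], numeric(N - ns)))
      y <- stats::fft(stats::fft(z) * K, inverse = TRUE) / N
      out[i, ] <- Re(y)[(m + 1L):(m + ns)]
      out[i + 1L, ] <- Im(y)[(m + 1L):(m + ns)]
      i <- i + 2L
    } else {
      z <- c(data[i, ], numeric(N - ns))
      y <- stats::fft(stats::fft(z) * K, inverse = TRUE) / N
      out[i, ] <- Re(y)[(m + 1L):(m + ns)]
      i <- i + 1L
    }
  }
  out
}

#' Filter a recording with one or more FIR filters
#'
#' Applies the (combined) zero-phase compensated windowed-sinc kernel to the
#' continuous data by FFT convolution.
#'
#' @param recording An [oddball_recording()].
#' @param specs A single [fir_spec()] or list of them (applied jointly as
#'   one combined kernel).
#' @return The filtered recording.
#' @export
filter_recording <- function(recording, specs) {
  if (inherits(specs, "fir_spec")) specs <- list(specs)
  kernels <- lapply(specs, design_fir, rate = recording$srate)
  kernel <- Reduce(combine_kernels, kernels)
  recording$data <- fft_filter_matrix(recording$data, kernel)
  recording
}

#' Re-reference a recording to the average of all channels
#'
#' @param recording An [oddball_recording()] with at least 2 channels.
#' @return The re-referenced recording (per-sample channel mean subtracted).
#' @export
rereference_average <- function(recording) {
  if (nrow(recording$data) < 2) {
    stop("average re-referencing needs at least 2 channels", call. = FALSE)
  }
  mu <- colMeans(recording$data)
  recording$data <- recording$data - rep(mu, each = nrow(recording$data))
  recording$reference <- "average"
  recording
}

#' Epoching specification
#'
#' @param window Epoch window in ms, half-open `[lo, hi)`; default
#'   `c(-200, 1000)` (1200 samples at 1000 Hz).
#' @param baseline Baseline window in ms, half-open; must lie inside
#'   `window`. Default `c(-200, 0)`.
#' @param srate Sampling rate in Hz.
#' @return An object of class `epoch_spec`.
#' @export
epoch_spec <- function(window = c(-200, 1000), baseline = c(-200, 0),
                       srate = 1000) {
  if (baseline[1] < window[1] || baseline[2] > window[2]) {
    stop("baseline window must lie inside the epoch window", call. = FALSE)
  }
  structure(list(window = window, baseline = baseline, srate = srate),
            class = "epoch_spec")
}

#' Cut stimulus-locked epochs and apply baseline correction
#'
#' Epochs cover `[window[1], window[2])` ms relative to each event onset
#' (sample at time t is the recording sample at `onset + t`). The
#' per-channel mean over the baseline window is removed from every epoch.
#' Events whose epoch would exceed the recording bounds are dropped and
#' logged.
#'
#' @param recording An [oddball_recording()] (1000 Hz).
#' @param events Event data frame with at least `index`, `onset` (ms),
#'   `position`, `is_target`, `is_first_post_target_standard` (and
#'   optionally `correct`).
#' @param spec An [epoch_spec()].
#' @param margin Extra ms kept on both sides of the window (for later
#'   latency alignment); baseline correction still uses `spec$baseline`.
#' @return An object of class `erp_epochs`: trials x channels x time array
#'   plus event labels and a selection log.
#' @export
epoch_recording <- function(recording, events, spec = epoch_spec(),
                            margin = 0) {
  stopifnot(recording$srate == spec$srate)
  times <- seq(spec$window[1] - margin, spec$window[2] + margin - 1)
  ns <- ncol(recording$data)
  onset_samp <- round(events$onset) - recording$t0 + 1L
  lo <- onset_samp + times[1]
  hi <- onset_samp + times[length(times)]
  ok <- lo >= 1L & hi <= ns
  log <- data.frame(index = events$index[!ok],
                    reason = rep("epoch_out_of_bounds", sum(!ok)),
                    stringsAsFactors = FALSE)
  events <- events[ok, , drop = FALSE]
  onset_samp <- onset_samp[ok]

  nch <- nrow(recording$data)
  ntr <- nrow(events)
  nt <- length(times)
  arr <- array(0, dim = c(ntr, nch, nt))
  idx <- outer(onset_samp, times, "+")  # trials x time sample indices
  for (ch in seq_len(nch)) {
    arr[, ch, ] <- recording$data[ch, ][idx]
  }
  bsel <- times >= spec$baseline[1] & times < spec$baseline[2]
  bmean <- rowMeans(arr[, , bsel, drop = FALSE], dims = 2)
  arr <- arr - c(bmean)  # recycles trials x channels over time

  structure(list(data = arr, times = times, channels = recording$channels,
                 events = events, spec = spec, margin = margin, log = log),
            class = "erp_epochs")
}

#' @export
print.erp_epochs <- function(x, ...) {
  cat(sprintf("Epochs: %d trials x %d channels x %d samples (%g to %g ms)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$times), max(x$times)))
  if (nrow(x$log)) {
    cat("dropped:", paste(sprintf("%s=%d", names(table(x$log$reason)),
                                  table(x$log$reason)), collapse = ", "), "\n")
  }
  invisible(x)
}

drop_trials <- function(epochs, drop, reason) {
  drop <- as.logical(drop)
  if (any(drop)) {
    epochs$log <- rbind(epochs$log,
                        data.frame(index = epochs$events$index[drop],
                                   reason = reason, stringsAsFactors = FALSE))
    epochs$data <- epochs$data[!drop, , , drop = FALSE]
    epochs$events <- epochs$events[!drop, , drop = FALSE]
  }
  epochs
}

#' Keep only trials with a correct behavioral response
#'
#' A correct response after a target and no response after a standard.
#' Removals are logged with reason `"incorrect"`.
#'
#' @param epochs An `erp_epochs`.
#' @param responses Optional data frame with columns `index` and `correct`
#'   covering every retained trial; by default the `correct` column of the
#'   epoch events is used.
#' @return The filtered `erp_epochs`.
#' @export
select_trials <- function(epochs, responses = NULL) {
  if (is.null(responses)) {
    if (is.null(epochs$events$correct)) {
      stop("no response records: events lack a `correct` column",
           call. = FALSE)
    }
    correct <- epochs$events$correct
  } else {
    m <- match(epochs$events$index, responses$index)
    if (anyNA(m)) {
      stop("missing response record for trial(s) ",
           paste(epochs$events$index[is.na(m)][1:min(3, sum(is.na(m)))],
                 collapse = ", "), call. = FALSE)
    }
    correct <- responses$correct[m]
  }
  if (anyNA(correct)) stop("missing response record", call. = FALSE)
  drop_trials(epochs, !correct, "incorrect")
}

#' Exclude the first standard following each target
#'
#' @param epochs An `erp_epochs` whose events carry the
#'   `is_first_post_target_standard` flag.
#' @return The filtered `erp_epochs` (idempotent).
#' @export
exclude_post_target_standards <- function(epochs) {
  if (is.null(epochs$events$is_first_post_target_standard)) {
    stop("events lack the `is_first_post_target_standard` flag", call. = FALSE)
  }
  drop_trials(epochs, epochs$events$is_first_post_target_standard,
              "first_post_target_standard")
}

#' Reject epochs by absolute amplitude threshold
#'
#' Removes every trial in which any retained channel exceeds `threshold` uV
#' in absolute value at any sample (including margin samples, so the
#' retained set is invariant under later alignment shifts).
#'
#' @param epochs An `erp_epochs`.
#' @param threshold Absolute amplitude threshold in uV (positive).
#' @return The filtered `erp_epochs`.
#' @export
reject_by_amplitude <- function(epochs, threshold = 100) {
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  m <- epochs$data
  dim(m) <- c(dim(epochs$data)[1], prod(dim(epochs$data)[2:3]))
  bad <- rowSums(m > threshold | m < -threshold) > 0
  drop_trials(epochs, bad, "amplitude")
}

#' Average epochs belonging to one design cell
#'
#' Selects trials by event labels and returns their element-wise mean. The
#' azimuth dimension pools left+right targets, distance pools near+far
#' (pass `position = c("left", "right")` etc.).
#'
#' @param epochs An `erp_epochs`.
#' @param position Optional position label(s) to select.
#' @param target Optional logical: select targets (`TRUE`) or standards.
#' @param min_trials Minimum trial count; below it the waveform is returned
#'   with a warning and flagged `low_n` in its labels.
#' @param labels Extra labels attached to the waveform.
#' @return An [erp_waveform()].
#' @export
average_cell <- function(epochs, position = NULL, target = NULL,
                         min_trials = 20, labels = list()) {
  sel <- rep(TRUE, nrow(epochs$events))
  if (!is.null(position)) sel <- sel & epochs$events$position %in% position
  if (!is.null(target)) sel <- sel & epochs$events$is_target == target
  n <- sum(sel)
  if (n == 0) stop("empty design cell", call. = FALSE)
  if (n < min_trials) {
    warning(sprintf("cell average based on only %d trials (minimum %d)",
                    n, min_trials), call. = FALSE)
    labels$low_n <- TRUE
  }
  avg <- colMeans(epochs$data[sel, , , drop = FALSE])
  erp_waveform(avg, epochs$times, epochs$channels, n_trials = n,
               labels = labels)
}

#' Run the fixed preprocessing chain on one session
#'
#' Order (logged): filter, average re-reference, epoch + baseline, select
#' correct trials, exclude first post-target standards, reject by
#' amplitude.
#'
#' @param recording An [oddball_recording()].
#' @param events Event table including a `correct` column.
#' @param filters List of [fir_spec()]s.
#' @param spec An [epoch_spec()].
#' @param reject_threshold Amplitude-rejection threshold, uV.
#' @param margin Epoch margin in ms (see [epoch_recording()]).
#' @param keep_channels Optional channel subset to filter and epoch. The
#'   average reference is always computed over all channels first; by
#'   linearity the result on the kept channels is identical to filtering
#'   everything then subsetting.
#' @return An `erp_epochs` after all selection stages, with a full log.
#' @export
preprocess_session <- function(recording, events,
                               filters = default_filters(),
                               spec = epoch_spec(),
                               reject_threshold = 100,
                               margin = 0,
                               keep_channels = NULL) {
  if (!is.null(keep_channels)) {
    miss <- setdiff(keep_channels, recording$channels)
    if (length(miss)) stop("unknown channel(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    mu <- colMeans(recording$data)
    sub <- recording$data[match(keep_channels, recording$channels), ,
                          drop = FALSE]
    recording$data <- sub - rep(mu, each = nrow(sub))
    recording$channels <- keep_channels
    recording$reference <- "average"
    recording <- filter_recording(recording, filters)
  } else {
    recording <- filter_recording(recording, filters)
    recording <- rereference_average(recording)
  }
  epochs <- epoch_recording(recording, events, spec, margin = margin)
  epochs <- select_trials(epochs)
  epochs <- exclude_post_target_standards(epochs)
  epochs <- reject_by_amplitude(epochs, reject_threshold)
  epochs$pipeline <- c("filter", "rereference_average", "epoch_baseline",
                       "select_correct", "exclude_post_target_standards",
                       "reject_amplitude")
  epochs
}

#' Default FIR filters of the pipeline
#'
#' @return List with the 0.25-Hz high-pass (length 6601) and 33.75-Hz
#'   low-pass (length 441) Hamming-windowed sinc specifications.
#' @export
default_filters <- function() {
  list(fir_spec("highpass", 0.25, 6601),
       fir_spec("lowpass", 33.75, 441))
}
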
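# ERP waveforms and component measurement (peaks, fractional-area latency,
# windowed mean amplitudes).

#' Construct an ERP waveform
#'
#' @param data Numeric matrix, channels x time (uV). A vector is treated as
#'   a single channel.
#' @param times Time axis in ms (1-ms steps).
#' @param channels Channel names.
#' @param n_trials Number of trials contributing to the average.
#' @param labels Named list of cell labels (age, environment, position or
#'   dimension, ...).
#' @return An object of class `erp_waveform`.
#' @export
erp_waveform <- function(data, times, channels = rownames(data),
                         n_trials = NA_integer_, labels = list()) {
  if (is.null(dim(data))) data <- matrix(data, nrow = 1)
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(data)))
  stopifnot(ncol(data) == length(times), nrow(data) == length(channels))
  rownames(data) <- channels
  structure(list(data = data, times = as.numeric(times), channels = channels,
                 n_trials = n_trials, labels = labels),
            class = "erp_waveform")
}

#' @export
print.erp_waveform <- function(x, ...) {
  cat(sprintf("ERP waveform: %d channel(s), %d-%d ms, n_trials = %s\n",
              length(x$channels), min(x$times), max(x$times),
              as.character(x$n_trials)))
  if (length(x$labels)) {
    cat("labels:", paste(names(x$labels), unlist(x$labels), sep = "=",
                         collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.erp_waveform <- function(x, channels = x$channels, ...) {
  sel <- match(channels, x$channels)
  graphics::matplot(x$times, t(x$data[sel, , drop = FALSE]), type = "l",
                    xlab = "time (ms)", ylab = "amplitude (uV)", ...)
  graphics::abline(v = 0, h = 0, col = "grey70")
  invisible(x)
}

#' Difference wave (target minus standard)
#'
#' @param target,standard `erp_waveform`s on identical channel/time axes.
#' @return An `erp_waveform` with `target$data - standard$data`; labels are
#'   taken from the target with `kind = "difference"`.
#' @export
difference_wave <- function(target, standard) {
  if (!identical(target$times, standard$times) ||
      !identical(target$channels, standard$channels)) {
    stop("target and standard waveforms must share channel and time axes",
         call. = FALSE)
  }
  labels <- target$labels
  labels$kind <- "difference"
  erp_waveform(target$data - standard$data, target$times, target$channels,
               n_trials = min(target$n_trials, standard$n_trials),
               labels = labels)
}

#' Average a waveform over an electrode grid
#'
#' @param waveform An `erp_waveform`.
#' @param grid Character vector of channel names (all must be present).
#' @return A single-channel `erp_waveform` (channel name `"grid"`).
#' @export
grid_average <- function(waveform, grid) {
  miss <- setdiff(grid, waveform$channels)
  if (length(miss)) {
    stop("unknown channel(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  m <- waveform$data[match(grid, waveform$channels), , drop = FALSE]
  erp_waveform(colMeans(m), waveform$times, "grid",
               n_trials = waveform$n_trials, labels = waveform$labels)
}

#' Measurement specification for one ERP component
#'
#' @param component Component name.
#' @param grid Channel grid for averaging (character vector).
#' @param window Measurement window in ms, `c(lo, hi)` (inside the epoch).
#' @param polarity `"positive"` or `"negative"`.
#' @param method `"peak"` (peak amplitude + latency) or `"fal"`
#'   (fractional-area latency + windowed mean amplitude).
#' @param fal_fraction Area fraction for the FAL (default 0.5).
#' @param mean_halfwidth Half-width (ms) of the mean-amplitude window around
#'   the FAL (default 10, i.e. a 20-ms window).
#' @param area `"rectified"` (half-wave rectify to the stated polarity
#'   before integrating) or `"signed"`.
#' @return An object of class `measure_spec`.
#' @export
measure_spec <- function(component, grid, window, polarity,
                         method = c("peak", "fal"), fal_fraction = 0.5,
                         mean_halfwidth = 10,
                         area = c("rectified", "signed")) {
  method <- match.arg(method)
  area <- match.arg(area)
  polarity <- match.arg(polarity, c("positive", "negative"))
  if (fal_fraction <= 0 || fal_fraction >= 1) {
    stop("`fal_fraction` must lie in (0, 1)", call. = FALSE)
  }
  if (window[1] >= window[2]) stop("invalid window", call. = FALSE)
  structure(list(component = component, grid = grid, window = window,
                 polarity = polarity, method = method,
                 fal_fraction = fal_fraction, mean_halfwidth = mean_halfwidth,
                 area = area),
            class = "measure_spec")
}

#' Default measurement specifications
#'
#' P1/N1/P2 are peak measures on the frontocentral grid (windows 50-60,
#' 50-200 and 100-400 ms). MMN and P3b are 50% fractional-area latencies
#' plus 20-ms windowed mean amplitudes on their grids; their windows
#' (100-300 and 250-900 ms) bracket every reported mean latency.
#'
#' @param grids Named grids, see [erp_grids()].
#' @return Named list of `measure_spec`s.
#' @export
default_measure_specs <- function(grids = erp_grids()) {
  list(
    P1 = measure_spec("P1", grids$p1, c(50, 60), "positive", "peak"),
    N1 = measure_spec("N1", grids$p1, c(50, 200), "negative", "peak"),
    P2 = measure_spec("P2", grids$p1, c(100, 400), "positive", "peak"),
    MMN = measure_spec("MMN", grids$mmn, c(100, 300), "negative", "fal"),
    P3b = measure_spec("P3b", grids$p3b, c(250, 900), "positive", "fal")
  )
}

wf_single_channel <- function(waveform) {
  if (nrow(waveform$data) != 1) {
    stop("expected a single-channel waveform (use grid_average() first)",
         call. = FALSE)
  }
  drop(waveform$data)
}

wf_window_index <- function(times, window) {
  idx <- which(times >= window[1] & times <= window[2])
  if (!length(idx)) stop("measurement window is empty", call. = FALSE)
  idx
}

#' Peak amplitude and latency within a window
#'
#' Finds the extremum of the stated polarity inside the window; ties are
#' broken to the earliest sample. If no sample has the stated polarity the
#' extremum is still returned but flagged `low_confidence`.
#'
#' @param waveform Single-channel `erp_waveform`.
#' @param spec A [measure_spec()] with `method = "peak"`.
#' @return List with `component`, `amplitude` (uV), `latency` (ms),
#'   `low_confidence`, `method`.
#' @export
peak_measure <- function(waveform, spec) {
  x <- wf_single_channel(waveform)
  idx <- wf_window_index(waveform$times, spec$window)
  sgn <- if (spec$polarity == "positive") 1 else -1
  v <- sgn * x[idx]
  k <- which.max(v)  # earliest index on ties
  list(component = spec$component,
       amplitude = x[idx[k]],
       latency = waveform$times[idx[k]],
       low_confidence = v[k] <= 0,
       method = "peak")
}

#' Fractional-area latency
#'
#' Half-wave rectifies the waveform to the spec's polarity inside the
#' window (or uses the signed area, `spec$area = "signed"`), forms the
#' cumulative area by trapezoidal integration, and returns the time at which
#' it crosses `fal_fraction` of the total area, linearly interpolated
#' between samples.
#'
#' @param waveform Single-channel `erp_waveform`.
#' @param spec A [measure_spec()].
#' @return Latency in ms.
#' @export
fractional_area_latency <- function(waveform, spec) {
  fal <- fal_core(wf_single_channel(waveform), waveform$times, spec)
  if (is.na(fal)) {
    stop(sprintf("no %s-polarity area for %s in window [%g, %g] ms",
                 spec$polarity, spec$component, spec$window[1],
                 spec$window[2]), call. = FALSE)
  }
  fal
}

# FAL without the error contract: NA when the (rectified) area vanishes.
fal_core <- function(x, times, spec) {
  idx <- wf_window_index(times, spec$window)
  sgn <- if (spec$polarity == "positive") 1 else -1
  r <- sgn * x[idx]
  if (spec$area == "rectified") r <- pmax(r, 0)
  tt <- times[idx]
  n <- length(r)
  cum <- c(0, cumsum((r[-1] + r[-n]) / 2 * diff(tt)))
  total <- cum[n]
  if (total <= 0) return(NA_real_)
  target <- spec$fal_fraction * total
  k <- which(cum >= target)[1]
  if (k == 1) return(tt[1])
  # linear interpolation of the cumulative-area curve between samples
  tt[k - 1] + (target - cum[k - 1]) / (cum[k] - cum[k - 1]) * (tt[k] - tt[k - 1])
}

#' Windowed mean amplitude
#'
#' Mean of the waveform over the closed window `[center - halfwidth,
#' center + halfwidth]`, computed as the integral of the piecewise-linear
#' waveform over the (possibly fractional) window divided by its width, so
#' a linear ramp returns exactly its value at `center`.
#'
#' @param waveform Single-channel `erp_waveform`.
#' @param center Window centre in ms (e.g. an individual FAL).
#' @param halfwidth Half-width in ms.
#' @return Mean amplitude in uV.
#' @export
windowed_mean_amplitude <- function(waveform, center, halfwidth = 10) {
  x <- wf_single_channel(waveform)
  tt <- waveform$times
  a <- center - halfwidth
  b <- center + halfwidth
  if (a < tt[1] || b > tt[length(tt)]) {
    stop(sprintf(
      "mean-amplitude window [%.1f, %.1f] ms exceeds the epoch [%g, %g] ms",
      a, b, tt[1], tt[length(tt)]), call. = FALSE)
  }
  interp <- function(t) {
    k <- floor(t - tt[1]) + 1
    w <- t - tt[k]
    if (w == 0 || k >= length(tt)) x[k] else (1 - w) * x[k] + w * x[k + 1]
  }
  ka <- ceiling(a - tt[1]) + 1  # first grid index strictly inside (a, b]
  kb <- floor(b - tt[1]) + 1    # last grid index inside [a, b)
  # integral over [a, b] of the piecewise-linear interpolant
  area <- 0
  if (tt[ka] > a) area <- area + (interp(a) + x[ka]) / 2 * (tt[ka] - a)
  if (kb > ka) area <- area + sum((x[ka:(kb - 1)] + x[(ka + 1):kb]) / 2)
  if (b > tt[kb]) area <- area + (x[kb] + interp(b)) / 2 * (b - tt[kb])
  area / (b - a)
}

#' Measure one component on a single-channel waveform
#'
#' Applies the spec's method: `"peak"` gives peak amplitude/latency,
#' `"fal"` gives the fractional-area latency and the windowed mean
#' amplitude around it.
#'
#' With `absent = "error"` (default) a waveform without any area of the
#' stated polarity raises the no-component error of
#' [fractional_area_latency()]. The cohort pipeline uses
#' `absent = "midpoint"`: such a component is treated as absent and scored
#' at the window midpoint (the windowed mean there as its amplitude),
#' keeping jackknife score vectors complete when a cell's true response is
#' essentially zero.
#'
#' @param waveform Single-channel `erp_waveform` (already grid-averaged).
#' @param spec A [measure_spec()].
#' @param absent `"error"` or `"midpoint"` (FAL measures only).
#' @return List with `component`, `amplitude`, `latency`, `method` (and
#'   `low_confidence` for peaks, `absent` for the midpoint fallback).
#' @export
measure_component <- function(waveform, spec,
                              absent = c("error", "midpoint")) {
  absent <- match.arg(absent)
  if (spec$method == "peak") {
    peak_measure(waveform, spec)
  } else {
    fal <- if (absent == "midpoint") {
      fal_core(wf_single_channel(waveform), waveform$times, spec)
    } else {
      fractional_area_latency(waveform, spec)
    }
    is_absent <- is.na(fal)
    if (is_absent) fal <- mean(spec$window)
    list(component = spec$component,
         amplitude = windowed_mean_amplitude(waveform, fal,
                                             spec$mean_halfwidth),
         latency = fal,
         method = "fal",
         absent = is_absent)
  }
}

# Shift a waveform in time by an integer number of ms: the new waveform at
# time t equals the old one at t - shift (so a component at latency L moves
# to L + shift). Samples shifted in from outside the recorded range are
# filled with the edge value; pipeline use always shifts within a margin.
shift_waveform <- function(waveform, shift) {
  shift <- as.integer(round(shift))
  if (shift == 0) return(waveform)
  x <- waveform$data
  n <- ncol(x)
  src <- pmin(pmax(seq_len(n) - shift, 1L), n)
  waveform$data <- x[, src, drop = FALSE]
  waveform
}

# Crop a waveform to a time window [lo, hi) and optionally re-apply
# baseline correction over [base_lo, base_hi).
crop_waveform <- function(waveform, window, baseline = NULL) {
  keep <- waveform$times >= window[1] & waveform$times < window[2]
  waveform$data <- waveform$data[, keep, drop = FALSE]
  waveform$times <- waveform$times[keep]
  if (!is.null(baseline)) {
    b <- waveform$times >= baseline[1] & waveform$times < baseline[2]
    waveform$data <- waveform$data -
      rowMeans(waveform$data[, b, drop = FALSE])
  }
  waveform
}
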
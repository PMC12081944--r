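# Cohort-level containers and the measurement chain shared by the full EEG
# pipeline and the waveform-level simulator.

ENVS <- c("real", "virtual")
DIMS <- c("azimuth", "distance")

#' Construct a cohort trace container
#'
#' Grid-averaged per-participant traces feeding component measurement:
#' target-dimension ERPs on the frontocentral grid (P1/N1/P2) and
#' target-minus-standard difference waves on the MMN and P3b grids.
#'
#' @param times Time axis in ms.
#' @param participants Data frame with `participant` and `age`.
#' @param target_p1,diff_mmn,diff_p3b Arrays `[participant, environment,
#'   dimension, time]` (environments real/virtual, dimensions
#'   azimuth/distance).
#' @return An object of class `cohort_traces`.
#' @export
cohort_traces <- function(times, participants, target_p1, diff_mmn,
                          diff_p3b) {
  for (a in list(target_p1, diff_mmn, diff_p3b)) {
    stopifnot(length(dim(a)) == 4, dim(a)[1] == nrow(participants),
              dim(a)[2] == 2, dim(a)[3] == 2, dim(a)[4] == length(times))
  }
  structure(list(times = times, participants = participants,
                 target_p1 = target_p1, diff_mmn = diff_mmn,
                 diff_p3b = diff_p3b),
            class = "cohort_traces")
}

trace_array_for <- function(traces, component) {
  switch(component,
         P1 = , N1 = , P2 = traces$target_p1,
         MMN = traces$diff_mmn,
         P3b = traces$diff_p3b,
         stop("unknown component: ", component))
}

# Measure chain on a single trace vector (already grid-averaged). Uses the
# midpoint fallback so absent components yield defined scores.
measure_trace <- function(vec, times, spec) {
  measure_component(erp_waveform(vec, times), spec, absent = "midpoint")
}

#' Jackknife component scores for a whole cohort
#'
#' For every component, environment and dimension cell, computes
#' leave-one-participant-out scores (within age group) of the component's
#' measure chain: grid average (already applied in the traces), then peak
#' (P1/N1/P2 amplitude) or 50% fractional-area latency plus 20-ms windowed
#' mean amplitude (MMN/P3b).
#'
#' @param traces A [cohort_traces()].
#' @param specs Measurement specs, see [default_measure_specs()].
#' @return Long data frame of jackknife scores: `component`, `measure`
#'   (amplitude/latency), `participant`, `age`, `environment`, `dimension`,
#'   `score`.
#' @export
measure_cohort <- function(traces, specs = default_measure_specs()) {
  parts <- traces$participants
  out <- list()
  n <- nrow(parts)
  for (spec in specs) {
    arr <- trace_array_for(traces, spec$component)
    kinds <- if (spec$method == "peak") "amplitude" else
      c("amplitude", "latency")
    for (ei in seq_along(ENVS)) for (di in seq_along(DIMS)) {
      waves <- arr[, ei, di, ]
      # leave-one-out averages within age group, measured once each
      amp <- lat <- numeric(n)
      for (g in unique(parts$age)) {
        idx <- which(parts$age == g)
        if (length(idx) < 3) {
          stop("jackknife groups need at least 3 participants",
               call. = FALSE)
        }
        tot <- colSums(waves[idx, , drop = FALSE])
        for (i in idx) {
          m <- measure_trace((tot - waves[i, ]) / (length(idx) - 1),
                             traces$times, spec)
          amp[i] <- m$amplitude
          lat[i] <- m$latency
        }
      }
      for (kind in kinds) {
        out[[length(out) + 1L]] <- data.frame(
          component = spec$component, measure = kind,
          participant = parts$participant, age = parts$age,
          environment = ENVS[ei], dimension = DIMS[di],
          score = if (kind == "amplitude") amp else lat,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Grand-average component measures per design cell
#'
#' Measures each component on the unweighted participant-mean trace of
#' every age x environment x dimension cell.
#'
#' @param traces A [cohort_traces()].
#' @param specs Measurement specs.
#' @return Data frame: component, age, environment, dimension, amplitude,
#'   latency, n.
#' @export
grand_measures <- function(traces, specs = default_measure_specs()) {
  parts <- traces$participants
  out <- list()
  for (spec in specs) {
    arr <- trace_array_for(traces, spec$component)
    for (ag in unique(parts$age)) {
      sel <- parts$age == ag
      for (ei in seq_along(ENVS)) for (di in seq_along(DIMS)) {
        avg <- colMeans(arr[sel, ei, di, , drop = FALSE][, 1, 1, ])
        m <- measure_trace(avg, traces$times, spec)
        out[[length(out) + 1L]] <- data.frame(
          component = spec$component, age = ag, environment = ENVS[ei],
          dimension = DIMS[di], amplitude = m$amplitude,
          latency = m$latency, n = sum(sel), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Run the full inference battery on cohort scores
#'
#' Per component and measure: jackknife-corrected mixed ANOVA, post hoc
#' real-vs-virtual t-tests per age group and dimension (BH-FDR within the
#' component's family) and JZS Bayes factors on the corrected paired t.
#'
#' @param scores Long score table from [measure_cohort()].
#' @param bf_rscale Cauchy prior scale for the Bayes factors.
#' @return List with `anova` (one table per component:measure) and
#'   `environment_contrasts` (post hoc + BF table shaped like the
#'   real-vs-virtual comparison matrix).
#' @export
infer_cohort <- function(scores, bf_rscale = sqrt(2) / 2) {
  keys <- unique(scores[, c("component", "measure")])
  anovas <- list()
  posthocs <- list()
  for (i in seq_len(nrow(keys))) {
    comp <- keys$component[i]; kind <- keys$measure[i]
    sub <- scores[scores$component == comp & scores$measure == kind, ]
    anovas[[paste(comp, kind, sep = ":")]] <- corrected_mixed_anova(sub)
    ages <- unique(sub$age)
    contrasts <- list()
    for (ag in ages) for (d in DIMS) {
      contrasts[[length(contrasts) + 1L]] <- list(
        name = sprintf("real vs virtual | %s %s", d, ag),
        a = list(age = ag, environment = "real", dimension = d),
        b = list(age = ag, environment = "virtual", dimension = d))
    }
    ph <- corrected_posthoc_t(sub, contrasts)
    ph$component <- comp
    ph$measure <- kind
    ph$bf10 <- vapply(seq_len(nrow(ph)), function(j) {
      jzs_bf_one_sample(ph$t[j], n = ph$df[j] + 1, r = bf_rscale)$bf10
    }, numeric(1))
    ph$bf_category <- vapply(ph$bf10, classify_bf, character(1))
    posthocs[[length(posthocs) + 1L]] <- ph
  }
  list(anova = anovas,
       environment_contrasts = do.call(rbind, posthocs))
}

# ---------------------------------------------------------------------------
# Waveform-level cohort simulator: draws the per-participant grid traces
# directly (component bumps + smooth residual noise emulating the
# trial-averaged EEG noise left after preprocessing), skipping continuous
# EEG synthesis. Used for the calibration studies (type-I error, effect-sign
# recovery), where thousands of cohorts are needed; the full-EEG path is
# exercised by the recovery tests.

# Smooth residual noise: iid knots every `spacing` ms, linearly
# interpolated, scaled so the marginal per-sample SD equals `sd`.
smooth_noise <- function(times, sd, spacing = 15) {
  if (sd == 0) return(numeric(length(times)))
  k0 <- times[1] - spacing
  n_knots <- ceiling((times[length(times)] - k0) / spacing) + 2
  y <- stats::rnorm(n_knots, 0, sd * sqrt(3 / 2))
  p <- (times - k0) / spacing
  k <- floor(p)
  w <- p - k
  (1 - w) * y[k + 1] + w * y[k + 2]
}

#' Simulate per-participant ERP traces without continuous EEG
#'
#' Fast emulation of the full pipeline's output: per participant,
#' environment and dimension it realizes the ground-truth component
#' parameters (subject intercepts, cell jitter, latency jitter), renders
#' target-ERP traces (P1+N1+P2) and difference-wave traces (MMN, P3b) on
#' their grids, and adds smooth residual noise with the amplitude the full
#' pipeline leaves after trial averaging. Latency alignment is assumed
#' perfect (no technical offsets are injected).
#'
#' @param truth An `oddball_truth`.
#' @param n_per_group Participants per age group.
#' @param seed Optional integer seed.
#' @param resid_sd Named per-trace residual noise SDs in uV
#'   (`target_p1`, `diff_mmn`, `diff_p3b`); defaults were measured from the
#'   full generator's signal-free trace windows at default noise level and
#'   trial counts (see the methods vignette).
#' @param times Trace time axis in ms.
#' @param traces Which trace families to render (any of `"target_p1"`,
#'   `"diff_mmn"`, `"diff_p3b"`); the others are left zero. Restricting
#'   them speeds up large calibration studies.
#' @return A [cohort_traces()].
#' @export
simulate_measure_cohort <- function(truth, n_per_group = 22, seed = NULL,
                                    resid_sd = c(target_p1 = 0.19,
                                                 diff_mmn = 0.10,
                                                 diff_p3b = 0.18),
                                    times = seq(-200, 999),
                                    traces = c("target_p1", "diff_mmn",
                                               "diff_p3b")) {
  if (!is.null(seed)) set.seed(seed)
  n <- 2L * n_per_group
  parts <- data.frame(participant = seq_len(n),
                      age = rep(c("younger", "older"), each = n_per_group),
                      stringsAsFactors = FALSE)
  eff <- draw_participant_effects(truth, n)
  nt <- length(times)
  target_p1 <- array(0, c(n, 2, 2, nt))
  diff_mmn <- array(0, c(n, 2, 2, nt))
  diff_p3b <- array(0, c(n, 2, 2, nt))
  for (i in seq_len(n)) {
    for (ei in seq_along(ENVS)) {
      params <- session_component_params(truth, parts$age[i], ENVS[ei],
                                         eff$amplitude[i, ])
      for (di in seq_along(DIMS)) {
        if ("target_p1" %in% traces) {
          early <- params[params$dimension == "all", ]
          v <- numeric(nt)
          for (j in seq_len(nrow(early))) {
            v <- v + bump_trace(times, early$lat_realized[j],
                                early$width[j], early$peak[j])
          }
          target_p1[i, ei, di, ] <- v +
            smooth_noise(times, resid_sd[["target_p1"]])
        }
        if ("diff_mmn" %in% traces) {
          mm <- params[params$component == "MMN" &
                         params$dimension == DIMS[di], ]
          diff_mmn[i, ei, di, ] <-
            bump_trace(times, mm$lat_realized, mm$width, mm$peak) +
            smooth_noise(times, resid_sd[["diff_mmn"]])
        }
        if ("diff_p3b" %in% traces) {
          p3 <- params[params$component == "P3b" &
                         params$dimension == DIMS[di], ]
          diff_p3b[i, ei, di, ] <-
            bump_trace(times, p3$lat_realized, p3$width, p3$peak) +
            smooth_noise(times, resid_sd[["diff_p3b"]])
        }
      }
    }
  }
  cohort_traces(times, parts, target_p1, diff_mmn, diff_p3b)
}
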
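# End-to-end study orchestration: simulate -> preprocess -> align ->
# measure -> infer, reproducible from config + seed.

#' Study run configuration
#'
#' Bundles every tunable of the pipeline. The defaults are the full-scale
#' study: 22 participants per age group, two sessions (real, virtual) each,
#' 900-trial sequences, 64-channel synthesis, the default ground truth and
#' measurement specs.
#'
#' @param n_per_group Participants per age group.
#' @param sequence A [sequence_spec()].
#' @param truth An `oddball_truth` table.
#' @param filters List of [fir_spec()]s.
#' @param epoch An [epoch_spec()].
#' @param margin Epoch margin (ms) retained for alignment shifts.
#' @param reject_threshold Amplitude rejection threshold, uV.
#' @param min_trials Minimum trials per analysis cell (warning below).
#' @param measures Measurement specs, see [default_measure_specs()].
#' @param alignment_window P1 search window for alignment, ms.
#' @param montage Channel names of the synthesized cap.
#' @param keep_channels Channels carried through preprocessing (`NULL` =
#'   union of the analysis grids; average reference always uses the full
#'   montage).
#' @param lead_in First onset time, ms.
#' @param duration_pad Recording tail after the last onset, ms.
#' @return An object of class `run_config`.
#' @export
run_config <- function(n_per_group = 22,
                       sequence = sequence_spec(),
                       truth = ground_truth_default(),
                       filters = default_filters(),
                       epoch = epoch_spec(),
                       margin = 32,
                       reject_threshold = 100,
                       min_trials = 20,
                       measures = default_measure_specs(),
                       alignment_window = c(30, 90),
                       montage = montage_64(),
                       keep_channels = NULL,
                       lead_in = 4000,
                       duration_pad = 4800) {
  structure(list(
    n_per_group = as.integer(n_per_group), sequence = sequence,
    truth = truth, filters = filters, epoch = epoch, margin = margin,
    reject_threshold = reject_threshold, min_trials = min_trials,
    measures = measures, alignment_window = alignment_window,
    montage = montage, keep_channels = keep_channels, lead_in = lead_in,
    duration_pad = duration_pad
  ), class = "run_config")
}

#' Validate a run configuration
#'
#' Checks sequence feasibility, window containment, grid channel existence
#' and probability ranges, and lists every defaulted (source-unstated)
#' parameter of the pipeline.
#'
#' @param config A [run_config()].
#' @return List with `valid` (logical), `violations` (character vector) and
#'   `defaults` (data frame naming substituted parameters and their
#'   values).
#' @export
validate_config <- function(config) {
  v <- character()
  if (!isTRUE(sequence_feasible(config$sequence, quiet = TRUE))) {
    v <- c(v, "stimulus sequence specification is infeasible")
  }
  ep <- config$epoch
  if (ep$baseline[1] < ep$window[1] || ep$baseline[2] > ep$window[2]) {
    v <- c(v, "baseline window outside the epoch window")
  }
  for (ms in config$measures) {
    if (ms$window[1] < ep$window[1] || ms$window[2] >= ep$window[2]) {
      v <- c(v, sprintf("%s measurement window [%g, %g] outside the epoch",
                        ms$component, ms$window[1], ms$window[2]))
    }
    miss <- setdiff(ms$grid, config$montage)
    if (length(miss)) {
      v <- c(v, sprintf("%s grid channel(s) missing from montage: %s",
                        ms$component, paste(miss, collapse = ", ")))
    }
  }
  if (any(config$truth$accuracy$p <= 0 | config$truth$accuracy$p >= 1)) {
    v <- c(v, "accuracy probabilities outside (0, 1)")
  }
  if (config$reject_threshold <= 0) {
    v <- c(v, "rejection threshold must be positive")
  }
  if (config$margin < 25) {
    v <- c(v, "epoch margin must cover the 25-ms alignment sanity bound")
  }
  defaults <- data.frame(
    parameter = c("isi_distribution", "sequence_start", "component_shape",
                  "lateral_speaker_distance", "false_alarm_rate",
                  "rejection_threshold_uV", "p1_search_window_ms",
                  "mmn_fal_window_ms", "p3b_fal_window_ms",
                  "fal_area_handling", "logit_adjustment"),
    value = c("uniform 1-ms grid over the ISI range",
              "leading standard run of min_gap..max_gap",
              "raised-cosine bump, widths P1 30 / N1 60 / P2 120 / MMN 80 / P3b 300 ms",
              "4 m radial", sprintf("%.3g", config$truth$false_alarm),
              sprintf("%.3g", config$reject_threshold),
              sprintf("[%g, %g]", config$alignment_window[1],
                      config$alignment_window[2]),
              "[100, 300]", "[250, 900]",
              "half-wave rectified to component polarity",
              "(k + 0.5) / (n + 1)"),
    stringsAsFactors = FALSE
  )
  list(valid = length(v) == 0, violations = v, defaults = defaults)
}

# Process one session (participant x environment) and return a compact
# summary: per-position margin-epoch averages, behavioral aggregates and
# selection bookkeeping. This is a fused, streaming implementation of
# simulate -> filter -> re-reference -> epoch/baseline -> select -> exclude
# -> reject -> per-cell average, numerically identical to chaining the
# module functions (asserted in the test suite) but allocation-light enough
# for full-scale cohorts.
process_session <- function(participant, age, environment, config, seed,
                            amp_intercepts, ability, precomp) {
  set.seed(seed)
  events <- generate_sequence(config$sequence, lead_in = config$lead_in)
  events <- simulate_behavior(events, config$truth, environment,
                              ability = ability)
  truth <- config$truth
  # identical RNG draw order as synthesize_session_filtered
  params <- session_component_params(truth, age, environment, amp_intercepts)
  ns <- as.integer(max(events$onset) + config$duration_pad)

  keep <- config$keep_channels
  if (is.null(keep)) {
    keep <- unique(unlist(lapply(config$measures, `[[`, "grid")))
  }
  nk <- length(keep)
  n_rest <- length(config$montage) - nk

  # filtered component signal traces, one per source topography
  sigs <- list()
  wsig <- list()
  for (i in seq_len(nrow(params))) {
    row <- params[i, ]
    onsets <- component_onsets(row, events, truth, environment)
    trace <- place_template(ns, onsets,
                            filtered_template(row, precomp$kernel))
    g <- row$grid
    if (is.null(sigs[[g]])) {
      sigs[[g]] <- trace
      wsig[[g]] <- component_topography(row$component, config$montage)[keep]
    } else {
      sigs[[g]] <- sigs[[g]] + trace
    }
  }

  # trial bookkeeping (fixed pipeline order)
  times <- seq(config$epoch$window[1] - config$margin,
               config$epoch$window[2] + config$margin - 1)
  nt <- length(times)
  onset_samp <- as.integer(round(events$onset))  # t0 = 1: sample == time
  in_bounds <- onset_samp + times[1] >= 1L & onset_samp + times[nt] <= ns
  n_incorrect <- sum(in_bounds & !events$correct)
  n_flagged <- sum(in_bounds & events$correct &
                     events$is_first_post_target_standard)
  cand <- in_bounds & events$correct & !events$is_first_post_target_standard
  cand_events <- events[cand, , drop = FALSE]
  ncand <- nrow(cand_events)
  idx <- outer(onset_samp[cand], as.integer(times), "+")
  bsel <- times >= config$epoch$baseline[1] & times < config$epoch$baseline[2]
  gather <- function(v) {
    M <- v[idx]
    dim(M) <- dim(idx)
    M
  }

  # filtered 1/f noise, epoched channel-by-channel as it is generated (the
  # continuous traces are never all held at once); the montage channels
  # outside `keep` enter only through the average reference and are drawn
  # as one aggregate trace with sd * sqrt(n_rest)
  arr <- array(0, c(ncand, nt, nk))
  refsum <- numeric(ns)
  if (!is.null(precomp$spectrum)) {
    ci <- 1L
    while (ci <= nk + 1L) {
      pair <- noise_from_spectrum(ns, min(2L, nk + 2L - ci),
                                  precomp$spectrum, precomp$active)
      for (j in seq_len(nrow(pair))) {
        if (ci + j - 1L <= nk) {
          refsum <- refsum + pair[j, ]
          arr[, , ci + j - 1L] <- gather(pair[j, ])
        } else {
          refsum <- refsum + pair[j, ] * sqrt(max(n_rest, 0))
        }
      }
      ci <- ci + nrow(pair)
    }
  }
  m_ref <- gather(refsum / length(config$montage))
  m_sig <- lapply(sigs, gather)

  bad <- rep(FALSE, ncand)
  thr <- config$reject_threshold
  for (ci in seq_len(nk)) {
    M <- arr[, , ci] - m_ref
    for (g in names(sigs)) {
      if (wsig[[g]][ci] != 0) M <- M + wsig[[g]][ci] * m_sig[[g]]
    }
    M <- M - rowMeans(M[, bsel, drop = FALSE])
    bad <- bad | rowSums(M > thr | M < -thr) > 0
    arr[, , ci] <- M
  }

  positions <- c(config$sequence$standard_label,
                 config$sequence$target_labels)
  cells <- lapply(positions, function(p) {
    sel <- cand_events$position == p & !bad
    if (!any(sel)) stop(sprintf("empty design cell %s/%s/%s", participant,
                                environment, p), call. = FALSE)
    erp_waveform(t(colMeans(arr[sel, , , drop = FALSE], dims = 1)),
                 times, keep, n_trials = sum(sel),
                 labels = list(participant = participant, age = age,
                               environment = environment, position = p))
  })
  names(cells) <- positions

  counts <- c(nrow(events), sum(in_bounds), sum(!in_bounds), n_incorrect,
              n_flagged, sum(bad), ncand - sum(bad))
  list(participant = participant, age = age, environment = environment,
       cells = cells, behavior = aggregate_behavior(events),
       counts = counts,
       count_names = c("events", "epochs", "epoch_out_of_bounds",
                       "incorrect", "first_post_target_standard",
                       "amplitude", "retained"))
}

# Trial-count weighted mean of a list of waveforms (equals pooling their
# underlying trials).
pool_waveforms <- function(wfs) {
  w <- vapply(wfs, function(x) x$n_trials, numeric(1))
  data <- Reduce(`+`, Map(function(x, wi) x$data * wi, wfs, w)) / sum(w)
  out <- wfs[[1]]
  out$data <- data
  out$n_trials <- sum(w)
  out
}

#' Run the full synthetic oddball study
#'
#' Simulates the cohort (each participant contributes one real and one
#' virtual session), preprocesses every session (filter, average reference,
#' epoch/baseline, correct-trials-only, first-post-target exclusion,
#' amplitude rejection), derives the pooled P1 reference latency and the
#' per-cell alignment shifts, re-epochs with aligned markers, forms
#' dimension-pooled target ERPs and difference waves, measures all
#' components (jackknifed and grand-average), and runs the corrected
#' ANOVAs, post hoc tests, Bayes factors and the behavioral logit analysis.
#'
#' @param config A [run_config()].
#' @param seed Master seed; expands to per-session substreams.
#' @return An object of class `oddball_study`.
#' @export
run_study <- function(config = run_config(), seed = 1) {
  val <- validate_config(config)
  if (!val$valid) {
    stop("invalid configuration:\n  ",
         paste(val$violations, collapse = "\n  "), call. = FALSE)
  }
  t_start <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(label, t0) {
    timings[[label]] <<- proc.time()[["elapsed"]] - t0
    proc.time()[["elapsed"]]
  }

  set.seed(seed)
  n <- 2L * config$n_per_group
  parts <- data.frame(participant = seq_len(n),
                      age = rep(c("younger", "older"),
                                each = config$n_per_group),
                      stringsAsFactors = FALSE)
  session_seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * n),
                          nrow = n)
  eff <- draw_participant_effects(config$truth, n)

  # worst-case recording length fixes the FFT size for all sessions
  ns_max <- config$lead_in + (config$sequence$n_total - 1L) *
    (config$sequence$stimulus_duration + config$sequence$isi_range[2]) +
    config$duration_pad
  precomp <- fast_precompute(ns_max, config$filters,
                             noise_sd = config$truth$noise_sd,
                             noise_exponent = config$truth$noise_exponent)

  t0 <- proc.time()[["elapsed"]]
  sessions <- vector("list", 2L * n)
  k <- 0L
  for (i in seq_len(n)) {
    for (ei in seq_along(ENVS)) {
      k <- k + 1L
      sessions[[k]] <- process_session(
        parts$participant[i], parts$age[i], ENVS[ei], config,
        seed = session_seeds[i, ei], amp_intercepts = eff$amplitude[i, ],
        ability = eff$ability[i], precomp = precomp)
    }
  }
  t0 <- tick("simulate_preprocess", t0)

  # ---- alignment ----------------------------------------------------------
  crop0 <- function(wf) crop_waveform(wf, config$epoch$window)
  all_cells <- unlist(lapply(sessions, `[[`, "cells"), recursive = FALSE)
  pooled <- crop0(pool_waveforms(all_cells))
  p1_grid <- config$measures$P1$grid
  reference <- reference_p1_latency(pooled, grid = p1_grid,
                                    window = config$alignment_window)
  cell_key <- function(s, p) paste(s$environment, s$age, p, sep = "|")
  groups <- list()
  for (s in sessions) for (p in names(s$cells)) {
    key <- cell_key(s, p)
    groups[[key]] <- c(groups[[key]], list(s$cells[[p]]))
  }
  cell_wfs <- lapply(groups, function(g) crop0(pool_waveforms(g)))
  report <- cell_shifts(cell_wfs, reference, grid = p1_grid,
                        window = config$alignment_window,
                        max_shift = config$margin - 1)
  t0 <- tick("alignment", t0)

  # ---- aligned traces -----------------------------------------------------
  times <- seq(config$epoch$window[1], config$epoch$window[2] - 1)
  nt <- length(times)
  target_p1 <- array(0, c(n, 2, 2, nt))
  diff_mmn <- array(0, c(n, 2, 2, nt))
  diff_p3b <- array(0, c(n, 2, 2, nt))
  grids <- list(p1 = config$measures$P1$grid,
                mmn = config$measures$MMN$grid,
                p3b = config$measures$P3b$grid)
  low_n <- character()
  for (s in sessions) {
    i <- s$participant
    ei <- match(s$environment, ENVS)
    shifted <- lapply(names(s$cells), function(p) {
      sh <- report_shift(report, s$environment, s$age, p)
      crop_waveform(shift_waveform(s$cells[[p]], sh), config$epoch$window,
                    baseline = config$epoch$baseline)
    })
    names(shifted) <- names(s$cells)
    standard <- shifted[[config$sequence$standard_label]]
    for (di in seq_along(DIMS)) {
      pos <- dimension_positions(DIMS[di])
      target <- pool_waveforms(shifted[pos])
      if (target$n_trials < config$min_trials) {
        low_n <- c(low_n, sprintf("%s/%s/%s (%d trials)", i, s$environment,
                                  DIMS[di], target$n_trials))
      }
      diff <- difference_wave(target, standard)
      target_p1[i, ei, di, ] <- drop(grid_average(target, grids$p1)$data)
      diff_mmn[i, ei, di, ] <- drop(grid_average(diff, grids$mmn)$data)
      diff_p3b[i, ei, di, ] <- drop(grid_average(diff, grids$p3b)$data)
    }
  }
  if (length(low_n)) {
    warning("cells below the minimum trial count: ",
            paste(low_n, collapse = "; "), call. = FALSE)
  }
  traces <- cohort_traces(times, parts, target_p1, diff_mmn, diff_p3b)
  t0 <- tick("traces", t0)

  # ---- measurement and inference -----------------------------------------
  grand <- grand_measures(traces, config$measures)
  scores <- measure_cohort(traces, config$measures)
  inference <- infer_cohort(scores)
  t0 <- tick("measure_infer", t0)

  behavior_tab <- do.call(rbind, lapply(sessions, function(s) {
    cbind(data.frame(participant = s$participant, age = s$age,
                     environment = s$environment, stringsAsFactors = FALSE),
          s$behavior)
  }))
  behavior <- behavior_analysis(behavior_tab)
  t0 <- tick("behavior", t0)

  counts <- do.call(rbind, lapply(sessions, function(s) {
    d <- as.data.frame(as.list(stats::setNames(s$counts, s$count_names)))
    cbind(data.frame(participant = s$participant, age = s$age,
                     environment = s$environment, stringsAsFactors = FALSE),
          d)
  }))
  manifest <- list(
    package_version = as.character(utils::packageVersion("oddballerp")),
    seed = seed,
    config_hash = config_hash(config),
    n_participants = n,
    n_sessions = 2L * n,
    counts = counts,
    timings = timings,
    total_elapsed = proc.time()[["elapsed"]] - t_start
  )

  structure(list(config = config, seed = seed, participants = parts,
                 reference_latency = reference, alignment = report,
                 traces = traces, grand = grand, scores = scores,
                 anova = inference$anova,
                 environment_contrasts = inference$environment_contrasts,
                 behavior = behavior, manifest = manifest),
            class = "oddball_study")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::serializeJSON(config, digits = 10), f)
  unname(tools::md5sum(f))
}

#' @export
print.oddball_study <- function(x, ...) {
  cat(sprintf("Oddball ERP study: %d participants (2 x %d), seed %d\n",
              nrow(x$participants), x$config$n_per_group, x$seed))
  cat(sprintf("P1 reference latency: %g ms; mean shift real %.2f ms, virtual %.2f ms\n",
              x$reference_latency,
              x$alignment$summary$mean[x$alignment$summary$environment == "real"],
              x$alignment$summary$mean[x$alignment$summary$environment == "virtual"]))
  cat(sprintf("Elapsed: %.1f s\n", x$manifest$total_elapsed))
  cat("Components measured:",
      paste(unique(x$grand$component), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.oddball_study <- function(object, ...) {
  structure(list(study = object), class = "summary.oddball_study")
}

#' @export
print.summary.oddball_study <- function(x, ...) {
  s <- x$study
  print(s)
  cat("\n-- Grand-average component measures (mean over cells) --\n")
  agg <- stats::aggregate(cbind(amplitude, latency) ~ component + dimension,
                          data = s$grand, FUN = mean)
  print(agg, row.names = FALSE)
  cat("\n-- Jackknife-corrected mixed ANOVAs --\n")
  for (nm in names(s$anova)) {
    cat(nm, "\n")
    tab <- s$anova[[nm]]
    tab$F <- round(tab$F, 2); tab$p <- signif(tab$p, 3)
    tab$eta_p <- round(tab$eta_p, 3)
    print(tab[, c("effect", "F", "df1", "df2", "p", "eta_p")],
          row.names = FALSE)
  }
  cat("\n-- Real vs virtual contrasts (corrected t, BH-FDR, JZS BF) --\n")
  ec <- s$environment_contrasts
  ec$t <- round(ec$t, 2); ec$p_fdr <- signif(ec$p_fdr, 3)
  ec$bf10 <- signif(ec$bf10, 3)
  print(ec[, c("component", "measure", "contrast", "t", "p_fdr", "bf10",
               "bf_category")], row.names = FALSE)
  cat("\n-- Behavior (logit ANOVA) --\n")
  print(s$behavior$anova, row.names = FALSE)
  invisible(x)
}

#' @export
plot.oddball_study <- function(x, what = c("difference", "target"), ...) {
  what <- match.arg(what)
  tr <- x$traces
  arr <- if (what == "difference") tr$diff_mmn else tr$target_p1
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (di in 1:2) {
    real <- colMeans(arr[, 1, di, ])
    virt <- colMeans(arr[, 2, di, ])
    graphics::plot(tr$times, real, type = "l", col = "black",
                   xlab = "time (ms)", ylab = "amplitude (uV)",
                   main = paste(what, DIMS[di]),
                   ylim = range(real, virt))
    graphics::lines(tr$times, virt, lty = 2, col = "grey40")
    graphics::abline(v = 0, h = 0, col = "grey80")
    graphics::legend("topright", c("real", "virtual"), lty = 1:2,
                     col = c("black", "grey40"), bty = "n")
  }
  invisible(x)
}
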
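# Constrained oddball stimulus sequences.

#' Specification of an oddball stimulus sequence
#'
#' Defaults reproduce the spatial-oddball design: 900 trials, four target
#' positions with 54 trials each (216 targets, 24%), the remaining 684 trials
#' (76%) standards at the centre position, every target followed by 2-6
#' standards, 500-ms stimuli separated by interstimulus intervals drawn
#' uniformly from 1300-1700 ms at 1-ms resolution.
#'
#' @param n_total Total number of trials.
#' @param n_per_target Trials per target position.
#' @param target_labels Target position labels.
#' @param min_gap,max_gap Minimum/maximum number of standards after each
#'   target (also bounds the leading run of standards).
#' @param isi_range Interstimulus interval range in ms (uniform, 1-ms grid).
#' @param stimulus_duration Stimulus duration in ms (enters event timing
#'   only; audio is not synthesized).
#' @param standard_label Label of the standard position.
#' @return An object of class `sequence_spec`.
#' @export
sequence_spec <- function(n_total = 900, n_per_target = 54,
                          target_labels = c("left", "right", "near", "far"),
                          min_gap = 2, max_gap = 6,
                          isi_range = c(1300, 1700),
                          stimulus_duration = 500,
                          standard_label = "center") {
  spec <- structure(list(
    n_total = as.integer(n_total),
    n_per_target = as.integer(n_per_target),
    target_labels = as.character(target_labels),
    min_gap = as.integer(min_gap), max_gap = as.integer(max_gap),
    isi_range = as.numeric(isi_range),
    stimulus_duration = as.numeric(stimulus_duration),
    standard_label = standard_label
  ), class = "sequence_spec")
  spec$n_targets <- spec$n_per_target * length(spec$target_labels)
  spec$n_standards <- spec$n_total - spec$n_targets
  spec
}

#' Check that a sequence specification is feasible
#'
#' A design is feasible when the standard budget can be tiled as a leading
#' run plus one gap of `min_gap`..`max_gap` standards after each target.
#'
#' @param spec A [sequence_spec()].
#' @return `TRUE` (invisibly) if feasible, otherwise an error (or `FALSE`
#'   with `quiet = TRUE`).
#' @param quiet Return `FALSE` instead of erroring on infeasibility.
#' @export
sequence_feasible <- function(spec, quiet = FALSE) {
  fail <- function(msg) {
    if (quiet) return(FALSE)
    stop(msg, call. = FALSE)
  }
  if (spec$n_standards < 0) return(fail("more targets than total trials"))
  if (spec$min_gap < 2 || spec$max_gap > 6 || spec$min_gap > spec$max_gap) {
    return(fail("gap bounds must satisfy 2 <= min_gap <= max_gap <= 6"))
  }
  n_runs <- spec$n_targets + 1L  # leading run + one run after each target
  lo <- n_runs * spec$min_gap
  hi <- n_runs * spec$max_gap
  if (spec$n_targets > 0 && (spec$n_standards < lo || spec$n_standards > hi)) {
    return(fail(sprintf(
      "standard budget %d cannot be tiled into %d runs of %d-%d",
      spec$n_standards, n_runs, spec$min_gap, spec$max_gap)))
  }
  invisible(TRUE)
}

#' Generate a constrained oddball sequence
#'
#' Target identities are a random permutation of the per-position budgets.
#' Standards are tiled as a leading run plus a run of `min_gap`..`max_gap`
#' standards after every target: all runs start at `min_gap` and the
#' remaining budget is distributed uniformly at random over the runs with
#' per-run cap `max_gap`. Onsets accumulate stimulus duration plus a uniform
#' integer ISI. The first standard after each target is flagged (these
#' trials are excluded from ERP averaging to avoid post-deviance
#' distraction effects).
#'
#' @param spec A [sequence_spec()].
#' @param seed Optional integer seed (uses the current RNG state if `NULL`).
#' @param lead_in Time of the first stimulus onset, ms.
#' @return An object of class `oddball_sequence`: a data frame with columns
#'   `index`, `onset` (ms), `position`, `is_target`,
#'   `is_first_post_target_standard`; the spec is attached as attribute
#'   `spec`.
#' @export
generate_sequence <- function(spec = sequence_spec(), seed = NULL,
                              lead_in = 4000) {
  sequence_feasible(spec)
  if (!is.null(seed)) set.seed(seed)

  if (spec$n_targets > 0) {
    targets <- sample(rep(spec$target_labels, each = spec$n_per_target))
    n_runs <- spec$n_targets + 1L
    extra_total <- spec$n_standards - n_runs * spec$min_gap
    cap <- spec$max_gap - spec$min_gap
    # uniform constrained composition: sample `extra_total` increment slots
    # out of n_runs * cap available
    slots <- rep.int(seq_len(n_runs), cap)
    extra <- tabulate(slots[sample.int(length(slots), extra_total)], n_runs)
    runs <- spec$min_gap + extra
    position <- character(spec$n_total)
    i <- 1L
    for (k in seq_len(n_runs)) {
      if (runs[k] > 0) {
        position[i:(i + runs[k] - 1L)] <- spec$standard_label
        i <- i + runs[k]
      }
      if (k <= spec$n_targets) {
        position[i] <- targets[k]
        i <- i + 1L
      }
    }
  } else {
    position <- rep(spec$standard_label, spec$n_total)
  }

  is_target <- position != spec$standard_label
  first_post <- c(FALSE, is_target[-spec$n_total]) & !is_target

  isi <- sample.int(spec$isi_range[2] - spec$isi_range[1] + 1L,
                    spec$n_total, replace = TRUE) + spec$isi_range[1] - 1L
  soa <- spec$stimulus_duration + isi
  onset <- lead_in + c(0, cumsum(soa[-spec$n_total]))

  ev <- data.frame(
    index = seq_len(spec$n_total),
    onset = onset,
    position = position,
    is_target = is_target,
    is_first_post_target_standard = first_post,
    stringsAsFactors = FALSE
  )
  structure(ev, class = c("oddball_sequence", "data.frame"), spec = spec)
}

# Lengths of maximal standard runs between targets (and the leading/trailing
# runs); used by tests and validate_config.
standard_run_lengths <- function(events) {
  r <- rle(!events$is_target)
  r$lengths[r$values]
}
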
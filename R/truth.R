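# Ground-truth tables driving the synthetic EEG generator.
#
# Cell means reproduce the reported condition means of the validation study
# this package re-implements: marginal means plus interaction contrasts were
# solved for a full cell-mean table per component (the derivation is laid
# out in the methods vignette, including the consistency checks on every
# reported margin). Between-subject and per-cell SDs are back-computed from
# the reported F statistics; latency jitter is deliberately small (most
# observed latency variance is attributed to single-subject measurement
# noise, see vignette).

#' Default ground-truth table for the synthetic oddball cohort
#'
#' Per design cell (age group x environment x target dimension) amplitudes
#' (uV), latencies (ms) and widths (ms) of the five ERP components, noise
#' parameters, per-environment technical onset offsets, and behavioral
#' accuracy probabilities. P1/N1/P2 occur on every trial; MMN and P3b only
#' on target trials (so they appear in target-minus-standard difference
#' waves). Deviance-component amplitudes are the value their designated
#' measure (20-ms windowed mean at the 50% fractional-area latency) returns;
#' the generator rescales bump peaks accordingly.
#'
#' @param noise_sd Per-channel SD of the broadband 1/f background noise, uV.
#' @param noise_exponent Spectral exponent beta of the 1/f^beta noise power
#'   spectrum.
#' @param onset_offset Named numeric: injected technical onset offset (ms)
#'   per environment. Positive means the sound reaches the ear after the
#'   marker.
#' @return An object of class `oddball_truth`.
#' @export
ground_truth_default <- function(noise_sd = 10, noise_exponent = 1,
                                 onset_offset = c(real = 4, virtual = -5)) {
  g <- function(component, age, environment, dimension, amplitude, latency) {
    data.frame(component = component, age = age, environment = environment,
               dimension = dimension, amplitude = amplitude,
               latency = latency, stringsAsFactors = FALSE)
  }
  ages <- c("younger", "older")
  envs <- c("real", "virtual")
  cells <- expand.grid(age = ages, environment = envs,
                       stringsAsFactors = FALSE)

  # Early components: one value per age x environment, all trials.
  p1 <- g("P1", cells$age, cells$environment, "all",
          amplitude = ifelse(cells$age == "younger", 0.88, 1.32),
          latency = 57)
  n1_amp <- c(younger.real = -0.56, older.real = -1.10,
              younger.virtual = -0.34, older.virtual = -1.30)
  n1 <- g("N1", cells$age, cells$environment, "all",
          amplitude = as.numeric(n1_amp[paste(cells$age, cells$environment,
                                              sep = ".")]),
          latency = 100)
  p2_amp <- c(younger.real = 1.525, older.real = 3.055,
              younger.virtual = 1.295, older.virtual = 2.825)
  p2 <- g("P2", cells$age, cells$environment, "all",
          amplitude = as.numeric(p2_amp[paste(cells$age, cells$environment,
                                              sep = ".")]),
          latency = 180)

  # Deviance components: one value per age x environment x dimension.
  dcells <- expand.grid(age = ages, environment = envs,
                        dimension = c("azimuth", "distance"),
                        stringsAsFactors = FALSE)
  key <- paste(dcells$age, dcells$environment, dcells$dimension, sep = ".")
  mmn_amp <- c(
    younger.real.azimuth = -1.29, older.real.azimuth = -0.96,
    younger.virtual.azimuth = -1.00, older.virtual.azimuth = -0.67,
    younger.real.distance = -0.64, older.real.distance = -0.31,
    younger.virtual.distance = -0.35, older.virtual.distance = -0.02)
  mmn_lat <- c(
    younger.real.azimuth = 135.805, older.real.azimuth = 135.805,
    younger.virtual.azimuth = 159.835, older.virtual.azimuth = 159.835,
    younger.real.distance = 177.595, older.real.distance = 177.595,
    younger.virtual.distance = 201.625, older.virtual.distance = 201.625)
  mmn <- g("MMN", dcells$age, dcells$environment, dcells$dimension,
           amplitude = as.numeric(mmn_amp[key]),
           latency = as.numeric(mmn_lat[key]))
  p3_amp <- c(
    younger.real.azimuth = 3.625, older.real.azimuth = 3.62,
    younger.virtual.azimuth = 3.335, older.virtual.azimuth = 2.54,
    younger.real.distance = 2.635, older.real.distance = 2.79,
    younger.virtual.distance = 2.345, older.virtual.distance = 2.03)
  p3_lat <- c(
    younger.real.azimuth = 447.195, older.real.azimuth = 433.395,
    younger.virtual.azimuth = 466.175, older.virtual.azimuth = 452.375,
    younger.real.distance = 537.25, older.real.distance = 563.07,
    younger.virtual.distance = 587.84, older.virtual.distance = 613.66)
  p3b <- g("P3b", dcells$age, dcells$environment, dcells$dimension,
           amplitude = as.numeric(p3_amp[key]),
           latency = as.numeric(p3_lat[key]))

  components <- rbind(p1, n1, p2, mmn, p3b)
  shape <- data.frame(
    component = c("P1", "N1", "P2", "MMN", "P3b"),
    width = c(30, 60, 120, 80, 300),
    polarity = c(1, -1, 1, -1, 1),
    grid = c("p1", "p1", "p1", "mmn", "p3b"),
    # SDs: between-subject intercept, per participant x cell jitter (uV),
    # true latency jitter (ms)
    subject_sd = c(0.79, 1.09, 1.63, 0.44, 1.00),
    cell_sd = c(0.50, 0.64, 0.78, 0.52, 1.03),
    latency_sd = c(3, 5, 8, 6, 15),
    stringsAsFactors = FALSE
  )
  components <- merge(components, shape, by = "component", sort = FALSE)

  accuracy <- data.frame(
    environment = rep(envs, each = 2),
    dimension = rep(c("azimuth", "distance"), 2),
    p = c(0.968, 0.948, 0.953, 0.922),
    stringsAsFactors = FALSE
  )

  truth <- structure(list(
    components = components,
    noise_sd = noise_sd,
    noise_exponent = noise_exponent,
    onset_offset = onset_offset,
    accuracy = accuracy,
    false_alarm = 0.01,
    behavior_subject_sd = 0.5,   # participant ability, logit scale
    behavior_cell_sd = 0.25      # cell-level ability jitter, logit scale
  ), class = "oddball_truth")
  validate_truth(truth)
  truth
}

#' Null ground-truth table
#'
#' Collapses every component's cell means (amplitude and latency) to its
#' grand mean, keeping all variability parameters. Used for type-I-error
#' calibration of the corrected statistics.
#'
#' @param truth An `oddball_truth` (default table if omitted).
#' @return An `oddball_truth` with no condition effects.
#' @export
ground_truth_null <- function(truth = ground_truth_default()) {
  comp <- truth$components
  for (cp in unique(comp$component)) {
    i <- comp$component == cp
    comp$amplitude[i] <- mean(comp$amplitude[i])
    comp$latency[i] <- mean(comp$latency[i])
  }
  acc <- truth$accuracy
  acc$p <- mean(acc$p)
  truth$components <- comp
  truth$accuracy <- acc
  truth
}

validate_truth <- function(truth) {
  comp <- truth$components
  neg <- comp$component %in% c("N1", "MMN")
  if (any(comp$amplitude[neg] > 0)) {
    stop("N1/MMN amplitudes must be <= 0", call. = FALSE)
  }
  if (any(comp$amplitude[!neg] < 0)) {
    stop("P1/P2/P3b amplitudes must be >= 0", call. = FALSE)
  }
  if (any(comp$latency < 0 | comp$latency > 1000)) {
    stop("component latencies must lie inside the epoch window", call. = FALSE)
  }
  if (any(truth$accuracy$p <= 0 | truth$accuracy$p >= 1)) {
    stop("accuracy probabilities must lie in (0, 1)", call. = FALSE)
  }
  if (truth$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.oddball_truth <- function(x, ...) {
  cat("Ground-truth table:", nrow(x$components), "component cells\n")
  cat(sprintf("noise: 1/f^%.2g, sd %.3g uV; onset offsets: %s\n",
              x$noise_exponent, x$noise_sd,
              paste(names(x$onset_offset), x$onset_offset, sep = "=",
                    collapse = ", ")))
  print(x$components[, c("component", "age", "environment", "dimension",
                         "amplitude", "latency")], row.names = FALSE)
  invisible(x)
}

# Resolve the truth rows applying to one session cell (age x environment).
# Returns the component rows; dimension "all" rows apply to every trial,
# azimuth rows to left/right targets, distance rows to near/far targets.
truth_for_cell <- function(truth, age, environment) {
  comp <- truth$components
  rows <- comp[comp$age == age & comp$environment == environment, ]
  if (nrow(rows) == 0) {
    stop(sprintf("ground truth does not cover cell %s/%s", age, environment),
         call. = FALSE)
  }
  rows
}

# Onset offset (ms) for an environment, possibly position-specific when
# truth$onset_offset is a data frame with environment/position/offset.
truth_offset <- function(truth, environment, position) {
  oo <- truth$onset_offset
  if (is.data.frame(oo)) {
    off <- numeric(length(position))
    for (i in seq_along(position)) {
      j <- which(oo$environment == environment &
                   (oo$position == position[i] | oo$position == "all"))
      if (!length(j)) stop("no onset offset for ", environment, "/",
                           position[i], call. = FALSE)
      off[i] <- oo$offset[j[1]]
    }
    off
  } else {
    if (!environment %in% names(oo)) {
      stop("no onset offset for environment ", environment, call. = FALSE)
    }
    rep(unname(oo[environment]), length(position))
  }
}

# Per-participant random effects: amplitude intercept per component (shared
# across both environment sessions) and behavioral ability.
draw_participant_effects <- function(truth, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  comps <- unique(truth$components$component)
  sds <- truth$components$subject_sd[match(comps, truth$components$component)]
  amp <- matrix(stats::rnorm(n * length(comps), 0, rep(sds, each = n)),
                nrow = n, dimnames = list(NULL, comps))
  list(amplitude = amp,
       ability = stats::rnorm(n, 0, truth$behavior_subject_sd))
}
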
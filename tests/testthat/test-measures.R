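# Brute-force oracle for the fractional-area latency: explicit scan over
# trapezoid areas with linear interpolation of the cumulative curve.
fal_oracle <- function(x, times, window, polarity, fraction,
                       area = "rectified") {
  sel <- times >= window[1] & times <= window[2]
  r <- if (polarity == "positive") x[sel] else -x[sel]
  if (area == "rectified") r[r < 0] <- 0
  tt <- times[sel]
  total <- 0
  for (i in seq_len(length(r) - 1)) {
    total <- total + (r[i] + r[i + 1]) / 2 * (tt[i + 1] - tt[i])
  }
  target <- fraction * total
  cum <- 0
  for (i in seq_len(length(r) - 1)) {
    seg <- (r[i] + r[i + 1]) / 2 * (tt[i + 1] - tt[i])
    if (cum + seg >= target) {
      return(tt[i] + (target - cum) / seg * (tt[i + 1] - tt[i]))
    }
    cum <- cum + seg
  }
  tt[length(tt)]
}

test_that("difference waves subtract element-wise and are linear", {
  set.seed(1)
  a <- erp_waveform(matrix(rnorm(20), 2), times = 0:9, channels = c("A", "B"))
  b <- erp_waveform(matrix(rnorm(20), 2), times = 0:9, channels = c("A", "B"))
  d <- difference_wave(a, b)
  expect_equal(d$data, a$data - b$data, ignore_attr = TRUE)
  expect_equal(difference_wave(a, a)$data, a$data * 0, ignore_attr = TRUE)
  # adding a common waveform to both sides leaves the difference unchanged
  c0 <- erp_waveform(matrix(rnorm(20), 2), times = 0:9,
                     channels = c("A", "B"))
  ac <- a; ac$data <- a$data + c0$data
  bc <- b; bc$data <- b$data + c0$data
  expect_equal(difference_wave(ac, bc)$data, d$data, tolerance = 1e-12)
  bad <- erp_waveform(matrix(rnorm(10), 2), times = 0:4,
                      channels = c("A", "B"))
  expect_error(difference_wave(a, bad), "share")
})

test_that("grid averaging equals the brute-force channel mean", {
  set.seed(2)
  grids <- erp_grids()
  wf <- erp_waveform(matrix(rnorm(64 * 50), 64), times = 0:49,
                     channels = montage_64())
  g <- grid_average(wf, grids$mmn)
  brute <- rep(0, 50)
  for (ch in grids$mmn) brute <- brute + wf$data[ch, ]
  expect_equal(drop(g$data), brute / length(grids$mmn), tolerance = 1e-12,
               ignore_attr = TRUE)
  # one-channel grid returns that channel; uniform topography is unchanged
  expect_equal(drop(grid_average(wf, "Cz")$data), wf$data["Cz", ],
               ignore_attr = TRUE)
  uni <- erp_waveform(matrix(1.5, 4, 10), times = 0:9,
                      channels = c("Fz", "F1", "F2", "FCz"))
  expect_equal(drop(grid_average(uni, c("Fz", "F1"))$data), rep(1.5, 10))
  expect_error(grid_average(wf, c("Fz", "nope")), "unknown channel")
})

test_that("peak measures find the stated-polarity extremum, earliest on ties", {
  x <- numeric(100)
  x[31] <- 2; x[61] <- 2         # tie: earliest wins
  x[41] <- -3
  wf <- wf1(x)
  sp_pos <- measure_spec("P", "grid", c(0, 99), "positive", "peak")
  sp_neg <- measure_spec("N", "grid", c(0, 99), "negative", "peak")
  mp <- peak_measure(wf, sp_pos)
  expect_equal(mp$amplitude, 2)
  expect_equal(mp$latency, 30)
  expect_false(mp$low_confidence)
  mn <- peak_measure(wf, sp_neg)
  expect_equal(mn$amplitude, -3)
  expect_equal(mn$latency, 40)
  # degenerate contract: no positive sample -> least-negative, flagged
  neg <- wf1(-(1:50))
  m <- peak_measure(neg, measure_spec("P", "g", c(0, 49), "positive", "peak"))
  expect_equal(m$amplitude, -1)
  expect_true(m$low_confidence)
})

test_that("fractional-area latency matches symmetry cases and the oracle", {
  # rectangular pulse spanning 100-200 ms -> FAL 150
  times <- 0:400
  x <- as.numeric(times >= 100 & times <= 200)
  sp <- measure_spec("C", "g", c(50, 350), "positive", "fal")
  expect_equal(fractional_area_latency(wf1(x, times), sp), 150)
  # symmetric bump centred at 160 -> FAL 160
  b <- oddballerp:::bump_trace(times, 160, 80, -2.5)
  spn <- measure_spec("C", "g", c(50, 350), "negative", "fal")
  expect_equal(fractional_area_latency(wf1(b, times), spn), 160,
               tolerance = 1e-9)
  # random waveforms: equality with the brute-force scan at 1e-9 ms
  set.seed(3)
  for (i in 1:25) {
    y <- cumsum(rnorm(401)) / 5 + rnorm(401)
    frac <- runif(1, 0.2, 0.8)
    pol <- sample(c("positive", "negative"), 1)
    spr <- measure_spec("C", "g", c(30, 370), pol, "fal",
                        fal_fraction = frac)
    expect_equal(fractional_area_latency(wf1(y, times), spr),
                 fal_oracle(y, times, c(30, 370), pol, frac),
                 tolerance = 1e-9)
    sps <- measure_spec("C", "g", c(30, 370), pol, "fal",
                        fal_fraction = frac, area = "signed")
    ok <- tryCatch(fractional_area_latency(wf1(y, times), sps),
                   error = function(e) NULL)
    if (!is.null(ok)) {
      expect_equal(ok, fal_oracle(y, times, c(30, 370), pol, frac,
                                  area = "signed"),
                   tolerance = 1e-9)
    }
  }
  # zero rectified area errors
  expect_error(fractional_area_latency(wf1(-x, times), sp), "no positive")
})

test_that("FAL is scale-invariant and shift-equivariant", {
  times <- 0:600
  set.seed(4)
  y <- pmax(oddballerp:::bump_trace(times, 250, 120, 1) + rnorm(601, 0, 0.05), 0)
  sp <- measure_spec("C", "g", c(100, 420), "positive", "fal")
  f0 <- fractional_area_latency(wf1(y, times), sp)
  expect_equal(fractional_area_latency(wf1(7.3 * y, times), sp), f0,
               tolerance = 1e-9)
  # shift the waveform by 50 ms and the window with it
  sh <- c(rep(0, 50), y[1:551])
  sp2 <- measure_spec("C", "g", c(150, 470), "positive", "fal")
  expect_equal(fractional_area_latency(wf1(sh, times), sp2), f0 + 50,
               tolerance = 1e-9)
})

test_that("windowed mean amplitude integrates the piecewise-linear waveform", {
  times <- 0:200
  expect_equal(windowed_mean_amplitude(wf1(rep(4.2, 201), times), 77.3, 10),
               4.2)
  # linear ramp -> value at the (fractional) centre
  ramp <- 0.5 * times - 20
  expect_equal(windowed_mean_amplitude(wf1(ramp, times), 101.37, 10),
               0.5 * 101.37 - 20, tolerance = 1e-9)
  expect_equal(windowed_mean_amplitude(wf1(ramp, times), 50, 25),
               0.5 * 50 - 20, tolerance = 1e-9)
  # clipped windows are an error, never silently truncated
  expect_error(windowed_mean_amplitude(wf1(ramp, times), 195, 10), "exceeds")
  expect_error(windowed_mean_amplitude(wf1(ramp, times), 5, 10), "exceeds")
})

test_that("noiseless bumps round-trip through the measurement chain", {
  # every component of the default table, unfiltered epochs: amplitudes to
  # 0.01 uV, latencies to 1 ms
  truth <- quiet_truth()
  specs <- default_measure_specs()
  times <- seq(-200, 999)
  for (i in seq_len(nrow(truth$components))) {
    row <- truth$components[i, ]
    peak <- row$amplitude
    if (row$component %in% c("MMN", "P3b")) {
      peak <- peak / oddballerp:::deviance_window_factor(row$width)
    }
    x <- oddballerp:::bump_trace(times, row$latency, row$width, peak)
    m <- measure_component(wf1(x, times), specs[[row$component]])
    expect_lt(abs(m$amplitude - row$amplitude), 0.01)
    expect_lt(abs(m$latency - row$latency), 1)
  }
})

test_that("grid averaging commutes with trial averaging", {
  set.seed(5)
  grids <- erp_grids()
  trials <- lapply(1:6, function(i) {
    matrix(rnorm(64 * 30), 64, dimnames = list(montage_64(), NULL))
  })
  avg <- Reduce(`+`, trials) / 6
  g_then_avg <- Reduce(`+`, lapply(trials, function(m) {
    colMeans(m[grids$p1, ])
  })) / 6
  avg_then_g <- drop(grid_average(erp_waveform(avg, 0:29), grids$p1)$data)
  expect_equal(avg_then_g, g_then_avg, tolerance = 1e-9, ignore_attr = TRUE)
})
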
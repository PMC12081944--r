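test_that("windowed-sinc FIR kernels are linear-phase with correct gains", {
  rate <- 1000
  hp <- design_fir(fir_spec("highpass", 0.25, 6601), rate)
  lp <- design_fir(fir_spec("lowpass", 33.75, 441), rate)
  # symmetric about the centre tap
  expect_equal(hp, rev(hp), tolerance = 1e-12)
  expect_equal(lp, rev(lp), tolerance = 1e-12)
  # DC gains
  expect_equal(abs(fir_response(lp, 0, rate)), 1, tolerance = 1e-3)
  expect_equal(abs(fir_response(hp, 0, rate)), 0, tolerance = 1e-3)
  # -6 dB at the cutoff (windowed-sinc convention)
  expect_equal(abs(fir_response(lp, 33.75, rate)), 0.5, tolerance = 0.01)
  expect_equal(abs(fir_response(hp, 0.25, rate)), 0.5, tolerance = 0.01)
  expect_error(design_fir(fir_spec("lowpass", 600, 441), rate), "Nyquist")
  expect_error(fir_spec("lowpass", 33.75, 440), "odd")
})

test_that("a 10-Hz sinusoid passes the filter chain within 1%", {
  rate <- 1000
  n <- 20000
  t <- seq_len(n) / rate
  x <- sin(2 * pi * 10 * t)
  rec <- oddball_recording(matrix(x, 1), channels = "Cz", srate = rate)
  out <- filter_recording(rec, default_filters())
  mid <- 8000:12000  # away from edges
  expect_equal(max(abs(out$data[1, mid])), 1, tolerance = 0.01)
  # group-delay compensation: zero-phase (no shift of the sinusoid)
  expect_lt(max(abs(out$data[1, mid] - x[mid])), 0.01)
})

test_that("average re-referencing zeroes the per-sample channel mean", {
  set.seed(6)
  d <- matrix(rnorm(8 * 500), 8)
  rec <- rereference_average(oddball_recording(d))
  expect_lt(max(abs(colMeans(rec$data))), 1e-12)
  # identical channels -> all-zero output; mean-zero input unchanged
  same <- oddball_recording(matrix(rep(rnorm(100), each = 4), 4))
  expect_equal(max(abs(rereference_average(same)$data)), 0)
  d0 <- d - rep(colMeans(d), each = 8)
  expect_equal(rereference_average(oddball_recording(d0))$data, d0,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(rereference_average(oddball_recording(matrix(1, 1, 10))),
               "2 channels")
})

test_that("epoching honours the indexing contract and baselines", {
  # constant recording -> all-zero epochs after baseline correction
  ev <- data.frame(index = 1:2, onset = c(1000, 3000), position = "center",
                   is_target = FALSE, is_first_post_target_standard = FALSE)
  rec <- oddball_recording(matrix(5, 2, 5000), t0 = 1)
  ep <- epoch_recording(rec, ev)
  expect_equal(dim(ep$data), c(2, 2, 1200))
  expect_equal(max(abs(ep$data)), 0)
  expect_equal(ep$times, seq(-200, 999))
  # a synthetic bump 57 ms after onset peaks at epoch time 57
  x <- numeric(5000)
  x[1000 + 57] <- 1  # t0 = 1: sample i is time i
  rec2 <- oddball_recording(matrix(x, 1, 5000, byrow = TRUE), t0 = 1)
  ep2 <- epoch_recording(rec2, ev[1, ])
  expect_equal(ep$times[which.max(ep2$data[1, 1, ])], 57)
  # events too close to the recording edge are dropped and logged
  ev3 <- data.frame(index = 1:2, onset = c(150, 3000), position = "center",
                    is_target = FALSE, is_first_post_target_standard = FALSE)
  ep3 <- epoch_recording(rec, ev3)
  expect_equal(dim(ep3$data)[1], 1)
  expect_equal(ep3$log$reason, "epoch_out_of_bounds")
  expect_equal(ep3$log$index, 1)
})

test_that("retained epochs have machine-zero baselines", {
  truth <- quiet_truth(noise_sd = 3)
  s <- literal_session(truth, seq_spec = small_seq(30, 2))
  ep <- s$epochs
  bsel <- ep$times >= -200 & ep$times < 0
  bmeans <- rowMeans(ep$data[, , bsel, drop = FALSE], dims = 2)
  expect_lt(max(abs(bmeans)), 1e-9)
})

test_that("trial selection keeps correct trials and logs the rest", {
  truth <- quiet_truth()
  ev <- generate_sequence(small_seq(), seed = 3)
  syn <- synthesize_participant(ev, truth, "younger", "real", seed = 4)
  ep0 <- epoch_recording(syn$recording, transform(ev, correct = TRUE))
  expect_equal(dim(select_trials(ep0)$data), dim(ep0$data))  # identity
  # all-wrong targets -> only standards remain
  ev2 <- transform(ev, correct = !ev$is_target)
  ep2 <- select_trials(epoch_recording(syn$recording, ev2))
  expect_true(all(!ep2$events$is_target))
  expect_equal(sum(ep2$log$reason == "incorrect"), sum(ev$is_target))
  # missing response record is a hard error
  ep3 <- epoch_recording(syn$recording, ev)
  expect_error(select_trials(ep3), "correct")
  expect_error(select_trials(ep0, responses = data.frame(index = 1,
                                                         correct = TRUE)),
               "missing response")
})

test_that("first post-target standards are excluded idempotently", {
  truth <- quiet_truth()
  ev <- generate_sequence(small_seq(), seed = 5)
  syn <- synthesize_participant(ev, truth, "younger", "real", seed = 6)
  ep <- epoch_recording(syn$recording, transform(ev, correct = TRUE))
  n_flag <- sum(ev$is_first_post_target_standard)
  ep1 <- exclude_post_target_standards(ep)
  expect_equal(dim(ep$data)[1] - dim(ep1$data)[1], n_flag)
  ep2 <- exclude_post_target_standards(ep1)
  expect_equal(ep2$data, ep1$data)
  expect_equal(nrow(ep2$log), nrow(ep1$log))
})

test_that("amplitude rejection removes exactly the offending trials", {
  truth <- quiet_truth(noise_sd = 5)
  s <- literal_session(truth, seq_spec = small_seq(30, 2))
  ep <- s$epochs
  expect_equal(sum(ep$log$reason == "amplitude"), 0)  # clean synthesis
  # inject a 500-uV spike into one retained trial
  ep$data[3, 5, 600] <- 500
  ep2 <- reject_by_amplitude(ep, 100)
  expect_equal(dim(ep$data)[1] - dim(ep2$data)[1], 1)
  expect_equal(ep2$log$index[ep2$log$reason == "amplitude"],
               ep$events$index[3])
  expect_error(reject_by_amplitude(ep, -5), "positive")
})

test_that("Gaussian exceedance rates match the analytic probability", {
  set.seed(7)
  n_tr <- 600; n_ch <- 2; n_t <- 40
  sd <- 40; thr <- 100
  ep <- structure(list(
    data = array(rnorm(n_tr * n_ch * n_t, 0, sd), c(n_tr, n_ch, n_t)),
    times = seq_len(n_t) - 1, channels = c("A", "B"),
    events = data.frame(index = seq_len(n_tr)),
    log = data.frame(index = integer(), reason = character())
  ), class = "erp_epochs")
  ep2 <- reject_by_amplitude(ep, thr)
  p_single <- 2 * pnorm(-thr / sd)
  p_trial <- 1 - (1 - p_single)^(n_ch * n_t)
  frac <- 1 - dim(ep2$data)[1] / n_tr
  expect_lt(abs(frac - p_trial), 3.5 * sqrt(p_trial * (1 - p_trial) / n_tr))
})

test_that("trial-count bookkeeping is conserved through the chain", {
  truth <- quiet_truth(noise_sd = 5)
  ev <- generate_sequence(small_seq(), seed = 9)
  ev <- simulate_behavior(ev, truth, "real", seed = 10)
  syn <- synthesize_participant(ev, truth, "younger", "real", seed = 11)
  ep <- preprocess_session(syn$recording, ev)
  expect_equal(dim(ep$data)[1] + nrow(ep$log), nrow(ev))
  expect_identical(ep$pipeline,
                   c("filter", "rereference_average", "epoch_baseline",
                     "select_correct", "exclude_post_target_standards",
                     "reject_amplitude"))
})

test_that("filtering then epoching leaves noiseless peak latencies intact", {
  truth <- quiet_truth()
  s <- literal_session(truth, seq_spec = small_seq(40, 2))
  std <- average_cell(s$epochs, position = "center", min_trials = 1)
  g <- grid_average(std, erp_grids()$p1)
  m <- peak_measure(oddballerp:::crop_waveform(g, c(-200, 1000)),
                    default_measure_specs()$P1)
  expect_lt(abs(m$latency - 57), 1.5)
})

test_that("frequency-domain noise shaping equals generate-then-filter", {
  # same spectrum draws: ifft(z * s) then FIR filtering must equal
  # ifft(z * s * H) up to numerical error away from the edges
  n <- 6000
  filters <- list(fir_spec("highpass", 1, 801),
                  fir_spec("lowpass", 40, 201))
  pre <- oddballerp:::fast_precompute(n, filters, noise_sd = 10)
  set.seed(12)
  broadband <- noise_1f(n, 1, sd = 10)
  set.seed(12)
  shaped <- noise_1f(n, 1, sd = 10, response = pre$response,
                     active_tol = 0)
  filtered <- filter_recording(oddball_recording(broadband), filters)
  mid <- 1500:4500
  expect_lt(max(abs(filtered$data[1, mid] - shaped[1, mid])), 1e-8)
})
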
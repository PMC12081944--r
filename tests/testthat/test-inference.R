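# Independent oracles: brute-force BH step-up, noncentral-t quadrature for
# the JZS Bayes factor, and stats::aov for the mixed ANOVA.

bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- p[o][i:m] * m / (i:m)
    adj[o[i]] <- min(1, min(vals))
  }
  adj
}

jzs_oracle <- function(t, n, r, n_grid = 20001) {
  nu <- n - 1
  th <- seq(-pi / 2 + 1e-9, pi / 2 - 1e-9, length.out = n_grid)
  f <- vapply(th, function(x) {
    suppressWarnings(stats::dt(t, nu, ncp = r * tan(x) * sqrt(n))) / pi
  }, numeric(1))
  h <- diff(th[1:2])
  w <- c(1, rep(c(4, 2), (n_grid - 3) / 2), 4, 1) * h / 3
  sum(w * f) / stats::dt(t, nu)
}

aov_F <- function(d) {
  a <- summary(stats::aov(value ~ age * environment * dimension +
                            Error(factor(participant) /
                                    (environment * dimension)), data = d))
  out <- c()
  for (stratum in a) {
    tab <- stratum[[1]]
    eff <- trimws(rownames(tab))
    keep <- eff != "Residuals"
    out[eff[keep]] <- tab[keep, "F value"]
  }
  out
}

random_design <- function(n1, n2, seed, effect = 0) {
  set.seed(seed)
  parts <- data.frame(participant = seq_len(n1 + n2),
                      age = rep(c("younger", "older"), c(n1, n2)))
  d <- expand.grid(participant = parts$participant,
                   environment = c("real", "virtual"),
                   dimension = c("azimuth", "distance"),
                   stringsAsFactors = FALSE)
  d$age <- parts$age[d$participant]
  subj <- rnorm(n1 + n2)
  d$value <- subj[d$participant] + rnorm(nrow(d)) +
    effect * (d$age == "older") * (d$dimension == "azimuth")
  d
}

test_that("the mixed 2x2x2 ANOVA engine reproduces aov exactly", {
  for (seed in 1:4) {
    d <- random_design(9, 9, seed, effect = 0.5)
    mine <- mixed_anova_222(d)
    ref <- aov_F(d)
    expect_equal(mine$F[match(names(ref), mine$effect)], unname(ref),
                 tolerance = 1e-10)
  }
  # all-constant response: F = 0, not NaN
  d0 <- random_design(4, 4, 1)
  d0$value <- 3.2
  expect_true(all(mixed_anova_222(d0)$F == 0))
})

test_that("jackknife scores obey the linear-measure identities", {
  set.seed(13)
  n <- 12
  x <- matrix(rnorm(n * 40), n)
  group <- rep(c("a", "b"), each = 6)
  win_mean <- function(v) mean(v[5:15])
  sc <- jackknife_scores(x, group, win_mean)
  ind <- apply(x, 1, win_mean)
  for (g in c("a", "b")) {
    i <- which(group == g)
    m <- mean(ind[i])
    # score_i = (n*mbar - m_i)/(n-1) for linear measures
    expect_equal(sc[i], (length(i) * m - ind[i]) / (length(i) - 1),
                 tolerance = 1e-12)
    # mean of leave-one-out scores equals the grand score
    expect_equal(mean(sc[i]), m, tolerance = 1e-12)
  }
  # identical participants -> every score equals the common score
  xc <- matrix(rep(rnorm(40), each = n), n)
  scc <- jackknife_scores(xc, group, win_mean)
  expect_equal(scc, rep(win_mean(xc[1, ]), n), tolerance = 1e-12)
  # retransformation inverts the jackknife map
  expect_equal(jackknife_retransform(sc, group), ind, tolerance = 1e-10)
  expect_error(jackknife_scores(x[1:4, ], rep(c("a", "b"), 2), win_mean),
               "at least 3")
})

test_that("corrected statistics equal conventional ones for linear measures", {
  # the pipeline's central correctness check: jackknife + correction on a
  # fixed-window mean is identical (1e-6) to the conventional analysis of
  # individual scores, for t and F alike
  set.seed(14)
  n <- 8
  parts <- data.frame(participant = seq_len(2 * n),
                      age = rep(c("younger", "older"), each = n))
  win_mean <- function(v) mean(v[10:30])
  scores <- NULL
  individual <- NULL
  for (e in c("real", "virtual")) for (dm in c("azimuth", "distance")) {
    waves <- matrix(rnorm(2 * n * 50), 2 * n) +
      (e == "real") * 0.4 + (parts$age == "older") * 0.6
    sc <- jackknife_scores(waves, parts$age, win_mean)
    ind <- apply(waves, 1, win_mean)
    scores <- rbind(scores, data.frame(
      participant = parts$participant, age = parts$age, environment = e,
      dimension = dm, score = sc))
    individual <- rbind(individual, data.frame(
      participant = parts$participant, age = parts$age, environment = e,
      dimension = dm, value = ind))
  }
  corr <- corrected_mixed_anova(scores)
  conv <- mixed_anova_222(individual)
  expect_equal(corr$F, conv$F, tolerance = 1e-6)
  expect_equal(corr$p, conv$p, tolerance = 1e-6)
  expect_equal(corr$eta_p, conv$eta_p, tolerance = 1e-6)
  # uncorrected jackknife F overstates by (n-1)^2 for equal groups
  expect_equal(corr$F_uncorrected, conv$F * (n - 1)^2, tolerance = 1e-6)

  # post hoc paired t: corrected == conventional
  ct <- list(list(name = "real vs virtual | azimuth younger",
                  a = list(age = "younger", environment = "real",
                           dimension = "azimuth"),
                  b = list(age = "younger", environment = "virtual",
                           dimension = "azimuth")))
  ph <- corrected_posthoc_t(scores, ct)
  iy <- individual[individual$age == "younger" &
                     individual$dimension == "azimuth", ]
  d <- iy$value[iy$environment == "real"] -
    iy$value[iy$environment == "virtual"]
  t_conv <- mean(d) / (sd(d) / sqrt(n))
  expect_equal(ph$t, t_conv, tolerance = 1e-6)
  expect_equal(ph$df, n - 1)
  # identical cells give t = 0
  ct0 <- list(list(name = "same", a = ct[[1]]$a, b = ct[[1]]$a))
  expect_equal(corrected_posthoc_t(scores, ct0)$t, 0)
  expect_error(corrected_posthoc_t(scores, list()), "empty")
})

test_that("corrected statistics stay exact with unbalanced groups", {
  set.seed(15)
  n1 <- 7; n2 <- 10
  parts <- data.frame(participant = seq_len(n1 + n2),
                      age = rep(c("younger", "older"), c(n1, n2)))
  win_mean <- function(v) mean(v[3:9])
  scores <- NULL; individual <- NULL
  for (e in c("real", "virtual")) for (dm in c("azimuth", "distance")) {
    waves <- matrix(rnorm((n1 + n2) * 12), n1 + n2)
    scores <- rbind(scores, data.frame(
      participant = parts$participant, age = parts$age, environment = e,
      dimension = dm, score = jackknife_scores(waves, parts$age, win_mean)))
    individual <- rbind(individual, data.frame(
      participant = parts$participant, age = parts$age, environment = e,
      dimension = dm, value = apply(waves, 1, win_mean)))
  }
  corr <- corrected_mixed_anova(scores)
  conv <- mixed_anova_222(individual)
  expect_equal(corr$F, conv$F, tolerance = 1e-6)
})

test_that("BH-FDR matches the brute-force step-up definition", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  set.seed(16)
  for (i in 1:20) {
    p <- runif(sample(2:12, 1))^sample(1:3, 1)
    adj <- bh_fdr(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    # monotone in rank order, capped at 1
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    expect_true(all(adj <= 1 & adj >= p))
  }
  expect_error(bh_fdr(c(0.2, 1.4)), "0, 1")
  expect_error(bh_fdr(c(0.2, NA)), "0, 1")
})

test_that("the JZS Bayes factor matches high-resolution quadrature", {
  set.seed(17)
  cases <- rbind(expand.grid(t = c(0, 0.8, 2.24, 3.5, -2.5, 5),
                             n = c(12, 22, 80), r = c(sqrt(2) / 2, 1)))
  for (i in seq_len(nrow(cases))) {
    bf <- jzs_bf_one_sample(cases$t[i], n = cases$n[i], r = cases$r[i])
    expect_rel_equal(bf$bf10, jzs_oracle(cases$t[i], cases$n[i],
                                         cases$r[i]), 1e-6)
  }
  # data-vector interface agrees with the t-statistic interface
  x <- rnorm(22, 0.4)
  tv <- mean(x) / (sd(x) / sqrt(22))
  expect_equal(jzs_bf_one_sample(x)$bf10,
               jzs_bf_one_sample(tv, n = 22)$bf10, tolerance = 1e-9)
  # t = 0 favors the null; BF10 strictly increases in |t| at fixed n
  expect_lt(jzs_bf_one_sample(0, n = 20)$bf10, 1)
  ts <- seq(0, 6, by = 0.5)
  bfs <- vapply(ts, function(t) jzs_bf_one_sample(t, n = 22)$bf10,
                numeric(1))
  expect_true(all(diff(bfs) > 0))
  expect_equal(vapply(-ts, function(t) jzs_bf_one_sample(t, n = 22)$bf10,
                      numeric(1)), bfs, tolerance = 1e-9)
  expect_error(jzs_bf_one_sample(2, n = 1), "n >= 2")
  expect_error(jzs_bf_one_sample(2, n = 20, r = -1), "positive")
})

test_that("Jeffreys categories follow the conventional bands", {
  expect_equal(classify_bf(0.2), "moderate H0")
  expect_equal(classify_bf(1), "no preference")
  expect_equal(classify_bf(38.85), "very strong H1")
  expect_equal(classify_bf(34.19), "very strong H1")
  expect_equal(classify_bf(0.16), "moderate H0")
  expect_equal(classify_bf(4.5), "moderate H1")
  expect_equal(classify_bf(1.53), "anecdotal H1")
  expect_equal(classify_bf(0.71), "anecdotal H0")
  expect_equal(classify_bf(150), "extreme H1")
  expect_equal(classify_bf(1 / 150), "extreme H0")
  expect_error(classify_bf(0), "positive")
  expect_error(classify_bf(-2), "positive")
})

test_that("behavioral logits are finite and the dimension effect is found", {
  expect_equal(adjusted_logit(54, 108), 0, tolerance = 1e-2)
  expect_true(is.finite(adjusted_logit(108, 108)))
  expect_true(is.finite(adjusted_logit(0, 108)))
  expect_error(adjusted_logit(0, 0), "zero-trial")

  # power check: cohorts drawn from the default accuracy model detect the
  # azimuth > distance main effect in > 90% of replicates
  truth <- ground_truth_default()
  set.seed(18)
  n <- 22
  hits <- 0
  n_rep <- 40
  for (rep in seq_len(n_rep)) {
    rows <- NULL
    for (i in seq_len(2 * n)) {
      ability <- rnorm(1, 0, truth$behavior_subject_sd)
      for (e in c("real", "virtual")) {
        acc <- truth$accuracy[truth$accuracy$environment == e, ]
        p <- plogis(qlogis(acc$p) + ability +
                      rnorm(2, 0, truth$behavior_cell_sd))
        k <- rbinom(2, 108, p)
        rows <- rbind(rows, data.frame(
          participant = i, age = c("younger", "older")[1 + (i > n)],
          environment = e, dimension = acc$dimension, k = k, n = 108))
      }
    }
    res <- behavior_analysis(rows)
    pdim <- res$anova$p[res$anova$effect == "dimension"]
    est <- mean(res$scores$logit[res$scores$dimension == "azimuth"]) -
      mean(res$scores$logit[res$scores$dimension == "distance"])
    if (pdim < 0.05 && est > 0) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.9)
})
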
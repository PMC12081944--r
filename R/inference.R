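# Jackknife scoring, corrected mixed ANOVA, post hoc t-tests, BH-FDR.
#
# Jackknife scores are measures taken on leave-one-participant-out group
# averages (within the between-subject group only). For linear measures this
# shrinks within-group deviations by 1/(n-1); correction inverts that map
# exactly ("retransformation"), which coincides with the classical
# divide-by-(n-1) rule for equal groups and stays exact for unequal ones.
# The linear-measure equivalence (corrected statistics == conventional
# statistics on individual scores) is the pipeline's central correctness
# check and is asserted in the test suite.

#' Leave-one-out jackknife scores for one design cell
#'
#' @param x Numeric matrix, participants x time (or any per-participant
#'   numeric vectors to be averaged element-wise).
#' @param group Factor/character of between-subject group memberships
#'   (leave-one-out averages are formed within group).
#' @param fun Measure: a function of the leave-one-out average vector
#'   returning one number.
#' @return Numeric vector of n scores (`fun` applied to the average of the
#'   participant's group excluding that participant).
#' @export
jackknife_scores <- function(x, group, fun) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  group <- as.character(group)
  n <- nrow(x)
  scores <- numeric(n)
  for (g in unique(group)) {
    idx <- which(group == g)
    if (length(idx) < 3) {
      stop("jackknife groups need at least 3 participants", call. = FALSE)
    }
    tot <- colSums(x[idx, , drop = FALSE])
    for (i in idx) {
      scores[i] <- fun((tot - x[i, ]) / (length(idx) - 1))
    }
  }
  scores
}

# Invert the jackknife map within each group: from leave-one-out scores J_i
# back to (pseudo-)individual scores y_i = n * mean(J) - (n-1) * J_i.
# Exact inverse for linear measures; the standard correction otherwise.
jackknife_retransform <- function(scores, group) {
  group <- as.character(group)
  out <- numeric(length(scores))
  for (g in unique(group)) {
    idx <- which(group == g)
    n <- length(idx)
    out[idx] <- n * mean(scores[idx]) - (n - 1) * scores[idx]
  }
  out
}

#' Mixed 2x2x2 repeated-measures ANOVA
#'
#' One between-subject factor (`age`) and two within-subject factors
#' (`environment`, `dimension`), each with two levels. Computed through
#' per-participant contrast scores, which is exact for this design and
#' corresponds to Type-III (unweighted-means) sums of squares when the
#' groups are unbalanced. Partial eta squared is `F / (F + df2)`.
#'
#' @param data Data frame with columns `participant`, `age`, `environment`,
#'   `dimension` and the response in `value`.
#' @param value Name of the response column.
#' @return Data frame: effect, F, df1, df2, p, eta_p.
#' @export
mixed_anova_222 <- function(data, value = "value") {
  need <- c("participant", "age", "environment", "dimension", value)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  lev <- function(v) {
    u <- if (is.factor(v)) levels(v) else sort(unique(as.character(v)))
    if (length(u) != 2) stop("factors must have exactly 2 levels",
                             call. = FALSE)
    u
  }
  age_l <- lev(data$age); env_l <- lev(data$environment)
  dim_l <- lev(data$dimension)
  ids <- unique(data$participant)
  cell <- function(p, e, d) {
    v <- data[[value]][data$participant == p & data$environment == e &
                         data$dimension == d]
    if (length(v) != 1) stop("design must have one value per cell",
                             call. = FALSE)
    v
  }
  m <- t(vapply(ids, function(p) {
    c(cell(p, env_l[1], dim_l[1]), cell(p, env_l[1], dim_l[2]),
      cell(p, env_l[2], dim_l[1]), cell(p, env_l[2], dim_l[2]))
  }, numeric(4)))
  age <- vapply(ids, function(p) {
    as.character(data$age[data$participant == p][1])
  }, character(1))
  n1 <- sum(age == age_l[1]); n2 <- sum(age == age_l[2])
  if (n1 < 2 || n2 < 2) stop("each age group needs >= 2 participants",
                             call. = FALSE)
  # orthonormal-ish within-subject contrasts (scaling cancels in F)
  contrasts <- list(
    mean = c(1, 1, 1, 1) / 4,
    environment = c(1, 1, -1, -1) / 2,
    dimension = c(1, -1, 1, -1) / 2,
    `environment:dimension` = c(1, -1, -1, 1) / 2
  )
  df2 <- n1 + n2 - 2
  res <- lapply(names(contrasts), function(nm) {
    sc <- drop(m %*% contrasts[[nm]])
    s1 <- sc[age == age_l[1]]; s2 <- sc[age == age_l[2]]
    s2p <- (sum((s1 - mean(s1))^2) + sum((s2 - mean(s2))^2)) / df2
    # within-subject main effect / interaction with age
    tests <- list()
    est_main <- (mean(s1) + mean(s2)) / 2
    se_main <- sqrt(s2p * (1 / n1 + 1 / n2)) / 2
    est_int <- mean(s1) - mean(s2)
    se_int <- sqrt(s2p * (1 / n1 + 1 / n2))
    tstat <- function(est, se) if (est == 0) 0 else est / se
    if (nm == "mean") {
      data.frame(effect = "age", t = tstat(est_int, se_int),
                 stringsAsFactors = FALSE)
    } else {
      rbind(
        data.frame(effect = nm, t = tstat(est_main, se_main),
                   stringsAsFactors = FALSE),
        data.frame(effect = paste0("age:", nm), t = tstat(est_int, se_int),
                   stringsAsFactors = FALSE)
      )
    }
  })
  res <- do.call(rbind, res)
  res$F <- res$t^2
  res$df1 <- 1L
  res$df2 <- df2
  res$p <- stats::pf(res$F, 1, df2, lower.tail = FALSE)
  res$eta_p <- res$F / (res$F + df2)
  res[, c("effect", "F", "df1", "df2", "p", "eta_p")]
}

#' Jackknife-corrected mixed ANOVA
#'
#' Takes leave-one-out jackknife scores, inverts the jackknife shrinkage
#' within each age group (exactly the divide-by-(n-1) correction for equal
#' groups), and runs the mixed 2x2x2 ANOVA. For measures that are linear in
#' the per-participant waveforms the result equals the conventional ANOVA
#' on individual scores.
#'
#' @param scores Data frame with `participant`, `age`, `environment`,
#'   `dimension`, `score` (jackknife scores).
#' @return Data frame as [mixed_anova_222()], plus `F_uncorrected` (the
#'   ANOVA on the raw jackknife scores) and the per-group `divisor`.
#' @export
corrected_mixed_anova <- function(scores) {
  key <- interaction(scores$environment, scores$dimension, drop = TRUE)
  corrected <- scores
  for (k in levels(key)) {
    i <- key == k
    corrected$score[i] <- jackknife_retransform(scores$score[i],
                                                scores$age[i])
  }
  out <- mixed_anova_222(corrected, value = "score")
  raw <- mixed_anova_222(scores, value = "score")
  out$F_uncorrected <- raw$F
  ng <- table(scores$age[!duplicated(scores$participant)])
  out$divisor <- if (length(unique(ng)) == 1) unique(ng) - 1 else NA_integer_
  out
}

#' Jackknife-corrected post hoc t-tests with BH-FDR adjustment
#'
#' Each contrast compares two design cells on the retransformed
#' (jackknife-corrected) scores: paired when both cells belong to the same
#' participants, two-sample (pooled) when they differ in age group.
#'
#' @param scores As in [corrected_mixed_anova()].
#' @param contrasts List; each element is a list with `name` and two cell
#'   selectors `a` and `b`, themselves named lists of column = level (e.g.
#'   `list(age = "older", environment = "real", dimension = "azimuth")`).
#' @return Data frame: contrast, t (corrected), df, p, p_fdr (BH-adjusted
#'   across the family), estimate (mean difference a - b).
#' @export
corrected_posthoc_t <- function(scores, contrasts) {
  if (!length(contrasts)) stop("empty contrast family", call. = FALSE)
  key <- interaction(scores$environment, scores$dimension, drop = TRUE)
  corrected <- scores
  for (k in levels(key)) {
    i <- key == k
    corrected$score[i] <- jackknife_retransform(scores$score[i],
                                                scores$age[i])
  }
  pick <- function(sel) {
    keep <- rep(TRUE, nrow(corrected))
    for (nm in names(sel)) keep <- keep & corrected[[nm]] == sel[[nm]]
    corrected[keep, ]
  }
  rows <- lapply(contrasts, function(ct) {
    a <- pick(ct$a); b <- pick(ct$b)
    if (!nrow(a) || !nrow(b)) {
      stop("contrast ", ct$name, " references an empty cell", call. = FALSE)
    }
    if (setequal(a$participant, b$participant)) {
      d <- a$score[match(b$participant, a$participant)] - b$score
      n <- length(d)
      se <- stats::sd(d) / sqrt(n)
      tv <- if (mean(d) == 0) 0 else mean(d) / se
      data.frame(contrast = ct$name, t = tv, df = n - 1,
                 estimate = mean(d), n = n, stringsAsFactors = FALSE)
    } else {
      n1 <- nrow(a); n2 <- nrow(b)
      s2p <- ((n1 - 1) * stats::var(a$score) +
                (n2 - 1) * stats::var(b$score)) / (n1 + n2 - 2)
      est <- mean(a$score) - mean(b$score)
      se <- sqrt(s2p * (1 / n1 + 1 / n2))
      tv <- if (est == 0) 0 else est / se
      data.frame(contrast = ct$name, t = tv, df = n1 + n2 - 2,
                 estimate = est, n = n1 + n2, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$p <- 2 * stats::pt(abs(out$t), out$df, lower.tail = FALSE)
  out$p_fdr <- bh_fdr(out$p)
  out[, c("contrast", "estimate", "t", "df", "n", "p", "p_fdr")]
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values (monotone in rank order, capped at 1).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_fdr <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}
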
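# Summary statistics and tests: coefficient of repeatability (CoR),
# coefficient of variation (CoV), exact Wilcoxon signed-rank, Welch's t-test
# from summary statistics, and two-sample sample-size calculations.

#' Coefficient of repeatability
#'
#' CoR = 1.96 x SD of the signed intra-subject test-retest differences
#' (session 2 minus session 1), with the sample (n - 1) SD.
#'
#' @param session1,session2 aligned per-subject values, or `session1` a
#'   data.frame with columns subject, session, value
#' @export
coefficient_of_repeatability <- function(session1, session2 = NULL) {
  if (is.data.frame(session1)) {
    df <- session1
    subs <- unique(df$subject)
    v1 <- v2 <- numeric(length(subs))
    for (i in seq_along(subs)) {
      r1 <- df$value[df$subject == subs[i] & df$session == 1]
      r2 <- df$value[df$subject == subs[i] & df$session == 2]
      if (length(r1) != 1 || length(r2) != 1)
        stop(errorCondition(paste0("subject ", subs[i], " is missing a session"),
                            class = c("slamrecon_pairing_error", "error")))
      v1[i] <- r1; v2[i] <- r2
    }
    session1 <- v1; session2 <- v2
  }
  if (length(session1) != length(session2))
    stop(errorCondition("sessions have different lengths",
                        class = c("slamrecon_pairing_error", "error")))
  if (length(session1) < 2) stop_param("need at least 2 subjects")
  if (anyNA(session1) || anyNA(session2))
    stop(errorCondition("missing session values",
                        class = c("slamrecon_pairing_error", "error")))
  1.96 * stats::sd(session2 - session1)
}

#' Coefficient of variation
#'
#' SD of a measure across all scans divided by its mean. Either pass raw
#' values in `x`, or a mean in `x` together with `sd`.
#'
#' @param x raw values, or the mean when `sd` is given
#' @param sd optional SD to pair with a mean
#' @export
coefficient_of_variation <- function(x, sd = NULL) {
  if (is.null(sd)) {
    m <- mean(x); s <- stats::sd(x)
  } else {
    m <- x; s <- sd
  }
  if (m == 0) stop(errorCondition("CoV undefined for zero mean",
                                  class = c("slamrecon_undefined_error", "error")))
  s / m
}

# Exact two-sided p for the signed-rank statistic by dynamic programming over
# the 2^n sign assignments. Ranks may be half-integers (average ranks for
# ties), so everything is doubled to stay integer.
wilcoxon_exact_p <- function(ranks, w_obs) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  # poly[i] = number of sign assignments with doubled W+ equal to i - 1
  poly <- numeric(total + 1)
  poly[1] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), poly[seq_len(total + 1 - r)])
    poly <- poly + shifted
  }
  poly <- poly / 2^length(r2)
  w2 <- round(2 * w_obs)
  p_le <- sum(poly[seq_len(w2 + 1)])
  p_ge <- sum(poly[(w2 + 1):(total + 1)])
  min(1, 2 * min(p_le, p_ge))
}

#' Paired two-tailed Wilcoxon signed-rank test
#'
#' Zero differences are dropped and tied absolute differences receive
#' average ranks. Exact two-sided p by sign-pattern enumeration for n <= 25;
#' normal approximation with continuity and tie correction above.
#'
#' @param x,y paired samples of equal length
#' @return list(statistic = W+, n = number of nonzero differences, p)
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop_param("x and y must have equal length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    stop(errorCondition("all differences are zero: test undefined",
                        class = c("slamrecon_undefined_error", "error")))
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= 25) {
    p <- wilcoxon_exact_p(r, w)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = w, n = n, p = p)
}

#' Welch's two-sample t-test from summary statistics
#'
#' @param mean_a,sd_a,n_a group A mean, SD, size
#' @param mean_b,sd_b,n_b group B mean, SD, size
#' @return list(t, df, p) with the Welch-Satterthwaite degrees of freedom and
#'   two-tailed p
#' @export
welch_t <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (n_a < 2 || n_b < 2) stop_param("each group needs n >= 2")
  if (sd_a < 0 || sd_b < 0 || (sd_a == 0 && sd_b == 0))
    stop_param("SDs must be >= 0 and not both zero")
  va <- sd_a^2 / n_a; vb <- sd_b^2 / n_b
  t <- (mean_a - mean_b) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Welch's t-test on raw samples (summary-statistic wrapper)
#' @param a,b numeric vectors
#' @export
welch_t_raw <- function(a, b) {
  welch_t(mean(a), stats::sd(a), length(a), mean(b), stats::sd(b), length(b))
}

#' Two-sample sample-size calculation
#'
#' `normal_approx`: \eqn{n = \lceil 2 \sigma^2 (z_{1-\alpha/2} +
#' z_{1-\beta})^2 / \Delta^2 \rceil} per group. `noncentral_t`: iterative
#' exact power via the noncentral t distribution ([stats::power.t.test()]).
#' The SD convention is selectable and recorded in the result.
#'
#' @param mean_a,sd_a,mean_b,sd_b group summaries
#' @param power target power in (0, 1)
#' @param alpha two-sided significance level in (0, 1)
#' @param convention "normal_approx" or "noncentral_t"
#' @param sd_choice which sigma to use: "a", "b" or "pooled"
#' @return list(n_per_group, n_total, convention, sd_used, delta)
#' @export
sample_size_two_sample <- function(mean_a, sd_a, mean_b, sd_b,
                                   power = 0.8, alpha = 0.05,
                                   convention = c("normal_approx", "noncentral_t"),
                                   sd_choice = c("a", "b", "pooled")) {
  convention <- match.arg(convention)
  sd_choice <- match.arg(sd_choice)
  if (power <= 0 || power >= 1 || alpha <= 0 || alpha >= 1)
    stop_param("power and alpha must be in (0, 1)")
  delta <- abs(mean_a - mean_b)
  if (delta == 0) stop_param("zero effect size")
  sigma <- switch(sd_choice, a = sd_a, b = sd_b,
                  pooled = sqrt((sd_a^2 + sd_b^2) / 2))
  n <- switch(convention,
    normal_approx = {
      z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
      ceiling(2 * sigma^2 * z^2 / delta^2)
    },
    noncentral_t = ceiling(stats::power.t.test(delta = delta, sd = sigma,
                                               power = power,
                                               sig.level = alpha)$n))
  n <- max(n, 2L)
  list(n_per_group = n, n_total = 2 * n, convention = convention,
       sd_used = sigma, delta = delta)
}
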
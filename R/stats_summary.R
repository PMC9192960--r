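#' Two-sample pooled-variance t test from summary statistics
#'
#' Recomputes the classical pooled t statistic from printed group means, SDs
#' and sizes, as used for demographic and psychometric comparisons:
#' \deqn{t = \frac{m_1 - m_2}{s_p \sqrt{1/n_1 + 1/n_2}},\qquad
#'   s_p^2 = \frac{(n_1-1)s_1^2 + (n_2-1)s_2^2}{n_1+n_2-2},}
#' with `df = n1 + n2 - 2` and a two-sided p-value.
#'
#' @param m1,sd1,n1 Mean, SD and size of group 1.
#' @param m2,sd2,n2 Mean, SD and size of group 2.
#' @return A one-row tibble: `t`, `df`, `p`.
#' @export
#' @examples
#' pooled_t_from_summary(15.28, 9.49, 43, 1.13, 1.23, 24)  # t = 7.247, df 65
pooled_t_from_summary <- function(m1, sd1, n1, m2, sd2, n2) {
  n1 <- assert_count(n1, "n1", min = 2L)
  n2 <- assert_count(n2, "n2", min = 2L)
  assert_scalar_num(sd1, "sd1", nonneg = TRUE)
  assert_scalar_num(sd2, "sd2", nonneg = TRUE)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 == 0) {
    if (m1 == m2) return(tibble(t = 0, df = df, p = 1))
    stop("zero pooled variance with unequal means: t is infinite.",
         call. = FALSE)
  }
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  tibble(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Chi-squared test with Yates continuity correction for a 2x2 table
#'
#' \deqn{\chi^2 = \frac{n\,(\max(|ad - bc| - n/2,\, 0))^2}
#'   {(a+b)(c+d)(a+c)(b+d)}}
#' on 1 degree of freedom, as used for gender frequency comparisons.
#'
#' @param a,b,c,d Cell counts: rows are groups, columns the binary attribute.
#' @return A one-row tibble: `chisq`, `df`, `p`.
#' @export
#' @examples
#' yates_chi2(21, 22, 10, 14)  # 0.095
yates_chi2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers.", call. = FALSE)
  }
  n <- sum(counts)
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop("all table margins must be > 0.", call. = FALSE)
  stat <- n * max(abs(a * d - b * c) - n / 2, 0)^2 / prod(margins)
  tibble(chisq = stat, df = 1L, p = pchisq(stat, 1, lower.tail = FALSE))
}

#' Cohen's d with 95% CI from a t statistic
#'
#' Standardized mean difference recovered from a two-sample t statistic,
#' \eqn{d = |t| \sqrt{1/n_1 + 1/n_2}}, with the normal-approximation interval
#' \deqn{d \pm 1.96\sqrt{\frac{n_1+n_2}{n_1 n_2} + \frac{d^2}{2(n_1+n_2)}}.}
#' The result is invariant to the sign of `t`.
#'
#' @param t Two-sample t statistic.
#' @param n1,n2 Group sizes.
#' @param conf_z Normal quantile for the interval, default 1.96.
#' @return A one-row tibble: `d`, `ci_low`, `ci_high`, `n1`, `n2`.
#' @export
#' @examples
#' cohens_d_from_t(-2.908, 43, 24)  # d = 0.74 [0.23, 1.26]
cohens_d_from_t <- function(t, n1, n2, conf_z = 1.96) {
  n1 <- assert_count(n1, "n1", min = 2L)
  n2 <- assert_count(n2, "n2", min = 2L)
  d <- abs(t) * sqrt(1 / n1 + 1 / n2)
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  tibble(d = d, ci_low = d - conf_z * se, ci_high = d + conf_z * se,
         n1 = n1, n2 = n2)
}

#' Inference for a Pearson correlation from r and n
#'
#' Two-sided p-value from \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on `n - 2` df, and
#' the Fisher-z (variance-stabilized) 95% confidence interval
#' \eqn{\tanh(\mathrm{atanh}(r) \pm 1.96/\sqrt{n-3})}.
#'
#' @param r Correlation coefficient.
#' @param n Sample size, >= 4.
#' @param conf_z Normal quantile for the interval, default 1.96.
#' @return A one-row tibble: `r`, `n`, `t`, `p`, `ci_low`, `ci_high`,
#'   `degenerate` (TRUE when `|r| = 1`).
#' @export
#' @examples
#' pearson_test(0.456, 21)  # p = 0.038
pearson_test <- function(r, n, conf_z = 1.96) {
  n <- assert_count(n, "n", min = 4L)
  if (abs(r) > 1) stop("`r` must lie in [-1, 1].", call. = FALSE)
  if (abs(r) == 1) {
    return(tibble(r = r, n = n, t = Inf * sign(r), p = 0,
                  ci_low = r, ci_high = r, degenerate = TRUE))
  }
  t <- r * sqrt((n - 2) / (1 - r^2))
  z <- atanh(r)
  hw <- conf_z / sqrt(n - 3)
  tibble(r = r, n = n, t = t, p = 2 * pt(-abs(t), n - 2),
         ci_low = tanh(z - hw), ci_high = tanh(z + hw), degenerate = FALSE)
}

#' Required sample size for a two-sample t test
#'
#' Smallest total n (at the given allocation ratio) whose two-sample t-test
#' power reaches the target, with power computed exactly from the noncentral t
#' distribution: for group sizes \eqn{n_1, n_2} the noncentrality is
#' \eqn{d\sqrt{n_1 n_2/(n_1+n_2)}} and power is the tail probability beyond
#' the central-t critical value.
#'
#' @param d True standardized difference, > 0.
#' @param power Target power in (0, 1), default 0.85.
#' @param alpha Significance level, default 0.05.
#' @param one_sided One-sided test (default TRUE) or two-sided.
#' @param ratio Allocation ratio `n1/n2`, default 1.
#' @param max_n Search cap on total n.
#' @return A one-row tibble: `n_total`, `n1`, `n2`, `achieved_power`.
#' @export
#' @examples
#' required_n(0.74, power = 0.85)  # total n = 52 at equal allocation
required_n <- function(d, power = 0.85, alpha = 0.05, one_sided = TRUE,
                       ratio = 1, max_n = 1e5) {
  assert_scalar_num(d, "d", positive = TRUE)
  assert_scalar_num(power, "power", positive = TRUE)
  if (power >= 1) stop("`power` must be in (0, 1).", call. = FALSE)
  assert_scalar_num(ratio, "ratio", positive = TRUE)
  tail_alpha <- if (one_sided) alpha else alpha / 2
  power_at <- function(n1, n2) {
    df <- n1 + n2 - 2
    if (df < 1) return(0)
    ncp <- d * sqrt(n1 * n2 / (n1 + n2))
    crit <- qt(1 - tail_alpha, df)
    pt(crit, df, ncp = ncp, lower.tail = FALSE)
  }
  for (n_total in 4:max_n) {
    n2 <- max(2L, round(n_total / (1 + ratio)))
    n1 <- n_total - n2
    if (n1 < 2L) next
    if (power_at(n1, n2) >= power) {
      return(tibble(n_total = n_total, n1 = n1, n2 = n2,
                    achieved_power = power_at(n1, n2)))
    }
  }
  stop("target power unreachable within `max_n`.", call. = FALSE)
}
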
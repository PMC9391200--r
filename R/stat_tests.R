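# The statistical test family used throughout the repertoire comparisons:
# two-proportion Z without continuity correction, Welch's unequal-variance t,
# Brown-Forsythe unequal-variance ANOVA on means, and Dunnett's T3 pairwise
# procedure based on the studentized maximum modulus distribution.

pc_test_result <- function(method, statistic, p_value, estimate = NULL,
                           df = NULL, ci = NULL, degenerate = FALSE) {
  structure(list(method = method, statistic = statistic, p_value = p_value,
                 estimate = estimate, df = df, ci = ci,
                 degenerate = degenerate),
            class = "pc_test")
}

#' @export
print.pc_test <- function(x, ...) {
  cat("<pc_test> ", x$method, ": statistic = ", fmt_num(x$statistic),
      if (!is.null(x$df)) paste0(", df = ", fmt_num(x$df)),
      ", p = ", fmt_num(x$p_value),
      if (isTRUE(x$degenerate)) " [degenerate]", "\n", sep = "")
  invisible(x)
}

#' Two-proportion Z test (no continuity correction)
#'
#' Tests equality of two binomial proportions with the pooled-variance Z
#' statistic and no continuity correction. `z^2` equals the Pearson
#' chi-square statistic of the 2x2 table without Yates correction.
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @return A `pc_test` with `statistic` (z), two-sided `p_value`, and
#'   `estimate` = c(p1, p2). When the pooled proportion is 0 or 1 the
#'   statistic is undefined; a degenerate result with z = 0, p = 1 is
#'   returned and flagged.
#' @export
two_proportion_z <- function(x1, n1, x2, n2) {
  stopifnot(n1 >= 1, n2 >= 1, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1
  p2 <- x2 / n2
  pool <- (x1 + x2) / (n1 + n2)
  if (pool <= 0 || pool >= 1) {
    return(pc_test_result("two-proportion Z", 0, 1, estimate = c(p1, p2),
                          degenerate = TRUE))
  }
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  z <- (p1 - p2) / se
  pc_test_result("two-proportion Z", z, 2 * stats::pnorm(-abs(z)),
                 estimate = c(p1 = p1, p2 = p2))
}

#' Welch's unpaired t test
#'
#' Unequal-variance t test with the Welch-Satterthwaite degrees of freedom.
#'
#' @param sample_a,sample_b Numeric vectors, each of length >= 2.
#' @return A `pc_test` with `statistic`, `df`, two-sided `p_value`,
#'   `estimate` = mean difference. Zero variance in both samples yields a
#'   flagged degenerate result (p = 1 if means equal, p = 0 otherwise).
#' @export
welch_t <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) >= 2, length(sample_b) >= 2)
  na <- length(sample_a); nb <- length(sample_b)
  va <- stats::var(sample_a); vb <- stats::var(sample_b)
  d <- mean(sample_a) - mean(sample_b)
  if (va == 0 && vb == 0) {
    return(pc_test_result("Welch t", if (d == 0) 0 else Inf * sign(d),
                          if (d == 0) 1 else 0, estimate = d,
                          degenerate = TRUE))
  }
  se2 <- va / na + vb / nb
  t <- d / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  pc_test_result("Welch t", t, 2 * stats::pt(-abs(t), df), estimate = d,
                 df = df)
}

#' Brown-Forsythe unequal-variance one-way ANOVA on means
#'
#' The Brown & Forsythe (1974) F* statistic for comparing k group means
#' under heteroscedasticity:
#' \deqn{F^* = \sum_i n_i (\bar x_i - \bar x)^2 / \sum_i (1 - n_i/N) s_i^2}
#' with numerator df = k - 1 and Satterthwaite-type denominator df.
#'
#' @param groups Named list of numeric vectors (>= 2 values each, >= 2
#'   groups).
#' @return A `pc_test` with `statistic` (F*), `df` = c(df1, df2), `p_value`.
#' @export
brown_forsythe <- function(groups) {
  k <- length(groups)
  stopifnot(k >= 2)
  n <- vapply(groups, length, integer(1))
  if (any(n < 2)) stop("each group needs >= 2 observations", call. = FALSE)
  N <- sum(n)
  m <- vapply(groups, mean, numeric(1))
  v <- vapply(groups, stats::var, numeric(1))
  grand <- sum(n * m) / N
  num <- sum(n * (m - grand)^2)
  wden <- (1 - n / N) * v
  den <- sum(wden)
  if (den == 0) {
    return(pc_test_result("Brown-Forsythe ANOVA", if (num == 0) 0 else Inf,
                          if (num == 0) 1 else 0, df = c(k - 1, NA),
                          degenerate = TRUE))
  }
  fstar <- num / den
  ci <- wden / den
  df2 <- 1 / sum(ci^2 / (n - 1))
  pc_test_result("Brown-Forsythe ANOVA", fstar,
                 stats::pf(fstar, k - 1, df2, lower.tail = FALSE),
                 df = c(df1 = k - 1, df2 = df2))
}

#' Studentized maximum modulus distribution function
#'
#' P(max_{i=1..m} |T_i| <= x) where the T_i are m standard t variates
#' sharing one chi (df = nu) denominator. Computed by numerical integration
#' over the scaled-chi density (absolute tolerance 1e-8; the documented
#' target accuracy for adjusted p values is 1e-6).
#'
#' @param x Quantile (>= 0).
#' @param m Number of comparisons.
#' @param nu Degrees of freedom (may be fractional).
#' @return The CDF value.
#' @export
psmm <- function(x, m, nu) {
  if (x <= 0) return(0)
  if (!is.finite(nu)) return((2 * stats::pnorm(x) - 1)^m)
  # s ~ chi_nu / sqrt(nu); density via dchisq change of variables
  integrand <- function(s) {
    (2 * stats::pnorm(x * s) - 1)^m * 2 * nu * s *
      stats::dchisq(nu * s^2, df = nu)
  }
  stats::integrate(integrand, 0, Inf, rel.tol = 1e-10, abs.tol = 1e-10,
                   stop.on.error = FALSE)$value
}

#' Monte-Carlo studentized maximum modulus CDF (validation fallback)
#'
#' @param x Quantile.
#' @param m Number of comparisons.
#' @param nu Degrees of freedom.
#' @param nsim Number of simulations.
#' @param seed RNG seed.
#' @return Estimated CDF value.
#' @export
psmm_mc <- function(x, m, nu, nsim = 2e5, seed = 1L) {
  with_seed(seed, {
    s <- sqrt(stats::rchisq(nsim, df = nu) / nu)
    z <- matrix(abs(stats::rnorm(nsim * m)), nrow = nsim)
    mx <- apply(z, 1, max) / s
    mean(mx <= x)
  })
}

#' Omnibus and pairwise comparisons for several unequal-variance groups
#'
#' Runs the Brown-Forsythe unequal-variance ANOVA across all groups,
#' followed by Dunnett's T3 pairwise procedure: each pair is compared with
#' the Welch statistic, and the adjusted p value is obtained from the
#' studentized maximum modulus distribution with m = number of pairs and
#' the pair's Welch degrees of freedom. Adjusted p values are monotone in
#' |t| for fixed df and never smaller than the unadjusted Welch p.
#'
#' @param groups Named list (>= 3 for the omnibus) of numeric vectors,
#'   each length >= 2.
#' @return List with `omnibus` (`pc_test`) and `pairwise` (data.frame:
#'   group1, group2, t, df, p_welch, p_adjusted).
#' @export
group_tests <- function(groups) {
  k <- length(groups)
  if (k < 3) stop("omnibus comparison needs >= 3 groups", call. = FALSE)
  n <- vapply(groups, length, integer(1))
  if (any(n < 2)) stop("each group needs >= 2 observations", call. = FALSE)
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_len(k))
  omnibus <- brown_forsythe(groups)
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    w <- welch_t(groups[[i1]], groups[[i2]])
    p_adj <- if (isTRUE(w$degenerate)) {
      w$p_value
    } else {
      min(1, max(0, 1 - psmm(abs(w$statistic), m, w$df)))
    }
    data.frame(group1 = names(groups)[i1], group2 = names(groups)[i2],
               t = w$statistic, df = if (is.null(w$df)) NA_real_ else w$df,
               p_welch = w$p_value,
               p_adjusted = max(p_adj, w$p_value),
               stringsAsFactors = FALSE)
  })
  list(omnibus = omnibus, pairwise = do.call(rbind, rows))
}

#' Serialize test results to a flat TSV
#'
#' @param tests List of `pc_test` objects (named).
#' @param path Output path.
#' @export
write_tests_tsv <- function(tests, path) {
  rows <- lapply(names(tests), function(nm) {
    t <- tests[[nm]]
    data.frame(name = nm, method = t$method,
               statistic = fmt_num(t$statistic),
               df = if (is.null(t$df)) "" else paste(fmt_num(t$df),
                                                     collapse = ","),
               p = fmt_num(t$p_value),
               estimate = if (is.null(t$estimate)) "" else
                 paste(fmt_num(t$estimate), collapse = ","),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
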
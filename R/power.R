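## Exact unconditional power of the Fisher exact test for rare carrier
## variants. Carrier counts in cases and controls are independent binomials;
## power is the total probability of (x_cases, x_controls) pairs whose
## realized 2x2 table is significant under the conditional exact test. The
## binomial supports are truncated where the tail mass drops below
## truncation_eps, and the discarded mass is reported as a bound on the
## absolute error of the power value.

#' Control-group carrier frequency from an odds ratio
#'
#' The odds ratio is defined on the odds scale:
#' `odds_control = [p_case / (1 - p_case)] / OR`.
#'
#' @param p_case Carrier probability in cases, in (0, 1).
#' @param odds_ratio Odds ratio (> 0) of carriage, cases vs controls.
#' @return Carrier probability in controls.
#' @export
control_freq_from_or <- function(p_case, odds_ratio) {
  stopifnot(p_case > 0, p_case < 1)
  if (odds_ratio <= 0) stop("odds_ratio must be > 0")
  odds <- (p_case / (1 - p_case)) / odds_ratio
  odds / (1 + odds)
}

#' Exact unconditional power of the Fisher exact test
#'
#' Computes, by full enumeration over truncated binomial supports, the
#' probability that the one-tailed (or two-tailed) Fisher exact test rejects
#' at level `alpha` when carriers arise independently at frequency `p_case`
#' in cases and `p_control` in controls (a dominant carrier model).
#'
#' @param n_cases,n_controls Group sizes.
#' @param p_case Carrier probability in cases.
#' @param odds_ratio Odds ratio from which `p_control` is derived on the odds
#'   scale (ignored when `p_control` is given directly).
#' @param p_control Optional carrier probability in controls.
#' @param alpha Significance level (default 0.05).
#' @param tail `"one.sided"` (enrichment in cases; default) or `"two.sided"`.
#' @param truncation_eps Binomial tail mass discarded per group margin
#'   (default 1e-12). A warning is issued if the resulting error bound
#'   exceeds 1e-6.
#' @return Object of class `power_result`: `power`, `error_bound`,
#'   `n_support` (enumerated support sizes per group), and the design.
#' @export
fisher_exact_power <- function(n_cases, n_controls, p_case, odds_ratio = NULL,
                               p_control = NULL, alpha = 0.05,
                               tail = c("one.sided", "two.sided"),
                               truncation_eps = 1e-12) {
  tail <- match.arg(tail)
  stopifnot(n_cases >= 1, n_controls >= 1, p_case > 0, p_case < 1,
            alpha > 0, alpha < 1, truncation_eps > 0)
  if (is.null(p_control)) {
    if (is.null(odds_ratio))
      stop("supply either odds_ratio or p_control")
    p_control <- control_freq_from_or(p_case, odds_ratio)
  }
  stopifnot(p_control >= 0, p_control < 1)

  sup <- function(n, p) {
    lo <- qbinom(truncation_eps / 2, n, p)
    hi <- qbinom(truncation_eps / 2, n, p, lower.tail = FALSE)
    lo:hi
  }
  x1 <- sup(n_cases, p_case)
  x2 <- sup(n_controls, p_control)
  w1 <- dbinom(x1, n_cases, p_case)
  w2 <- dbinom(x2, n_controls, p_control)
  error_bound <- (1 - sum(w1)) + (1 - sum(w2))
  if (error_bound > 1e-6)
    warning("truncation error bound ", format(error_bound),
            " exceeds 1e-6; decrease truncation_eps")

  N <- n_cases + n_controls
  g1 <- rep(x1, times = length(x2))
  g2 <- rep(x2, each = length(x1))
  m <- g1 + g2
  if (tail == "one.sided") {
    pv <- phyper(g1 - 1, m, N - m, n_cases, lower.tail = FALSE)
  } else {
    pv <- vapply(seq_along(g1), function(k)
      fisher_two_sided_hyper(g1[k], m[k], n_cases, n_controls), numeric(1))
  }
  sig <- pv <= alpha
  power <- as.numeric(crossprod(w1, matrix(sig, nrow = length(x1))) %*% w2)
  structure(list(power = power, error_bound = error_bound,
                 n_support = c(cases = length(x1), controls = length(x2)),
                 n_cases = n_cases, n_controls = n_controls,
                 p_case = p_case, p_control = p_control,
                 alpha = alpha, tail = tail),
            class = "power_result")
}

# two-sided minimum-likelihood P for a table with a carriers among n1 cases,
# m carriers overall; matches the fisher.test convention (relative tolerance
# on probability ties)
fisher_two_sided_hyper <- function(a, m, n1, n2) {
  lo <- max(0L, m - n2)
  hi <- min(m, n1)
  d <- dhyper(lo:hi, m, n1 + n2 - m, n1)
  min(1, sum(d[d <= d[a - lo + 1L] * (1 + 1e-7)]))
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("exact %s Fisher power: %.4f (alpha = %g)\n", x$tail, x$power,
              x$alpha))
  cat(sprintf("  design: %d cases (p = %g) vs %d controls (p = %g)\n",
              x$n_cases, x$p_case, x$n_controls, x$p_control))
  cat(sprintf("  truncation error bound: %.2e; support %d x %d\n",
              x$error_bound, x$n_support[1], x$n_support[2]))
  invisible(x)
}

#' Power over a table of designs
#'
#' @param specs `data.frame` with columns n_cases, n_controls, p_case and
#'   either odds_ratio or p_control; optional alpha and tail columns.
#' @param ... Defaults passed to [fisher_exact_power()].
#' @return `specs` with appended `power` and `error_bound` columns.
#' @export
power_table <- function(specs, ...) {
  res <- lapply(seq_len(nrow(specs)), function(i) {
    args <- as.list(specs[i, intersect(names(specs),
      c("n_cases", "n_controls", "p_case", "odds_ratio", "p_control",
        "alpha", "tail")), drop = FALSE])
    do.call(fisher_exact_power, c(args, list(...)))
  })
  specs$power <- vapply(res, `[[`, numeric(1), "power")
  specs$error_bound <- vapply(res, `[[`, numeric(1), "error_bound")
  specs
}

#' Summarize a set of powers
#'
#' @param powers Numeric vector of power values.
#' @return Named vector: median and minimum.
#' @export
power_summary <- function(powers) {
  c(median = median(powers), min = min(powers))
}
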
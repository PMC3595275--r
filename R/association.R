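## Rare-carrier case-control statistics: exact tests on 2x2 carrier tables,
## odds ratios with Woolf and exact conditional confidence intervals,
## carrier-frequency estimates, pooled-cohort comparisons and multiple-testing
## adjustment. Exact tests follow the conventions of stats::fisher.test: the
## two-sided P is the minimum-likelihood sum (probabilities of all tables with
## fixed margins no more probable than the observed one) and the one-sided P
## is the hypergeometric tail toward enrichment in group 1.

#' A 2x2 carrier table
#'
#' @param a,b Carriers / non-carriers in group 1 (e.g. obese).
#' @param c,d Carriers / non-carriers in group 2 (e.g. non-obese).
#' @return A list of class `two_by_two`.
#' @export
two_by_two <- function(a, b, c, d) {
  v <- c(a = as.numeric(a)[1], b = as.numeric(b)[1],
         c = as.numeric(c)[1], d = as.numeric(d)[1])
  if (any(v < 0) || any(v != round(v))) stop("cell counts must be non-negative integers")
  structure(as.list(v), class = "two_by_two")
}

as_matrix_2x2 <- function(tab) {
  matrix(c(tab$a, tab$c, tab$b, tab$d), nrow = 2,
         dimnames = list(group = c("g1", "g2"), carrier = c("yes", "no")))
}

check_margins <- function(tab) {
  if ((tab$a + tab$b) == 0L || (tab$c + tab$d) == 0L ||
      (tab$a + tab$c) == 0L || (tab$b + tab$d) == 0L)
    stop("fisher_p undefined: empty margin in 2x2 table")
}

#' Fisher exact P-value for a 2x2 carrier table
#'
#' @param tab A [two_by_two()] table.
#' @param tail `"two.sided"` (minimum-likelihood convention) or `"one.sided"`
#'   (enrichment of carriers in group 1).
#' @return P-value.
#' @export
fisher_p <- function(tab, tail = c("two.sided", "one.sided")) {
  tail <- match.arg(tail)
  check_margins(tab)
  alternative <- if (tail == "one.sided") "greater" else "two.sided"
  stats::fisher.test(as_matrix_2x2(tab), alternative = alternative)$p.value
}

#' Odds ratio with confidence interval
#'
#' `method = "sample"` gives the cross-product (sample) odds ratio
#' `(a*d)/(b*c)` with a Woolf log-scale interval; `method = "exact"` gives the
#' conditional maximum-likelihood estimate with the exact conditional
#' (Cornfield-type) interval obtained by root-finding on noncentral
#' hypergeometric tails (as implemented by `stats::fisher.test`).
#'
#' @param tab A [two_by_two()] table.
#' @param method `"sample"` or `"exact"`.
#' @param conf_level Confidence level (default 0.95).
#' @param haldane Apply the Haldane-Anscombe +0.5 correction to every cell for
#'   the sample estimate (useful with zero cells)?
#' @return List with `estimate`, `conf_int` (length 2), `method` and
#'   `degenerate` (TRUE when a zero cell makes the sample estimate 0/Inf).
#' @export
odds_ratio <- function(tab, method = c("sample", "exact"), conf_level = 0.95,
                       haldane = FALSE) {
  method <- match.arg(method)
  z <- qnorm(1 - (1 - conf_level) / 2)
  if (method == "sample") {
    x <- c(tab$a, tab$b, tab$c, tab$d)
    degenerate <- any(x == 0)
    if (haldane) x <- x + 0.5
    est <- (x[1] * x[4]) / (x[2] * x[3])
    if (degenerate && !haldane) {
      ci <- c(NA_real_, NA_real_)
    } else {
      se <- sqrt(sum(1 / x))
      ci <- exp(log(est) + c(-1, 1) * z * se)
    }
    return(list(estimate = est, conf_int = ci, method = "sample_woolf",
                degenerate = degenerate))
  }
  ft <- stats::fisher.test(as_matrix_2x2(tab), conf.level = conf_level)
  list(estimate = unname(ft$estimate), conf_int = as.numeric(ft$conf.int),
       method = "exact_conditional", degenerate = FALSE)
}

#' Carrier-frequency estimate with confidence interval
#'
#' Wald interval `p +/- z * sqrt(p(1-p)/n)` truncated to `[0, 1]` by default;
#' Clopper-Pearson exact interval behind `method = "exact"`.
#'
#' @param x Carrier count.
#' @param n Total sample count (> 0).
#' @param conf_level Confidence level.
#' @param method `"wald"` or `"exact"`.
#' @return List with `estimate` and `conf_int`.
#' @export
carrier_frequency <- function(x, n, conf_level = 0.95,
                              method = c("wald", "exact")) {
  method <- match.arg(method)
  x <- unname(as.numeric(x)); n <- unname(as.numeric(n))
  if (n <= 0) stop("carrier_frequency undefined for n = 0")
  if (x < 0 || x > n) stop("x must be in [0, n]")
  p <- x / n
  if (method == "wald") {
    z <- qnorm(1 - (1 - conf_level) / 2)
    half <- z * sqrt(p * (1 - p) / n)
    ci <- pmin(pmax(c(p - half, p + half), 0), 1)
  } else {
    al <- (1 - conf_level) / 2
    lo <- if (x == 0) 0 else stats::qbeta(al, x, n - x + 1)
    hi <- if (x == n) 1 else stats::qbeta(1 - al, x + 1, n - x)
    ci <- c(lo, hi)
  }
  list(estimate = p, conf_int = ci, method = method)
}

#' Pool cohorts into a 2x2 comparison and test
#'
#' Builds a carrier table from per-cohort carrier counts, with one set of
#' cohorts on each side, and delegates to [fisher_p()] and [odds_ratio()].
#' A cohort may contribute to at most one side.
#'
#' @param counts `data.frame` with columns `cohort`, `carriers`, `total`.
#' @param side1,side2 Character vectors of cohort names.
#' @param tail Tail convention for the headline P (both are returned).
#' @return List of class `association_result`: `table` ([two_by_two()]),
#'   `p_two_sided`, `p_one_sided`, `or_sample`, `or_exact`, `freq_side1`,
#'   `freq_side2`.
#' @export
pool_and_test <- function(counts, side1, side2, tail = c("two.sided", "one.sided")) {
  tail <- match.arg(tail)
  stopifnot(all(c("cohort", "carriers", "total") %in% names(counts)))
  overlap <- intersect(side1, side2)
  if (length(overlap) > 0L)
    stop("cohort(s) on both sides of the comparison: ",
         paste(overlap, collapse = ", "))
  missing <- setdiff(c(side1, side2), counts$cohort)
  if (length(missing) > 0L)
    stop("unknown cohort(s): ", paste(missing, collapse = ", "))
  pick <- function(side) {
    sel <- counts[counts$cohort %in% side, , drop = FALSE]
    c(carriers = sum(sel$carriers), total = sum(sel$total))
  }
  s1 <- pick(side1); s2 <- pick(side2)
  tab <- two_by_two(s1["carriers"], s1["total"] - s1["carriers"],
                    s2["carriers"], s2["total"] - s2["carriers"])
  structure(list(
    table = tab,
    p_two_sided = fisher_p(tab, "two.sided"),
    p_one_sided = fisher_p(tab, "one.sided"),
    p = fisher_p(tab, tail),
    or_sample = odds_ratio(tab, "sample"),
    or_exact = odds_ratio(tab, "exact"),
    freq_side1 = carrier_frequency(s1["carriers"], s1["total"]),
    freq_side2 = carrier_frequency(s2["carriers"], s2["total"])
  ), class = "association_result")
}

#' Per-region obese vs non-obese exact tests from a carrier matrix
#'
#' Pools obese samples (obese case groups plus obese members of the
#' population cohort) against non-obese samples (control groups plus
#' normal-weight population members); overweight individuals are excluded
#' from the comparison. Regions that are uncallable or have no carriers on
#' either side get `NA` P-values.
#'
#' @param cm A [build_carrier_matrix()] object.
#' @return `data.frame` per region: carrier and total counts per side,
#'   two-sided and one-sided Fisher P, sample odds ratio.
#' @export
case_control_test <- function(cm) {
  ph <- cm$phenotypes[!cm$phenotypes$excluded, , drop = FALSE]
  obese <- ph$group %in% c("case_obese_child", "case_obese_adult") |
    (ph$group == "population" & !is.na(ph$weight_class) &
       ph$weight_class == "obese")
  nonob <- ph$group %in% c("control_child", "control_adult") |
    (ph$group == "population" & !is.na(ph$weight_class) &
       ph$weight_class == "normal")
  st <- cm$status[ph$sample_id, , drop = FALSE]
  res <- lapply(colnames(st), function(rid) {
    if (cm$index$uncallable[region_row(cm$index, rid)]) {
      return(data.frame(region_id = rid, carriers_obese = 0L,
                        n_obese = sum(obese), carriers_nonobese = 0L,
                        n_nonobese = sum(nonob), p_two_sided = NA_real_,
                        p_one_sided = NA_real_, or_sample = NA_real_,
                        stringsAsFactors = FALSE))
    }
    carrier <- st[, rid] == "carrier"
    a <- sum(carrier & obese); n1 <- sum(obese)
    c_ <- sum(carrier & nonob); n2 <- sum(nonob)
    if (a + c_ == 0L) {
      p2 <- p1 <- or <- NA_real_
    } else {
      tab <- two_by_two(a, n1 - a, c_, n2 - c_)
      p2 <- fisher_p(tab, "two.sided")
      p1 <- fisher_p(tab, "one.sided")
      or <- odds_ratio(tab, "sample")$estimate
    }
    data.frame(region_id = rid, carriers_obese = a, n_obese = n1,
               carriers_nonobese = c_, n_nonobese = n2,
               p_two_sided = p2, p_one_sided = p1, or_sample = or,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Carrier vs reciprocal-carrier counts by cohort
#'
#' Tabulates, per region and cohort, expected-class carriers and reciprocal
#' (opposite-class) carriers; no test is performed.
#'
#' @param cm A [build_carrier_matrix()] object.
#' @return Long `data.frame`: region_id, cohort, n_carrier, n_reciprocal, n.
#' @export
reciprocal_frequency_table <- function(cm) {
  ph <- cm$phenotypes[!cm$phenotypes$excluded, , drop = FALSE]
  st <- cm$status[ph$sample_id, , drop = FALSE]
  out <- list()
  for (rid in colnames(st)) {
    for (coh in unique(ph$cohort)) {
      sel <- ph$cohort == coh
      out[[paste(rid, coh)]] <- data.frame(
        region_id = rid, cohort = coh,
        n_carrier = sum(st[sel, rid] == "carrier"),
        n_reciprocal = sum(st[sel, rid] == "reciprocal_carrier"),
        n = sum(sel), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Multiple-testing adjustment
#'
#' Bonferroni or Benjamini-Hochberg step-up adjustment (wraps
#' `stats::p.adjust`); `m` overrides the number of tests.
#'
#' @param p Numeric vector of P-values in `[0, 1]`.
#' @param method `"BH"` or `"bonferroni"`.
#' @param m Number of comparisons (defaults to `length(p)`).
#' @return Adjusted P-values.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni"), m = length(p)) {
  method <- match.arg(method)
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = method, n = m)
}

#' @export
print.association_result <- function(x, ...) {
  t <- x$table
  cat(sprintf("2x2: %d/%d vs %d/%d\n", t$a, t$a + t$b, t$c, t$c + t$d))
  cat(sprintf("  P (two-sided) = %.3g, P (one-sided) = %.3g\n",
              x$p_two_sided, x$p_one_sided))
  cat(sprintf("  OR (sample)  = %.3g [%.3g, %.3g] (Woolf)\n",
              x$or_sample$estimate, x$or_sample$conf_int[1],
              x$or_sample$conf_int[2]))
  cat(sprintf("  OR (exact)   = %.3g [%.3g, %.3g] (conditional)\n",
              x$or_exact$estimate, x$or_exact$conf_int[1],
              x$or_exact$conf_int[2]))
  invisible(x)
}
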
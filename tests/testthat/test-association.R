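test_that("fisher_p matches direct hypergeometric enumeration on random tables", {
  set.seed(101)
  for (i in 1:60) {
    n1 <- sample(1:12, 1); n2 <- sample(1:12, 1)
    a <- sample(0:n1, 1); c_ <- sample(0:n2, 1)
    tab <- two_by_two(a, n1 - a, c_, n2 - c_)
    if ((a + c_) == 0 || (a + c_) == n1 + n2) next  # empty carrier margin
    expect_equal(fisher_p(tab, "two.sided"),
                 oracle_fisher(a, n1 - a, c_, n2 - c_, "two.sided"),
                 tolerance = 1e-10)
    expect_equal(fisher_p(tab, "one.sided"),
                 oracle_fisher(a, n1 - a, c_, n2 - c_, "one.sided"),
                 tolerance = 1e-10)
  }
})

test_that("fisher_p handles degenerate and balanced tables", {
  expect_equal(fisher_p(two_by_two(1, 1, 1, 1)), 1)
  expect_error(fisher_p(two_by_two(0, 0, 3, 4)), "empty margin")
  tab <- two_by_two(6, 1810, 0, 4526)
  # two-sided is at least the point probability and, for this one-sided-
  # extreme split, coincides with the one-sided tail
  expect_gte(fisher_p(tab, "two.sided"),
             dhyper(6, 6, 1810 + 4526, 1816))
  expect_equal(fisher_p(tab, "two.sided"), fisher_p(tab, "one.sided"),
               tolerance = 1e-12)
})

test_that("odds ratios reproduce the published pooled estimates", {
  or1 <- odds_ratio(two_by_two(5, 640, 11, 54130), "sample")
  expect_equal(signif(or1$estimate, 3), 38.4)
  or2 <- odds_ratio(two_by_two(10, 1975, 14, 69189), "sample")
  expect_equal(signif(or2$estimate, 3), 25.0)
  # exact conditional estimate is also available, with a finite interval
  ex <- odds_ratio(two_by_two(10, 1975, 14, 69189), "exact")
  expect_true(ex$conf_int[1] > 1 && ex$conf_int[2] < Inf)
  expect_true(ex$conf_int[1] < ex$estimate && ex$estimate < ex$conf_int[2])
})

test_that("sample odds ratio symmetries and zero-cell handling", {
  tab <- two_by_two(7, 93, 3, 197)
  or <- odds_ratio(tab, "sample")$estimate
  # swapping both rows and both columns leaves the estimate unchanged
  expect_equal(odds_ratio(two_by_two(197, 3, 93, 7), "sample")$estimate, or)
  # swapping one margin inverts it
  expect_equal(odds_ratio(two_by_two(3, 197, 7, 93), "sample")$estimate, 1 / or)
  expect_equal(odds_ratio(two_by_two(9, 21, 9, 21), "sample")$estimate, 1)
  z <- odds_ratio(two_by_two(5, 95, 0, 100), "sample")
  expect_true(z$degenerate)
  expect_equal(z$estimate, Inf)
  zh <- odds_ratio(two_by_two(5, 95, 0, 100), "sample", haldane = TRUE)
  expect_true(is.finite(zh$estimate) && all(is.finite(zh$conf_int)))
})

test_that("carrier frequencies reproduce the published Wald intervals", {
  pop <- carrier_frequency(14, 69203)
  expect_equal(signif(pop$estimate, 2), 2.0e-4)
  expect_equal(signif(pop$conf_int, 2), c(9.6e-5, 3.1e-4))
  cases <- carrier_frequency(10, 1985)
  expect_equal(round(100 * cases$estimate, 1), 0.5)
  expect_equal(round(100 * cases$conf_int, 2), c(0.19, 0.82))
  # degenerate Wald at zero carriers
  z <- carrier_frequency(0, 1000)
  expect_equal(z$estimate, 0)
  expect_equal(z$conf_int, c(0, 0))
  expect_error(carrier_frequency(1, 0), "n = 0")
  # interval width shrinks as 1/sqrt(n) at fixed estimate
  w <- vapply(c(1e3, 1e5, 1e7), function(n)
    diff(carrier_frequency(round(0.02 * n), n)$conf_int), numeric(1))
  expect_true(all(diff(w) < 0))
  expect_lt(w[3], w[1] / 50)
})

test_that("pooled cohort comparisons reproduce the published tests", {
  counts <- data.frame(
    cohort = c("child_fr", "seo_uk", "goos_uk", "adult_fr", "bariatric_fr",
               "nfbc1966", "egcut", "colaus", "decode", "ship",
               "wtccc2_gain", "isc_parc"),
    carriers = c(5, 3, 2, 0, 0, 4, 0, 1, 6, 0, 2, 1),
    total = c(645, 278, 1062, 701, 139, 5213, 2665, 5612, 36583, 4068,
              7362, 7700), stringsAsFactors = FALSE)
  pop_direct <- c("nfbc1966", "egcut", "colaus", "decode", "ship")
  pop_all <- c(pop_direct, "wtccc2_gain", "isc_parc")
  child_all <- c("child_fr", "seo_uk", "goos_uk")

  r1 <- pool_and_test(counts, "child_fr", pop_direct)
  expect_equal(r1$table$a, 5); expect_equal(r1$table$c, 11)
  expect_equal(r1$p_two_sided, 8.74e-7, tolerance = 5e-3)

  r2 <- pool_and_test(counts, child_all, pop_all)
  expect_equal(r2$table$a + r2$table$b, 1985)
  expect_equal(r2$table$c + r2$table$d, 69203)
  expect_equal(r2$p_two_sided, 3.81e-10, tolerance = 5e-3)

  r3 <- pool_and_test(counts, "child_fr", "nfbc1966")
  expect_equal(r3$p_two_sided, 1.4e-3, tolerance = 0.05)

  # adult obesity total vs child obesity total
  r4 <- pool_and_test(counts, child_all, c("adult_fr", "bariatric_fr"))
  expect_equal(r4$p_two_sided, 0.039, tolerance = 0.05)

  expect_error(pool_and_test(counts, c("child_fr", "nfbc1966"),
                             c("nfbc1966")), "both sides")
  expect_error(pool_and_test(counts, "child_fr", "nowhere"), "unknown cohort")
})

test_that("case-control tests pool obese case groups with obese population members", {
  loc <- make_loci(make_locus(3, chrom = "c1", region_id = "r3"))
  r <- loc$regions
  ph <- rbind(
    phen(sprintf("ob%02d", 1:20), group = "case_obese_child", bmi = 33),
    phen(sprintf("ct%02d", 1:20), group = "control_child", bmi = 22),
    phen(sprintf("po%02d", 1:30), group = "population",
         bmi = c(rep(33, 5), rep(27, 5), rep(22, 20))))
  calls <- rbind(seg("ob01", "c1", r$start - 100, r$end + 100, 1),
                 seg("po01", "c1", r$start - 100, r$end + 100, 1),  # obese pop
                 seg("po06", "c1", r$start - 100, r$end + 100, 1))  # overweight
  cm <- build_carrier_matrix(calls, ph, loc$index)
  cc <- case_control_test(cm)
  expect_equal(cc$carriers_obese, 2L)        # case + obese population member
  expect_equal(cc$n_obese, 25L)              # overweight excluded
  expect_equal(cc$carriers_nonobese, 0L)
  expect_equal(cc$n_nonobese, 40L)
  expect_equal(cc$p_two_sided,
               oracle_fisher(2, 23, 0, 40, "two.sided"), tolerance = 1e-10)
})

test_that("reciprocal tabulation is a pure counting identity", {
  loc <- make_loci(make_locus(4, chrom = "c1", region_id = "r4"))
  r <- loc$regions
  ph <- phen(c("s1", "s2", "s3"), cohort = c("A", "A", "B"))
  calls <- rbind(seg("s1", "c1", r$start - 5000, r$end + 5000, 1),
                 seg("s2", "c1", r$start - 5000, r$end + 5000, 3))
  cm <- build_carrier_matrix(calls, ph, loc$index)
  tab <- reciprocal_frequency_table(cm)
  a <- tab[tab$cohort == "A", ]
  expect_equal(a$n_carrier, 1L)
  expect_equal(a$n_reciprocal, 1L)
  expect_equal(tab[tab$cohort == "B", ]$n_carrier, 0L)
})

test_that("p-value adjustment matches the step-up definition", {
  expect_equal(adjust_pvalues(0.01, "bonferroni", m = 18), 0.18)
  p_same <- rep(0.03, 5)
  expect_equal(adjust_pvalues(p_same, "BH"), p_same)
  set.seed(7)
  for (i in 1:10) {
    p <- runif(sample(3:20, 1))
    # direct step-up formula
    m <- length(p); o <- order(p, decreasing = TRUE)
    ro <- order(o)
    expected <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
    expect_equal(adjust_pvalues(p, "BH"), expected)
    expect_true(all(adjust_pvalues(p, "BH") <= 1))
  }
})
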
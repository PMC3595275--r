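## Quantitative-trait association of carrier status with BMI in a population
## cohort: two-way ANOVA on log10 BMI with sex fitted first (sequential sums
## of squares, the aov idiom), Welch t comparisons of carrier means, Z-score
## analysis of carriers against their own cohort's BMI distribution, and
## subgroup contrasts for loci where variants of different extent may have
## different effects.

#' Two-way ANOVA of carrier status on log10 BMI
#'
#' Fits `log_bmi ~ sex + carrier(s)` with sequential (type-I) sums of squares
#' so that the carrier factor is tested after sex, matching the classical
#' two-way `aov` idiom; `type = "type2"` gives order-independent type-II
#' tests instead. In joint mode several carrier indicators are fitted in a
#' single model. Effect sizes are back-transformed to the BMI scale via the
#' carrier and non-carrier geometric means.
#'
#' @param log_bmi Numeric response: log10-transformed BMI.
#' @param sex Factor-like sex covariate.
#' @param carriers Logical/0-1 vector (one region) or matrix with one column
#'   per region (joint mode).
#' @param min_carriers Regions with fewer carriers are skipped (default 3).
#' @param type `"sequential"` (type-I, sex first) or `"type2"`.
#' @param conf_level Confidence level for the BMI-change interval.
#' @return `data.frame` per tested region: n_carriers, F, p, mean BMI change
#'   of carriers with confidence interval (kg/m^2, back-transformed).
#' @export
anova_carrier_bmi <- function(log_bmi, sex, carriers, min_carriers = 3L,
                              type = c("sequential", "type2"),
                              conf_level = 0.95) {
  type <- match.arg(type)
  if (is.null(dim(carriers))) carriers <- cbind(region = carriers)
  carriers <- carriers != 0
  if (is.null(colnames(carriers)))
    colnames(carriers) <- paste0("region", seq_len(ncol(carriers)))
  stopifnot(length(log_bmi) == nrow(carriers), length(sex) == length(log_bmi))
  if (stats::var(log_bmi) == 0)
    stop("zero variance in response; ANOVA undefined")
  keep <- colSums(carriers) >= min_carriers
  if (!any(keep)) {
    return(data.frame(region = character(0), n_carriers = integer(0),
                      f_value = numeric(0), p_value = numeric(0),
                      bmi_change = numeric(0), change_lo = numeric(0),
                      change_hi = numeric(0), stringsAsFactors = FALSE))
  }
  carriers <- carriers[, keep, drop = FALSE]
  dat <- data.frame(y = log_bmi, sex = factor(sex))
  for (j in colnames(carriers)) dat[[j]] <- factor(carriers[, j],
                                                   levels = c(FALSE, TRUE))
  terms <- colnames(carriers)
  fml <- stats::as.formula(paste("y ~ sex +", paste(terms, collapse = " + ")))
  fit <- lm(fml, data = dat)
  at <- if (type == "sequential") anova(fit) else type2_anova(fit, dat, terms)
  rows <- lapply(terms, function(tm) {
    i <- match(tm, rownames(at))
    cc <- carriers[, tm]
    eff <- bmi_change_ci(log_bmi, cc, conf_level)
    data.frame(region = tm, n_carriers = sum(cc),
               f_value = at[i, "F value"], p_value = at[i, "Pr(>F)"],
               bmi_change = eff[1], change_lo = eff[2], change_hi = eff[3],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# type-II test of each carrier term: F from comparing the full model to the
# model dropping only that term
type2_anova <- function(fit, dat, terms) {
  full <- fit
  tab <- matrix(NA_real_, nrow = length(terms), ncol = 2,
                dimnames = list(terms, c("F value", "Pr(>F)")))
  for (tm in terms) {
    red <- stats::update(full, stats::as.formula(paste(". ~ . -", tm)),
                         data = dat)
    a <- anova(red, full)
    tab[tm, ] <- c(a[2, "F"], a[2, "Pr(>F)"])
  }
  tab
}

# mean BMI change (kg/m^2) of carriers vs non-carriers: difference of
# geometric means, with the t-based CI of the log-scale mean difference
# back-transformed around the non-carrier geometric mean
bmi_change_ci <- function(log_bmi, carrier, conf_level = 0.95) {
  x <- log_bmi[carrier]
  y <- log_bmi[!carrier]
  gm_y <- 10^mean(y)
  d <- mean(x) - mean(y)
  se <- sqrt(stats::var(x) / length(x) + stats::var(y) / length(y))
  df <- welch_df(stats::var(x), length(x), stats::var(y), length(y))
  tq <- stats::qt(1 - (1 - conf_level) / 2, df)
  ci_d <- d + c(-1, 1) * tq * se
  c(gm_y * (10^d - 1), gm_y * (10^ci_d - 1))
}

welch_df <- function(v1, n1, v2, n2) {
  (v1 / n1 + v2 / n2)^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
}

#' Welch t-test of carrier BMI against the rest of a cohort
#'
#' Heteroscedastic (Welch) two-sample t-test with Welch-Satterthwaite degrees
#' of freedom; the confidence interval for the mean difference is always the
#' central two-sided interval, while the P-value follows the requested tail.
#'
#' @param carrier_bmi BMI values of carriers (>= 2).
#' @param cohort_bmi BMI values of the comparison set (e.g. the remainder of
#'   the cohort).
#' @param tail `"one.sided"` (carriers higher), `"two.sided"`, or
#'   `"one.sided.less"`.
#' @param conf_level Confidence level.
#' @return List: `mean_diff`, `conf_int`, `p_value`, `df`, `n_carriers`.
#' @export
carrier_mean_test <- function(carrier_bmi, cohort_bmi,
                              tail = c("one.sided", "two.sided", "one.sided.less"),
                              conf_level = 0.95) {
  tail <- match.arg(tail)
  if (length(carrier_bmi) < 2L)
    stop("carrier_mean_test requires >= 2 carriers")
  alt <- switch(tail, one.sided = "greater", one.sided.less = "less",
                two.sided = "two.sided")
  tt <- t.test(carrier_bmi, cohort_bmi, alternative = alt, var.equal = FALSE)
  ci <- t.test(carrier_bmi, cohort_bmi, alternative = "two.sided",
               var.equal = FALSE, conf.level = conf_level)$conf.int
  list(mean_diff = mean(carrier_bmi) - mean(cohort_bmi),
       conf_int = as.numeric(ci), p_value = tt$p.value,
       df = unname(tt$parameter), n_carriers = length(carrier_bmi))
}

#' Z-score analysis of carrier BMI across cohorts
#'
#' Standardizes each carrier's BMI against its own cohort's mean and standard
#' deviation (computed from all non-excluded cohort members), then tests
#' whether the mean carrier Z-score exceeds 0 by a one-tailed normal test at
#' `mean(Z) * sqrt(n)`. The reported interval is `mean(Z) +/- z * sd(Z)/sqrt(n)`
#' by default (`sd_method = "sample"`); `sd_method = "null"` uses the
#' unit-variance null standard deviation instead.
#'
#' @param bmi,cohort BMI values and cohort labels for all samples.
#' @param carrier Logical: which samples are carriers.
#' @param sd_method `"sample"` or `"null"` (see above).
#' @param conf_level Confidence level for the mean-Z interval.
#' @return List: `z` (per-carrier scores), `mean_z`, `conf_int`,
#'   `p_one_sided`, `n_carriers`.
#' @export
zscore_test <- function(bmi, cohort, carrier, sd_method = c("sample", "null"),
                        conf_level = 0.95) {
  sd_method <- match.arg(sd_method)
  stopifnot(length(bmi) == length(cohort), length(bmi) == length(carrier))
  mu <- tapply(bmi, cohort, mean)
  sdv <- tapply(bmi, cohort, sd)
  if (any(is.na(sdv[unique(cohort[carrier])])) ||
      any(sdv[unique(cohort[carrier])] == 0))
    stop("cohort SD unavailable or zero for a carrier's cohort")
  z <- (bmi[carrier] - mu[cohort[carrier]]) / sdv[cohort[carrier]]
  z <- as.numeric(z)
  n <- length(z)
  if (n == 0L) stop("no carriers")
  mz <- mean(z)
  p <- pnorm(mz * sqrt(n), lower.tail = FALSE)
  zq <- qnorm(1 - (1 - conf_level) / 2)
  s <- if (sd_method == "sample" && n >= 2L) sd(z) else 1
  list(z = z, mean_z = mz, conf_int = mz + c(-1, 1) * zq * s / sqrt(n),
       p_one_sided = p, n_carriers = n)
}

#' Subgroup contrasts for variants of heterogeneous extent
#'
#' For a locus whose variants split into two subgroups (e.g. large deletions
#' extending beyond the canonical region vs small ones), tests each subgroup
#' against the population and the two subgroups against each other with
#' Welch t-tests in the stated direction. A subgroup of size 1 cannot support
#' a t-test and is handled as a single-observation Z-score against the
#' population mean and SD.
#'
#' @param bmi_a,bmi_b BMI values of the two carrier subgroups (non-empty).
#' @param bmi_population BMI values of the (non-carrier) population.
#' @param alternative Direction for subgroup A relative to the comparison
#'   set: `"less"`, `"greater"` or `"two.sided"`.
#' @return List with `a_vs_population`, `b_vs_population` (each: mean_diff,
#'   p_value, method) and `a_vs_b` (one-tailed Welch t in the stated
#'   direction).
#' @export
subgroup_contrast <- function(bmi_a, bmi_b, bmi_population,
                              alternative = c("less", "greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(bmi_a) == 0L || length(bmi_b) == 0L)
    stop("empty carrier subgroup")
  vs_pop <- function(x, alt) {
    if (length(x) == 1L) {
      z <- (x - mean(bmi_population)) / sd(bmi_population)
      p <- switch(alt, less = pnorm(z), greater = pnorm(z, lower.tail = FALSE),
                  two.sided = 2 * pnorm(-abs(z)))
      return(list(mean_diff = x - mean(bmi_population), p_value = p,
                  method = "single_observation_z"))
    }
    tt <- t.test(x, bmi_population, alternative = alt, var.equal = FALSE)
    list(mean_diff = mean(x) - mean(bmi_population), p_value = tt$p.value,
         method = "welch_t")
  }
  ab_alt <- alternative
  a_vs_b <- if (length(bmi_a) == 1L || length(bmi_b) == 1L) {
    one <- if (length(bmi_a) == 1L) bmi_a else bmi_b
    many <- if (length(bmi_a) == 1L) bmi_b else bmi_a
    z <- (one - mean(many)) / sd(many)
    if (length(bmi_b) == 1L) z <- -z  # keep direction: A relative to B
    p <- switch(ab_alt, less = pnorm(z), greater = pnorm(z, lower.tail = FALSE),
                two.sided = 2 * pnorm(-abs(z)))
    list(mean_diff = mean(bmi_a) - mean(bmi_b), p_value = p,
         method = "single_observation_z")
  } else {
    tt <- t.test(bmi_a, bmi_b, alternative = ab_alt, var.equal = FALSE)
    list(mean_diff = mean(bmi_a) - mean(bmi_b), p_value = tt$p.value,
         method = "welch_t")
  }
  pop_alt_b <- "two.sided"
  list(a_vs_population = vs_pop(bmi_a, alternative),
       b_vs_population = vs_pop(bmi_b, pop_alt_b),
       a_vs_b = a_vs_b)
}
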
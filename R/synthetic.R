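## Synthetic cohort generator with known ground truth. Emulates the inputs of
## the replication pipeline end to end: a probe map matching the published
## per-region probe coverage, phenotypes with obesity-ascertained case-control
## groups plus a population cohort, and segment-level copy-number calls for
## injected carriers -- full-span with breakpoint jitter for small regions,
## optionally fragmented (but never below the merge-rule coverage threshold)
## for probe-dense regions -- with optional reciprocal variants and
## group-differential false-positive/false-negative call error.

#' Specification of a synthetic cohort
#'
#' @param n Named group sizes. Defaults mirror the replication design:
#'   557 child controls, 645 obese children, 843 adult controls, 701 obese
#'   adults and a 5213-person population cohort.
#' @param carrier_freq Baseline (control/population) carrier frequency,
#'   scalar or named per-region vector.
#' @param freq_by_group Optional matrix of carrier probabilities, regions x
#'   groups (dimnames required), overriding `carrier_freq`/`case_or`: each
#'   sample carries at the frequency of its own group. Mutually exclusive
#'   with `case_or != 1`.
#' @param case_or Odds ratio of carriage for obese vs normal-weight samples
#'   (case-control style effect). Carrier probability follows weight class:
#'   obese samples carry at the case frequency, normal-weight at
#'   `carrier_freq`, overweight at the geometric midpoint on the odds scale.
#' @param bmi_shift Additive shift of carriers' log10 BMI (population-style
#'   effect). Mutually exclusive with `case_or != 1`.
#' @param reciprocal_freq Frequency of opposite-class variants among
#'   non-carriers.
#' @param bmi_mu,bmi_sigma Named (`M`, `F`) mean and SD of log10 BMI. The
#'   defaults (mu = log10(25.5) / log10(24.5), sigma = 0.07) give a realistic
#'   adult obesity prevalence of roughly 15-20 percent.
#' @param fragmentation_prob Probability that a carrier call at a probe-dense
#'   region (>= `merge_min_probes` in-region probes) is emitted as two
#'   fragments rather than one spanning call.
#' @param frag_min_coverage Minimum fraction of in-region probes jointly
#'   covered by the fragments; must exceed 0.5 so fragmentation never breaks
#'   the ground truth under the merge rule.
#' @param merge_min_probes In-region probe count from which fragmentation may
#'   apply (default 11, aligned with [qualification_rules()]).
#' @param jitter_probes Maximum breakpoint jitter, in flanking probes, added
#'   independently at each call end.
#' @param fp,fn Named (`case`, `control`) false-positive and false-negative
#'   call probabilities; `case` applies to the obese case groups, `control`
#'   to control groups and the population cohort.
#' @param exclude_prob Probability a sample is flagged excluded (emulating
#'   prior known single-locus variant carriers).
#' @param seed Integer seed; mandatory, all generation is reproducible from it.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n = c(control_child = 557L, case_obese_child = 645L,
                              control_adult = 843L, case_obese_adult = 701L,
                              population = 5213L),
                        carrier_freq = 0.002, freq_by_group = NULL,
                        case_or = 1, bmi_shift = 0,
                        reciprocal_freq = 0,
                        bmi_mu = c(M = log10(25.5), F = log10(24.5)),
                        bmi_sigma = c(M = 0.07, F = 0.07),
                        fragmentation_prob = 0.25, frag_min_coverage = 0.6,
                        merge_min_probes = 11L, jitter_probes = 2L,
                        fp = c(case = 0, control = 0),
                        fn = c(case = 0, control = 0),
                        exclude_prob = 0, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(all(names(n) %in% SAMPLE_GROUPS), all(n >= 0),
            all(carrier_freq >= 0 & carrier_freq <= 1),
            case_or > 0, reciprocal_freq >= 0, reciprocal_freq <= 1,
            all(bmi_sigma > 0), fragmentation_prob >= 0,
            fragmentation_prob <= 1, jitter_probes >= 0,
            all(fp >= 0 & fp <= 1), all(fn >= 0 & fn <= 1),
            exclude_prob >= 0, exclude_prob < 1)
  if (fragmentation_prob > 0 && frag_min_coverage <= 0.5)
    stop("frag_min_coverage must exceed 0.5: fragmentation below the merge ",
         "threshold would contradict the generated ground truth")
  if (case_or != 1 && bmi_shift != 0)
    stop("specify the effect either as case_or or as bmi_shift, not both")
  if (!is.null(freq_by_group)) {
    if (case_or != 1)
      stop("freq_by_group and case_or are mutually exclusive")
    stopifnot(is.matrix(freq_by_group), !is.null(dimnames(freq_by_group)),
              all(freq_by_group >= 0 & freq_by_group <= 1),
              all(colnames(freq_by_group) %in% SAMPLE_GROUPS))
  }
  structure(list(n = n, carrier_freq = carrier_freq,
                 freq_by_group = freq_by_group, case_or = case_or,
                 bmi_shift = bmi_shift, reciprocal_freq = reciprocal_freq,
                 bmi_mu = bmi_mu, bmi_sigma = bmi_sigma,
                 fragmentation_prob = fragmentation_prob,
                 frag_min_coverage = frag_min_coverage,
                 merge_min_probes = as.integer(merge_min_probes),
                 jitter_probes = as.integer(jitter_probes),
                 fp = fp, fn = fn, exclude_prob = exclude_prob,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Published candidate-locus fixture: 18 regions and a matching probe map
#'
#' The 18 candidate obesity loci (hg18, 1-based inclusive) with a synthetic
#' probe map whose in-region probe counts equal the published per-region
#' array coverage exactly (0 to 207 probes); 12 additional probes are placed
#' in each 500 kb flank so that calls at 1- and 2-probe regions can satisfy
#' the minimum consecutive-probe criterion by extending over flanking probes.
#'
#' @param flank_probes Number of synthetic probes per 500 kb flank.
#' @return List with `regions` (18-row region table) and `probe_map`.
#' @export
fixture_paper_regions <- function(flank_probes = 12L) {
  rg <- region_definitions(
    chrom = c("chr3", "chr6", "chr8", "chr10", "chr11", "chr11", "chr15",
              "chr16", "chr17", "chr22", "chr3", "chr5", "chr5", "chr5",
              "chr7", "chr7", "chr17", "chr19"),
    start = c(89250592, 52875284, 143268033, 541873, 72013333, 105716030,
              28700879, 28731428, 2224814, 49246176, 104059109, 53467427,
              77039051, 83835179, 20708193, 113843696, 49444406, 10489548),
    end = c(89319536, 52892054, 143634461, 818440, 72089312, 106419349,
            30231488, 28951376, 2256880, 49313898, 104092618, 53480255,
            77076628, 83874339, 20711088, 113859679, 49449022, 10512171),
    region_id = c("chr3_89.25Mb_gain", "chr6_52.88Mb_loss",
                  "chr8_143.27Mb_gain", "chr10_0.54Mb_gain",
                  "chr11_72.01Mb_gain", "chr11_105.72Mb_loss",
                  "chr15_28.70Mb_gain", "chr16_28.73Mb_loss",
                  "chr17_2.22Mb_gain", "chr22_49.25Mb_gain",
                  "chr3_104.06Mb_loss", "chr5_53.47Mb_gain",
                  "chr5_77.04Mb_loss", "chr5_83.84Mb_loss",
                  "chr7_20.71Mb_loss", "chr7_113.84Mb_loss",
                  "chr17_49.44Mb_gain", "chr19_10.49Mb_loss"),
    variant_class = c("gain", "loss", "gain", "gain", "gain", "loss", "gain",
                      "loss", "gain", "gain", "loss", "gain", "loss", "loss",
                      "loss", "loss", "gain", "loss"))
  n_probes <- c(3L, 0L, 68L, 42L, 11L, 113L, 207L, 28L, 6L, 11L,
                2L, 2L, 5L, 3L, 2L, 1L, 1L, 4L)
  pm <- list()
  for (i in seq_len(nrow(rg))) {
    np <- n_probes[i]
    inside <- if (np == 0L) numeric(0)
              else if (np == 1L) round((rg$start[i] + rg$end[i]) / 2)
              else round(seq(rg$start[i], rg$end[i], length.out = np))
    left <- round(seq(rg$start[i] - 480000, rg$start[i] - 20000,
                      length.out = flank_probes))
    right <- round(seq(rg$end[i] + 20000, rg$end[i] + 480000,
                       length.out = flank_probes))
    pos <- c(left, inside, right)
    pm[[i]] <- data.frame(chrom = rg$chrom[i], position = pos,
                          probe_id = sprintf("p_%s_%03d", rg$region_id[i],
                                             seq_along(pos)),
                          stringsAsFactors = FALSE)
  }
  probe_map <- validate_probe_map(do.call(rbind, pm))
  list(regions = rg, probe_map = probe_map)
}

GROUP_COHORT <- c(control_child = "child_cc", case_obese_child = "child_cc",
                  control_adult = "adult_cc", case_obese_adult = "adult_cc",
                  population = "population")
GROUP_ERRCLASS <- c(control_child = "control", case_obese_child = "case",
                    control_adult = "control", case_obese_adult = "case",
                    population = "control")

#' Generate a synthetic cohort
#'
#' Draws phenotypes, ground-truth carrier assignments and segment-level
#' copy-number calls according to a [cohort_spec()], against a region set and
#' probe map (defaults: [fixture_paper_regions()]). Everything is
#' reproducible from `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param regions,probe_map Region table and probe map; both default to the
#'   published-locus fixture.
#' @return List of class `synthetic_cohort`: `regions`, `probe_map`,
#'   `phenotypes`, `segment_calls`, `ground_truth` (sample_id, region_id,
#'   class in `{carrier, reciprocal}`), `index`, `spec`.
#' @export
generate_cohort <- function(spec, regions = NULL, probe_map = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(regions) || is.null(probe_map)) {
    fx <- fixture_paper_regions()
    if (is.null(regions)) regions <- fx$regions
    if (is.null(probe_map)) probe_map <- fx$probe_map
  }
  index <- build_region_probe_index(regions, probe_map)
  set.seed(spec$seed)

  n_tot <- sum(spec$n)
  group <- rep(names(spec$n), times = spec$n)
  sample_id <- sprintf("S%05d", seq_len(n_tot))
  sex <- sample(c("M", "F"), n_tot, replace = TRUE)
  age <- ifelse(grepl("child", group), round(runif(n_tot, 6, 17)),
                ifelse(group == "population", 31, round(runif(n_tot, 25, 60))))

  freq <- rep_len(spec$carrier_freq, nrow(regions))
  if (!is.null(names(spec$carrier_freq)) && length(spec$carrier_freq) > 1L)
    freq <- spec$carrier_freq[regions$region_id]
  names(freq) <- regions$region_id

  mu0 <- unname(spec$bmi_mu[sex])
  sigma0 <- unname(spec$bmi_sigma[sex])

  if (spec$case_or == 1 || spec$bmi_shift != 0) {
    # population-style effect: carriers drawn group-independently (or at
    # per-group frequencies), BMI shifted for carriers
    if (is.null(spec$freq_by_group)) {
      prob <- matrix(rep(freq, each = n_tot), nrow = n_tot)
    } else {
      fbg <- spec$freq_by_group
      missing_g <- setdiff(unique(group), colnames(fbg))
      if (length(missing_g) > 0L)
        stop("freq_by_group lacks group(s): ", paste(missing_g, collapse = ", "))
      missing_r <- setdiff(regions$region_id, rownames(fbg))
      if (length(missing_r) > 0L)
        stop("freq_by_group lacks region(s): ", paste(missing_r, collapse = ", "))
      prob <- t(fbg[regions$region_id, group, drop = FALSE])
    }
    carrier <- matrix(runif(n_tot * nrow(regions)) < prob, nrow = n_tot)
    shift <- rowSums(carrier) * spec$bmi_shift
    log_bmi <- truncate_by_group(mu0 + shift, sigma0, group)
  } else {
    # case-control-style effect: carrier probability follows weight class
    log_bmi <- truncate_by_group(mu0, sigma0, group)
    wc <- weight_class(10^log_bmi)
    odds0 <- freq / (1 - freq)
    carrier <- matrix(FALSE, n_tot, nrow(regions))
    for (j in seq_len(nrow(regions))) {
      oddsj <- odds0[j] * spec$case_or^c(normal = 0, overweight = 0.5,
                                         obese = 1)[wc]
      carrier[, j] <- runif(n_tot) < oddsj / (1 + oddsj)
    }
  }
  colnames(carrier) <- regions$region_id
  reciprocal <- matrix(runif(n_tot * nrow(regions)) < spec$reciprocal_freq,
                       nrow = n_tot) & !carrier
  colnames(reciprocal) <- regions$region_id

  excluded <- runif(n_tot) < spec$exclude_prob
  phenotypes <- validate_phenotypes(data.frame(
    sample_id = sample_id, cohort = unname(GROUP_COHORT[group]), group = group,
    sex = sex, age = age, bmi = round(10^log_bmi, 2), excluded = excluded,
    exclusion_reason = ifelse(excluded, "prior_single_locus_variant", ""),
    stringsAsFactors = FALSE))

  gt_idx <- which(carrier | reciprocal, arr.ind = TRUE)
  ground_truth <- data.frame(
    sample_id = sample_id[gt_idx[, 1L]],
    region_id = regions$region_id[gt_idx[, 2L]],
    class = ifelse(carrier[gt_idx], "carrier", "reciprocal"),
    stringsAsFactors = FALSE)
  ground_truth <- ground_truth[order(ground_truth$sample_id,
                                     ground_truth$region_id), , drop = FALSE]
  rownames(ground_truth) <- NULL

  errclass <- GROUP_ERRCLASS[group]
  names(errclass) <- sample_id
  by_chrom <- split(probe_map$position, probe_map$chrom)

  segs <- list()
  # carrier / reciprocal segment emission, with false negatives dropped
  for (k in seq_len(nrow(ground_truth))) {
    sid <- ground_truth$sample_id[k]
    if (runif(1) < spec$fn[errclass[sid]]) next
    j <- region_row(index, ground_truth$region_id[k])
    cls <- if (ground_truth$class[k] == "carrier") index$variant_class[j]
           else invert_class(index$variant_class[j])
    segs[[length(segs) + 1L]] <-
      emit_variant_segments(sid, j, cls, index, spec, by_chrom)
  }
  # false-positive expected-class calls in observed data only
  fp_rate <- spec$fp[errclass]
  for (j in seq_len(nrow(regions))) {
    eligible <- which(!carrier[, j] & !reciprocal[, j])
    hits <- eligible[runif(length(eligible)) < fp_rate[eligible]]
    for (i in hits)
      segs[[length(segs) + 1L]] <-
        emit_variant_segments(sample_id[i], j, index$variant_class[j], index,
                              spec, by_chrom)
  }
  segment_calls <- if (length(segs) > 0L) do.call(rbind, segs)
    else data.frame(sample_id = character(0), chrom = character(0),
                    start = numeric(0), end = numeric(0),
                    cn_state = integer(0), n_probes = integer(0),
                    stringsAsFactors = FALSE)
  segment_calls <- segment_calls[order(segment_calls$sample_id,
                                       segment_calls$chrom,
                                       segment_calls$start), , drop = FALSE]
  rownames(segment_calls) <- NULL

  structure(list(regions = regions, probe_map = probe_map,
                 phenotypes = phenotypes, segment_calls = segment_calls,
                 ground_truth = ground_truth, index = index, spec = spec),
            class = "synthetic_cohort")
}

# rejection-sample log10 BMI until each sample satisfies its group's
# ascertainment (cases obese, controls non-obese, population unconstrained)
truncate_by_group <- function(mu, sigma, group, max_iter = 200L) {
  lb <- rnorm(length(mu), mu, sigma)
  sample_ok <- function(i) {
    bmi <- 10^lb[i]
    (grepl("case_obese", group[i]) & bmi >= 30) |
      (grepl("control", group[i]) & bmi < 25) |
      (group[i] == "population")
  }
  bad <- which(!sample_ok(seq_along(lb)))
  it <- 0L
  while (length(bad) > 0L && it < max_iter) {
    lb[bad] <- rnorm(length(bad), mu[bad], sigma[bad])
    bad <- bad[!sample_ok(bad)]
    it <- it + 1L
  }
  if (length(bad) > 0L)
    stop("BMI ascertainment rejection sampling failed; check bmi_mu/bmi_sigma")
  lb
}

# one (possibly fragmented) variant call for one sample at one region;
# breakpoints land on probe coordinates or region bounds
emit_variant_segments <- function(sid, j, cls, index, spec, by_chrom) {
  rid <- index$region_id[j]
  pr <- attr(index, "probes")[[rid]]
  fl <- attr(index, "flank_probes")[[rid]]
  n_r <- length(pr)
  fl_left <- fl[fl < index$start[j]]
  fl_right <- fl[fl > index$end[j]]
  j_l <- sample.int(spec$jitter_probes + 1L, 1L) - 1L
  j_r <- sample.int(spec$jitter_probes + 1L, 1L) - 1L
  # a call must be able to satisfy the minimum consecutive-probe criterion
  need <- 3L - n_r - j_l - j_r
  if (need > 0L) {
    add_l <- min(need, length(fl_left) - j_l)
    j_l <- j_l + max(add_l, 0L)
    need <- need - max(add_l, 0L)
    if (need > 0L) j_r <- j_r + need
  }
  j_l <- min(j_l, length(fl_left))
  j_r <- min(j_r, length(fl_right))
  if (n_r + j_l + j_r < 3L)
    stop("region ", rid, " lacks flanking probes to emit a callable variant")
  start_c <- if (j_l > 0L) fl_left[length(fl_left) - j_l + 1L] else index$start[j]
  end_c <- if (j_r > 0L) fl_right[j_r] else index$end[j]
  cn <- if (cls == "loss") 1L else 3L
  chrom <- index$chrom[j]
  pos_all <- by_chrom[[chrom]]
  mk <- function(s, e) data.frame(sample_id = sid, chrom = chrom, start = s,
                                  end = e, cn_state = cn,
                                  n_probes = n_probes_in(pos_all, s, e),
                                  stringsAsFactors = FALSE)
  fragment <- n_r >= spec$merge_min_probes &&
    runif(1) < spec$fragmentation_prob
  if (fragment) {
    cov_target <- ceiling(runif(1, spec$frag_min_coverage, 0.95) * n_r)
    cov_target <- max(6L, min(cov_target, n_r - 1L))
    if (cov_target <= n_r - 1L && cov_target >= 6L) {
      k1_choices <- seq(3L, cov_target - 3L)
      k1 <- k1_choices[sample.int(length(k1_choices), 1L)]
      gap <- n_r - cov_target
      return(rbind(mk(start_c, pr[k1]), mk(pr[k1 + gap + 1L], end_c)))
    }
  }
  mk(start_c, end_c)
}

#' Write a synthetic cohort's files to a directory
#'
#' Emits regions.tsv, probe_map.tsv, segment_calls.tsv, phenotypes.tsv and
#' ground_truth.tsv in the package's tabular dialects.
#'
#' @param cohort A [generate_cohort()] object.
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_regions(cohort$regions, file.path(dir, "regions.tsv"))
  write_probe_map(cohort$probe_map, file.path(dir, "probe_map.tsv"))
  write_segment_calls(cohort$segment_calls, file.path(dir, "segment_calls.tsv"))
  write_phenotypes(cohort$phenotypes, file.path(dir, "phenotypes.tsv"))
  write_tsv(cohort$ground_truth, file.path(dir, "ground_truth.tsv"))
  invisible(dir)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$phenotypes), "samples,",
      nrow(x$regions), "regions,", nrow(x$segment_calls), "segment calls,",
      nrow(x$ground_truth), "true variant carriers (seed",
      paste0(x$spec$seed, ")\n"))
  invisible(x)
}
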
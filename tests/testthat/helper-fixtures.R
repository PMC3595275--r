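# Shared fixtures and independent oracles, built in code.

# One test locus: n_probes evenly spaced in-region probes (spacing bp apart)
# plus `flank_probes` probes on each side inside the flank window.
make_locus <- function(n_probes, chrom = "chrT", start = 1e6, spacing = 1000,
                       region_id = "r", variant_class = "loss",
                       flank_bp = 50000, flank_probes = 10) {
  end <- start + max(n_probes - 1, 1) * spacing
  inside <- if (n_probes == 0) numeric(0)
            else start + (seq_len(n_probes) - 1) * spacing
  left <- seq(start - flank_bp + 2000, start - 2000, length.out = flank_probes)
  right <- seq(end + 2000, end + flank_bp - 2000, length.out = flank_probes)
  pos <- round(c(left, inside, right))
  list(
    regions = region_definitions(chrom, start, end, region_id, variant_class,
                                 flank_bp = flank_bp),
    probe_map = data.frame(chrom = chrom, position = pos,
                           probe_id = sprintf("%s_p%03d", region_id,
                                              seq_along(pos)),
                           stringsAsFactors = FALSE)
  )
}

# combine loci on distinct chromosomes into one region set + probe map
make_loci <- function(...) {
  loci <- list(...)
  regions <- do.call(rbind, lapply(loci, `[[`, "regions"))
  probe_map <- do.call(rbind, lapply(loci, `[[`, "probe_map"))
  list(regions = regions, probe_map = validate_probe_map(probe_map),
       index = build_region_probe_index(regions, probe_map))
}

seg <- function(sample_id, chrom, start, end, cn_state, n_probes = NA_integer_) {
  data.frame(sample_id = sample_id, chrom = chrom, start = start, end = end,
             cn_state = cn_state, n_probes = n_probes,
             stringsAsFactors = FALSE)
}

phen <- function(sample_id, group = "population", cohort = "popA", sex = "M",
                 age = 31, bmi = 24, excluded = FALSE, reason = "") {
  validate_phenotypes(data.frame(
    sample_id = sample_id, cohort = cohort, group = group, sex = sex,
    age = age, bmi = bmi, excluded = excluded, exclusion_reason = reason,
    stringsAsFactors = FALSE))
}

# --- independent Fisher oracle: direct enumeration of the hypergeometric
# support (never calls fisher.test) ------------------------------------------
oracle_fisher <- function(a, b, c, d, tail = "two.sided") {
  m <- a + c                     # carriers margin
  n1 <- a + b; n2 <- c + d
  lo <- max(0, m - n2); hi <- min(m, n1)
  supp <- lo:hi
  pr <- exp(lchoose(n1, supp) + lchoose(n2, m - supp) - lchoose(n1 + n2, m))
  if (tail == "one.sided") return(min(1, sum(pr[supp >= a])))
  min(1, sum(pr[pr <= pr[match(a, supp)] * (1 + 1e-7)]))
}

# conditional null distribution of the two-sided exact P given the margins,
# for the randomized probability-integral transform: returns U(0,1) under
# the null even though the test statistic is discrete
randomized_pit_margins <- function(m, n1, n2, p_obs, u) {
  lo <- max(0, m - n2); hi <- min(m, n1)
  supp <- lo:hi
  pr <- exp(lchoose(n1, supp) + lchoose(n2, m - supp) - lchoose(n1 + n2, m))
  pv <- vapply(seq_along(supp), function(i)
    min(1, sum(pr[pr <= pr[i] * (1 + 1e-7)])), numeric(1))
  below <- sum(pr[pv < p_obs * (1 - 1e-9)])
  at <- sum(pr[abs(pv - p_obs) <= p_obs * 1e-9])
  below + u * at
}

# tiny end-to-end pipeline: generate -> qualify -> per-region case-control test
run_pipeline <- function(spec, regions = NULL, probe_map = NULL) {
  ch <- generate_cohort(spec, regions = regions, probe_map = probe_map)
  cm <- build_carrier_matrix(ch$segment_calls, ch$phenotypes, ch$index,
                             qualification_rules())
  list(cohort = ch, cm = cm, assoc = case_control_test(cm))
}
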
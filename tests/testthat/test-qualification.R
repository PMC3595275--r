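rules <- qualification_rules()

test_that("copy-number states map onto variant classes", {
  expect_true(matches_class(1, "loss"))
  expect_true(matches_class(0, "loss"))   # homozygous deletion is a loss
  expect_false(matches_class(3, "loss"))
  expect_true(matches_class(3, "gain"))
  expect_false(matches_class(2, "gain"))
  expect_false(matches_class(2, "loss"))
  expect_error(matches_class(-1, "loss"))
})

test_that("full-span rule: spanning calls qualify, off-by-one calls do not", {
  loc <- make_loci(make_locus(3, chrom = "c1", region_id = "r3"))
  r <- loc$regions
  # spanning deletion
  q <- qualify_sample_region(seg("s", "c1", r$start - 100, r$end + 100, 1),
                             "r3", loc$index, rules)
  expect_equal(q$status, "carrier")
  expect_false(q$provisional)
  # starts 1 bp inside the region: full-span rule violated
  q2 <- qualify_sample_region(seg("s", "c1", r$start + 1, r$end + 5000, 1),
                              "r3", loc$index, rules)
  expect_equal(q2$status, "non_carrier")
  # wrong class never qualifies
  q3 <- qualify_sample_region(seg("s", "c1", r$start - 100, r$end + 100, 3),
                              "r3", loc$index, rules)
  expect_equal(q3$status, "non_carrier")
})

test_that("minimum consecutive-probe support counts region plus flank", {
  loc <- make_loci(make_locus(1, chrom = "c1", region_id = "r1", spacing = 1000))
  r <- loc$regions
  fl <- attr(loc$index, "flank_probes")$r1
  # spans the region and two flank probes -> 3 probes of support
  q <- qualify_sample_region(seg("s", "c1", fl[9], fl[12], 1),
                             "r1", loc$index, rules)
  expect_equal(q$status, "carrier")
  expect_gte(q$supporting_probes, 3)
  # spans the region but only one extra flank probe -> discarded
  q2 <- qualify_sample_region(seg("s", "c1", fl[10], fl[11] + 1, 1),
                              "r1", loc$index, rules)
  expect_equal(q2$status, "non_carrier")
})

test_that("zero-probe regions are uncallable regardless of calls", {
  loc <- make_loci(make_locus(0, chrom = "c1", region_id = "r0"))
  q <- qualify_sample_region(seg("s", "c1", 1, 2e6, 1), "r0", loc$index, rules)
  expect_equal(q$status, "uncallable")
})

test_that("merge rule unions fragments and applies a strict >50% threshold", {
  loc <- make_loci(make_locus(28, chrom = "c1", region_id = "r28"))
  r <- loc$regions
  pr <- attr(loc$index, "probes")$r28
  # one call over all 28 probes: provisional merge-mode carrier
  q <- qualify_sample_region(seg("s", "c1", r$start, r$end, 1),
                             "r28", loc$index, rules)
  expect_equal(q$status, "carrier")
  expect_true(q$provisional)
  expect_equal(q$supporting_probes, 28L)
  # two fragments jointly covering 15/28 > 50% -> carrier
  frag <- rbind(seg("s", "c1", pr[1], pr[8], 1),
                seg("s", "c1", pr[22], pr[28], 1))
  q2 <- qualify_sample_region(frag, "r28", loc$index, rules)
  expect_equal(q2$status, "carrier")
  expect_equal(q2$supporting_probes, 15L)
  # 14/28 is not strictly more than half -> non-carrier
  frag14 <- rbind(seg("s", "c1", pr[1], pr[7], 1),
                  seg("s", "c1", pr[22], pr[28], 1))
  q3 <- qualify_sample_region(frag14, "r28", loc$index, rules)
  expect_equal(q3$status, "non_carrier")
  expect_equal(q3$supporting_probes, 14L)
  # overlapping fragments are unioned, not double-counted
  dup <- rbind(seg("s", "c1", pr[1], pr[10], 1),
               seg("s", "c1", pr[5], pr[14], 1))
  expect_equal(qualify_sample_region(dup, "r28", loc$index, rules)$supporting_probes,
               14L)
})

test_that("merge mode is monotone: extra matching calls never revoke carriers", {
  loc <- make_loci(make_locus(15, chrom = "c1", region_id = "rm"))
  pr <- attr(loc$index, "probes")$rm
  set.seed(42)
  for (i in 1:25) {
    k <- sample(2:6, 2)
    base <- rbind(seg("s", "c1", pr[1], pr[8 + k[1]], 1),
                  seg("s", "c1", pr[8], pr[8 + k[2]], 1))
    extra <- seg("s", "c1", pr[sample(15, 1)], pr[15], 1)
    st1 <- qualify_sample_region(base, "rm", loc$index, rules)$status
    st2 <- qualify_sample_region(rbind(base, extra), "rm", loc$index, rules)$status
    if (st1 == "carrier") expect_equal(st2, "carrier")
    # and order of calls never matters
    st3 <- qualify_sample_region(rbind(extra, base), "rm", loc$index, rules)$status
    expect_equal(st2, st3)
  }
})

test_that("splitting a spanning call's flanks into extra segments is neutral", {
  loc <- make_loci(make_locus(5, chrom = "c1", region_id = "r5"))
  r <- loc$regions
  fl <- attr(loc$index, "flank_probes")$r5
  whole <- seg("s", "c1", fl[5], fl[length(fl) - 4], 1)
  split3 <- rbind(seg("s", "c1", fl[5], r$start - 1, 1),
                  seg("s", "c1", r$start, r$end, 1),
                  seg("s", "c1", r$end + 1, fl[length(fl) - 4], 1))
  expect_equal(qualify_sample_region(whole, "r5", loc$index, rules)$status,
               "carrier")
  expect_equal(qualify_sample_region(split3, "r5", loc$index, rules)$status,
               "carrier")
})

test_that("reciprocal events use the same criteria with the class inverted", {
  loc <- make_loci(make_locus(4, chrom = "c1", region_id = "r4"))
  r <- loc$regions
  dup <- seg("s", "c1", r$start - 5000, r$end + 5000, 3)
  del <- seg("s", "c1", r$start - 5000, r$end + 5000, 1)
  expect_equal(qualify_reciprocal(dup, "r4", loc$index, rules)$status,
               "reciprocal_carrier")
  expect_equal(qualify_reciprocal(del, "r4", loc$index, rules)$status,
               "non_carrier")
  expect_equal(qualify_reciprocal(dup[0, ], "r4", loc$index, rules)$status,
               "non_carrier")
})

test_that("carrier matrix respects exclusions and rejects orphan samples", {
  loc <- make_loci(make_locus(3, chrom = "c1", region_id = "r3"),
                   make_locus(0, chrom = "c2", region_id = "r0"))
  r <- loc$regions[1, ]
  calls <- rbind(seg("s1", "c1", r$start - 100, r$end + 100, 1),
                 seg("s3", "c1", r$start - 100, r$end + 100, 1))
  ph <- phen(c("s1", "s2", "s3"), group = "case_obese_adult", bmi = 33,
             excluded = c(FALSE, FALSE, TRUE))
  cm <- build_carrier_matrix(calls, ph, loc$index)
  expect_equal(unname(cm$status[, "r3"]),
               c("carrier", "non_carrier", "carrier"))
  expect_true(all(cm$status[, "r0"] == "uncallable"))
  # excluded s3 is absent from every count
  cc <- carrier_counts(cm)
  expect_equal(sum(cc$n_carriers[cc$region_id == "r3"]), 1L)
  expect_equal(unique(cc$n[cc$region_id == "r3"]), 2L)
  expect_error(
    build_carrier_matrix(seg("ghost", "c1", 1, 10, 1), ph, loc$index),
    "ghost")
})

test_that("provisional merge-mode calls are listed for review", {
  loc <- make_loci(make_locus(12, chrom = "c1", region_id = "r12"))
  r <- loc$regions
  calls <- seg("s1", "c1", r$start, r$end, 1)
  cm <- build_carrier_matrix(calls, phen("s1"), loc$index)
  rep <- provisional_report(cm)
  expect_equal(rep$sample_id, "s1")
  expect_equal(rep$region_id, "r12")
})
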
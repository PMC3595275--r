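## Region-level carrier qualification from segment-level copy-number calls.
##
## Decision tree per sample x region:
##   (a) discard calls of the wrong class and calls supported by fewer than
##       min_consecutive_probes array probes (probes counted over the
##       region + flank window);
##   (b) zero in-region probes -> uncallable;
##   (c) fewer than merge_min_probes in-region probes -> carrier iff a single
##       surviving call spans the whole region [start, end];
##   (d) merge mode (>= merge_min_probes): union the in-region probes of all
##       surviving calls; provisional carrier iff strictly more than
##       merge_fraction of the in-region probes are altered.
## The same tree with the region's class inverted scores reciprocal carriers
## (duplication where a deletion is expected, and vice versa).

CARRIER_STATUSES <- c("carrier", "reciprocal_carrier", "non_carrier", "uncallable")

#' Qualification rule set
#'
#' @param min_consecutive_probes Minimum array probes a call must cover to be
#'   considered at all (default 3; counted over region + flank).
#' @param full_span_max_probes Documented upper probe count of the "short
#'   region" regime (default 6). The full-span rule is applied to every region
#'   below `merge_min_probes`.
#' @param merge_min_probes In-region probe count from which fragmented calls
#'   are merged (default 11).
#' @param merge_fraction Fraction of in-region probes that must be altered in
#'   merge mode; strictly greater-than (default 0.5, so 15/28 qualifies and
#'   14/28 does not).
#' @return A list of class `qualification_rules`.
#' @export
qualification_rules <- function(min_consecutive_probes = 3L,
                                full_span_max_probes = 6L,
                                merge_min_probes = 11L,
                                merge_fraction = 0.5) {
  stopifnot(min_consecutive_probes >= 1L,
            merge_fraction > 0, merge_fraction <= 1,
            full_span_max_probes < merge_min_probes)
  structure(list(min_consecutive_probes = as.integer(min_consecutive_probes),
                 full_span_max_probes = as.integer(full_span_max_probes),
                 merge_min_probes = as.integer(merge_min_probes),
                 merge_fraction = merge_fraction),
            class = "qualification_rules")
}

#' Does a copy-number state match a variant class?
#'
#' Losses are integer copy numbers below 2 (including homozygous deletions,
#' state 0); gains are above 2.
#'
#' @param cn_state Integer copy-number state(s), >= 0.
#' @param variant_class `"gain"` or `"loss"`.
#' @return Logical vector.
#' @export
matches_class <- function(cn_state, variant_class) {
  stopifnot(all(cn_state >= 0), variant_class %in% VARIANT_CLASSES)
  if (variant_class == "loss") cn_state < 2 else cn_state > 2
}

invert_class <- function(variant_class) {
  if (variant_class == "loss") "gain" else "loss"
}

n_probes_in <- function(positions, lo, hi) {
  # positions sorted; closed-interval count via binary search
  if (length(positions) == 0L) return(0L)
  findInterval(hi, positions) - findInterval(lo - 1, positions)
}

region_row <- function(index, region_id) {
  i <- match(region_id, index$region_id)
  if (is.na(i)) stop("unknown region_id: ", region_id)
  i
}

#' Qualify one sample at one region
#'
#' Applies the qualification decision tree (see the package vignette) to the
#' segment calls of a single sample for the region's expected variant class.
#'
#' @param calls Segment-call `data.frame` for one sample (any chromosomes;
#'   restricted internally to the region's chromosome).
#' @param region_id Region identifier present in `index`.
#' @param index A [build_region_probe_index()] object.
#' @param rules A [qualification_rules()] object.
#' @param variant_class Class to score; defaults to the region's expected
#'   class. Pass the inverted class to score reciprocal events (or use
#'   [qualify_reciprocal()]).
#' @return A list with `status` (`carrier` / `non_carrier` / `uncallable`),
#'   `supporting_probes` and `provisional` (TRUE for merge-mode calls, which
#'   in the original manual workflow were pending raw-intensity review).
#' @export
qualify_sample_region <- function(calls, region_id, index, rules,
                                  variant_class = NULL) {
  i <- region_row(index, region_id)
  if (is.null(variant_class)) variant_class <- index$variant_class[i]
  n_r <- index$n_probes_region[i]
  if (n_r == 0L)
    return(list(status = "uncallable", supporting_probes = 0L,
                provisional = FALSE))
  res <- list(status = "non_carrier", supporting_probes = 0L,
              provisional = FALSE)
  if (is.null(calls) || nrow(calls) == 0L) return(res)

  keep <- calls$chrom == index$chrom[i] &
    matches_class(calls$cn_state, variant_class)
  calls <- calls[keep, , drop = FALSE]
  if (nrow(calls) == 0L) return(res)

  fl <- attr(index, "flank_probes")[[region_id]]
  support <- vapply(seq_len(nrow(calls)),
                    function(k) n_probes_in(fl, calls$start[k], calls$end[k]),
                    integer(1))
  calls <- calls[support >= rules$min_consecutive_probes, , drop = FALSE]
  support <- support[support >= rules$min_consecutive_probes]
  if (nrow(calls) == 0L) return(res)

  if (n_r < rules$merge_min_probes) {
    spans <- calls$start <= index$start[i] & calls$end >= index$end[i]
    if (any(spans))
      return(list(status = "carrier",
                  supporting_probes = max(support[spans]),
                  provisional = FALSE))
    return(res)
  }
  # merge mode: union of altered in-region probes across surviving calls
  pr <- attr(index, "probes")[[region_id]]
  altered <- rep(FALSE, n_r)
  for (k in seq_len(nrow(calls)))
    altered <- altered | (pr >= calls$start[k] & pr <= calls$end[k])
  n_alt <- sum(altered)
  if (n_alt > rules$merge_fraction * n_r)
    return(list(status = "carrier", supporting_probes = n_alt,
                provisional = TRUE))
  list(status = "non_carrier", supporting_probes = n_alt, provisional = FALSE)
}

#' Qualify the reciprocal (opposite-class) event
#'
#' Identical criteria to [qualify_sample_region()] with the region's variant
#' class inverted; a qualifying sample has status `reciprocal_carrier`.
#'
#' @inheritParams qualify_sample_region
#' @return As [qualify_sample_region()], with `carrier` relabelled
#'   `reciprocal_carrier`.
#' @export
qualify_reciprocal <- function(calls, region_id, index, rules) {
  i <- region_row(index, region_id)
  res <- qualify_sample_region(calls, region_id, index, rules,
                               variant_class = invert_class(index$variant_class[i]))
  if (res$status == "carrier") res$status <- "reciprocal_carrier"
  res
}

#' Build the sample x region carrier matrix
#'
#' Scores every phenotyped sample at every region: expected-class carriers
#' first, then reciprocal (opposite-class) carriers among the remainder.
#' Excluded samples keep their status in the matrix but never enter the
#' stratified counts.
#'
#' @param calls All segment calls (`data.frame`; see [read_segment_calls()]).
#' @param phenotypes Phenotype table covering every sample with calls.
#' @param index A [build_region_probe_index()] object.
#' @param rules A [qualification_rules()] object.
#' @return An object of class `carrier_matrix`: list with `status` (character
#'   matrix samples x regions), `provisional` (logical matrix), `phenotypes`,
#'   `index`, and `counts` (per region x group x weight-class carrier counts,
#'   excluded samples removed).
#' @export
build_carrier_matrix <- function(calls, phenotypes, index, rules = qualification_rules()) {
  phenotypes <- validate_phenotypes(phenotypes)
  orphans <- setdiff(unique(calls$sample_id), phenotypes$sample_id)
  if (length(orphans) > 0L)
    stop("segment calls reference sample(s) absent from phenotype table: ",
         paste(orphans, collapse = ", "))
  samples <- phenotypes$sample_id
  regions <- index$region_id
  status <- matrix("non_carrier", nrow = length(samples), ncol = length(regions),
                   dimnames = list(samples, regions))
  provisional <- matrix(FALSE, nrow = length(samples), ncol = length(regions),
                        dimnames = list(samples, regions))
  status[, index$uncallable] <- "uncallable"
  calls_by_sample <- split(calls, calls$sample_id)
  for (sid in names(calls_by_sample)) {
    sc <- calls_by_sample[[sid]]
    for (j in seq_along(regions)) {
      if (index$uncallable[j]) next
      rid <- regions[j]
      # cheap overlap pre-check against the flank window
      win_lo <- index$start[j] - index$flank_bp[j]
      win_hi <- index$end[j] + index$flank_bp[j]
      if (!any(sc$chrom == index$chrom[j] & sc$start <= win_hi & sc$end >= win_lo))
        next
      q <- qualify_sample_region(sc, rid, index, rules)
      if (q$status == "carrier") {
        status[sid, j] <- "carrier"
        provisional[sid, j] <- q$provisional
      } else {
        r <- qualify_reciprocal(sc, rid, index, rules)
        if (r$status == "reciprocal_carrier") {
          status[sid, j] <- "reciprocal_carrier"
          provisional[sid, j] <- r$provisional
        }
      }
    }
  }
  cm <- structure(list(status = status, provisional = provisional,
                       phenotypes = phenotypes, index = index, rules = rules),
                  class = "carrier_matrix")
  cm$counts <- carrier_counts(cm)
  cm
}

#' Stratified carrier counts
#'
#' Tabulates expected-class carriers per region by group and weight class,
#' excluding samples flagged `excluded`.
#'
#' @param cm A [build_carrier_matrix()] object.
#' @param status_value Status to count (default `"carrier"`).
#' @return A long `data.frame`: region_id, group, weight_class, n_carriers, n.
#' @export
carrier_counts <- function(cm, status_value = "carrier") {
  ph <- cm$phenotypes[!cm$phenotypes$excluded, , drop = FALSE]
  st <- cm$status[ph$sample_id, , drop = FALSE]
  out <- list()
  for (rid in colnames(st)) {
    is_c <- st[, rid] == status_value
    key <- interaction(ph$group, ph$weight_class, drop = TRUE)
    agg_n <- tapply(rep(1L, nrow(ph)), key, sum)
    agg_c <- tapply(as.integer(is_c), key, sum)
    parts <- strsplit(names(agg_n), ".", fixed = TRUE)
    out[[rid]] <- data.frame(
      region_id = rid,
      group = vapply(parts, `[`, "", 1L),
      weight_class = vapply(parts, `[`, "", 2L),
      n_carriers = as.integer(agg_c),
      n = as.integer(agg_n),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Machine-readable review report of provisional merge-mode calls
#'
#' Merge-mode carriers are provisional: in the original array workflow each
#' was confirmed by manual inspection of raw intensity data, a step that is
#' replaced here by this report.
#'
#' @param cm A [build_carrier_matrix()] object.
#' @return `data.frame` of sample_id, region_id, status for provisional calls.
#' @export
provisional_report <- function(cm) {
  idx <- which(cm$provisional, arr.ind = TRUE)
  data.frame(sample_id = rownames(cm$status)[idx[, 1L]],
             region_id = colnames(cm$status)[idx[, 2L]],
             status = cm$status[idx],
             stringsAsFactors = FALSE)
}

#' @export
print.carrier_matrix <- function(x, ...) {
  cat("carrier_matrix:", nrow(x$status), "samples x", ncol(x$status),
      "regions;", sum(x$status == "carrier"), "carrier calls,",
      sum(x$status == "reciprocal_carrier"), "reciprocal\n")
  invisible(x)
}
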
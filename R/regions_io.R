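## Readers/writers and validation for the four tabular inputs, plus the
## region <-> probe index. Native coordinate convention is 1-based inclusive
## (genome build hg18); probe overlap uses closed intervals. The reported
## size_bp column is end - start, matching the convention of the published
## locus tables this package is designed to reproduce.

VARIANT_CLASSES <- c("gain", "loss")
SAMPLE_GROUPS <- c("case_obese_child", "control_child",
                   "case_obese_adult", "control_adult", "population")

#' Construct and validate a region definition table
#'
#' A region is a candidate structural-variant locus with 1-based inclusive
#' coordinates, an expected variant class (`gain` or `loss`) and a flanking
#' window used when counting probe support for calls that extend beyond the
#' region proper.
#'
#' @param chrom Chromosome labels (e.g. `"chr16"`).
#' @param start,end 1-based inclusive base-pair coordinates, `start <= end`.
#' @param region_id Unique region labels.
#' @param variant_class `"gain"` or `"loss"` per region.
#' @param flank_bp Flanking context in base pairs (default 500 kb).
#' @return A `data.frame` with one row per region and a `size_bp` column
#'   (`end - start`).
#' @export
region_definitions <- function(chrom, start, end, region_id, variant_class,
                               flank_bp = 500000L) {
  df <- data.frame(
    region_id = as.character(region_id),
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    variant_class = as.character(variant_class),
    flank_bp = as.numeric(flank_bp),
    stringsAsFactors = FALSE
  )
  validate_regions(df)
  df$size_bp <- df$end - df$start
  df
}

validate_regions <- function(df) {
  stopifnot(is.data.frame(df))
  bad <- which(df$start > df$end)
  if (length(bad) > 0L)
    stop("region(s) with start > end: ", paste(df$region_id[bad], collapse = ", "))
  bad <- which(!df$variant_class %in% VARIANT_CLASSES)
  if (length(bad) > 0L)
    stop("unknown variant_class for region(s): ",
         paste(df$region_id[bad], collapse = ", "))
  if (anyDuplicated(df$region_id))
    stop("duplicate region_id: ",
         paste(unique(df$region_id[duplicated(df$region_id)]), collapse = ", "))
  invisible(df)
}

#' Read region definitions from a BED-like TSV
#'
#' Columns: chrom, start, end, region_id, variant_class and optionally
#' flank_bp; lines starting with `#` are comments. By default coordinates are
#' taken as 1-based inclusive; set `zero_based = TRUE` for 0-based half-open
#' (UCSC BED) input, which is converted to the native convention
#' (`start + 1`, `end` unchanged).
#'
#' @param path File path.
#' @param zero_based Input uses 0-based half-open coordinates?
#' @param flank_bp Default flank when the file has no flank_bp column.
#' @return A validated region `data.frame` (see [region_definitions()]).
#' @export
read_regions <- function(path, zero_based = FALSE, flank_bp = 500000L) {
  raw <- read_tsv_checked(path, min_cols = 5L, what = "region file")
  starts <- parse_numeric_col(raw, 2L, path, "start")
  ends <- parse_numeric_col(raw, 3L, path, "end")
  if (zero_based) starts <- starts + 1
  fl <- if (ncol(raw) >= 6L) parse_numeric_col(raw, 6L, path, "flank_bp")
        else rep(flank_bp, nrow(raw))
  region_definitions(chrom = raw[[1L]], start = starts, end = ends,
                     region_id = raw[[4L]], variant_class = raw[[5L]],
                     flank_bp = fl)
}

#' Write region definitions as TSV
#' @param regions Region table from [region_definitions()] or [read_regions()].
#' @param path Output path.
#' @export
write_regions <- function(regions, path) {
  validate_regions(regions)
  write_tsv(regions[, c("chrom", "start", "end", "region_id",
                        "variant_class", "flank_bp")], path)
}

#' Read or validate a probe map
#'
#' A probe map lists array probe positions: columns chrom, position, probe_id.
#' Positions must be strictly increasing within each chromosome after sorting;
#' duplicate positions on a chromosome are rejected.
#'
#' @param path TSV file path.
#' @return A sorted probe-map `data.frame`.
#' @export
read_probe_map <- function(path) {
  raw <- read_tsv_checked(path, min_cols = 3L, what = "probe map")
  pm <- data.frame(chrom = as.character(raw[[1L]]),
                   position = parse_numeric_col(raw, 2L, path, "position"),
                   probe_id = as.character(raw[[3L]]),
                   stringsAsFactors = FALSE)
  validate_probe_map(pm)
}

validate_probe_map <- function(pm) {
  stopifnot(is.data.frame(pm), all(c("chrom", "position", "probe_id") %in% names(pm)))
  pm <- pm[order(pm$chrom, pm$position), , drop = FALSE]
  dup <- duplicated(pm[, c("chrom", "position")])
  if (any(dup))
    stop("duplicate probe position(s), e.g. ",
         pm$chrom[dup][1L], ":", pm$position[dup][1L])
  rownames(pm) <- NULL
  pm
}

#' Write a probe map as TSV
#' @param probe_map Probe map `data.frame`.
#' @param path Output path.
#' @export
write_probe_map <- function(probe_map, path) {
  write_tsv(probe_map[, c("chrom", "position", "probe_id")], path)
}

#' Read segment-level copy-number calls
#'
#' Calls are the tabular output of an upstream CNV caller: one contiguous
#' copy-number segment per row, columns sample_id, chrom, start, end,
#' cn_state (integer copy number, 2 = diploid), n_probes.
#'
#' @param path TSV file path.
#' @return A `data.frame` of segment calls.
#' @export
read_segment_calls <- function(path) {
  raw <- read_tsv_checked(path, min_cols = 6L, what = "segment calls")
  calls <- data.frame(sample_id = as.character(raw[[1L]]),
                      chrom = as.character(raw[[2L]]),
                      start = parse_numeric_col(raw, 3L, path, "start"),
                      end = parse_numeric_col(raw, 4L, path, "end"),
                      cn_state = parse_numeric_col(raw, 5L, path, "cn_state"),
                      n_probes = parse_numeric_col(raw, 6L, path, "n_probes"),
                      stringsAsFactors = FALSE)
  validate_segment_calls(calls)
}

validate_segment_calls <- function(calls) {
  if (any(calls$start > calls$end)) stop("segment call with start > end")
  if (any(calls$cn_state < 0)) stop("negative cn_state")
  if (any(calls$cn_state != round(calls$cn_state)))
    stop("cn_state must be integer copy number")
  calls
}

#' Write segment calls as TSV
#' @param calls Segment-call `data.frame`.
#' @param path Output path.
#' @export
write_segment_calls <- function(calls, path) {
  write_tsv(calls[, c("sample_id", "chrom", "start", "end",
                      "cn_state", "n_probes")], path)
}

#' Derive weight class from BMI
#'
#' Obese is BMI >= 30 kg/m^2, overweight 25 <= BMI < 30, normal (incl.
#' underweight) < 25; `NA` BMI gives `NA` class.
#'
#' @param bmi Numeric BMI values (kg/m^2).
#' @return Character vector in `{normal, overweight, obese}`.
#' @export
weight_class <- function(bmi) {
  out <- ifelse(bmi >= 30, "obese", ifelse(bmi >= 25, "overweight", "normal"))
  out[is.na(bmi)] <- NA_character_
  out
}

#' Read a phenotype table
#'
#' Columns: sample_id, cohort, group, sex, age, bmi, excluded,
#' exclusion_reason. `group` must be one of case_obese_child, control_child,
#' case_obese_adult, control_adult, population. A `weight_class` column is
#' derived from BMI. Excluded samples are kept in the table but are never
#' counted by downstream tabulations.
#'
#' @param path TSV file path.
#' @return A phenotype `data.frame` with derived `weight_class`.
#' @export
read_phenotypes <- function(path) {
  raw <- read_tsv_checked(path, min_cols = 8L, what = "phenotype table")
  ph <- data.frame(sample_id = as.character(raw[[1L]]),
                   cohort = as.character(raw[[2L]]),
                   group = as.character(raw[[3L]]),
                   sex = as.character(raw[[4L]]),
                   age = parse_numeric_col(raw, 5L, path, "age"),
                   bmi = parse_numeric_col(raw, 6L, path, "bmi", na_ok = TRUE),
                   excluded = as.logical(raw[[7L]]),
                   exclusion_reason = as.character(raw[[8L]]),
                   stringsAsFactors = FALSE)
  validate_phenotypes(ph)
}

validate_phenotypes <- function(ph) {
  if (anyDuplicated(ph$sample_id))
    stop("duplicate sample_id in phenotype table")
  bad <- setdiff(unique(ph$group), SAMPLE_GROUPS)
  if (length(bad) > 0L)
    stop("unknown group(s): ", paste(bad, collapse = ", "))
  if (!all(ph$sex %in% c("M", "F")))
    stop("sex must be M or F")
  if (any(is.na(ph$excluded)))
    stop("excluded flag must be TRUE/FALSE")
  ph$weight_class <- weight_class(ph$bmi)
  ph
}

#' Write a phenotype table as TSV
#' @param phenotypes Phenotype `data.frame`.
#' @param path Output path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  write_tsv(phenotypes[, c("sample_id", "cohort", "group", "sex", "age",
                           "bmi", "excluded", "exclusion_reason")], path)
}

#' Build the region <-> probe index
#'
#' For each region, collects the ordered probe positions inside the closed
#' interval `[start, end]` and inside the flank window
#' `[start - flank_bp, end + flank_bp]`. Regions with zero in-region probes
#' (including regions on chromosomes absent from the probe map) are flagged
#' uncallable, with a warning for absent chromosomes.
#'
#' @param regions Region table (see [region_definitions()]).
#' @param probe_map Sorted probe map (see [read_probe_map()]).
#' @return An object of class `region_probe_index`: the region table with
#'   `n_probes_region` and `uncallable` columns, plus per-region probe
#'   position lists in attributes `probes` (in-region) and `flank_probes`
#'   (flank window, includes the in-region probes).
#' @export
build_region_probe_index <- function(regions, probe_map) {
  validate_regions(regions)
  probe_map <- validate_probe_map(probe_map)
  by_chrom <- split(probe_map$position, probe_map$chrom)
  n <- nrow(regions)
  probes <- vector("list", n)
  flank_probes <- vector("list", n)
  n_in <- integer(n)
  missing_chrom <- character(0)
  for (i in seq_len(n)) {
    pos <- by_chrom[[regions$chrom[i]]]
    if (is.null(pos)) {
      missing_chrom <- c(missing_chrom, regions$region_id[i])
      pos <- numeric(0)
    }
    probes[[i]] <- pos[pos >= regions$start[i] & pos <= regions$end[i]]
    flank_probes[[i]] <- pos[pos >= regions$start[i] - regions$flank_bp[i] &
                             pos <= regions$end[i] + regions$flank_bp[i]]
    n_in[i] <- length(probes[[i]])
  }
  if (length(missing_chrom) > 0L)
    warning("chromosome absent from probe map; region(s) uncallable: ",
            paste(missing_chrom, collapse = ", "))
  idx <- regions
  idx$n_probes_region <- n_in
  idx$uncallable <- n_in == 0L
  names(probes) <- names(flank_probes) <- regions$region_id
  attr(idx, "probes") <- probes
  attr(idx, "flank_probes") <- flank_probes
  class(idx) <- c("region_probe_index", class(idx))
  idx
}

#' @export
print.region_probe_index <- function(x, ...) {
  cat("region_probe_index:", nrow(x), "regions,",
      sum(x$uncallable), "uncallable\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Write/read a per-region association table
#'
#' A flat TSV mirroring a per-locus replication summary: per-region carrier
#' counts in the obese and non-obese strata plus two-sided and one-sided
#' exact-test P-values and the sample odds ratio. `read_association_table`
#' round-trips the output of `write_association_table`.
#'
#' @param tbl Association table (e.g. from [case_control_test()]).
#' @param path Output path. For `write_association_json`, full nested results.
#' @return `read_association_table` returns the `data.frame`.
#' @export
write_association_table <- function(tbl, path) {
  write_tsv(tbl, path)
}

#' @rdname write_association_table
#' @export
read_association_table <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             comment.char = "#", check.names = FALSE)
}

#' @rdname write_association_table
#' @param results A list of association results (e.g. from [pool_and_test()]).
#' @export
write_association_json <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

## --- internal TSV helpers ---------------------------------------------------

read_tsv_checked <- function(path, min_cols, what) {
  if (!file.exists(path)) stop(what, " not found: ", path)
  raw <- tryCatch(
    read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
               comment.char = "#", check.names = FALSE,
               colClasses = "character"),
    error = function(e) stop("failed to parse ", what, " (", path, "): ",
                             conditionMessage(e)))
  if (ncol(raw) < min_cols)
    stop(what, " (", path, ") has ", ncol(raw), " columns; expected >= ",
         min_cols)
  raw
}

parse_numeric_col <- function(raw, j, path, name, na_ok = FALSE) {
  v <- raw[[j]]
  out <- suppressWarnings(as.numeric(v))
  bad <- which(is.na(out) & !(na_ok & (is.na(v) | v %in% c("", "NA"))))
  if (length(bad) > 0L)
    stop("malformed ", name, " at data line ", bad[1L], " of ", path,
         ": '", v[bad[1L]], "'")
  out
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}
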
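#' SNP filtering configuration
#'
#' SNPs are removed when any replicate pool in the analyzed stratum has read
#' depth below `min_depth` (the scan default of 9 excludes depth < 9, so a
#' depth of exactly 9 is retained) or a missing frequency. Both rules exist
#' to reduce false discoveries from low-coverage regions. An optional
#' quality-score floor can be enabled; it is off by default because the
#' exported Q-scores are not part of the standard filter.
#'
#' @param min_depth minimum per-pool read depth (reads); default 9.
#' @param require_all_pools if `TRUE` (default) every pool of the stratum
#'   must pass; if `FALSE`, a SNP survives when at least one pool per
#'   phenotype passes, and failing pool entries are masked so that downstream
#'   means use only valid pools.
#' @param min_qscore optional minimum SNP quality score (default `NULL`, no
#'   quality filtering).
#' @return list of class `"filter_config"`.
#' @export
filter_config <- function(min_depth = 9L, require_all_pools = TRUE,
                          min_qscore = NULL) {
  min_depth <- as.integer(min_depth)
  stopifnot(min_depth >= 0L, is.logical(require_all_pools))
  structure(list(min_depth = min_depth,
                 require_all_pools = require_all_pools,
                 min_qscore = min_qscore),
            class = "filter_config")
}

#' Filter pooled SNPs for one sex stratum
#'
#' @param x pool table (see [read_pool_table()]).
#' @param design a [pool_design()].
#' @param sex_stratum `"male"` or `"female"`; the male and female scans are
#'   fully separate and never share records.
#' @param config a [filter_config()].
#' @return The surviving rows of `x`, order preserved, with attribute
#'   `"attrition"` = named counts (`n_in`, `removed_depth`,
#'   `removed_missing`, `removed_qscore`, `n_out`). With
#'   `require_all_pools = FALSE`, entries failing depth/missingness in the
#'   surviving rows are masked to `NA`.
#' @export
filter_snps <- function(x, design, sex_stratum, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  sp <- stratum_pools(design, sex_stratum)
  pools <- c(sp$resistant, sp$susceptible)
  if (length(sp$resistant) == 0L || length(sp$susceptible) == 0L) {
    stop("stratum '", sex_stratum, "' lacks pools for one phenotype")
  }
  n <- nrow(x)
  freq_m <- as.matrix(x[, paste0(pools, "_freq"), drop = FALSE])
  depth_m <- as.matrix(x[, paste0(pools, "_depth"), drop = FALSE])
  present <- !is.na(freq_m) & !is.na(depth_m)
  depth_ok <- present & depth_m >= config$min_depth
  miss_fail <- rowSums(!present) > 0L
  depth_fail <- !miss_fail & rowSums(!depth_ok) > 0L
  q_ok <- rep(TRUE, n)
  if (!is.null(config$min_qscore)) {
    q_ok <- !is.na(x$qscore) & x$qscore >= config$min_qscore
  }
  if (config$require_all_pools) {
    keep <- !miss_fail & !depth_fail & q_ok
  } else {
    valid <- depth_ok
    r_idx <- match(sp$resistant, pools)
    s_idx <- match(sp$susceptible, pools)
    r_ok <- rowSums(valid[, r_idx, drop = FALSE]) > 0L
    s_ok <- rowSums(valid[, s_idx, drop = FALSE]) > 0L
    keep <- r_ok & s_ok & q_ok
    # mask failing entries so downstream means only use valid pools
    for (j in seq_along(pools)) {
      bad <- keep & !valid[, j]
      x[bad, paste0(pools[j], "_freq")] <- NA_real_
    }
  }
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pool_ids") <- attr(x, "pool_ids")
  attr(out, "attrition") <- c(
    n_in = n,
    removed_missing = sum(miss_fail & q_ok & config$require_all_pools),
    removed_depth = sum(depth_fail & q_ok & config$require_all_pools),
    removed_qscore = sum(!q_ok),
    n_out = nrow(out))
  out
}

#' Resistant-minus-susceptible allele frequency differences
#'
#' For every SNP, the frequency difference is the unweighted mean
#' non-reference allele frequency over the resistant replicate pools of the
#' stratum minus the mean over the susceptible pools. Positive values mean
#' the non-reference allele is enriched in resistant birds; negative values
#' mean it favors susceptibility.
#'
#' @param x filtered pool table (run [filter_snps()] first).
#' @param design a [pool_design()].
#' @param sex_stratum `"male"` or `"female"`.
#' @param allow_partial if `FALSE` (default) a missing frequency in any
#'   stratum pool is a precondition violation; if `TRUE` (for
#'   `require_all_pools = FALSE` filtering) means are taken over the
#'   available pools.
#' @return `data.frame` with `chrom`, `pos`, `delta`, `sex_stratum`,
#'   `n_pools_used`, sorted as the input.
#' @export
delta_frequency <- function(x, design, sex_stratum, allow_partial = FALSE) {
  sp <- stratum_pools(design, sex_stratum)
  rf <- as.matrix(x[, paste0(sp$resistant, "_freq"), drop = FALSE])
  sf <- as.matrix(x[, paste0(sp$susceptible, "_freq"), drop = FALSE])
  if (!allow_partial && (anyNA(rf) || anyNA(sf))) {
    stop("missing pool frequencies; run filter_snps() before ",
         "delta_frequency()")
  }
  if (allow_partial &&
      (any(rowSums(!is.na(rf)) == 0L) || any(rowSums(!is.na(sf)) == 0L))) {
    stop("some SNPs have no usable pool for one phenotype; filter first")
  }
  delta <- rowMeans(rf, na.rm = allow_partial) -
    rowMeans(sf, na.rm = allow_partial)
  data.frame(chrom = x$chrom, pos = x$pos, delta = delta,
             sex_stratum = sex_stratum,
             n_pools_used = rowSums(!is.na(rf)) + rowSums(!is.na(sf)),
             stringsAsFactors = FALSE)
}

#' Region-calling configuration
#'
#' The scan flags SNPs whose frequency difference reaches `c_low` (default
#' 0.20, i.e. +20 percentage points; comparisons are inclusive) and counts
#' how many also reach `c_high` (default 0.40). Flagged SNPs are clustered
#' along each chromosome by single linkage with a maximum gap of
#' `max_gap_bp`; clusters with at least `min_snps_low` members become
#' candidate regions. Defaults are chosen so that a ~123-134 kb cluster of
#' 170 qualifying SNPs is comfortably called.
#'
#' @param c_low low frequency-difference cutoff in `(0, 1]`; default 0.20.
#' @param c_high high cutoff, `c_low <= c_high <= 1`; default 0.40.
#' @param max_gap_bp maximum gap between clustered SNPs in bp; default 50000.
#' @param min_snps_low minimum SNPs at `c_low` per region; default 20.
#' @param auto_cutoff derive cutoffs from the data with [auto_cutoffs()].
#' @return list of class `"region_config"`.
#' @export
region_config <- function(c_low = 0.20, c_high = 0.40, max_gap_bp = 50000L,
                          min_snps_low = 20L, auto_cutoff = FALSE) {
  stopifnot(c_low > 0, c_low <= c_high, c_high <= 1, max_gap_bp >= 0,
            min_snps_low >= 1)
  structure(list(c_low = c_low, c_high = c_high,
                 max_gap_bp = as.integer(max_gap_bp),
                 min_snps_low = as.integer(min_snps_low),
                 auto_cutoff = isTRUE(auto_cutoff)),
            class = "region_config")
}

#' Data-driven frequency-difference cutoffs
#'
#' Reconstruction of the "average variance across the chromosome" rule used
#' to pick the 20%/40% cutoffs: in auto mode the low cutoff is
#' `mean(|delta|) + 3 * sd(|delta|)` rounded up to the nearest 0.05 (floor
#' 0.05), and the high cutoff is twice that, capped at 1. With auto mode off
#' (the default) the configured cutoffs are returned unchanged. Fewer than
#' 100 deltas refuse auto mode with a warning.
#'
#' @param deltas numeric vector of frequency differences, or the
#'   `data.frame` from [delta_frequency()].
#' @param config a [region_config()].
#' @return named numeric vector `c(c_low, c_high)`.
#' @export
auto_cutoffs <- function(deltas, config = region_config()) {
  if (is.data.frame(deltas)) deltas <- deltas$delta
  defaults <- c(c_low = config$c_low, c_high = config$c_high)
  if (!config$auto_cutoff) return(defaults)
  if (length(deltas) < 100L) {
    warning("fewer than 100 deltas; refusing auto cutoffs, using defaults")
    return(defaults)
  }
  a <- abs(deltas)
  raw <- mean(a) + 3 * stats::sd(a)
  # round to 2 decimals so multiples of 0.05 are exact doubles
  c_low <- round(max(0.05, ceiling(raw / 0.05) * 0.05), 2)
  c(c_low = c_low, c_high = round(min(1, 2 * c_low), 2))
}

#' Detect clustered candidate regions from per-SNP frequency differences
#'
#' SNPs with `delta >= c_low` are single-linkage clustered along each
#' chromosome with gaps of at most `max_gap_bp`; clusters with at least
#' `min_snps_low` members become resistance-direction regions. The same
#' procedure on `delta <= -c_low` yields susceptibility-direction regions.
#' Region spans are the min/max positions of member SNPs; `n_snps_high`
#' counts members at or beyond `c_high` in absolute value.
#'
#' @param deltas `data.frame` from [delta_frequency()], sorted by
#'   `(chrom, pos)`. Unsorted input is an error (no silent sort).
#' @param config a [region_config()]. With `auto_cutoff = TRUE` the cutoffs
#'   are derived via [auto_cutoffs()].
#' @return `data.frame` with columns `chrom`, `start`, `end`, `peak_delta`,
#'   `n_snps_low`, `n_snps_high`, `direction`, `sex_stratum`.
#' @export
detect_regions <- function(deltas, config = region_config()) {
  stopifnot(inherits(config, "region_config"))
  check_sorted(deltas)
  cuts <- auto_cutoffs(deltas, config)
  c_low <- cuts[["c_low"]]; c_high <- cuts[["c_high"]]
  stratum <- if (nrow(deltas)) unique(deltas$sex_stratum)[1] else NA_character_
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), peak_delta = numeric(0),
                      n_snps_low = integer(0), n_snps_high = integer(0),
                      direction = character(0), sex_stratum = character(0),
                      stringsAsFactors = FALSE)
  out <- list(empty)
  for (chrom in unique(deltas$chrom)) {
    d <- deltas[deltas$chrom == chrom, , drop = FALSE]
    for (dir in c("resistance", "susceptibility")) {
      sel <- if (dir == "resistance") d$delta >= c_low else d$delta <= -c_low
      if (!any(sel)) next
      pos <- d$pos[sel]
      del <- d$delta[sel]
      cl <- cumsum(c(1L, as.integer(diff(pos) > config$max_gap_bp)))
      for (k in unique(cl)) {
        idx <- cl == k
        if (sum(idx) < config$min_snps_low) next
        pd <- del[idx][which.max(abs(del[idx]))]
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = min(pos[idx]), end = max(pos[idx]),
          peak_delta = pd, n_snps_low = sum(idx),
          n_snps_high = sum(abs(del[idx]) >= c_high),
          direction = dir, sex_stratum = stratum, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "cutoffs") <- cuts
  res
}

check_sorted <- function(deltas) {
  if (!nrow(deltas)) return(invisible(TRUE))
  r <- rle(deltas$chrom)
  if (anyDuplicated(r$values)) {
    stop("deltas not sorted: chromosome blocks are interleaved")
  }
  unsorted <- tapply(deltas$pos, factor(deltas$chrom, levels = r$values),
                     is.unsorted)
  if (any(unsorted)) {
    stop("deltas not sorted by position within chromosome '",
         names(unsorted)[unsorted][1], "'")
  }
  invisible(TRUE)
}
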
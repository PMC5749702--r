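design8 <- full_pool_design()
male_pools <- design8$pool_id[design8$sex == "male"]

test_that("depth and missingness filters match the stated rules", {
  x <- make_pool_table(n = 4, design = design8)
  for (p in design8$pool_id) {
    x[[paste0(p, "_depth")]] <- c(9L, 8L, 30L, 30L)
    x[[paste0(p, "_freq")]] <- c(0.5, 0.5, 0.5, 0.5)
  }
  x$RM2_freq[3] <- NA     # missing in one male pool
  x$RF1_freq[4] <- NA     # missing in a FEMALE pool: male scan unaffected
  f <- filter_snps(x, design8, "male")
  # depth 9 kept (cutoff excludes < 9), depth 8 removed, missing removed
  expect_equal(f$pos, x$pos[c(1, 4)])
  att <- attr(f, "attrition")
  expect_equal(unname(att[c("n_in", "removed_depth", "removed_missing")]),
               c(4L, 1L, 1L))

  # qscore filter only when configured
  x2 <- x[c(1, 1), ]
  x2$pos <- c(1L, 2L)
  x2$qscore <- c(10, 40)
  expect_equal(nrow(filter_snps(x2, design8, "male")), 2)
  expect_equal(
    nrow(filter_snps(x2, design8, "male", filter_config(min_qscore = 20))), 1)
})

test_that("random tables: filter agrees with a row-by-row oracle and is monotone", {
  set.seed(21)
  for (rep in 1:5) {
    x <- make_pool_table(n = 60, design = design8)
    # sprinkle missing entries
    for (p in sample(design8$pool_id, 3)) {
      x[[paste0(p, "_freq")]][sample.int(60, 5)] <- NA
    }
    for (st in c("male", "female")) {
      got <- filter_snps(x, design8, st)
      expect_equal(got$pos, x$pos[oracle_filter(x, design8, st)])
    }
    # monotonicity: raising min_depth never increases survivors;
    # require_all_pools=TRUE survivors are a subset of the relaxed set
    n_by_depth <- vapply(c(0, 9, 20, 40), function(md) {
      nrow(filter_snps(x, design8, "male", filter_config(min_depth = md)))
    }, numeric(1))
    expect_true(all(diff(n_by_depth) <= 0))
    strict <- filter_snps(x, design8, "male")
    relaxed <- filter_snps(x, design8, "male",
                           filter_config(require_all_pools = FALSE))
    expect_true(all(strict$pos %in% relaxed$pos))
  }
})

test_that("delta_frequency is the difference of unweighted pool means", {
  x <- make_pool_table(n = 2, design = design8)
  vals <- list(RM1 = c(0.9, 0.5), RM2 = c(0.8, 0.5),
               SM1 = c(0.2, 0.5), SM2 = c(0.3, 0.5))
  for (p in names(vals)) x[[paste0(p, "_freq")]] <- vals[[p]]
  d <- delta_frequency(x, design8, "male")
  expect_equal(d$delta, c(0.60, 0))
  expect_equal(d$n_pools_used, c(4L, 4L))

  # 1000 random records against independent recomputation: exact agreement
  set.seed(22)
  x <- make_pool_table(n = 1000, design = design8)
  d <- delta_frequency(x, design8, "female")
  manual <- (x$RF1_freq + x$RF2_freq) / 2 - (x$SF1_freq + x$SF2_freq) / 2
  expect_identical(d$delta, manual)

  # antisymmetry: swapping phenotype roles negates every delta exactly
  swapped <- pool_design(design8$pool_id,
                         ifelse(design8$phenotype == "resistant",
                                "susceptible", "resistant"),
                         design8$sex, design8$replicate)
  expect_identical(delta_frequency(x, design8, "male")$delta,
                   -delta_frequency(x, swapped, "male")$delta)

  # missing frequency is a precondition violation unless partial allowed
  x$RM1_freq[5] <- NA
  expect_error(delta_frequency(x, design8, "male"), "filter")
})

test_that("auto_cutoffs follows the mean + 3 SD round-up rule", {
  cfg_off <- region_config()
  expect_equal(auto_cutoffs(rnorm(500, 0, 0.1), cfg_off),
               c(c_low = 0.20, c_high = 0.40))
  cfg_on <- region_config(auto_cutoff = TRUE)
  expect_equal(auto_cutoffs(rep(0, 500), cfg_on),
               c(c_low = 0.05, c_high = 0.10))
  expect_warning(out <- auto_cutoffs(rep(0.1, 50), cfg_on), "fewer than 100")
  expect_equal(out, c(c_low = 0.20, c_high = 0.40))
  # exact rule on a fixed vector
  set.seed(23)
  d <- rnorm(1000, 0, 0.08)
  a <- abs(d)
  expected_low <- max(0.05, ceiling((mean(a) + 3 * sd(a)) / 0.05) * 0.05)
  expect_equal(unname(auto_cutoffs(d, cfg_on)),
               c(expected_low, min(1, 2 * expected_low)))
})

test_that("auto cutoffs land near the analytic null scale at depth 30", {
  p <- sim_params(n_birds = 400, n_background_snps = 2000,
                  block_marker_count = 2, fixed_depth = 30,
                  missing_pool_rate = 0)
  set.seed(24)
  birds <- simulate_line(p)
  sim <- simulate_pools(birds, p)
  d <- delta_frequency(filter_snps(sim$pools, sim$design, "male"),
                       sim$design, "male")
  cuts <- auto_cutoffs(d, region_config(auto_cutoff = TRUE))
  expect_gte(cuts[["c_low"]], 0.15)
  expect_lte(cuts[["c_low"]], 0.35)
})

test_that("detect_regions clusters flagged SNPs with gap and count rules", {
  # all deltas zero -> no regions
  d0 <- data.frame(chrom = "2", pos = seq(1e6, 2e6, by = 1e4), delta = 0,
                   sex_stratum = "male", n_pools_used = 4L)
  expect_equal(nrow(detect_regions(d0)), 0)

  # 25 consecutive SNPs 1 kb apart at delta 0.5, rest 0 -> one region
  pos <- seq(1e6, by = 1000, length.out = 200)
  delta <- rep(0, 200)
  delta[80:104] <- 0.5
  d1 <- data.frame(chrom = "2", pos = pos, delta = delta,
                   sex_stratum = "male", n_pools_used = 4L)
  r <- detect_regions(d1)
  expect_equal(nrow(r), 1)
  expect_equal(r$start, pos[80])
  expect_equal(r$end, pos[104])
  expect_equal(r$n_snps_low, 25L)
  expect_equal(r$n_snps_high, 25L)
  expect_equal(r$direction, "resistance")
  expect_equal(r$peak_delta, 0.5)

  # same cluster negated -> susceptibility direction
  d1$delta <- -d1$delta
  r2 <- detect_regions(d1)
  expect_equal(r2$direction, "susceptibility")
  expect_equal(r2$peak_delta, -0.5)

  # a SNP exactly at c_low is included
  d1$delta <- abs(d1$delta)
  d1$delta[80] <- 0.2
  expect_equal(detect_regions(d1)$n_snps_low, 25L)

  # unsorted input errors, no silent sort
  expect_error(detect_regions(d1[sample.int(200), ]), "not sorted")
})

test_that("random delta tracks match the brute-force clustering oracle", {
  set.seed(25)
  for (rep in 1:8) {
    n <- 300
    d <- data.frame(
      chrom = sort(sample(c("1", "2"), n, TRUE)),
      pos = NA_integer_, delta = runif(n, -0.6, 0.6),
      sex_stratum = "male", n_pools_used = 4L, stringsAsFactors = FALSE)
    for (ch in unique(d$chrom)) {
      d$pos[d$chrom == ch] <- sort(sample.int(3e6, sum(d$chrom == ch)))
    }
    cfg <- region_config(c_low = 0.3, c_high = 0.5, max_gap_bp = 40000,
                         min_snps_low = 4)
    got <- detect_regions(d, cfg)
    want <- oracle_regions(d, 0.3, 0.5, 40000, 4)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got[, c("chrom", "start", "end", "n_snps_low",
                           "n_snps_high", "direction")],
                   want, ignore_attr = TRUE)
    }
  }
})

test_that("sex effect direction: causal skew is larger in males", {
  p <- sim_params(n_birds = 800, n_background_snps = 20)
  m <- f <- numeric(12)
  for (s in seq_along(m)) {
    set.seed(400 + s)
    birds <- simulate_line(p)
    sim <- simulate_pools(birds, p)
    for (sx in c("male", "female")) {
      d <- delta_frequency(filter_snps(sim$pools, sim$design, sx),
                           sim$design, sx)
      inb <- d$pos >= sim$truth$block_start & d$pos <= sim$truth$block_end
      if (sx == "male") m[s] <- mean(abs(d$delta[inb]))
      else f[s] <- mean(abs(d$delta[inb]))
    }
  }
  expect_gt(mean(m), mean(f))
  # and the analytic enumeration agrees on the direction
  expect_gt(expected_causal_delta(p, "male"),
            expected_causal_delta(p, "female"))
})
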
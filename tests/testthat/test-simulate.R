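test_that("simulated genotypes follow Hardy-Weinberg at the configured freqs", {
  p <- sim_params(n_birds = 5000, inconclusive_rate = 0)
  birds <- simulate_line(p, seed = 61)
  f <- p$haplotype_freqs
  expected <- c(G1 = f[["TAG"]]^2, G2 = f[["CCC"]]^2, G3 = f[["CCG"]]^2,
                G4 = 2 * f[["CCG"]] * f[["CCC"]],
                G5 = 2 * f[["TAG"]] * f[["CCC"]],
                G6 = 2 * f[["TAG"]] * f[["CCG"]])
  obs <- table(factor(birds$combined, levels = names(expected))) / 5000
  for (g in names(expected)) {
    se <- sqrt(expected[[g]] * (1 - expected[[g]]) / 5000)
    expect_lt(abs(obs[[g]] - expected[[g]]), 4 * se)
  }
  # f(TAC) = 0 -> no incompatible two-locus combinations, ever
  expect_false(any(birds$combined == "incompatible"))
  # genotype calls derive deterministically from the haplotype pair
  recalled <- call_combined_genotype(birds$intron6, birds$exon8)
  expect_identical(recalled, birds$combined)
})

test_that("flat penetrance gives a 50% resistant fraction and null deltas", {
  pen <- list(male = setNames(rep(0.5, 6), paste0("G", 1:6)),
              female = setNames(rep(0.5, 6), paste0("G", 1:6)))
  p <- sim_params(n_birds = 2000, penetrance = pen, inconclusive_rate = 0,
                  n_background_snps = 10)
  birds <- simulate_line(p, seed = 62)
  expect_lt(abs(mean(birds$phenotype == "resistant") - 0.5), 0.03)

  # no-association null: causal-marker deltas average ~0 over seeds
  deltas <- numeric(60)
  for (s in seq_along(deltas)) {
    set.seed(600 + s)
    b <- simulate_line(p)
    sim <- simulate_pools(b, p)
    d <- delta_frequency(filter_snps(sim$pools, sim$design, "male"),
                         sim$design, "male")
    inb <- d$pos >= sim$truth$block_start & d$pos <= sim$truth$block_end
    deltas[s] <- mean(d$delta[inb])
  }
  expect_lt(abs(mean(deltas)), 0.02)
  expect_equal(expected_causal_delta(p, "male"), 0)
})

test_that("pool frequencies converge to bird truth in the deep-coverage limit", {
  p <- sim_params(n_birds = 400, n_background_snps = 10,
                  fixed_depth = 1e6, missing_pool_rate = 0,
                  recomb_rate = 0)
  birds <- simulate_line(p, seed = 63)
  sim <- simulate_pools(birds, p)
  # at depth 1e6 the observed frequency equals the true pool frequency to 3
  # decimals; recompute the truth from the pooled birds' haplotypes
  members <- sim$truth$pool_members
  markers <- sim$truth$marker_pos
  classes <- sim$truth$marker_class
  idx <- sample(seq_along(markers), 10)
  for (i in idx) {
    carriers <- if (classes[i] == "intron6") c("CCC", "CCG") else
      c("CCC", "TAC")
    for (pool in names(members)) {
      bm <- birds[birds$bird_id %in% members[[pool]], ]
      true_f <- sum(bm$hap1 %in% carriers, bm$hap2 %in% carriers) /
        (2 * nrow(bm))
      obs <- sim$pools[sim$pools$pos == markers[i],
                       paste0(pool, "_freq")]
      expect_lt(abs(obs - true_f), 2e-3)
    }
  }
})

test_that("mean causal delta matches the exact enumeration oracle", {
  p <- sim_params(n_birds = 1200, n_background_snps = 10)
  want <- expected_causal_delta(p, "male", "intron6")
  got <- numeric(100)
  for (s in seq_along(got)) {
    set.seed(700 + s)
    b <- simulate_line(p)
    sim <- simulate_pools(b, p)
    d <- delta_frequency(filter_snps(sim$pools, sim$design, "male"),
                         sim$design, "male")
    intron_pos <- sim$truth$marker_pos[sim$truth$marker_class == "intron6"]
    got[s] <- mean(d$delta[d$pos %in% intron_pos])
  }
  mc_se <- sd(got) / sqrt(length(got))
  expect_lt(abs(mean(got) - want), 4 * mc_se + 0.005)
})

test_that("insufficient birds in a stratum is a named error", {
  p <- sim_params(n_birds = 30)
  birds <- simulate_line(p, seed = 64)
  expect_error(simulate_pools(birds, p), "insufficient")
})

test_that("Ct simulation recovers configured folds exactly at zero noise", {
  p4 <- sim_params(ct_noise_sd = 0, expression_folds = data.frame(
    group = "G2", tissue = "lung", fold = 4))
  birds <- make_birds(30, intron6 = rep(c("hom_ref", "hom_alt"), 15),
                      exon8 = rep(c("hom_ref", "hom_alt"), 15))
  birds$combined <- call_combined_genotype(birds$intron6, birds$exon8)
  ct <- simulate_ct_table(birds, p4, n_per_group = c(G1 = 5, G2 = 5),
                          seed = 65, tissues = "lung")
  fc <- ddct_fold_change(compute_delta_ct(ct))
  expect_equal(fc$fold_change[fc$group == "G2"], 4)
  expect_equal(fc$fold_change[fc$group == "G1"], 1)

  # fold 1 everywhere at zero noise -> all folds exactly 1
  p1 <- sim_params(ct_noise_sd = 0, expression_folds = data.frame(
    group = character(0), tissue = character(0), fold = numeric(0)))
  ct1 <- suppressMessages(
    simulate_ct_table(birds, p1, n_per_group = c(G1 = 5, G2 = 5),
                      seed = 66, tissues = "lung"))
  fc1 <- ddct_fold_change(compute_delta_ct(ct1))
  expect_equal(fc1$fold_change, c(1, 1))
})

test_that("identical seeds give byte-identical datasets", {
  p <- sim_params(n_birds = 120, n_background_snps = 200,
                  block_marker_count = 20)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(p, d1, seed = 67)
  simulate_dataset(p, d2, seed = 67)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a different seed changes the pools
  d3 <- withr::local_tempdir()
  simulate_dataset(p, d3, seed = 68)
  expect_false(identical(readLines(file.path(d1, "pools.tsv")),
                         readLines(file.path(d3, "pools.tsv"))))
})
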
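test_that("count tables follow the inclusion/exclusion bookkeeping", {
  # 10 birds: 4 R + 4 S + 2 inconclusive, all hom_alt
  b <- make_birds(10, phenotype = c(rep("resistant", 4),
                                    rep("susceptible", 4),
                                    rep("inconclusive", 2)),
                  intron6 = "hom_alt")
  tab <- build_count_table(b, "intron6", strata = "all")
  expect_equal(tab$n_total, 10L)
  expect_equal(tab$n_resistant, 4L)
  expect_equal(tab$n_susceptible, 4L)
  expect_equal(tab$r_freq, 0.5)

  # unknown-sex birds are counted in "all" but in neither sex stratum;
  # missing calls are excluded entirely
  b2 <- make_birds(6, sex = c("male", "male", "female", "unknown",
                              "unknown", "male"),
                   phenotype = "resistant", intron6 = "het")
  b2$intron6[6] <- NA
  tabs <- build_count_table(b2, "intron6")
  expect_equal(tabs$n_total[tabs$stratum == "all"], 5L)
  expect_equal(tabs$n_total[tabs$stratum == "male"], 2L)
  expect_equal(tabs$n_total[tabs$stratum == "female"], 1L)

  # empty stratum is not an error
  expect_equal(nrow(build_count_table(b2[0, ], "intron6")), 0)
})

test_that("random bird sets match an independent tally oracle", {
  set.seed(31)
  for (rep in 1:4) {
    b <- make_birds(120, line = sample(c("REL", "Y"), 120, TRUE))
    b$phenotype[sample.int(120, 10)] <- "inconclusive"
    b$intron6[sample.int(120, 8)] <- NA
    tab <- build_count_table(b, "intron6")
    for (i in seq_len(nrow(tab))) {
      want <- oracle_tally(b, "intron6", tab$line[i], tab$stratum[i],
                           tab$genotype_class[i])
      expect_equal(unlist(tab[i, c("n_total", "n_resistant",
                                   "n_susceptible")]),
                   want, ignore_attr = TRUE)
    }
  }
})

test_that("expected counts split rows at the stratum-wide resolved ratio", {
  tab <- data.frame(line = "L", stratum = "all",
                    genotype_class = c("a", "b"),
                    n_resistant = c(50, 10), n_susceptible = c(50, 0))
  out <- expected_counts(tab)
  # stratum ratio = 60/110
  expect_equal(out$expected_resistant, c(100, 10) * 60 / 110)
  expect_equal(out$expected_resistant + out$expected_susceptible,
               c(100, 10))

  # 60% resistant stratum, row with 10 resolved birds -> expected 6/4
  tab2 <- data.frame(line = "L", stratum = "all",
                     genotype_class = c("a", "b"),
                     n_resistant = c(6, 54), n_susceptible = c(4, 36))
  expect_equal(expected_counts(tab2)$expected_resistant[1], 6)
  expect_equal(expected_counts(tab2)$expected_susceptible[1], 4)

  # conservation over random tables: expectations sum to (R_total, S_total)
  set.seed(32)
  for (rep in 1:5) {
    t3 <- data.frame(line = "L", stratum = "all",
                     genotype_class = letters[1:5],
                     n_resistant = rpois(5, 40), n_susceptible = rpois(5, 30))
    o <- expected_counts(t3)
    expect_equal(sum(o$expected_resistant), sum(t3$n_resistant))
    expect_equal(sum(o$expected_susceptible), sum(t3$n_susceptible))
  }
})

test_that("per-row chi-square, tail probability and uncapped Bonferroni", {
  row <- data.frame(line = "L", stratum = "all", genotype_class = "x",
                    n_resistant = 70, n_susceptible = 30,
                    expected_resistant = 50, expected_susceptible = 50)
  out <- chi_square_rows(row, n_tests = 3)
  expect_equal(out$chi2, 16)
  expect_equal(out$p_raw, 6.33425e-05, tolerance = 1e-5)
  expect_equal(out$p_adj, out$p_raw * 3)

  # observed equal to expected: chi2 = 0, p_raw = 1, p_adj = n_tests (no cap)
  row$n_resistant <- row$expected_resistant <- 50
  row$n_susceptible <- row$expected_susceptible <- 50
  out <- chi_square_rows(row, n_tests = 3)
  expect_equal(out$chi2, 0)
  expect_equal(out$p_raw, 1)
  expect_equal(out$p_adj, 3)

  # p_adj is a plain product, never capped at 1
  row$n_resistant <- 53; row$n_susceptible <- 47
  for (nt in c(1L, 3L, 10L)) {
    o <- chi_square_rows(row, n_tests = nt)
    expect_equal(o$p_adj, o$p_raw * nt)
  }
  expect_gt(chi_square_rows(row, n_tests = 10)$p_adj, 1)
})

test_that("1-df tail probability equals the erfc closed form", {
  chi2 <- seq(0, 50, by = 0.25)
  p_pkg <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  p_erfc <- 2 * stats::pnorm(sqrt(chi2), lower.tail = FALSE)  # erfc(sqrt(x/2))
  expect_true(max(abs(p_pkg - p_erfc)) < 1e-10)
})

test_that("chi-square rows are invariant to swapping phenotype labels", {
  set.seed(33)
  tab <- data.frame(line = "L", stratum = "all", genotype_class = letters[1:4],
                    n_resistant = rpois(4, 50), n_susceptible = rpois(4, 30))
  a <- chi_square_rows(expected_counts(tab))
  sw <- tab
  names(sw)[names(sw) == "n_resistant"] <- "tmp"
  names(sw)[names(sw) == "n_susceptible"] <- "n_resistant"
  names(sw)[names(sw) == "tmp"] <- "n_susceptible"
  bsw <- chi_square_rows(expected_counts(sw))
  expect_equal(a$chi2, bsw$chi2)
  expect_equal(a$p_raw, bsw$p_raw)
})

test_that("degenerate rows: zero-resolved skipped, impossible expectation flagged", {
  tab <- data.frame(line = "L", stratum = "all", genotype_class = c("a", "b"),
                    n_resistant = c(0, 10), n_susceptible = c(0, 10))
  out <- chi_square_rows(expected_counts(tab))
  expect_true(is.na(out$chi2[1]))
  expect_false(out$undefined[1])

  tab2 <- data.frame(line = "L", stratum = "all", genotype_class = "a",
                     n_resistant = 5, n_susceptible = 5,
                     expected_resistant = 0, expected_susceptible = 10)
  out2 <- chi_square_rows(tab2)
  expect_true(out2$undefined)
  expect_true(is.na(out2$chi2))

  # low-count rows are tested but flagged
  tab3 <- data.frame(line = "L", stratum = "all", genotype_class = c("a", "b"),
                     n_resistant = c(3, 60), n_susceptible = c(2, 40))
  out3 <- chi_square_rows(expected_counts(tab3))
  expect_true(out3$low_count[1])
  expect_false(is.na(out3$chi2[1]))
})

test_that("Yates correction subtracts 0.5 from each deviation when enabled", {
  row <- data.frame(line = "L", stratum = "all", genotype_class = "x",
                    n_resistant = 14, n_susceptible = 6,
                    expected_resistant = 10, expected_susceptible = 10)
  plain <- chi_square_rows(row)$chi2
  corrected <- chi_square_rows(row, yates = TRUE)$chi2
  expect_equal(plain, 16 / 10 + 16 / 10)
  expect_equal(corrected, 2 * 3.5^2 / 10)
})

test_that("simulated effect: hom_alt male row is usually significant at n ~ 450 males", {
  p <- sim_params(n_birds = 950, inconclusive_rate = 0)
  hit <- logical(12)
  for (s in seq_along(hit)) {
    birds <- simulate_line(p, seed = 500 + s)
    tab <- associate(birds, "intron6", strata = "male")
    row <- tab[tab$genotype_class == "hom_alt", ]
    hit[s] <- row$p_adj < 0.05
  }
  expect_gt(mean(hit), 0.5)
})
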
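#' Genotype-by-phenotype count tables per line and stratum
#'
#' Builds, for each broiler line and stratum, one row per genotype class
#' with the bird counts needed for the per-genotype chi-square test:
#' `n_total` (all birds with a call, including inconclusive necropsies),
#' `n_resistant`/`n_susceptible` (phenotype-resolved only) and observed
#' phenotype frequencies. The `"all"` stratum includes birds of unknown sex;
#' inconclusive-phenotype birds count toward `n_total` but never toward a
#' phenotype group; birds with a missing call at the locus are excluded
#' entirely.
#'
#' @param birds bird table from [read_genotype_table()] or [simulate_line()].
#' @param locus name of the genotype column to classify by, or `"combined"`
#'   for the two-locus G1-G6 classification (computed from columns
#'   `intron6` and `exon8` when not already present; two-locus combinations
#'   incompatible with the three-haplotype model are excluded like missing
#'   calls, with a message).
#' @param lines lines to tabulate (default: all present).
#' @param strata subset of `c("all", "male", "female")`.
#' @return `data.frame` with columns `line`, `stratum`, `genotype_class`,
#'   `n_total`, `n_resistant`, `n_susceptible`, `r_freq`, `s_freq`. Empty
#'   strata yield no rows (not an error).
#' @export
build_count_table <- function(birds, locus, lines = NULL,
                              strata = c("all", "male", "female")) {
  strata <- match.arg(strata, several.ok = TRUE)
  if (identical(locus, "combined") && !"combined" %in% names(birds)) {
    birds$combined <- call_combined_genotype(birds$intron6, birds$exon8)
  }
  cls <- birds[[locus]]
  if (is.null(cls)) stop("no genotype column '", locus, "' in bird table")
  if (identical(locus, "combined")) {
    n_inc <- sum(cls == "incompatible", na.rm = TRUE)
    if (n_inc > 0) {
      message(n_inc, " bird(s) with two-locus genotypes incompatible with ",
              "the three-haplotype model excluded from the count table")
      cls[cls == "incompatible"] <- NA_character_
    }
    levels <- paste0("G", 1:6)
  } else {
    levels <- c("hom_ref", "het", "hom_alt")
    if (!all(cls %in% c(levels, NA))) levels <- sort(unique(stats::na.omit(cls)))
  }
  if (is.null(lines)) lines <- unique(birds$line)
  rows <- list()
  for (ln in lines) {
    for (st in strata) {
      in_st <- birds$line == ln &
        (st == "all" | birds$sex == st)
      sub_cls <- cls[in_st]
      sub_ph <- birds$phenotype[in_st]
      keep <- !is.na(sub_cls)
      sub_cls <- factor(sub_cls[keep], levels = levels)
      sub_ph <- sub_ph[keep]
      if (!length(sub_cls)) next
      n_total <- table(sub_cls)
      n_res <- table(sub_cls[sub_ph == "resistant"])
      n_sus <- table(sub_cls[sub_ph == "susceptible"])
      present <- n_total > 0
      resolved <- as.integer(n_res + n_sus)
      rows[[length(rows) + 1L]] <- data.frame(
        line = ln, stratum = st, genotype_class = levels,
        n_total = as.integer(n_total),
        n_resistant = as.integer(n_res),
        n_susceptible = as.integer(n_sus),
        r_freq = ifelse(resolved > 0, as.integer(n_res) / resolved, NA_real_),
        s_freq = ifelse(resolved > 0, as.integer(n_sus) / resolved, NA_real_),
        stringsAsFactors = FALSE)[present, , drop = FALSE]
    }
  }
  if (!length(rows)) {
    return(data.frame(line = character(0), stratum = character(0),
                      genotype_class = character(0), n_total = integer(0),
                      n_resistant = integer(0), n_susceptible = integer(0),
                      r_freq = numeric(0), s_freq = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Model-expected phenotype counts per genotype row
#'
#' Within each line-stratum table, each genotype class's phenotype-resolved
#' birds are expected to split resistant:susceptible at the stratum-wide
#' resolved ratio (the genotype frequency observed for the whole stratum
#' applied to the phenotype totals). Expected counts therefore sum, over the
#' rows of a table, to the stratum's resistant and susceptible totals.
#'
#' @param tab count table from [build_count_table()], or any `data.frame`
#'   with `line`, `stratum`, `n_resistant`, `n_susceptible`.
#' @return `tab` with `expected_resistant` and `expected_susceptible` added
#'   (`NA` when the stratum has no phenotype-resolved birds).
#' @export
expected_counts <- function(tab) {
  key <- paste(tab$line, tab$stratum, sep = "\r")
  r_tot <- as.numeric(tapply(tab$n_resistant, key, sum)[key])
  s_tot <- as.numeric(tapply(tab$n_susceptible, key, sum)[key])
  resolved <- tab$n_resistant + tab$n_susceptible
  ratio <- ifelse(r_tot + s_tot > 0, r_tot / (r_tot + s_tot), NA_real_)
  tab$expected_resistant <- as.numeric(resolved * ratio)
  tab$expected_susceptible <- as.numeric(resolved * (1 - ratio))
  tab
}

#' Per-genotype chi-square test with uncapped Bonferroni adjustment
#'
#' Each genotype row is tested on its two phenotype cells:
#' `chi2 = sum((obs - exp)^2 / exp)` with 1 degree of freedom, `p_raw` the
#' upper-tail chi-square probability and `p_adj = p_raw * n_tests`. The
#' Bonferroni product is deliberately not capped at 1, matching how adjusted
#' values above 1 are conventionally reported in this design. Rows with no
#' phenotype-resolved birds are skipped (`NA` statistics). A row with an
#' expected cell of 0 but a nonzero observed cell has an undefined statistic
#' and is flagged (`NA` with `undefined = TRUE`).
#'
#' @param tab table from [expected_counts()].
#' @param n_tests Bonferroni multiplier; default 3, the number of genotype
#'   classes in a single-locus stratum table (and the multiplier consistent
#'   with published adjusted values for the combined-genotype tables as
#'   well). Pass `NULL` to use the number of testable genotype classes in
#'   each line-stratum table instead.
#' @param yates apply the Yates continuity correction (subtract 0.5 from
#'   `|obs - exp|`); default `FALSE`, as no continuity correction is part of
#'   the standard analysis.
#' @return `tab` with `chi2`, `p_raw`, `p_adj`, `n_tests`, `low_count`
#'   (any expected cell below 5; such rows are still tested) and `undefined`.
#' @export
chi_square_rows <- function(tab, n_tests = 3L, yates = FALSE) {
  if (!"expected_resistant" %in% names(tab)) tab <- expected_counts(tab)
  key <- paste(tab$line, tab$stratum, sep = "\r")
  resolved <- tab$n_resistant + tab$n_susceptible
  testable <- resolved > 0 & !is.na(tab$expected_resistant)
  nt <- if (is.null(n_tests)) {
    unname(tapply(testable, key, sum)[key])
  } else {
    rep(as.integer(n_tests), nrow(tab))
  }
  if (any(nt < 1L, na.rm = TRUE)) stop("n_tests must be >= 1")
  chi2 <- p_raw <- rep(NA_real_, nrow(tab))
  undefined <- rep(FALSE, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    if (!testable[i]) next
    obs <- c(tab$n_resistant[i], tab$n_susceptible[i])
    exp_ <- c(tab$expected_resistant[i], tab$expected_susceptible[i])
    if (any(exp_ == 0 & obs > 0)) {
      undefined[i] <- TRUE
      next
    }
    dev <- abs(obs - exp_)
    if (yates) dev <- pmax(dev - 0.5, 0)
    ok <- exp_ > 0
    chi2[i] <- sum(dev[ok]^2 / exp_[ok])
    p_raw[i] <- stats::pchisq(chi2[i], df = 1, lower.tail = FALSE)
  }
  tab$chi2 <- chi2
  tab$p_raw <- p_raw
  tab$p_adj <- p_raw * nt
  tab$n_tests <- nt
  tab$low_count <- testable &
    (tab$expected_resistant < 5 | tab$expected_susceptible < 5)
  tab$undefined <- undefined
  tab
}

#' One-call genotype-phenotype association analysis
#'
#' Convenience wrapper: [build_count_table()] then [expected_counts()] then
#' [chi_square_rows()].
#'
#' @inheritParams build_count_table
#' @inheritParams chi_square_rows
#' @return association table, one row per line x stratum x genotype class.
#' @export
associate <- function(birds, locus, lines = NULL,
                      strata = c("all", "male", "female"),
                      n_tests = 3L, yates = FALSE) {
  tab <- build_count_table(birds, locus, lines = lines, strata = strata)
  chi_square_rows(expected_counts(tab), n_tests = n_tests, yates = yates)
}
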
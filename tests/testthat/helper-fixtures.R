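# Fixtures are built in code; no binary files. Oracles here are deliberately
# naive reimplementations (loops, all-pairs) independent of the package's
# vectorized code paths.

make_pool_table <- function(n = 10, design = full_pool_design(),
                            freqs = NULL, depths = NULL, chrom = "2",
                            pos = NULL) {
  pools <- design$pool_id
  if (is.null(pos)) pos <- sort(sample.int(1e6, n))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  x <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = unname(alt),
                  qscore = sample(30:60, n, replace = TRUE),
                  stringsAsFactors = FALSE)
  for (p in pools) {
    x[[paste0(p, "_depth")]] <- if (is.null(depths)) {
      sample(5:60, n, replace = TRUE)
    } else depths[[p]]
    x[[paste0(p, "_freq")]] <- if (is.null(freqs)) {
      round(runif(n), 4)
    } else freqs[[p]]
  }
  attr(x, "pool_ids") <- pools
  x
}

make_birds <- function(n = 20, line = "REL", sex = NULL, phenotype = NULL,
                       intron6 = NULL, exon8 = NULL) {
  data.frame(
    bird_id = sprintf("t%04d", seq_len(n)), line = line,
    sex = if (is.null(sex)) sample(c("male", "female"), n, TRUE) else sex,
    phenotype = if (is.null(phenotype)) {
      sample(c("resistant", "susceptible"), n, TRUE)
    } else phenotype,
    intron6 = if (is.null(intron6)) {
      sample(c("hom_ref", "het", "hom_alt"), n, TRUE)
    } else intron6,
    exon8 = if (is.null(exon8)) {
      sample(c("hom_ref", "het", "hom_alt"), n, TRUE)
    } else exon8,
    stringsAsFactors = FALSE)
}

# row-by-row filter oracle: explicit per-record re-check of the two rules
oracle_filter <- function(x, design, sex_stratum, min_depth = 9) {
  sub <- design[design$sex == sex_stratum, ]
  keep <- logical(nrow(x))
  for (i in seq_len(nrow(x))) {
    ok <- TRUE
    for (p in sub$pool_id) {
      f <- x[[paste0(p, "_freq")]][i]
      d <- x[[paste0(p, "_depth")]][i]
      if (is.na(f) || is.na(d) || d < min_depth) ok <- FALSE
    }
    keep[i] <- ok
  }
  which(keep)
}

# O(n^2)-style clustering oracle: grow each cluster by scanning neighbors
oracle_regions <- function(deltas, c_low = 0.2, c_high = 0.4,
                           max_gap = 50000, min_snps = 20) {
  out <- list()
  for (chrom in unique(deltas$chrom)) {
    d <- deltas[deltas$chrom == chrom, ]
    for (dir in c("resistance", "susceptibility")) {
      sel <- if (dir == "resistance") which(d$delta >= c_low) else
        which(d$delta <= -c_low)
      used <- rep(FALSE, length(sel))
      for (i in seq_along(sel)) {
        if (used[i]) next
        members <- i
        used[i] <- TRUE
        repeat {
          grew <- FALSE
          for (j in seq_along(sel)) {
            if (used[j]) next
            gaps <- abs(d$pos[sel[j]] - d$pos[sel[members]])
            if (min(gaps) <= max_gap) {
              members <- c(members, j)
              used[j] <- TRUE
              grew <- TRUE
            }
          }
          if (!grew) break
        }
        if (length(members) >= min_snps) {
          mp <- d$pos[sel[members]]
          md <- d$delta[sel[members]]
          out[[length(out) + 1L]] <- data.frame(
            chrom = chrom, start = min(mp), end = max(mp),
            n_snps_low = length(members),
            n_snps_high = sum(abs(md) >= c_high), direction = dir,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

# all-pairs interval overlap oracle (1-based inclusive)
oracle_overlap <- function(regions, genes) {
  lapply(seq_len(nrow(regions)), function(i) {
    hits <- character(0)
    for (j in seq_len(nrow(genes))) {
      if (regions$chrom[i] == genes$chrom[j] &&
          regions$start[i] <= genes$end[j] &&
          genes$start[j] <= regions$end[i]) {
        hits <- c(hits, genes$name[j])
      }
    }
    sort(unique(hits))
  })
}

# independent tally of genotype-by-phenotype counts
oracle_tally <- function(birds, locus, line, stratum, class) {
  n_total <- n_res <- n_sus <- 0L
  for (i in seq_len(nrow(birds))) {
    if (birds$line[i] != line) next
    if (stratum != "all" && birds$sex[i] != stratum) next
    g <- birds[[locus]][i]
    if (is.na(g) || g != class) next
    n_total <- n_total + 1L
    if (birds$phenotype[i] == "resistant") n_res <- n_res + 1L
    if (birds$phenotype[i] == "susceptible") n_sus <- n_sus + 1L
  }
  c(n_total = n_total, n_resistant = n_res, n_susceptible = n_sus)
}

# materialize a population from G1..G6 counts and count haplotypes directly
oracle_hap_freq <- function(counts) {
  model <- c(G1 = "TAG/TAG", G2 = "CCC/CCC", G3 = "CCG/CCG",
             G4 = "CCG/CCC", G5 = "TAG/CCC", G6 = "TAG/CCG")
  alleles <- character(0)
  for (g in names(counts)) {
    pair <- strsplit(model[[g]], "/")[[1]]
    alleles <- c(alleles, rep(pair, counts[[g]]))
  }
  table(alleles) / length(alleles)
}

# association table directly from published counts and frequencies
published_assoc <- function(locus, n_tests = 3) {
  tab <- published_genotype_table(locus)
  chi_square_rows(expected_counts(tab), n_tests = n_tests)
}
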
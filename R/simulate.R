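#' Parameters for the synthetic broiler-line generator
#'
#' The generator emulates the design behind the pooled-resequencing scan:
#' a line of hypobaric-challenged broilers segregating three haplotypes at
#' a causal block, a binary ascites phenotype produced by sex-dependent
#' penetrance of the combined genotype class, 8 DNA pools (2 phenotypes x
#' 2 sexes x 2 replicate pools of 10 birds), pooled read sampling at
#' Poisson depth, and a qPCR expression experiment keyed to the combined
#' genotype.
#'
#' Defaults are the published REL-line estimates: haplotype frequencies
#' 0.273 (TAG), 0.420 (CCC), 0.307 (CCG), 0 (TAC); penetrance
#' P(resistant | class, sex) of 0.72/0.62 (male/female) for intron-6
#' homozygous non-reference classes (G2, G3, G4), 0.50 for heterozygous
#' classes (G5, G6) and 0.49/0.46 for the homozygous reference class (G1);
#' a 134 kb causal block carrying 170 markers; pools of 10 birds at mean
#' depth 30; and true expression folds of 6.0/4.7/4.7 (G2) and
#' 4.5/3.4/4.04 (G4) in lung/heart/liver with 0.4-cycle Ct noise.
#'
#' @param n_birds population size (default 2000).
#' @param sex_ratio probability a bird is male (default 0.5).
#' @param haplotype_freqs named frequencies over TAG, CCC, CCG, TAC summing
#'   to 1.
#' @param penetrance list with numeric vectors `male` and `female`, each
#'   named over G1..G6 with values in `[0, 1]`. TAC-carrying birds (possible
#'   only when `f(TAC) > 0`) fall outside G1-G6 and use the G1 (homozygous
#'   reference) penetrance.
#' @param inconclusive_rate probability a bird's necropsy is inconclusive
#'   (default 0.02); such birds keep their genotype but no phenotype group.
#' @param n_background_snps unlinked neutral SNPs (default 5000).
#' @param background_freq_range uniform bounds for neutral non-reference
#'   allele frequencies (default `c(0.05, 0.95)`).
#' @param block_chrom,block_start causal block location (defaults "2",
#'   127620000, the coordinates of the scan's candidate region).
#' @param block_span_bp causal block length (default 134000 bp).
#' @param block_marker_count markers inside the block (default 170).
#' @param block_exon_offset offset of the exon-8-like boundary from the
#'   block start (default 88214 bp, the real intron-6/exon-8 geometry):
#'   markers beyond it behave like the exon-8 SNP (non-reference allele on
#'   CCC and TAC only), markers before it like the intron-6 SNPs
#'   (non-reference allele on CCC and CCG).
#' @param recomb_rate per-bp probability that a block marker's allele
#'   decouples from its haplotype, relative to the block anchor (default
#'   1e-8: recombination within the block is essentially absent, but
#'   configurable to create recombinant-like haplotypes).
#' @param pool_size birds per pool (default 10).
#' @param depth_mean mean Poisson read depth per pool per SNP (default 30).
#' @param fixed_depth if non-`NULL`, use this constant depth instead of
#'   Poisson sampling (used for calibration and the infinite-depth limit).
#' @param missing_pool_rate fraction of SNPs given depth 0 (missing
#'   frequency) in one random pool, to exercise the missingness filter
#'   (default 0.01).
#' @param misclassification_rate probability a pooled bird's phenotype label
#'   is wrong when pools are formed (default 0: pools are built from
#'   necropsy-confirmed birds).
#' @param expression_folds data.frame with columns `group`, `tissue`,
#'   `fold`: true expression fold change relative to the reference class.
#'   Unlisted group/tissue combinations have fold 1.
#' @param baseline_dct true Ct difference target-minus-reference gene in the
#'   reference class, cycles (default 4).
#' @param ct_noise_sd per-well Ct noise, cycles (default 0.4); each of the
#'   triplicate technical replicates draws independent noise.
#' @param seed optional random seed applied by the `simulate_*` functions.
#' @return list of class `"sim_params"`.
#' @export
sim_params <- function(n_birds = 2000L,
                       sex_ratio = 0.5,
                       haplotype_freqs = c(TAG = 0.273, CCC = 0.420,
                                           CCG = 0.307, TAC = 0),
                       penetrance = default_penetrance(),
                       inconclusive_rate = 0.02,
                       n_background_snps = 5000L,
                       background_freq_range = c(0.05, 0.95),
                       block_chrom = "2",
                       block_start = 127620000L,
                       block_span_bp = 134000L,
                       block_marker_count = 170L,
                       block_exon_offset = 88214L,
                       recomb_rate = 1e-8,
                       pool_size = 10L,
                       depth_mean = 30,
                       fixed_depth = NULL,
                       missing_pool_rate = 0.01,
                       misclassification_rate = 0,
                       expression_folds = default_expression_folds(),
                       baseline_dct = 4,
                       ct_noise_sd = 0.4,
                       seed = NULL) {
  p <- as.list(environment())
  stopifnot(p$n_birds >= 1, p$pool_size >= 1,
            abs(sum(p$haplotype_freqs) - 1) < 1e-8,
            all(p$haplotype_freqs >= 0),
            setequal(names(p$haplotype_freqs),
                     c("TAG", "CCC", "CCG", "TAC")),
            all(unlist(p$penetrance) >= 0), all(unlist(p$penetrance) <= 1),
            p$inconclusive_rate >= 0, p$inconclusive_rate < 1)
  for (sx in c("male", "female")) {
    if (!all(paste0("G", 1:6) %in% names(p$penetrance[[sx]]))) {
      stop("penetrance$", sx, " must name all classes G1..G6")
    }
  }
  structure(p, class = "sim_params")
}

#' @rdname sim_params
#' @export
default_penetrance <- function() {
  list(male = c(G1 = 0.49, G2 = 0.72, G3 = 0.72, G4 = 0.72,
                G5 = 0.50, G6 = 0.50),
       female = c(G1 = 0.46, G2 = 0.62, G3 = 0.62, G4 = 0.62,
                  G5 = 0.50, G6 = 0.50))
}

#' @rdname sim_params
#' @export
default_expression_folds <- function() {
  data.frame(group = rep(c("G2", "G4"), each = 3),
             tissue = rep(c("lung", "heart", "liver"), 2),
             fold = c(6.0, 4.7, 4.7, 4.5, 3.4, 4.04),
             stringsAsFactors = FALSE)
}

hap_state <- function(hap, locus) {
  unname(HAPLOTYPES[hap, locus])
}

#' Simulate one broiler line
#'
#' Each bird draws two haplotypes independently from `haplotype_freqs`
#' (Hardy-Weinberg pairing) and a sex; its intron-6 and exon-8 genotype
#' calls derive deterministically from the haplotype pair; its ascites
#' phenotype is Bernoulli with the penetrance of its combined genotype class
#' and sex (TAC carriers use the homozygous-reference penetrance); an
#' inconclusive-necropsy mask then hides the phenotype of a small fraction
#' of birds. Latent haplotypes are retained in columns `hap1`/`hap2` for
#' truth-checking.
#'
#' @param params a [sim_params()].
#' @param seed optional seed (overrides `params$seed`).
#' @param line line label for the output table (default `"SIM"`).
#' @return bird `data.frame`: `bird_id`, `line`, `sex`, `phenotype`,
#'   `intron6`, `exon8`, `combined`, `hap1`, `hap2`.
#' @export
simulate_line <- function(params = sim_params(), seed = NULL, line = "SIM") {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(seed)) seed <- params$seed
  if (!is.null(seed)) set.seed(seed)
  n <- params$n_birds
  haps <- names(params$haplotype_freqs)
  h1 <- sample(haps, n, replace = TRUE, prob = params$haplotype_freqs)
  h2 <- sample(haps, n, replace = TRUE, prob = params$haplotype_freqs)
  dosage_state <- function(d) c("hom_ref", "het", "hom_alt")[d + 1L]
  i6 <- dosage_state((hap_state(h1, "intron6") == "alt") +
                       (hap_state(h2, "intron6") == "alt"))
  e8 <- dosage_state((hap_state(h1, "exon8") == "alt") +
                       (hap_state(h2, "exon8") == "alt"))
  combined <- call_combined_genotype(i6, e8)
  sex <- ifelse(stats::runif(n) < params$sex_ratio, "male", "female")
  pen_class <- ifelse(combined %in% paste0("G", 1:6), combined, "G1")
  pen <- numeric(n)
  for (sx in c("male", "female")) {
    idx <- sex == sx
    pen[idx] <- params$penetrance[[sx]][pen_class[idx]]
  }
  phenotype <- ifelse(stats::runif(n) < pen, "resistant", "susceptible")
  phenotype[stats::runif(n) < params$inconclusive_rate] <- "inconclusive"
  data.frame(bird_id = sprintf("b%05d", seq_len(n)), line = line, sex = sex,
             phenotype = phenotype, intron6 = i6, exon8 = e8,
             combined = combined, hap1 = h1, hap2 = h2,
             stringsAsFactors = FALSE)
}

#' Simulate the 8-pool pooled-resequencing experiment
#'
#' Builds the canonical design ([full_pool_design()]): for each phenotype x
#' sex stratum, `2 * pool_size` phenotype-resolved birds are sampled without
#' replacement and split into two disjoint replicate pools. At each SNP the
#' true pool frequency is the non-reference allele count over `2*pool_size`
#' chromosomes; the observed frequency is `Binomial(d, true)/d` with depth
#' `d ~ Poisson(depth_mean)` (floored at 1) per pool per SNP. Background
#' SNPs are independent of phenotype: their pool allele counts are
#' `Binomial(2*pool_size, p)` draws at the SNP's population frequency.
#' Causal-block markers inherit each pooled bird's haplotype state:
#' intron-6-like markers carry the non-reference allele on CCC and CCG
#' haplotypes, exon-8-like markers on CCC (and TAC) only, with a per-marker
#' decoupling probability of `recomb_rate` per bp from the block anchor.
#' A `missing_pool_rate` fraction of SNPs gets depth 0 and a missing
#' frequency in one random pool.
#'
#' @param birds bird table from [simulate_line()] (latent haplotype columns
#'   required).
#' @param params a [sim_params()].
#' @param seed optional seed; the default leaves the RNG stream untouched so
#'   that [simulate_line()] + [simulate_pools()] form one reproducible
#'   sequence.
#' @return list with `design` (a [pool_design()]), `pools` (pool SNP table,
#'   sorted by position) and `truth` (block coordinates, marker positions
#'   and classes, pooled bird ids).
#' @export
simulate_pools <- function(birds, params = sim_params(), seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  design <- full_pool_design()
  k <- params$pool_size
  if (params$misclassification_rate > 0) {
    flip <- birds$phenotype %in% c("resistant", "susceptible") &
      stats::runif(nrow(birds)) < params$misclassification_rate
    birds$phenotype[flip] <- ifelse(birds$phenotype[flip] == "resistant",
                                    "susceptible", "resistant")
  }
  membership <- list()
  for (i in seq_len(nrow(design))) {
    ph <- design$phenotype[i]; sx <- design$sex[i]
    if (design$replicate[i] == 1L) {
      avail <- which(birds$phenotype == ph & birds$sex == sx)
      if (length(avail) < 2L * k) {
        stop("insufficient ", ph, " ", sx, " birds to fill 2 pools of ",
             k, " (have ", length(avail), ", need ", 2L * k, ")")
      }
      picked <- sample(avail, 2L * k)
      membership[[design$pool_id[i]]] <- picked[seq_len(k)]
      rep2 <- design$pool_id[design$phenotype == ph & design$sex == sx &
                               design$replicate == 2L]
      if (length(rep2)) membership[[rep2]] <- picked[(k + 1L):(2L * k)]
    }
  }
  n_pools <- nrow(design)

  # background SNPs: phenotype-independent allele counts per pool
  n_bg <- params$n_background_snps
  chrom_len <- 149000000L
  bg_pos <- sort(sample.int(chrom_len, n_bg))
  bg_p <- stats::runif(n_bg, params$background_freq_range[1],
                       params$background_freq_range[2])
  bg_true <- matrix(stats::rbinom(n_bg * n_pools, 2L * k, rep(bg_p, n_pools)),
                    nrow = n_bg, ncol = n_pools) / (2 * k)

  # causal block markers: allele states follow the pooled birds' haplotypes
  m <- params$block_marker_count
  mk_pos <- sort(sample(seq.int(params$block_start,
                                params$block_start + params$block_span_bp),
                        m))
  mk_class <- ifelse(mk_pos < params$block_start + params$block_exon_offset,
                     "intron6", "exon8")
  pooled_idx <- unlist(membership, use.names = FALSE)
  nb <- length(pooled_idx)
  carrier <- function(hap, class) {
    ifelse(class == "intron6", hap %in% c("CCC", "CCG"),
           hap %in% c("CCC", "TAC"))
  }
  r_marker <- pmin(1, params$recomb_rate * abs(mk_pos - params$block_start))
  dose <- matrix(0L, nrow = nb, ncol = m)
  for (hcol in c("hap1", "hap2")) {
    hap <- birds[[hcol]][pooled_idx]
    base <- outer(seq_len(nb), seq_len(m), function(i, j) {
      as.integer(carrier(hap[i], mk_class[j]))
    })
    flip <- matrix(stats::rbinom(nb * m, 1L, rep(r_marker, each = nb)),
                   nrow = nb)
    dose <- dose + as.integer(xor(base == 1L, flip == 1L))
  }
  mk_true <- matrix(0, nrow = m, ncol = n_pools)
  for (j in seq_len(n_pools)) {
    rows <- match(membership[[design$pool_id[j]]], pooled_idx)
    mk_true[, j] <- colSums(dose[rows, , drop = FALSE]) / (2 * k)
  }

  pos <- c(bg_pos, mk_pos)
  true_freq <- rbind(bg_true, mk_true)
  is_marker <- c(rep(FALSE, n_bg), rep(TRUE, m))
  ord <- order(pos)
  pos <- pos[ord]; true_freq <- true_freq[ord, , drop = FALSE]
  is_marker <- is_marker[ord]
  n_snps <- length(pos)

  depth <- if (!is.null(params$fixed_depth)) {
    matrix(as.integer(params$fixed_depth), n_snps, n_pools)
  } else {
    matrix(pmax(1L, stats::rpois(n_snps * n_pools, params$depth_mean)),
           n_snps, n_pools)
  }
  n_miss <- round(params$missing_pool_rate * n_snps)
  if (n_miss > 0) {
    miss_snp <- sample.int(n_snps, n_miss)
    miss_pool <- sample.int(n_pools, n_miss, replace = TRUE)
    depth[cbind(miss_snp, miss_pool)] <- 0L
  }
  obs <- matrix(NA_real_, n_snps, n_pools)
  nonzero <- depth > 0L
  obs[nonzero] <- stats::rbinom(sum(nonzero), depth[nonzero],
                                true_freq[nonzero]) / depth[nonzero]

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_snps, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  tab <- data.frame(chrom = params$block_chrom, pos = pos, ref = ref,
                    alt = unname(alt),
                    qscore = sample(30:60, n_snps, replace = TRUE),
                    stringsAsFactors = FALSE)
  for (j in seq_len(n_pools)) {
    tab[[paste0(design$pool_id[j], "_depth")]] <- depth[, j]
    tab[[paste0(design$pool_id[j], "_freq")]] <- obs[, j]
  }
  attr(tab, "pool_ids") <- design$pool_id
  truth <- list(block_chrom = params$block_chrom,
                block_start = params$block_start,
                block_end = params$block_start + params$block_span_bp,
                marker_pos = mk_pos,
                marker_class = mk_class,
                pool_members = lapply(membership,
                                      function(i) birds$bird_id[i]))
  list(design = design, pools = tab, truth = truth)
}

#' Simulate a qPCR Ct table keyed to combined genotype classes
#'
#' For each sampled bird and tissue, the true reference-gene Ct is 22
#' cycles and the true target Ct is `22 + baseline_dct - log2(fold)` with
#' `fold` the group/tissue entry of `expression_folds` (1 when not listed,
#' with a message). Each of the triplicate wells per reaction draws
#' independent `Normal(0, ct_noise_sd)` technical noise.
#'
#' @param birds bird table with a `combined` column.
#' @param params a [sim_params()].
#' @param n_per_group named sample sizes per combined genotype class
#'   (defaults to the published expression-panel sizes: 12, 14, 9, 8, 11, 1
#'   for G1..G6). Groups with fewer available birds use all of them.
#' @param seed optional seed.
#' @param tissues tissues to assay.
#' @return Ct table `data.frame` (see [read_ct_table()]).
#' @export
simulate_ct_table <- function(birds, params = sim_params(),
                              n_per_group = c(G1 = 12, G2 = 14, G3 = 9,
                                              G4 = 8, G5 = 11, G6 = 1),
                              seed = NULL,
                              tissues = c("lung", "heart", "liver")) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  folds <- params$expression_folds
  rows <- list()
  for (grp in names(n_per_group)) {
    avail <- which(birds$combined == grp)
    n_want <- n_per_group[[grp]]
    if (!length(avail)) next
    picked <- if (length(avail) >= n_want) sample(avail, n_want) else avail
    for (tissue in tissues) {
      f <- folds$fold[folds$group == grp & folds$tissue == tissue]
      if (!length(f)) {
        if (!grp %in% c("G1", folds$group)) {
          message("no configured fold for ", grp, "/", tissue,
                  "; assuming 1")
        }
        f <- 1
      }
      true_ref <- 22
      true_tgt <- true_ref + params$baseline_dct - log2(f)
      for (b in picked) {
        for (gene in c("CPQ", "TBP")) {
          mu <- if (gene == "TBP") true_ref else true_tgt
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = birds$bird_id[b], group = grp, tissue = tissue,
            gene = gene, replicate = 1:3,
            ct = mu + stats::rnorm(3, 0, params$ct_noise_sd),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a complete synthetic dataset to disk
#'
#' Runs [simulate_line()], [simulate_pools()] and [simulate_ct_table()] with
#' one seed and writes `genotypes.tsv`, `design.tsv`, `pools.tsv`, `ct.tsv`
#' and `truth.json` (latent parameters for recovery tests) into `out_dir`.
#' Identical seed and parameters produce byte-identical outputs.
#'
#' @param params a [sim_params()].
#' @param out_dir output directory (created if needed).
#' @param seed seed applied once at the start (overrides `params$seed`).
#' @return invisibly, named vector of file paths.
#' @export
simulate_dataset <- function(params = sim_params(), out_dir, seed = NULL) {
  if (is.null(seed)) seed <- params$seed
  if (!is.null(seed)) set.seed(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  birds <- simulate_line(params, seed = NULL)
  sim <- simulate_pools(birds, params, seed = NULL)
  ct <- simulate_ct_table(birds, params, seed = NULL)
  paths <- c(genotypes = file.path(out_dir, "genotypes.tsv"),
             design = file.path(out_dir, "design.tsv"),
             pools = file.path(out_dir, "pools.tsv"),
             ct = file.path(out_dir, "ct.tsv"),
             truth = file.path(out_dir, "truth.json"))
  write_genotype_table(birds, paths[["genotypes"]])
  write_pool_design(sim$design, paths[["design"]])
  write_pool_table(sim$pools, paths[["pools"]])
  write_ct_table(ct, paths[["ct"]])
  truth <- list(
    haplotype_freqs = as.list(params$haplotype_freqs),
    penetrance = params$penetrance,
    block = list(chrom = sim$truth$block_chrom,
                 start = sim$truth$block_start,
                 end = sim$truth$block_end),
    marker_pos = sim$truth$marker_pos,
    expression_folds = params$expression_folds,
    seed = seed)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Expected causal-marker frequency difference by exact enumeration
#'
#' Analytic oracle for the generator: conditions haplotype dosage on
#' phenotype via Bayes' rule over the Hardy-Weinberg genotype classes, with
#' the configured penetrance, and returns the expected resistant-minus-
#' susceptible pool frequency difference at a causal marker for one sex.
#' TAC carriers are grouped by their (intron-6, exon-8) states and use the
#' G1 penetrance, mirroring [simulate_line()].
#'
#' @param params a [sim_params()].
#' @param sex `"male"` or `"female"`.
#' @param marker_class `"intron6"` (non-reference allele on CCC and CCG) or
#'   `"exon8"` (on CCC and TAC).
#' @return expected delta (dimensionless, in `[-1, 1]`).
#' @export
expected_causal_delta <- function(params = sim_params(), sex = "male",
                                  marker_class = c("intron6", "exon8")) {
  marker_class <- match.arg(marker_class)
  sex <- match.arg(sex, c("male", "female"))
  f <- params$haplotype_freqs
  haps <- names(f)
  pen <- params$penetrance[[sex]]
  model <- combined_genotype_model()
  pairs <- expand.grid(h1 = haps, h2 = haps, stringsAsFactors = FALSE)
  pairs$p <- f[pairs$h1] * f[pairs$h2]
  key <- apply(pairs[, c("h1", "h2")], 1, function(h) {
    paste(sort(h), collapse = "/")
  })
  model_key <- vapply(model, function(s) {
    paste(sort(strsplit(s, "/")[[1]]), collapse = "/")
  }, character(1))
  cls <- names(model_key)[match(key, model_key)]
  cls[is.na(cls)] <- "G1"  # TAC carriers use hom_ref penetrance
  dose <- (carrier_at(pairs$h1, marker_class) +
             carrier_at(pairs$h2, marker_class))
  pr <- pen[cls]
  p_r <- sum(pairs$p * pr)
  e_r <- sum(pairs$p * pr * dose / 2) / p_r
  e_s <- sum(pairs$p * (1 - pr) * dose / 2) / (1 - p_r)
  unname(e_r - e_s)
}

carrier_at <- function(hap, marker_class) {
  if (marker_class == "intron6") {
    as.integer(hap %in% c("CCC", "CCG"))
  } else {
    as.integer(hap %in% c("CCC", "TAC"))
  }
}

#' Analytic null standard deviation of the pooled frequency difference
#'
#' For SNPs with a common true frequency `p` in all pools, constant depth
#' `d`, pools of `pool_size` birds and two replicate pools averaged per
#' phenotype, the variance of one observed pool frequency is binomial bird
#' sampling plus binomial read sampling:
#' `Var(f) = p(1-p)/K + p(1-p) (1 - 1/K) / d` with `K = 2 * pool_size`
#' chromosomes, and the difference of the two two-pool means has variance
#' equal to `Var(f)` (each mean contributes `Var(f)/2`). This closed form is
#' the oracle for null calibration of the scan.
#'
#' @param p true non-reference allele frequency.
#' @param depth constant read depth per pool.
#' @param pool_size birds per pool.
#' @return standard deviation of the null frequency difference.
#' @export
null_delta_sd <- function(p, depth, pool_size = 10) {
  K <- 2 * pool_size
  v_pool <- p * (1 - p) / K + p * (1 - p) * (1 - 1 / K) / depth
  sqrt(v_pool)
}
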
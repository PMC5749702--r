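#' The three-haplotype model for the intron-6 / exon-8 locus pair
#'
#' The two intron-6 SNPs are genotyped jointly as one locus with alleles
#' "TA" (reference) and "CC" (non-reference); the exon-8 SNP has alleles
#' "G" (reference) and "C" (non-reference). Three haplotypes segregate:
#' `TAG` (all reference), `CCC` (all non-reference) and `CCG` (recombinant:
#' non-reference intron 6 with reference exon 8). The fourth combination,
#' `TAC`, is excluded by the model (it is never observed); two-locus
#' genotypes that would require it are reported as incompatible.
#'
#' @format A character matrix with one row per haplotype (`TAG`, `CCC`,
#'   `CCG`, `TAC`) and columns `intron6`, `exon8` giving each haplotype's
#'   allele at the two loci (`"ref"`/`"alt"`).
#' @export
HAPLOTYPES <- local({
  m <- rbind(TAG = c("ref", "ref"),
             CCC = c("alt", "alt"),
             CCG = c("alt", "ref"),
             TAC = c("ref", "alt"))
  colnames(m) <- c("intron6", "exon8")
  m
})

#' Combined genotype classes G1-G6
#'
#' The six two-locus genotypes formed by pairs of the three model
#' haplotypes: G1 = TAG/TAG, G2 = CCC/CCC, G3 = CCG/CCG, G4 = CCG/CCC,
#' G5 = TAG/CCC, G6 = TAG/CCG.
#'
#' @return named character vector mapping class label to `"hap/hap"`.
#' @export
combined_genotype_model <- function() {
  c(G1 = "TAG/TAG", G2 = "CCC/CCC", G3 = "CCG/CCG",
    G4 = "CCG/CCC", G5 = "TAG/CCC", G6 = "TAG/CCG")
}

#' Classify two-locus unphased genotypes into G1-G6
#'
#' Under the three-haplotype (no-TAC) model the six valid combinations of
#' intron-6 and exon-8 genotype states map bijectively onto G1-G6; in
#' particular the double heterozygote resolves as TAG/CCC (G5), never as
#' TAC/CCG. The three combinations that force a TAC haplotype
#' (intron-6 `hom_ref` with exon-8 `het` or `hom_alt`, and intron-6 `het`
#' with exon-8 `hom_alt`) return `"incompatible"`. A missing call at either
#' locus returns `NA` (missing, not incompatible).
#'
#' @param intron6,exon8 character vectors of genotype states
#'   (`hom_ref`/`het`/`hom_alt`, or assay labels accepted by
#'   [normalize_genotype()]).
#' @return character vector of `"G1"`..`"G6"`, `"incompatible"`, or `NA`.
#' @examples
#' call_combined_genotype("CC", "C")   # G2
#' call_combined_genotype("YM", "S")   # G5, resolved as TAG/CCC
#' call_combined_genotype("TA", "C")   # incompatible (forces TAC)
#' @export
call_combined_genotype <- function(intron6, exon8) {
  i6 <- normalize_genotype(intron6, "intron6")
  e8 <- normalize_genotype(exon8, "exon8")
  map <- c("hom_ref.hom_ref" = "G1",
           "hom_alt.hom_alt" = "G2",
           "hom_alt.hom_ref" = "G3",
           "hom_alt.het"     = "G4",
           "het.het"         = "G5",
           "het.hom_ref"     = "G6",
           "hom_ref.het"     = "incompatible",
           "hom_ref.hom_alt" = "incompatible",
           "het.hom_alt"     = "incompatible")
  out <- unname(map[paste(i6, e8, sep = ".")])
  out[is.na(i6) | is.na(e8)] <- NA_character_
  out
}

#' Tabulate combined genotype classes
#'
#' @param birds bird table with `intron6` and `exon8` columns (a `combined`
#'   column, if present, is used directly).
#' @return named integer vector over G1-G6 with attribute
#'   `"n_incompatible"`; incompatible birds are reported, not silently
#'   dropped.
#' @export
combined_genotype_counts <- function(birds) {
  g <- if ("combined" %in% names(birds)) birds$combined else
    call_combined_genotype(birds$intron6, birds$exon8)
  counts <- table(factor(g, levels = paste0("G", 1:6)))
  out <- stats::setNames(as.integer(counts), names(counts))
  attr(out, "n_incompatible") <- sum(g == "incompatible", na.rm = TRUE)
  out
}

#' Haplotype frequencies by allele counting from G1-G6 counts
#'
#' Every bird carries two haplotypes, so with `N` classified birds there are
#' `2N` alleles and
#' `f(TAG) = (2 G1 + G5 + G6) / 2N`,
#' `f(CCG) = (2 G3 + G4 + G6) / 2N`,
#' `f(CCC) = (2 G2 + G4 + G5) / 2N`.
#' Counting conserves alleles exactly: the three haplotype counts sum to
#' `2N` before normalization, and the frequencies sum to 1.
#'
#' @param genotype_counts named non-negative counts for `G1`..`G6` (missing
#'   names are treated as 0).
#' @return list with `freq` (named frequencies over TAG, CCC, CCG),
#'   `hap_counts` (integer allele counts) and `n_alleles` (`2N`).
#' @examples
#' count_haplotype_frequencies(
#'   c(G1 = 166, G6 = 82, G5 = 59, G3 = 178, G4 = 94, G2 = 287))
#' @export
count_haplotype_frequencies <- function(genotype_counts) {
  g <- stats::setNames(rep(0, 6), paste0("G", 1:6))
  g[names(genotype_counts)] <- genotype_counts
  if (any(g < 0)) stop("genotype counts must be non-negative")
  n <- sum(g)
  if (n == 0) stop("total genotype count is zero")
  hap <- c(TAG = 2 * g[["G1"]] + g[["G5"]] + g[["G6"]],
           CCC = 2 * g[["G2"]] + g[["G4"]] + g[["G5"]],
           CCG = 2 * g[["G3"]] + g[["G4"]] + g[["G6"]])
  list(freq = hap / (2 * n), hap_counts = hap, n_alleles = 2 * n)
}

#' Tabulate the nine raw two-locus genotype combinations
#'
#' @param intron6,exon8 genotype state vectors (see
#'   [call_combined_genotype()]).
#' @return 3x3 integer matrix, rows = intron-6 state, cols = exon-8 state,
#'   both ordered `hom_ref`, `het`, `hom_alt`. Pairs with a missing call are
#'   excluded.
#' @export
two_locus_counts <- function(intron6, exon8) {
  lv <- c("hom_ref", "het", "hom_alt")
  i6 <- factor(normalize_genotype(intron6, "intron6"), levels = lv)
  e8 <- factor(normalize_genotype(exon8, "exon8"), levels = lv)
  ok <- !is.na(i6) & !is.na(e8)
  m <- table(i6[ok], e8[ok])
  matrix(as.integer(m), 3, 3, dimnames = list(intron6 = lv, exon8 = lv))
}

# compatible unordered haplotype pairs per two-locus genotype cell
.cell_pairs <- list(
  "hom_ref.hom_ref" = list(c("TAG", "TAG")),
  "hom_ref.het"     = list(c("TAG", "TAC")),
  "hom_ref.hom_alt" = list(c("TAC", "TAC")),
  "het.hom_ref"     = list(c("TAG", "CCG")),
  "het.het"         = list(c("TAG", "CCC"), c("CCG", "TAC")),
  "het.hom_alt"     = list(c("CCC", "TAC")),
  "hom_alt.hom_ref" = list(c("CCG", "CCG")),
  "hom_alt.het"     = list(c("CCG", "CCC")),
  "hom_alt.hom_alt" = list(c("CCC", "CCC")))

pair_prob <- function(freq, pair) {
  p <- freq[pair[1]] * freq[pair[2]]
  if (pair[1] != pair[2]) p <- 2 * p
  unname(p)
}

#' EM haplotype frequency estimation over all four haplotypes
#'
#' Standard two-locus expectation-maximization for unphased genotype data
#' over \{TAG, CCC, CCG, TAC\}. Only the double-heterozygote cell is phase
#' ambiguous (TAG/CCC vs CCG/TAC); the E step assigns it in proportion to
#' the products of current haplotype frequencies, and the M step re-counts.
#' This is the quantitative diagnostic for the absent fourth haplotype: on
#' data generated without TAC the EM estimate of `f(TAC)` collapses toward
#' 0, and its log-likelihood is never below that of the allele-counting
#' solution extended with `f(TAC) = 0`.
#'
#' @param genotype_counts 3x3 matrix from [two_locus_counts()] (rows
#'   intron-6, cols exon-8, ordered `hom_ref`, `het`, `hom_alt`).
#' @param max_iter maximum EM iterations (default 10000).
#' @param tol stop when the largest frequency change is below this
#'   (default 1e-10).
#' @return list with `freq` (TAG, CCC, CCG, TAC), `loglik`, `n_iter`,
#'   `converged`.
#' @export
em_haplotype_frequencies <- function(genotype_counts, max_iter = 10000L,
                                     tol = 1e-10) {
  m <- as.matrix(genotype_counts)
  stopifnot(identical(dim(m), c(3L, 3L)), all(m >= 0))
  n <- sum(m)
  if (n == 0) stop("all genotype counts are zero")
  lv <- c("hom_ref", "het", "hom_alt")
  counts <- stats::setNames(as.vector(t(m)),
                            as.vector(t(outer(lv, lv, paste, sep = "."))))
  haps <- c("TAG", "CCC", "CCG", "TAC")
  freq <- stats::setNames(rep(0.25, 4), haps)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    hap_counts <- stats::setNames(rep(0, 4), haps)
    for (cell in names(counts)) {
      nc <- counts[[cell]]
      if (nc == 0) next
      pairs <- .cell_pairs[[cell]]
      w <- vapply(pairs, pair_prob, numeric(1), freq = freq)
      if (sum(w) == 0) w <- rep(1, length(w))
      w <- w / sum(w)
      for (k in seq_along(pairs)) {
        hap_counts[pairs[[k]][1]] <- hap_counts[pairs[[k]][1]] + nc * w[k]
        hap_counts[pairs[[k]][2]] <- hap_counts[pairs[[k]][2]] + nc * w[k]
      }
    }
    new_freq <- hap_counts / (2 * n)
    if (max(abs(new_freq - freq)) < tol) {
      freq <- new_freq
      converged <- TRUE
      break
    }
    freq <- new_freq
  }
  list(freq = freq, loglik = two_locus_loglik(counts, freq),
       n_iter = it, converged = converged)
}

two_locus_loglik <- function(counts, freq) {
  ll <- 0
  for (cell in names(counts)) {
    nc <- counts[[cell]]
    if (nc == 0) next
    p <- sum(vapply(.cell_pairs[[cell]], pair_prob, numeric(1), freq = freq))
    if (p <= 0) return(-Inf)
    ll <- ll + nc * log(p)
  }
  ll
}

#' Log-likelihood of a haplotype frequency vector for two-locus counts
#'
#' Multinomial log-likelihood of the nine-cell genotype table under
#' Hardy-Weinberg random pairing of haplotypes; used to compare the EM
#' solution with the allele-counting solution extended with `f(TAC) = 0`.
#'
#' @param genotype_counts 3x3 matrix from [two_locus_counts()].
#' @param freq named frequencies over TAG, CCC, CCG (TAC optional, default 0).
#' @return log-likelihood (`-Inf` when an observed cell has probability 0).
#' @export
haplotype_loglik <- function(genotype_counts, freq) {
  m <- as.matrix(genotype_counts)
  lv <- c("hom_ref", "het", "hom_alt")
  counts <- stats::setNames(as.vector(t(m)),
                            as.vector(t(outer(lv, lv, paste, sep = "."))))
  full <- stats::setNames(rep(0, 4), c("TAG", "CCC", "CCG", "TAC"))
  full[names(freq)] <- freq
  two_locus_loglik(counts, full)
}
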
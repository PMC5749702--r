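#' Published genotype count tables for three broiler lines
#'
#' Reference genotype-by-phenotype tables from the published genotyping of
#' three ascites-phenotyped broiler lines (research line REL and commercial
#' lines Y and Z): per-line, per-stratum counts and observed
#' resistant/susceptible frequencies at the intron-6 locus (labels
#' TA/YM/CC), the exon-8 locus (G/S/C), and the combined two-locus G1-G6
#' classes, plus which rows the publication marked significant
#' (adjusted p < 0.05). These serve as fixed inputs for reproducing the
#' downstream association and haplotype-frequency computations; the raw
#' per-bird data are not public.
#'
#' @param locus `"intron6"`, `"exon8"` or `"combined"`.
#' @return `data.frame` with columns `line`, `stratum`, `genotype_class`,
#'   `n_total`, `r_freq`, `s_freq`, `starred` plus derived `n_resistant`,
#'   `n_susceptible` (frequency times count, rounded to published
#'   precision).
#' @export
published_genotype_table <- function(locus = c("intron6", "exon8",
                                               "combined")) {
  locus <- match.arg(locus)
  raw <- switch(locus, intron6 = .pub_intron6, exon8 = .pub_exon8,
                combined = .pub_combined)
  tab <- utils::read.table(text = raw, header = TRUE,
                           stringsAsFactors = FALSE)
  tab$n_resistant <- tab$n_total * tab$r_freq
  tab$n_susceptible <- tab$n_total * tab$s_freq
  tab$starred <- tab$starred == 1
  tab
}

#' @rdname published_genotype_table
#' @details `published_combined_counts()` returns the combined-genotype
#'   counts for one line in the `"all"` stratum as a named vector over
#'   G1..G6 — for the REL line: G1 = 166, G6 = 82, G5 = 59, G3 = 178,
#'   G4 = 94, G2 = 287 (866 birds), the input for the published haplotype
#'   frequency estimates of 27.3\% TAG, 30.7\% CCG and 42\% CCC.
#' @param line `"REL"`, `"Y"` or `"Z"`.
#' @export
published_combined_counts <- function(line = "REL") {
  tab <- published_genotype_table("combined")
  tab <- tab[tab$line == line & tab$stratum == "all", , drop = FALSE]
  stats::setNames(tab$n_total, tab$genotype_class)
}

.pub_intron6 <- "
line stratum genotype_class n_total r_freq s_freq starred
REL all TA 198 0.46 0.54 1
REL all YM 151 0.50 0.50 0
REL all CC 615 0.66 0.34 1
REL male TA 87 0.49 0.51 1
REL male YM 68 0.56 0.44 0
REL male CC 294 0.72 0.28 1
REL female TA 84 0.46 0.54 0
REL female YM 69 0.45 0.55 0
REL female CC 256 0.62 0.38 0
Y all TA 86 0.36 0.64 1
Y all YM 36 0.44 0.56 0
Y all CC 66 0.74 0.26 1
Y male TA 38 0.37 0.63 1
Y male YM 17 0.53 0.47 0
Y male CC 37 0.81 0.19 1
Y female TA 48 0.35 0.65 0
Y female YM 19 0.37 0.63 0
Y female CC 29 0.65 0.35 0
Z all TA 54 0.45 0.55 1
Z all YM 27 0.44 0.56 0
Z all CC 104 0.82 0.18 1
Z male TA 21 0.38 0.62 1
Z male YM 14 0.64 0.36 0
Z male CC 71 0.86 0.14 0
Z female TA 31 0.48 0.52 0
Z female YM 12 0.18 0.82 0
Z female CC 32 0.72 0.28 0
"

.pub_exon8 <- "
line stratum genotype_class n_total r_freq s_freq starred
REL all G 574 0.55 0.45 1
REL all S 244 0.65 0.35 0
REL all C 373 0.69 0.31 1
REL male G 269 0.59 0.41 0
REL male S 110 0.70 0.30 0
REL male C 167 0.72 0.28 0
REL female G 230 0.52 0.48 0
REL female S 112 0.60 0.40 0
REL female C 164 0.68 0.32 0
Y all G 103 0.40 0.60 0
Y all S 8 0.37 0.63 0
Y all C 37 0.89 0.11 1
Y male G 45 0.47 0.53 0
Y male S 3 0.33 0.67 0
Y male C 20 0.90 0.10 1
Y female G 58 0.35 0.65 0
Y female S 5 0.40 0.60 0
Y female C 15 0.87 0.13 1
Z all G 91 0.50 0.50 1
Z all S 33 0.73 0.27 0
Z all C 49 0.90 0.10 1
Z male G 46 0.52 0.48 1
Z male S 23 0.87 0.13 0
Z male C 30 0.93 0.07 1
Z female G 41 0.44 0.56 0
Z female S 10 0.40 0.60 0
Z female C 19 0.84 0.16 1
"

.pub_combined <- "
line stratum genotype_class n_total r_freq s_freq starred
REL all G1 166 0.45 0.55 1
REL all G6 82 0.53 0.47 0
REL all G5 59 0.51 0.49 0
REL all G3 178 0.56 0.44 0
REL all G4 94 0.73 0.27 0
REL all G2 287 0.71 0.29 1
REL male G1 76 0.51 0.49 1
REL male G6 42 0.55 0.45 0
REL male G5 20 0.65 0.35 0
REL male G3 83 0.63 0.37 0
REL male G4 49 0.73 0.27 0
REL male G2 137 0.76 0.24 0
REL female G1 65 0.41 0.59 0
REL female G6 32 0.52 0.48 0
REL female G5 34 0.44 0.56 0
REL female G3 76 0.50 0.50 0
REL female G4 36 0.71 0.29 0
REL female G2 115 0.69 0.31 1
Y all G1 75 0.32 0.68 1
Y all G6 4 0.50 0.50 0
Y all G5 5 0.40 0.60 0
Y all G3 23 0.61 0.39 0
Y all G4 2 0.50 0.50 0
Y all G2 35 0.89 0.11 1
Y male G1 32 0.37 0.63 1
Y male G6 2 0.50 0.50 0
Y male G5 2 0.00 1.00 0
Y male G3 11 0.73 0.27 0
Y male G4 1 1.00 0.00 0
Y male G2 20 0.90 0.10 1
Y female G1 43 0.28 0.72 0
Y female G6 2 0.50 0.50 0
Y female G5 3 0.67 0.33 0
Y female G3 12 0.50 0.50 0
Y female G4 1 0.00 1.00 0
Y female G2 15 0.87 0.13 1
Z all G1 45 0.38 0.62 1
Z all G6 11 0.46 0.54 0
Z all G5 12 0.50 0.50 0
Z all G3 32 0.66 0.34 0
Z all G4 18 0.89 0.11 0
Z all G2 49 0.90 0.10 1
Z male G1 19 0.37 0.63 1
Z male G6 5 0.40 0.60 0
Z male G5 8 0.75 0.25 0
Z male G3 22 0.68 0.32 0
Z male G4 15 0.93 0.07 1
Z male G2 30 0.93 0.07 1
Z female G1 25 0.36 0.64 1
Z female G6 5 0.40 0.60 0
Z female G5 4 0.00 1.00 0
Z female G3 9 0.56 0.44 0
Z female G4 3 0.67 0.33 0
Z female G2 19 0.84 0.16 1
"
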
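#' Read a per-bird genotype/phenotype table
#'
#' Tab-separated, one row per bird, columns `bird_id`, `line`, `sex`,
#' `phenotype`, then one column per genotyped locus. Genotype labels may be
#' the assay labels used for the intron-6 locus (`TA` homozygous reference,
#' `YM` heterozygous, `CC` homozygous non-reference), the exon-8 locus
#' (`G`, `S`, `C`), or the normalized states `hom_ref`/`het`/`hom_alt`/
#' `missing`. Phenotypes: `resistant`/`susceptible`/`inconclusive`
#' (synonyms `R`/`S`/`U`). Birds with an inconclusive necropsy are retained:
#' they count toward population totals but never toward phenotype groups.
#'
#' @param path path to the TSV file.
#' @return A `data.frame` with normalized `sex`, `phenotype` and genotype
#'   states (`NA` for missing calls). Locus column names are preserved.
#' @export
read_genotype_table <- function(path) {
  if (!file.exists(path)) stop("genotype table not found: ", path)
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         na.strings = c("NA", ""), stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  need <- c("bird_id", "line", "sex", "phenotype")
  if (!all(need %in% names(x))) {
    stop("genotype table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(x$bird_id)) {
    stop("duplicate bird_id: ",
         paste(unique(x$bird_id[duplicated(x$bird_id)]), collapse = ", "))
  }
  x$sex <- normalize_sex(x$sex)
  x$phenotype <- normalize_phenotype(x$phenotype)
  loci <- setdiff(names(x), c(need, "combined"))
  for (l in loci) x[[l]] <- normalize_genotype(x[[l]], locus = l)
  if ("combined" %in% names(x)) {
    ok <- x$combined %in% c(paste0("G", 1:6), "incompatible") |
      is.na(x$combined)
    if (!all(ok)) {
      stop("invalid combined genotype label: ",
           paste(unique(x$combined[!ok]), collapse = ", "))
    }
  }
  x
}

#' Normalize genotype labels to hom_ref/het/hom_alt
#'
#' @param x character vector of genotype labels.
#' @param locus locus name, used only in error messages.
#' @return character vector of `"hom_ref"`, `"het"`, `"hom_alt"`, or `NA`.
#' @export
normalize_genotype <- function(x, locus = "locus") {
  map <- c(TA = "hom_ref", YM = "het", CC = "hom_alt",
           G = "hom_ref", S = "het", C = "hom_alt",
           hom_ref = "hom_ref", het = "het", hom_alt = "hom_alt")
  x0 <- trimws(as.character(x))
  out <- unname(map[x0])
  out[is.na(x0) | tolower(x0) %in% c("missing", "na", "")] <- NA_character_
  unknown <- !is.na(x0) & is.na(out) &
    !(tolower(x0) %in% c("missing", "na", ""))
  if (any(unknown)) {
    stop("unknown genotype label at locus '", locus, "': ",
         paste(unique(x0[unknown]), collapse = ", "))
  }
  out
}

#' Write a per-bird genotype table
#'
#' Emits normalized genotype states; missing calls are written as `"NA"`.
#'
#' @param birds bird table `data.frame`.
#' @param path output file path.
#' @export
write_genotype_table <- function(birds, path) {
  drop <- intersect(c("hap1", "hap2"), names(birds))
  if (length(drop)) birds <- birds[, setdiff(names(birds), drop)]
  utils::write.table(birds, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
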
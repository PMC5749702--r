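#' Pool design: which DNA pool plays which role
#'
#' A pool design maps pool identifiers to their role in the case-control
#' pooled-sequencing layout: ascites phenotype (resistant or susceptible),
#' sex, and replicate number. The full design used for the scan is 8 pools:
#' 2 phenotypes x 2 sexes x 2 replicate pools, each pool built from equal
#' amounts of DNA from 10 birds. Designs with a single replicate per
#' phenotype-sex combination are accepted; the replicate count per
#' combination is recorded in the `"n_replicates"` attribute.
#'
#' @param pool_id character vector of unique pool identifiers.
#' @param phenotype character vector, `"resistant"` or `"susceptible"`
#'   (synonyms `"R"`/`"S"` accepted).
#' @param sex character vector, `"male"` or `"female"` (synonyms `"M"`/`"F"`).
#' @param replicate integer vector of replicate indices within each
#'   phenotype-sex combination.
#' @return A `data.frame` of class `"pool_design"` with columns `pool_id`,
#'   `phenotype`, `sex`, `replicate`.
#' @examples
#' full_pool_design()
#' @export
pool_design <- function(pool_id, phenotype, sex, replicate) {
  phenotype <- normalize_phenotype(phenotype, allow_inconclusive = FALSE)
  sex <- normalize_sex(sex, allow_unknown = FALSE)
  pool_id <- as.character(pool_id)
  replicate <- as.integer(replicate)
  n <- length(pool_id)
  if (length(phenotype) != n || length(sex) != n || length(replicate) != n) {
    stop("pool_id, phenotype, sex and replicate must have equal length")
  }
  if (anyDuplicated(pool_id)) {
    stop("duplicate pool_id: ", paste(pool_id[duplicated(pool_id)], collapse = ", "))
  }
  d <- data.frame(pool_id = pool_id, phenotype = phenotype, sex = sex,
                  replicate = replicate, stringsAsFactors = FALSE)
  combos <- expand.grid(phenotype = c("resistant", "susceptible"),
                        sex = c("male", "female"), stringsAsFactors = FALSE)
  n_rep <- mapply(function(p, s) sum(d$phenotype == p & d$sex == s),
                  combos$phenotype, combos$sex)
  if (any(n_rep < 1)) {
    miss <- combos[n_rep < 1, , drop = FALSE]
    stop("pool design must contain at least one pool per phenotype-sex ",
         "combination; missing: ",
         paste(paste(miss$phenotype, miss$sex), collapse = ", "))
  }
  attr(d, "n_replicates") <- stats::setNames(
    as.integer(n_rep), paste(combos$phenotype, combos$sex, sep = "."))
  class(d) <- c("pool_design", "data.frame")
  d
}

#' The canonical 8-pool design
#'
#' Two replicate pools for each phenotype-sex combination, named
#' `RM1, RM2, SM1, SM2, RF1, RF2, SF1, SF2` (phenotype initial, sex
#' initial, replicate).
#'
#' @return A [pool_design()] with 8 pools.
#' @export
full_pool_design <- function() {
  grid <- expand.grid(replicate = 1:2,
                      phenotype = c("resistant", "susceptible"),
                      sex = c("male", "female"),
                      stringsAsFactors = FALSE)
  ids <- paste0(toupper(substr(grid$phenotype, 1, 1)),
                toupper(substr(grid$sex, 1, 1)), grid$replicate)
  pool_design(ids, grid$phenotype, grid$sex, grid$replicate)
}

#' @rdname pool_design
#' @param path file path of a tab-separated design table with columns
#'   `pool_id`, `phenotype`, `sex`, `replicate`.
#' @export
read_pool_design <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("pool_id", "phenotype", "sex", "replicate")
  if (!all(need %in% names(d))) {
    stop("design table must have columns: ", paste(need, collapse = ", "))
  }
  pool_design(d$pool_id, d$phenotype, d$sex, d$replicate)
}

#' @rdname pool_design
#' @param design a [pool_design()].
#' @export
write_pool_design <- function(design, path) {
  stopifnot(inherits(design, "pool_design"))
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Pools belonging to one sex stratum, split by phenotype
#'
#' @param design a [pool_design()].
#' @param sex_stratum `"male"` or `"female"`.
#' @return list with character vectors `resistant` and `susceptible`.
#' @export
stratum_pools <- function(design, sex_stratum) {
  sex_stratum <- match.arg(sex_stratum, c("male", "female"))
  sub <- design[design$sex == sex_stratum, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("no pools in design for sex stratum '", sex_stratum, "'")
  }
  list(resistant = sub$pool_id[sub$phenotype == "resistant"],
       susceptible = sub$pool_id[sub$phenotype == "susceptible"])
}

# ---- label normalization helpers (shared across readers) ----

normalize_phenotype <- function(x, allow_inconclusive = TRUE) {
  x0 <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x0))
  out[x0 %in% c("r", "res", "resistant")] <- "resistant"
  out[x0 %in% c("s", "sus", "susceptible")] <- "susceptible"
  out[x0 %in% c("u", "i", "inc", "inconclusive", "unknown", "na", "")] <- "inconclusive"
  bad <- is.na(x0) | is.na(out)
  out[is.na(x0)] <- "inconclusive"
  if (any(is.na(out))) {
    stop("unknown phenotype label: ",
         paste(unique(x0[is.na(out)]), collapse = ", "))
  }
  if (!allow_inconclusive && any(out == "inconclusive")) {
    stop("phenotype must be resistant or susceptible here")
  }
  out
}

normalize_sex <- function(x, allow_unknown = TRUE) {
  x0 <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x0))
  out[x0 %in% c("m", "male")] <- "male"
  out[x0 %in% c("f", "female")] <- "female"
  out[is.na(x0) | x0 %in% c("u", "unknown", "na", "")] <- "unknown"
  if (any(is.na(out))) {
    stop("unknown sex label: ", paste(unique(x0[is.na(out)]), collapse = ", "))
  }
  if (!allow_unknown && any(out == "unknown")) {
    stop("sex must be male or female here")
  }
  out
}
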
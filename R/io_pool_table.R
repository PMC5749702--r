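#' Read a per-pool SNP frequency table
#'
#' The pool-table dialect is tab-separated, one row per SNP, with columns
#' `chrom pos ref alt qscore` followed by `<pool>_depth` and `<pool>_freq`
#' for every pool in the design. `freq` is the non-reference allele
#' frequency in `[0, 1]`; `depth` is the read depth. `"NA"` or an empty
#' cell marks a missing entry, which is distinct from depth 0. Positions are
#' 1-based genomic coordinates.
#'
#' @param path path to the TSV file.
#' @param design a [pool_design()]; every design pool must have both columns
#'   in the header and no extra pool columns may be present.
#' @return A `data.frame` sorted by `(chrom, pos)` with the columns above and
#'   attribute `"pool_ids"`.
#' @export
read_pool_table <- function(path, design) {
  stopifnot(inherits(design, "pool_design"))
  if (!file.exists(path)) stop("pool table not found: ", path)
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         na.strings = c("NA", ""), stringsAsFactors = FALSE,
                         check.names = FALSE)
  base_cols <- c("chrom", "pos", "ref", "alt", "qscore")
  if (!all(base_cols %in% names(x))) {
    stop("pool table must start with columns: ",
         paste(base_cols, collapse = ", "))
  }
  want <- pool_columns(design$pool_id)
  missing_cols <- setdiff(want, names(x))
  if (length(missing_cols)) {
    stop("pool table is missing pool column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(grep("_(depth|freq)$", names(x), value = TRUE), want)
  if (length(extra)) {
    stop("unknown pool column(s) not in design: ",
         paste(extra, collapse = ", "))
  }
  x <- x[, c(base_cols, want)]
  x$chrom <- as.character(x$chrom)
  x$pos <- as.integer(x$pos)
  validate_pool_table(x, design$pool_id)
  x <- x[order(x$chrom, x$pos), , drop = FALSE]
  rownames(x) <- NULL
  attr(x, "pool_ids") <- design$pool_id
  x
}

pool_columns <- function(pool_ids) {
  as.vector(rbind(paste0(pool_ids, "_depth"), paste0(pool_ids, "_freq")))
}

validate_pool_table <- function(x, pool_ids) {
  if (any(x$pos < 1L, na.rm = TRUE)) {
    stop("pos must be >= 1 (line ", which(x$pos < 1L)[1] + 1L, ")")
  }
  same <- !is.na(x$ref) & !is.na(x$alt) & x$ref == x$alt
  if (any(same)) {
    stop("ref and alt alleles identical (line ", which(same)[1] + 1L, ")")
  }
  if (any(x$qscore < 0, na.rm = TRUE)) {
    stop("qscore must be non-negative (line ",
         which(x$qscore < 0)[1] + 1L, ")")
  }
  for (p in pool_ids) {
    f <- x[[paste0(p, "_freq")]]
    bad <- !is.na(f) & (f < 0 | f > 1)
    if (any(bad)) {
      stop("frequency outside [0, 1] in pool '", p, "' (line ",
           which(bad)[1] + 1L, ")")
    }
    d <- x[[paste0(p, "_depth")]]
    badd <- !is.na(d) & d < 0
    if (any(badd)) {
      stop("negative depth in pool '", p, "' (line ",
           which(badd)[1] + 1L, ")")
    }
  }
  invisible(x)
}

#' Write a per-pool SNP frequency table
#'
#' Inverse of [read_pool_table()]; missing entries are written as `"NA"`.
#' Writing then re-reading a table reproduces all fields exactly.
#'
#' @param x pool table `data.frame` (as returned by [read_pool_table()] or
#'   [simulate_pools()]).
#' @param path output file path.
#' @export
write_pool_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
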
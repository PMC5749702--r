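#' Write candidate regions as BED plus a companion TSV report
#'
#' Internal coordinates are 1-based inclusive; the BED file uses the 0-based
#' half-open convention (`start - 1`, `end`). The companion TSV keeps the
#' full region record: span, peak frequency difference (6 decimals), SNP
#' counts at the low and high cutoffs, direction and stratum.
#'
#' @param regions region `data.frame` from [detect_regions()] (may be empty).
#' @param path output path prefix; `<path>.bed` and `<path>.tsv` are written.
#' @return invisibly, the two file paths.
#' @export
write_regions <- function(regions, path) {
  bed_path <- paste0(path, ".bed")
  tsv_path <- paste0(path, ".tsv")
  if (nrow(regions)) {
    name <- sprintf("%s_%s_%s:%d-%d", regions$direction, regions$sex_stratum,
                    regions$chrom, regions$start, regions$end)
    bed <- data.frame(chrom = regions$chrom, start = regions$start - 1L,
                      end = regions$end, name = name)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    file.create(bed_path)
  }
  out <- regions
  out$span_bp <- if (nrow(out)) out$end - out$start + 1L else integer(0)
  out$peak_delta <- if (nrow(out)) sprintf("%.6f", out$peak_delta) else character(0)
  utils::write.table(out, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(bed = bed_path, tsv = tsv_path))
}

#' Read back a region report written by [write_regions()]
#'
#' @param path the path prefix passed to [write_regions()].
#' @return region `data.frame`.
#' @export
read_regions <- function(path) {
  x <- utils::read.table(paste0(path, ".tsv"), header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  x$chrom <- as.character(x$chrom)
  x
}

#' Attach overlapping gene names to candidate regions
#'
#' Genes are read from a GFF3 file (features of type `gene`); a gene is
#' attached to a region when their 1-based inclusive spans intersect.
#' Chromosome names are matched as exact strings, with no alias resolution,
#' to avoid silent mismatches.
#'
#' @param regions region `data.frame` with `chrom`, `start`, `end`.
#' @param gff path to a GFF3 file.
#' @return `regions` with an added `genes` column (comma-separated names,
#'   `""` when no gene overlaps).
#' @export
annotate_regions <- function(regions, gff) {
  for (pkg in c("rtracklayer", "GenomicRanges", "IRanges", "S4Vectors")) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      stop("package '", pkg, "' is required for annotate_regions()")
    }
  }
  g <- tryCatch(rtracklayer::import(gff, format = "gff3"),
                error = function(e) stop("malformed GFF3: ",
                                         conditionMessage(e)))
  g <- g[S4Vectors::mcols(g)$type == "gene"]
  nm <- S4Vectors::mcols(g)$Name
  if (is.null(nm)) nm <- S4Vectors::mcols(g)$ID
  nm[is.na(nm)] <- as.character(S4Vectors::mcols(g)$ID[is.na(nm)])
  regions$genes <- ""
  if (!nrow(regions) || !length(g)) return(regions)
  q <- GenomicRanges::GRanges(regions$chrom,
                              IRanges::IRanges(regions$start, regions$end))
  hits <- GenomicRanges::findOverlaps(q, g)
  if (length(hits)) {
    by_region <- split(nm[S4Vectors::subjectHits(hits)],
                       S4Vectors::queryHits(hits))
    for (i in names(by_region)) {
      regions$genes[as.integer(i)] <-
        paste(sort(unique(by_region[[i]])), collapse = ",")
    }
  }
  regions
}
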
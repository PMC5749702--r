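#' Read a qPCR Ct table
#'
#' Tab-separated with columns `sample_id`, `group` (combined genotype class
#' G1-G6), `tissue` (`lung`/`heart`/`liver`), `gene`, `replicate`, `ct`
#' (cycle-threshold, cycles, > 0). Technical replicates of a reaction are
#' separate rows and are averaged before analysis.
#'
#' @param path path to the TSV file.
#' @return validated `data.frame`.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop("Ct table not found: ", path)
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         na.strings = c("NA", ""), stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "tissue", "gene", "replicate", "ct")
  if (!all(need %in% names(x))) {
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(x$ct <= 0, na.rm = TRUE)) stop("ct values must be positive")
  x
}

#' @rdname read_ct_table
#' @param ct Ct table `data.frame`.
#' @export
write_ct_table <- function(ct, path) {
  utils::write.table(ct, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Average technical replicates per sample, tissue and gene
#'
#' @param ct Ct table (see [read_ct_table()]).
#' @return `data.frame` with one row per sample x tissue x gene and the mean
#'   `ct` over technical replicates.
#' @export
average_replicates <- function(ct) {
  out <- stats::aggregate(ct ~ sample_id + group + tissue + gene, data = ct,
                          FUN = mean)
  out[order(out$sample_id, out$tissue, out$gene), , drop = FALSE]
}

#' Per-sample delta-Ct against the reference gene
#'
#' Technical replicates are averaged first; then for each sample and tissue,
#' `delta_ct = Ct(target) - Ct(reference gene)`. Samples missing either
#' measurement are excluded and listed in the `"excluded"` attribute with a
#' reason.
#'
#' @param ct Ct table.
#' @param reference_gene name of the normalization gene (default `"TBP"`).
#' @return `data.frame` with `sample_id`, `group`, `tissue`, `delta_ct`.
#' @export
compute_delta_ct <- function(ct, reference_gene = "TBP") {
  avg <- average_replicates(ct)
  genes <- unique(avg$gene)
  if (!reference_gene %in% genes) {
    stop("reference gene '", reference_gene, "' not present in Ct table")
  }
  targets <- setdiff(genes, reference_gene)
  if (length(targets) != 1L) {
    stop("expected exactly one target gene, found: ",
         paste(targets, collapse = ", "))
  }
  tg <- avg[avg$gene == targets, c("sample_id", "group", "tissue", "ct")]
  rf <- avg[avg$gene == reference_gene, c("sample_id", "tissue", "ct")]
  names(tg)[names(tg) == "ct"] <- "ct_target"
  names(rf)[names(rf) == "ct"] <- "ct_ref"
  merged <- merge(tg, rf, by = c("sample_id", "tissue"), all = TRUE)
  miss <- is.na(merged$ct_target) | is.na(merged$ct_ref)
  excluded <- merged[miss, c("sample_id", "tissue")]
  if (nrow(excluded)) {
    excluded$reason <- ifelse(is.na(merged$ct_target[miss]),
                              "missing target Ct", "missing reference Ct")
    message(nrow(excluded), " sample/tissue pair(s) excluded for missing Ct")
  }
  out <- merged[!miss, , drop = FALSE]
  out$delta_ct <- out$ct_target - out$ct_ref
  out <- out[order(out$tissue, out$group, out$sample_id),
             c("sample_id", "group", "tissue", "delta_ct")]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Welch's unequal-variance t-test
#'
#' `t = (mean(a) - mean(b)) / sqrt(s2a/na + s2b/nb)` with
#' Welch-Satterthwaite degrees of freedom and a two-tailed p-value.
#' Degenerate inputs are defined explicitly: zero variance in both samples
#' with equal means gives `p = 1`; zero variance with unequal means gives
#' `p = 0` flagged as degenerate.
#'
#' @param a,b numeric vectors with at least 2 values each.
#' @return list with `t`, `df`, `p`, `degenerate`.
#' @export
welch_t_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("each sample needs at least 2 values")
  }
  va <- stats::var(a); vb <- stats::var(b)
  na <- length(a); nb <- length(b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = NA_real_, p = 1, degenerate = TRUE))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = NA_real_, p = 0,
                degenerate = TRUE))
  }
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df = df)
  list(t = tstat, df = df, p = p, degenerate = FALSE)
}

#' Fold changes per combined genotype and tissue (delta-delta-Ct)
#'
#' For each tissue, every sample's `delta_delta_ct` is its `delta_ct` minus
#' the mean `delta_ct` of the reference group in that tissue (so a group
#' standard deviation exists); per group, `fold_change = 2^(-mean ddCt)`
#' under perfect doubling efficiency. The p-value is a two-tailed Welch
#' t-test of the group's `delta_ct` values against the reference group's
#' (equivalent to testing ddCt, which differs only by a common shift).
#' Groups with fewer than 2 samples get a fold change but no p-value.
#' Significance is annotated at both the 0.05 study-wide threshold and the
#' stricter 0.02 threshold used for figure stars.
#'
#' @param dct `data.frame` from [compute_delta_ct()].
#' @param reference_group reference combined genotype (default `"G1"`),
#'   which has `fold_change = 1` by construction; it needs at least 2
#'   samples per tissue.
#' @return `data.frame` with one row per group x tissue: `n`, `mean_ddct`,
#'   `sd_ddct`, `fold_change`, `p_value`, `sig_05`, `sig_02`.
#' @export
ddct_fold_change <- function(dct, reference_group = "G1") {
  rows <- list()
  for (tissue in unique(dct$tissue)) {
    d <- dct[dct$tissue == tissue, , drop = FALSE]
    ref <- d$delta_ct[d$group == reference_group]
    if (length(ref) < 2L) {
      stop("reference group '", reference_group, "' has fewer than 2 ",
           "samples in tissue '", tissue, "'")
    }
    ref_mean <- mean(ref)
    for (grp in unique(d$group)) {
      v <- d$delta_ct[d$group == grp]
      ddct <- v - ref_mean
      p <- if (grp == reference_group) {
        NA_real_
      } else if (length(v) >= 2L) {
        welch_t_test(v, ref)$p
      } else {
        NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group = grp, tissue = tissue, n = length(v),
        mean_ddct = mean(ddct),
        sd_ddct = if (length(v) >= 2L) stats::sd(ddct) else NA_real_,
        fold_change = 2^(-mean(ddct)),
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$sig_05 <- !is.na(out$p_value) & out$p_value < 0.05
  out$sig_02 <- !is.na(out$p_value) & out$p_value < 0.02
  out <- out[order(out$tissue, out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}
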
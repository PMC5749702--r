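#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates the stages — optional simulation, the per-sex allele
#' frequency-difference scan, genotype and combined-genotype association,
#' haplotype frequency estimation with the EM diagnostic, and expression
#' analysis — writing each stage's tables plus a machine-readable
#' `summary.json` that echoes every effective parameter, so outputs are
#' self-describing. Stages never mutate one another's inputs and each is
#' independently invokable on its files through the exported functions or
#' the command-line interface.
#'
#' @param config a configuration list or path to a JSON file. Recognized
#'   sections (all optional unless needed by a requested stage):
#'   \describe{
#'     \item{seed}{integer seed applied once at the start.}
#'     \item{simulate}{`TRUE` or a named list of [sim_params()] overrides;
#'       when present, input files are generated into `out_dir/sim`.}
#'     \item{pools, design, genotypes, ct}{input file paths (ignored for
#'       inputs produced by the simulate stage).}
#'     \item{scan}{list: `strata` (default `c("male", "female")`),
#'       `min_depth`, `require_all_pools`, `min_qscore`, `c_low`, `c_high`,
#'       `max_gap_bp`, `min_snps_low`, `auto_cutoff`.}
#'     \item{assoc}{list: `loci` (default `c("intron6", "exon8",
#'       "combined")`), `n_tests`, `yates`.}
#'     \item{expr}{list: `reference_group` (default `"G1"`),
#'       `reference_gene` (default `"TBP"`).}
#'     \item{gff}{optional GFF3 path for region annotation.}
#'   }
#' @param out_dir output directory.
#' @param seed overrides `config$seed`.
#' @return invisibly, the summary list (also written as JSON).
#' @export
run_pipeline <- function(config = list(), out_dir, seed = NULL) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  if (is.null(seed)) seed <- config$seed
  if (!is.null(seed)) set.seed(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message("[poolscan] ", ...)
  summary <- list(seed = seed, stages = character(0))

  # ---- simulate (optional) ----
  if (!is.null(config$simulate) && !isFALSE(config$simulate)) {
    overrides <- if (is.list(config$simulate)) config$simulate else list()
    params <- do.call(sim_params, overrides)
    sim_dir <- file.path(out_dir, "sim")
    log_msg("simulate: ", params$n_birds, " birds -> ", sim_dir)
    paths <- simulate_dataset(params, sim_dir, seed = NULL)
    config$pools <- paths[["pools"]]
    config$design <- paths[["design"]]
    config$genotypes <- paths[["genotypes"]]
    config$ct <- paths[["ct"]]
    summary$stages <- c(summary$stages, "simulate")
    summary$simulate <- list(
      params = params[setdiff(names(params),
                              c("penetrance", "expression_folds"))],
      files = as.list(paths))
  }

  # ---- scan ----
  if (!is.null(config$pools) && !is.null(config$design)) {
    sc <- config$scan
    strata <- sc$strata %||% c("male", "female")
    fcfg <- filter_config(min_depth = sc$min_depth %||% 9L,
                          require_all_pools = sc$require_all_pools %||% TRUE,
                          min_qscore = sc$min_qscore)
    rcfg <- region_config(c_low = sc$c_low %||% 0.20,
                          c_high = sc$c_high %||% 0.40,
                          max_gap_bp = sc$max_gap_bp %||% 50000L,
                          min_snps_low = sc$min_snps_low %||% 20L,
                          auto_cutoff = sc$auto_cutoff %||% FALSE)
    design <- read_pool_design(config$design)
    pools <- read_pool_table(config$pools, design)
    summary$scan <- list(filter = unclass(fcfg), regions = unclass(rcfg),
                         strata = strata, per_stratum = list())
    for (st in strata) {
      filtered <- filter_snps(pools, design, st, fcfg)
      att <- attr(filtered, "attrition")
      log_msg("scan [", st, "]: ", att[["n_in"]], " SNPs in, ",
              att[["removed_missing"]], " removed by missingness, ",
              att[["removed_depth"]], " by depth, ",
              att[["n_out"]], " kept")
      deltas <- delta_frequency(filtered, design, st,
                                allow_partial = !fcfg$require_all_pools)
      regions <- detect_regions(deltas, rcfg)
      if (!is.null(config$gff) && nrow(regions)) {
        regions <- annotate_regions(regions, config$gff)
      }
      delta_path <- file.path(out_dir, paste0("deltas_", st, ".tsv"))
      utils::write.table(deltas, delta_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      region_prefix <- file.path(out_dir, paste0("regions_", st))
      write_regions(regions, region_prefix)
      summary$scan$per_stratum[[st]] <- list(
        attrition = as.list(att),
        cutoffs = as.list(attr(regions, "cutoffs")),
        n_regions = nrow(regions),
        regions = regions,
        files = list(deltas = delta_path,
                     bed = paste0(region_prefix, ".bed"),
                     tsv = paste0(region_prefix, ".tsv")))
    }
    summary$stages <- c(summary$stages, "scan")
  }

  # ---- assoc + haplotype ----
  if (!is.null(config$genotypes)) {
    birds <- read_genotype_table(config$genotypes)
    loci <- config$assoc$loci %||% c("intron6", "exon8", "combined")
    loci <- intersect(loci, c(names(birds), "combined"))
    assoc_tabs <- list()
    for (locus in loci) {
      tab <- associate(birds, locus,
                       n_tests = config$assoc$n_tests %||% 3L,
                       yates = config$assoc$yates %||% FALSE)
      path <- file.path(out_dir, paste0("assoc_", locus, ".tsv"))
      utils::write.table(tab, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      assoc_tabs[[locus]] <- list(file = path,
                                  n_significant = sum(tab$p_adj < 0.05,
                                                      na.rm = TRUE))
      log_msg("assoc [", locus, "]: ", nrow(tab), " rows")
    }
    summary$assoc <- assoc_tabs
    summary$stages <- c(summary$stages, "assoc")

    if (all(c("intron6", "exon8") %in% names(birds))) {
      haplo <- list()
      for (ln in unique(birds$line)) {
        sub <- birds[birds$line == ln, , drop = FALSE]
        counts <- combined_genotype_counts(sub)
        cf <- count_haplotype_frequencies(counts)
        em <- em_haplotype_frequencies(two_locus_counts(sub$intron6,
                                                        sub$exon8))
        haplo[[ln]] <- list(
          genotype_counts = as.list(counts),
          n_incompatible = attr(counts, "n_incompatible"),
          counting_freq = as.list(cf$freq),
          em_freq = as.list(em$freq),
          em_loglik = em$loglik,
          em_converged = em$converged)
        log_msg("haplo [", ln, "]: f(TAC) EM = ",
                signif(em$freq[["TAC"]], 3))
      }
      haplo_path <- file.path(out_dir, "haplotypes.json")
      jsonlite::write_json(haplo, haplo_path, auto_unbox = TRUE, digits = NA)
      summary$haplotype <- haplo
      summary$stages <- c(summary$stages, "haplo")
    }
  }

  # ---- expression ----
  if (!is.null(config$ct)) {
    ct <- read_ct_table(config$ct)
    dct <- compute_delta_ct(ct,
                            reference_gene = config$expr$reference_gene %||%
                              "TBP")
    fc <- ddct_fold_change(dct,
                           reference_group = config$expr$reference_group %||%
                             "G1")
    path <- file.path(out_dir, "fold_changes.tsv")
    utils::write.table(fc, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    summary$expression <- list(file = path, fold_changes = fc)
    summary$stages <- c(summary$stages, "expr")
    log_msg("expr: ", nrow(fc), " group x tissue rows")
  }

  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  log_msg("summary written to ", summary_path)
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
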
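#' Pipeline configuration
#'
#' Bundles everything one end-to-end run needs: the simulation
#' configuration (or paths to existing tables), QC thresholds, model and
#' mixture tolerances, the FDR target and the output directory. A single
#' `seed` fans out to fixed per-stage offsets so each stage is
#' independently reproducible.
#'
#' @param sim A [sim_config()]; used when no input tables are given.
#' @param out_dir Output directory for stage tables (created if needed);
#'   `NULL` keeps everything in memory.
#' @param snr_threshold,r_threshold QC thresholds (defaults 1 and 0.85).
#' @param fdr_target Target FDR for DE calling, in (0, 0.5). Default 0.01.
#' @param reml_tol,reml_max_iter REML convergence settings.
#' @param em_n_starts Mixture EM restarts.
#' @param seed Master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), out_dir = NULL,
                            snr_threshold = 1, r_threshold = 0.85,
                            fdr_target = 0.01, reml_tol = 1e-6,
                            reml_max_iter = 200L, em_n_starts = 5L,
                            seed = 1L) {
  if (fdr_target <= 0 || fdr_target >= 0.5)
    stop("fdr_target must lie in (0, 0.5)")
  structure(list(sim = sim, out_dir = out_dir,
                 snr_threshold = snr_threshold, r_threshold = r_threshold,
                 fdr_target = fdr_target, reml_tol = reml_tol,
                 reml_max_iter = as.integer(reml_max_iter),
                 em_n_starts = as.integer(em_n_starts),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

write_stage <- function(df, out_dir, name, manifest, stage, seed) {
  if (is.null(out_dir)) return(manifest)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  path <- file.path(out_dir, paste0(name, ".tsv"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  rbind(manifest,
        data.frame(file = path, stage = stage, seed = seed,
                   checksum = unname(tools::md5sum(path)),
                   stringsAsFactors = FALSE))
}

#' Run the full simulate - QC - fit - DE - report pipeline
#'
#' Simulates a dye-swap experiment under the configuration, applies the
#' spot filters, fits the normalization mixed model, calls DE genes per
#' contrast through the mixture route, and returns all stage results plus
#' per-stage counts. When `out_dir` is set, each stage table is written as
#' tab-separated text and listed in a manifest with its checksum. In
#' written QC tables, spots that failed the filters carry a literal zero
#' reading (they are treated as missing inside the model).
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage messages.
#' @return A list of class `pipeline_result`: `design`, `truth`, `qc`
#'   (in-memory QC table), `fit`, `de` (per-gene per-contrast results),
#'   `summary` (per-stage counts), `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- data.frame(file = character(0), stage = character(0),
                         seed = integer(0), checksum = character(0),
                         stringsAsFactors = FALSE)
  sim <- config$sim
  sim$seed <- config$seed

  design <- simulate_design(sim)
  manifest <- write_stage(design, config$out_dir, "design", manifest,
                          "simulate", config$seed)
  sim_out <- simulate_spots(design, sim, seed = config$seed + 1L)
  say("simulate: %d spots over %d channels", nrow(sim_out$spots),
      nrow(design))
  manifest <- write_stage(sim_out$truth, config$out_dir, "truth", manifest,
                          "simulate", config$seed + 1L)

  qc <- apply_qc(sim_out$spots, config$snr_threshold, config$r_threshold)
  counts <- attr(qc, "qc_counts")
  say("qc: %d passed, %d failed", counts["passed"], counts["failed"])
  if (!is.null(config$out_dir)) {
    qc_out <- qc
    qc_out$log2_intensity[!qc_out$passed] <- 0  # written-table convention
    manifest <- write_stage(qc_out, config$out_dir, "qc", manifest, "qc",
                            config$seed)
  }

  fit <- dyeswap_mm(qc, design, tol = config$reml_tol,
                    max_iter = config$reml_max_iter)
  say("fit: %d genes, REML %s in %d iterations", length(fit$spec$genes),
      if (fit$converged) "converged" else "did not converge",
      fit$iterations)
  manifest <- write_stage(
    data.frame(gene_id = rownames(fit$hg), fit$hg, check.names = FALSE),
    config$out_dir, "normalized_expression", manifest, "fit", config$seed)

  de <- de_analysis(fit, fdr_target = config$fdr_target,
                    n_starts = config$em_n_starts,
                    seed = config$seed + 2L)
  n_de <- vapply(split(de$de_flag, de$contrast), sum, 1L)
  say("de: %s", paste(names(n_de), n_de, sep = "=", collapse = " "))
  manifest <- write_stage(de, config$out_dir, "de_results", manifest, "de",
                          config$seed + 2L)

  res <- list(design = design, truth = sim_out$truth, qc = qc, fit = fit,
              de = de,
              summary = list(qc = counts, n_genes = length(fit$spec$genes),
                             de_per_contrast = n_de,
                             variances = fit$variances),
              manifest = manifest, config = config)
  class(res) <- "pipeline_result"
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Dye-swap pipeline run\n")
  cat(sprintf("  spots: %d passed / %d failed QC\n",
              x$summary$qc["passed"], x$summary$qc["failed"]))
  cat(sprintf("  genes fitted: %d\n", x$summary$n_genes))
  cat("  DE per contrast:",
      paste(names(x$summary$de_per_contrast), x$summary$de_per_contrast,
            sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Per-contrast and intersection counts of DE genes
#'
#' The counts behind a three-set Venn diagram: per-contrast totals, each
#' pairwise intersection, and the triple intersection.
#'
#' @param results DE results table (`gene_id`, `contrast`, `de_flag`).
#' @return Named integer vector.
#' @export
report_venn <- function(results) {
  s <- summarise_de(results)
  c(s$per_contrast, s$overlap, total = s$total_genes)
}

#' Chromosome distribution of DE genes per contrast
#'
#' Tallies DE calls by chromosome for each contrast. The X chromosome is
#' reported as category "30" (the convention that numbers it after the 29
#' bovine autosomes); genes without an assignment land in "unplaced".
#'
#' @param results DE results table.
#' @param chrom_map Named vector or (`gene_id`, `chrom`) data.frame.
#' @return Data frame with `contrast`, `chrom`, `n`.
#' @export
report_chromosome_distribution <- function(results, chrom_map) {
  if (is.data.frame(chrom_map))
    chrom_map <- stats::setNames(as.character(chrom_map$chrom),
                                 chrom_map$gene_id)
  chrom_map[chrom_map %in% c("X", "chrX")] <- "30"
  rows <- lapply(CONTRASTS, function(cn) {
    g <- unique(results$gene_id[results$contrast == cn & results$de_flag])
    if (!length(g)) return(NULL)
    ch <- chrom_map[g]
    ch[is.na(ch)] <- "unplaced"
    tab <- table(ch)
    data.frame(contrast = cn, chrom = names(tab), n = as.integer(tab),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(contrast = character(0), chrom = character(0),
                      n = integer(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
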
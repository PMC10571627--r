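#' Run the full analysis pipeline from files to files
#'
#' Reads counts, survival (or condition) metadata and a GMT collection,
#' fits [sgsea()], and writes to the output directory: the per-gene
#' statistics (`gene_stats.tsv`), the enrichment table (`enrichment.tsv`),
#' the top positive/negative significant pathways (`top_positive.tsv`,
#' `top_negative.tsv`) and a JSON run manifest recording the package
#' version, seed, parameters and input checksums. Two runs with the same
#' manifest produce byte-identical outputs.
#'
#' @param counts_path,gmt_path Input files.
#' @param survival_path Survival table (survival mode).
#' @param conditions_path Condition labels (foldchange mode).
#' @param out_dir Output directory, created if needed.
#' @param mode `"survival"` or `"foldchange"`.
#' @param orientation Count file layout, see [read_counts()].
#' @param time_col,status_col,condition_col,reference Metadata column
#'   options.
#' @param top_k Rows per top table.
#' @param quiet Suppress progress messages.
#' @param ... Further arguments to [sgsea()] (`min_mean_reads`, `ties`,
#'   `rank_stat`, `min_size`, `max_size`, `n_perm`, `exponent`, `alpha`,
#'   `seed`).
#' @return The `sgsea` fit, invisibly; side effect: files in `out_dir`.
#' @export
run_pipeline <- function(counts_path, gmt_path, survival_path = NULL,
                         conditions_path = NULL, out_dir = ".",
                         mode = c("survival", "foldchange"),
                         orientation = "genes_by_samples",
                         time_col = "time", status_col = "status",
                         condition_col = "condition", reference = NULL,
                         top_k = 10L, quiet = FALSE, ...) {
  mode <- match.arg(mode)
  say <- function(...) if (!quiet) message("[", mode, "] ", ...)
  if (mode == "survival" && is.null(survival_path))
    stop("survival mode requires --survival", call. = FALSE)
  if (mode == "foldchange" && is.null(conditions_path))
    stop("foldchange mode requires --conditions", call. = FALSE)
  say("reading inputs")
  counts <- read_counts(counts_path, orientation = orientation)
  sets <- read_gmt(gmt_path)
  survival <- conditions <- NULL
  if (mode == "survival") {
    survival <- read_survival(survival_path, time_col = time_col,
                              status_col = status_col)
  } else {
    conditions <- read_conditions(conditions_path,
                                  condition_col = condition_col,
                                  reference = reference)
  }
  say("fitting (", nrow(counts), " genes, ", ncol(counts), " samples)")
  fit <- sgsea(counts, sets, survival = survival, conditions = conditions,
               mode = mode, ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say("writing results to ", out_dir)
  utils::write.table(fit$gene_stats, file.path(out_dir, "gene_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_results(fit$results, file.path(out_dir, "enrichment.tsv"))
  tops <- top_tables(fit, k = top_k, alpha = fit$params$alpha)
  utils::write.table(tops$positive, file.path(out_dir, "top_positive.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tops$negative, file.path(out_dir, "top_negative.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  inputs <- c(counts = counts_path, gmt = gmt_path,
              survival = survival_path, conditions = conditions_path)
  manifest <- list(
    package = "survenrich",
    version = as.character(utils::packageVersion("survenrich")),
    mode = mode,
    statistic = attr(fit$ranking, "statistic"),
    params = fit$params,
    inputs = as.list(inputs),
    input_md5 = as.list(tools::md5sum(unlist(inputs))),
    n_samples = fit$n_samples,
    n_genes_ranked = length(fit$ranking),
    n_genes_filtered = fit$n_filtered,
    n_pathways_tested = nrow(fit$results))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(fit)
}

#' Write a simulated dataset to disk
#'
#' Emits `counts.tsv`, `survival.tsv` or `conditions.tsv`, `sets.gmt` and
#' `truth.tsv` (the planted effects) for documentation walkthroughs and
#' golden-file tests.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory.
#' @param mode `"survival"` or `"foldchange"`.
#' @return Paths of the written files, invisibly.
#' @export
write_simulated_dataset <- function(cfg, out_dir,
                                    mode = c("survival", "foldchange")) {
  mode <- match.arg(mode)
  sim <- simulate_dataset(cfg, mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(out_dir, "counts.tsv"),
             sets = file.path(out_dir, "sets.gmt"),
             truth = file.path(out_dir, "truth.tsv"))
  write_counts(sim$counts, paths[["counts"]])
  write_gmt(sim$sets, paths[["sets"]])
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (mode == "survival") {
    paths[["survival"]] <- file.path(out_dir, "survival.tsv")
    write_survival(sim$survival, paths[["survival"]])
  } else {
    paths[["conditions"]] <- file.path(out_dir, "conditions.tsv")
    cond_df <- data.frame(sample = sim$conditions$sample,
                          condition = as.character(sim$conditions$group),
                          stringsAsFactors = FALSE)
    utils::write.table(cond_df, paths[["conditions"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
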
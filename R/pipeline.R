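#' Run the full pipeline: simulate, count, quantify, test, report
#'
#' Chains every stage over a simulated experiment: writes the FASTQ tree,
#' extracts and counts barcodes, computes the Expression-Index table, runs
#' the grouped nonparametric comparisons, and writes all report surfaces
#' (\code{counts.tsv}, \code{extraction_stats.tsv}, \code{ei.tsv},
#' \code{stats.tsv}, \code{ranks.tsv}, \code{heatmap.tsv},
#' \code{bubble.tsv}, \code{boxplot_data.tsv}, \code{run_summary.json})
#' under \code{outdir}. Byte-reproducible from the seed.
#'
#' @param outdir output directory.
#' @param kit a [kit_design()].
#' @param truth a [ground_truth()]; its seed is the run seed.
#' @param layout experiment layout data frame.
#' @param spec an [anchor_spec()]; default derived from the template.
#' @param pseudocount,mode passed to [ei_fit()].
#' @return invisibly, a list with the \code{ei_fit} object and all written
#'   paths.
#' @export
run_pipeline <- function(outdir, kit = default_kit(),
                         truth = ground_truth(), layout = default_layout(),
                         spec = NULL, pseudocount = 0.5,
                         mode = "barcode_mean") {
  sim <- simulate_experiment(kit, truth, layout, outdir)
  if (is.null(spec))
    spec <- anchor_spec(sim$template$left_anchor,
                        barcode_length = barcode_length(kit))
  cx <- count_experiment(sim$samples, kit, spec)
  write_counts(cx$counts, file.path(outdir, "counts.tsv"))
  utils::write.table(cx$stats, file.path(outdir, "extraction_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  fit <- ei_fit(cx$counts, sim$samples, kit, pseudocount = pseudocount,
                mode = mode)
  write_ei(fit$ei, file.path(outdir, "ei.tsv"))
  write_stats(c(fit$comparisons$class, fit$comparisons$within_csp),
              file.path(outdir, "stats.tsv"))

  ranks <- do.call(rbind, lapply(seq_len(nrow(fit$scopes)), function(i)
    cbind(model = fit$scopes$model[i], capsid = fit$scopes$capsid[i],
          fit$ranks[[i]])))
  utils::write.table(ranks, file.path(outdir, "ranks.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  hm <- heatmap_matrix(fit$ei, fit$scopes, kit = kit, value = "ei")
  utils::write.table(
    data.frame(promoter = rownames(hm), hm, check.names = FALSE),
    file.path(outdir, "heatmap.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(bubble_summary(fit$ei), file.path(outdir, "bubble.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(boxplot_data(fit$ei),
                     file.path(outdir, "boxplot_data.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  run_summary(outdir, cx$stats, fit$ei,
              c(fit$comparisons$class, fit$comparisons$within_csp),
              seed = truth$seed)
  invisible(list(fit = fit, sim = sim, counts = cx$counts,
                 stats = cx$stats, outdir = outdir))
}
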
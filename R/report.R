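#' Rank promoters within one scope
#'
#' Promoters are ordered by decreasing mean EI proportion over replicates
#' (\code{ei_mean}); exact ties share the minimum rank and are listed
#' alphabetically.
#'
#' @param ei an \code{ei_table}.
#' @param model model label of the scope.
#' @param capsid capsid label of the scope.
#' @return data frame \code{promoter}, \code{ei_mean}, \code{n},
#'   \code{rank}, in rank order.
#' @export
rank_promoters <- function(ei, model, capsid) {
  sub <- ei[ei$model == model & ei$capsid == capsid, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop(sprintf("no EI rows for scope %s/%s", model, capsid))
  mu <- tapply(sub$ei_proportion, sub$promoter, mean)
  n <- tapply(sub$replicate, sub$promoter, function(x) length(unique(x)))
  ord <- order(-mu, names(mu))
  mu <- mu[ord]; n <- n[ord]
  rk <- rank(-mu, ties.method = "min")
  data.frame(promoter = names(mu), ei_mean = unname(mu),
             n = as.integer(unname(n)), rank = as.integer(rk),
             stringsAsFactors = FALSE)
}

#' Promoter-by-scope heat-map matrix
#'
#' One column per requested (model, capsid) scope, rows in kit promoter
#' order; cells are the replicate mean of raw EI or of EI proportion. For
#' single-subject scopes the cell is that replicate's value directly.
#'
#' @param ei an \code{ei_table}.
#' @param scopes data frame with columns \code{model}, \code{capsid}.
#' @param kit a [kit_design()] fixing promoter row order (default: order of
#'   appearance in \code{ei}).
#' @param value \code{"ei"} or \code{"ei_proportion"}.
#' @return numeric matrix, promoters x scopes, columns named
#'   \code{model.capsid}; the value choice is stored in
#'   \code{attr(, "value")}.
#' @export
heatmap_matrix <- function(ei, scopes, kit = NULL,
                           value = c("ei", "ei_proportion")) {
  value <- match.arg(value)
  promoters <- if (!is.null(kit)) kit_constructs(kit)$promoter
               else unique(ei$promoter)
  cols <- lapply(seq_len(nrow(scopes)), function(i) {
    sub <- ei[ei$model == scopes$model[i] & ei$capsid == scopes$capsid[i], ]
    if (nrow(sub) == 0L)
      stop(sprintf("scope %s/%s not present in EI table", scopes$model[i],
                   scopes$capsid[i]))
    mu <- tapply(sub[[value]], sub$promoter, mean)
    unname(mu[promoters])
  })
  m <- do.call(cbind, cols)
  rownames(m) <- promoters
  colnames(m) <- paste(scopes$model, scopes$capsid, sep = ".")
  attr(m, "value") <- value
  m
}

#' Cross-model bubble summary (mean expression intensity)
#'
#' One cell per promoter x model: the mean over replicates of
#' \code{ei_proportion} (EI proportions rather than raw EI, so cells are
#' comparable across models), with the replicate count. Capsid batches are
#' averaged together by default or kept as separate cells.
#'
#' @param ei an \code{ei_table}.
#' @param by_capsid keep capsids as separate cells instead of averaging.
#' @return data frame \code{promoter}, \code{model} (and \code{capsid} if
#'   kept), \code{ei_mean}, \code{n}.
#' @export
bubble_summary <- function(ei, by_capsid = FALSE) {
  keys <- if (by_capsid) list(promoter = ei$promoter, model = ei$model,
                              capsid = ei$capsid)
          else list(promoter = ei$promoter, model = ei$model)
  agg <- stats::aggregate(ei$ei_proportion, by = keys, FUN = mean)
  cnt <- stats::aggregate(ei$replicate, by = keys,
                          FUN = function(x) length(unique(x)))
  names(agg)[ncol(agg)] <- "ei_mean"
  agg$n <- as.integer(cnt$x)
  ord <- if (by_capsid) order(agg$model, agg$capsid, -agg$ei_mean)
         else order(agg$model, -agg$ei_mean)
  out <- agg[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Machine-readable run summary
#'
#' Writes a JSON summary of a completed pipeline run: package version, seed,
#' input digests, per-sample extraction tallies (flagging samples with zero
#' assigned reads), tested scopes and headline rankings. Identical inputs
#' give an identical summary file.
#'
#' @param outdir directory the pipeline wrote to.
#' @param stats extraction stats data frame from [count_experiment()].
#' @param ei the \code{ei_table}.
#' @param comparisons list from [run_group_comparisons()].
#' @param seed the run seed.
#' @param path output path (default \code{outdir/run_summary.json}).
#' @return the summary list, invisibly.
#' @export
run_summary <- function(outdir, stats, ei, comparisons, seed,
                        path = file.path(outdir, "run_summary.json")) {
  scopes <- unique(ei[, c("model", "capsid")])
  headline <- lapply(seq_len(nrow(scopes)), function(i) {
    rk <- rank_promoters(ei, scopes$model[i], scopes$capsid[i])
    list(model = scopes$model[i], capsid = scopes$capsid[i],
         top_promoter = rk$promoter[1L], top_ei_mean = rk$ei_mean[1L])
  })
  inputs <- c("kit.tsv", "samples.tsv", "counts.tsv", "ei.tsv")
  present <- file.path(outdir, inputs)[file.exists(file.path(outdir, inputs))]
  digest <- if (length(present))
    as.list(stats::setNames(tools::md5sum(present), basename(present)))
  else list()
  flagged <- stats$sample_id[stats$assigned_reads == 0L]
  summary <- list(
    package = "promEI",
    version = as.character(utils::packageVersion("promEI")),
    seed = seed,
    input_md5 = digest,
    stages = list(simulate = "ok", count = if (length(flagged)) "flagged"
                  else "ok", quantify = "ok", stats = "ok", report = "ok"),
    samples_flagged_zero_assigned = as.list(flagged),
    extraction = stats,
    n_scopes_tested = length(comparisons),
    headline_rankings = headline)
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  invisible(summary)
}

#' Boxplot-ready long table
#'
#' The replicate-level values behind the class-level and within-CSP
#' boxplots: one row per scope x promoter x replicate with the class label
#' used in grouped comparisons.
#'
#' @param ei an \code{ei_table}.
#' @return data frame \code{model}, \code{capsid}, \code{replicate},
#'   \code{promoter}, \code{group}, \code{class}, \code{ei},
#'   \code{ei_proportion}.
#' @export
boxplot_data <- function(ei) {
  cls <- c(ubiquitous = "CMV", cardiac_specific = "CSP",
           liver_specific = "LSP")
  out <- as.data.frame(ei)
  out$class <- unname(cls[out$group])
  out[, c("model", "capsid", "replicate", "promoter", "group", "class",
          "ei", "ei_proportion")]
}
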
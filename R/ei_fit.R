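#' Fit the Expression-Index model to a barcode-seq experiment
#'
#' The central fitting function: from a barcode x sample count matrix and
#' the experiment layout it estimates relative promoter activity per
#' (model, capsid, replicate) as the Expression Index (premix-normalised
#' cDNA share over premix-normalised gDNA share), and runs the grouped
#' nonparametric inference (Kruskal-Wallis + Dunn/Bonferroni) at both the
#' promoter-class level (CMV vs pooled CSP vs LSP) and within the
#' cardiac-specific subset.
#'
#' @param counts barcode x sample integer matrix (e.g. from
#'   [count_experiment()]).
#' @param sheet a \code{sample_sheet} describing the libraries.
#' @param kit the [kit_design()].
#' @param pseudocount pseudocount added to every library (default 0.5).
#' @param mode promoter aggregation, \code{"barcode_mean"} or
#'   \code{"count_pooled"}.
#' @param alpha significance level for flags (default 0.05).
#' @return an object of class \code{ei_fit} with components \code{ei} (the
#'   \code{ei_table}), \code{comparisons} (per-level lists of test
#'   results), \code{ranks} (per-scope ranking tables), \code{kit},
#'   \code{sheet} and \code{call}.
#' @seealso [ei_table()], [run_group_comparisons()], [rank_promoters()]
#' @export
ei_fit <- function(counts, sheet, kit, pseudocount = 0.5,
                   mode = c("barcode_mean", "count_pooled"), alpha = 0.05) {
  mode <- match.arg(mode)
  ei <- ei_table(counts, sheet, kit, pseudocount = pseudocount, mode = mode)
  comparisons <- list(
    class = run_group_comparisons(ei, "class", alpha = alpha, quiet = TRUE),
    within_csp = run_group_comparisons(ei, "within_csp", alpha = alpha,
                                       quiet = TRUE))
  scopes <- unique(ei[, c("model", "capsid")])
  ranks <- lapply(seq_len(nrow(scopes)), function(i)
    rank_promoters(ei, scopes$model[i], scopes$capsid[i]))
  names(ranks) <- paste(scopes$model, scopes$capsid, sep = ".")
  structure(list(ei = ei, comparisons = comparisons, ranks = ranks,
                 scopes = scopes, kit = kit, sheet = sheet,
                 pseudocount = pseudocount, mode = mode, alpha = alpha,
                 call = match.call()),
            class = "ei_fit")
}

#' @export
print.ei_fit <- function(x, ...) {
  cat("Expression-Index fit\n")
  cat(sprintf("  %d promoters, %d barcodes, %d scopes (model x capsid), %d EI values\n",
              length(unique(x$ei$promoter)), nrow(x$kit), nrow(x$scopes),
              nrow(x$ei)))
  cat(sprintf("  aggregation: %s; pseudocount: %g\n", x$mode, x$pseudocount))
  top <- vapply(x$ranks, function(r) r$promoter[1L], character(1L))
  cat("  top promoter per scope:\n")
  for (nm in names(top)) cat(sprintf("    %-24s %s\n", nm, top[[nm]]))
  invisible(x)
}

#' @export
summary.ei_fit <- function(object, ...) {
  structure(list(fit = object,
                 stats = stats_table(c(object$comparisons$class,
                                       object$comparisons$within_csp)),
                 bubble = bubble_summary(object$ei)),
            class = "summary.ei_fit")
}

#' @export
print.summary.ei_fit <- function(x, ...) {
  print(x$fit)
  omni <- x$stats[x$stats$row_type == "omnibus", ]
  cat("\nOmnibus Kruskal-Wallis tests:\n")
  for (i in seq_len(nrow(omni)))
    cat(sprintf("  %s/%s [%s]: H = %.3f, df = %d, p = %.4g%s\n",
                omni$model[i], omni$capsid[i], omni$level[i],
                omni$statistic[i], omni$df[i], omni$p[i],
                if (isTRUE(omni$significant[i])) " *" else ""))
  sig <- x$stats[x$stats$row_type == "pairwise" & x$stats$significant, ]
  cat(sprintf("\n%d significant pairwise comparisons (Dunn, Bonferroni-adjusted p < %g)\n",
              nrow(sig), x$fit$alpha))
  invisible(x)
}

#' Mean EI proportion per promoter and model
#'
#' @param object an \code{ei_fit}.
#' @param ... unused.
#' @return promoter x model matrix of \code{ei_mean} (capsids averaged),
#'   rows in kit construct order.
#' @export
coef.ei_fit <- function(object, ...) {
  bb <- bubble_summary(object$ei)
  promoters <- kit_constructs(object$kit)$promoter
  models <- unique(object$ei$model)
  m <- matrix(NA_real_, length(promoters), length(models),
              dimnames = list(promoters, models))
  for (i in seq_len(nrow(bb)))
    m[bb$promoter[i], bb$model[i]] <- bb$ei_mean[i]
  m
}

#' Boxplot of EI proportions for one scope
#'
#' Replicate-level EI proportions, either by promoter class or by
#' individual cardiac-specific promoter, mirroring the screen's primary
#' result display.
#'
#' @param x an \code{ei_fit}.
#' @param model,capsid scope to plot (default: first scope).
#' @param level \code{"class"} or \code{"within_csp"}.
#' @param ... passed to [graphics::boxplot()].
#' @return invisibly, the plotted data.
#' @export
plot.ei_fit <- function(x, model = x$scopes$model[1L],
                        capsid = x$scopes$capsid[1L],
                        level = c("class", "within_csp"), ...) {
  level <- match.arg(level)
  sub <- x$ei[x$ei$model == model & x$ei$capsid == capsid, ]
  if (nrow(sub) == 0L) stop(sprintf("scope %s/%s not in fit", model, capsid))
  if (level == "class") {
    cls <- c(ubiquitous = "CMV", cardiac_specific = "CSP",
             liver_specific = "LSP")
    fac <- factor(cls[sub$group], levels = c("CMV", "CSP", "LSP"))
  } else {
    sub <- sub[sub$group == "cardiac_specific", ]
    fac <- factor(sub$promoter)
  }
  graphics::boxplot(sub$ei_proportion ~ fac,
                    xlab = if (level == "class") "promoter class"
                           else "cardiac-specific promoter",
                    ylab = "EI proportion",
                    main = sprintf("%s / %s", model, capsid), ...)
  invisible(sub)
}
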
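# pooled midranks and tie summary shared by the omnibus and post-hoc tests
pooled_ranks <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1L)) == 0L))
    stop("empty group")
  x <- unlist(groups, use.names = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations in total")
  rk <- rank(x)  # midranks
  sizes <- vapply(groups, length, integer(1L))
  idx <- rep(seq_along(groups), sizes)
  ties <- table(x)
  list(ranks = rk, group = idx, sizes = sizes, N = length(x),
       tie_term = sum(ties^3 - ties))
}

#' Kruskal-Wallis omnibus test (tie-corrected)
#'
#' Rank-based k-sample test on pooled midranks:
#' \eqn{H = [12/(N(N+1))] \sum_i R_i^2/n_i - 3(N+1)}, divided by the tie
#' correction \eqn{1 - \sum(t^3 - t)/(N^3 - N)}; p from the
#' \eqn{\chi^2_{k-1}} upper tail.
#'
#' @param groups list of numeric vectors, one per group (each nonempty,
#'   total N >= 3).
#' @return list with \code{H}, \code{df}, \code{p}.
#' @export
kruskal_wallis <- function(groups) {
  pr <- pooled_ranks(groups)
  Rsum <- tapply(pr$ranks, pr$group, sum)
  N <- pr$N
  H <- 12 / (N * (N + 1)) * sum(Rsum^2 / pr$sizes) - 3 * (N + 1)
  tie_corr <- 1 - pr$tie_term / (N^3 - N)
  if (tie_corr <= 0)
    stop("all pooled values are tied; test statistic undefined")
  H <- H / tie_corr
  df <- length(groups) - 1L
  list(H = H, df = df, p = stats::pchisq(H, df, lower.tail = FALSE))
}

#' Dunn's post-hoc pairwise comparisons
#'
#' For every pair of groups, the standardised difference in mean pooled
#' midranks,
#' \eqn{z = (\bar r_i - \bar r_j) / \sqrt{[N(N+1)/12 -
#' \sum(t^3-t)/(12(N-1))] (1/n_i + 1/n_j)}}, with two-sided
#' \eqn{p = 2\Phi(-|z|)} and Bonferroni adjustment
#' \eqn{p_{adj} = \min(1, p \cdot k(k-1)/2)}.
#'
#' @param groups list of numeric vectors, one per group.
#' @param correction multiplicity correction; only \code{"bonferroni"}.
#' @return data frame with one row per pair: \code{group_a}, \code{group_b},
#'   \code{z}, \code{p}, \code{p_adj}.
#' @export
dunn_posthoc <- function(groups, correction = "bonferroni") {
  correction <- match.arg(correction, "bonferroni")
  pr <- pooled_ranks(groups)
  k <- length(groups)
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_len(k))
  rbar <- tapply(pr$ranks, pr$group, mean)
  N <- pr$N
  var_base <- N * (N + 1) / 12 - pr$tie_term / (12 * (N - 1))
  m <- k * (k - 1L) / 2L
  pairs <- utils::combn(k, 2L)
  res <- lapply(seq_len(ncol(pairs)), function(c_) {
    i <- pairs[1L, c_]; j <- pairs[2L, c_]
    se <- sqrt(var_base * (1 / pr$sizes[i] + 1 / pr$sizes[j]))
    z <- (rbar[i] - rbar[j]) / se
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(group_a = names(groups)[i], group_b = names(groups)[j],
               z = unname(z), p = unname(p),
               p_adj = min(1, unname(p) * m), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Shapiro-Wilk normality annotation
#'
#' Thin wrapper over the standard Shapiro-Wilk routine; the pipeline always
#' proceeds nonparametrically, so this only annotates reports.
#'
#' @param values numeric vector, 3 <= n <= 5000, non-constant.
#' @return list with \code{W} and \code{p}.
#' @export
shapiro_wilk <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3L || length(values) > 5000L)
    stop("Shapiro-Wilk needs 3 <= n <= 5000")
  if (stats::var(values) == 0) stop("zero variance: constant vector")
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Grouped nonparametric comparisons over an EI table
#'
#' Per (model, capsid) scope, replicate-level \code{ei_proportion} values
#' are compared either between promoter classes (\code{level = "class"}:
#' all cardiac-specific promoters pooled into one CSP group vs CMV vs LSP)
#' or between the individual cardiac-specific promoters
#' (\code{level = "within_csp"}). Each scope gets a Kruskal-Wallis omnibus
#' test plus Dunn's Bonferroni-adjusted pairwise comparisons, and a
#' Shapiro-Wilk annotation on the pooled values. Scopes with fewer than 2
#' replicates (single large-animal subjects) are skipped with a notice and
#' reported descriptively only.
#'
#' @param ei an \code{ei_table}.
#' @param level \code{"class"} or \code{"within_csp"}.
#' @param alpha significance level for the \code{significant} flag.
#' @param quiet suppress skip notices.
#' @return list of per-scope results, each with \code{model}, \code{capsid},
#'   \code{level}, \code{method}, \code{statistic}, \code{df}, \code{p},
#'   \code{shapiro_p}, \code{pairwise} (data frame with
#'   \code{significant} flag); skipped scopes are omitted.
#' @export
run_group_comparisons <- function(ei, level = c("class", "within_csp"),
                                  alpha = 0.05, quiet = FALSE) {
  level <- match.arg(level)
  scopes <- unique(ei[, c("model", "capsid")])
  out <- list()
  for (i in seq_len(nrow(scopes))) {
    sub <- ei[ei$model == scopes$model[i] & ei$capsid == scopes$capsid[i], ]
    n_rep <- length(unique(sub$replicate))
    if (n_rep < 2L) {
      if (!quiet)
        message(sprintf(
          "skipping %s/%s: %d replicate(s); reported descriptively only",
          scopes$model[i], scopes$capsid[i], n_rep))
      next
    }
    if (level == "class") {
      grp_of <- c(ubiquitous = "CMV", cardiac_specific = "CSP",
                  liver_specific = "LSP")
      lab <- grp_of[sub$group]
    } else {
      sub <- sub[sub$group == "cardiac_specific", , drop = FALSE]
      lab <- sub$promoter
    }
    groups <- split(sub$ei_proportion, lab)
    if (length(groups) < 2L) next
    kw <- kruskal_wallis(groups)
    pw <- dunn_posthoc(groups)
    pw$significant <- pw$p_adj < alpha
    sw <- tryCatch(shapiro_wilk(sub$ei_proportion)$p,
                   error = function(e) NA_real_)
    out[[length(out) + 1L]] <-
      list(model = scopes$model[i], capsid = scopes$capsid[i], level = level,
           method = "kruskal_wallis", statistic = kw$H, df = kw$df, p = kw$p,
           shapiro_p = sw, pairwise = pw)
  }
  out
}

#' Flatten comparison results to a TSV-ready table
#'
#' One \code{omnibus} row per scope followed by its pairwise rows.
#'
#' @param results list from [run_group_comparisons()] (one level or the
#'   concatenation of both).
#' @return data frame with columns \code{model}, \code{capsid},
#'   \code{level}, \code{row_type}, \code{method}, \code{statistic},
#'   \code{df}, \code{p}, \code{group_a}, \code{group_b}, \code{z},
#'   \code{p_adj}, \code{significant}.
#' @export
stats_table <- function(results) {
  rows <- lapply(results, function(r) {
    omni <- data.frame(model = r$model, capsid = r$capsid, level = r$level,
                       row_type = "omnibus", method = r$method,
                       statistic = r$statistic, df = r$df, p = r$p,
                       group_a = NA, group_b = NA, z = NA, p_adj = NA,
                       significant = r$p < 0.05, stringsAsFactors = FALSE)
    pw <- data.frame(model = r$model, capsid = r$capsid, level = r$level,
                     row_type = "pairwise", method = "dunn",
                     statistic = NA, df = NA, p = r$pairwise$p,
                     group_a = r$pairwise$group_a,
                     group_b = r$pairwise$group_b, z = r$pairwise$z,
                     p_adj = r$pairwise$p_adj,
                     significant = r$pairwise$significant,
                     stringsAsFactors = FALSE)
    rbind(omni, pw)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a flattened stats table to TSV
#' @param results list from [run_group_comparisons()] or a data frame from
#'   [stats_table()].
#' @param path TSV path.
#' @return \code{path}, invisibly.
#' @export
write_stats <- function(results, path) {
  tab <- if (is.data.frame(results)) results else stats_table(results)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
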
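#' Pseudocounted read proportions
#'
#' \eqn{p_i = (c_i + a) / \sum_j (c_j + a)}. The pseudocount keeps premix
#' denominators strictly positive so downstream ratios stay finite when a
#' barcode drops out of one library.
#'
#' @param counts nonnegative count vector.
#' @param pseudocount \eqn{a \ge 0} added to every barcode (default 0.5).
#' @return proportion vector summing to 1.
#' @export
proportions <- function(counts, pseudocount = 0.5) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (pseudocount < 0) stop("pseudocount must be nonnegative")
  tot <- sum(counts) + length(counts) * pseudocount
  if (tot <= 0) stop("empty sample: all counts zero and no pseudocount")
  (counts + pseudocount) / tot
}

#' Normalise sample proportions to the pre-transduction mix
#'
#' Each barcode's share in the sample is divided by its share in the premix
#' library (\eqn{r_i = p_i / p^{premix}_i}), then renormalised to sum to 1
#' (\eqn{R_i = r_i / \sum_j r_j}), giving the barcode's abundance relative
#' to what was actually in the vector pool.
#'
#' @param p_sample proportion vector for the sample.
#' @param p_premix strictly positive proportion vector for the premix, same
#'   barcode universe.
#' @return normalised abundance vector \eqn{R} summing to 1.
#' @export
premix_normalize <- function(p_sample, p_premix) {
  if (length(p_sample) != length(p_premix))
    stop("sample and premix proportion vectors differ in length")
  if (any(p_premix <= 0)) stop("premix proportions must be strictly positive")
  r <- p_sample / p_premix
  r / sum(r)
}

#' Expression Index per barcode
#'
#' EI is premix-normalised expression over premix-normalised cell entry:
#' \eqn{EI_i = R^{RNA}_i / R^{DNA}_i}. EI = 1 means the promoter's output
#' exactly tracks how many vector genomes entered the cells.
#'
#' @param R_rna normalised cDNA/mRNA abundances from [premix_normalize()].
#' @param R_dna normalised gDNA abundances, same barcode universe.
#' @return EI vector over barcodes.
#' @export
expression_index <- function(R_rna, R_dna) {
  if (length(R_rna) != length(R_dna))
    stop("RNA and DNA abundance vectors differ in length")
  if (any(R_dna <= 0)) stop("DNA abundances must be strictly positive")
  R_rna / R_dna
}

#' Aggregate per-barcode EI to promoter level
#'
#' \code{barcode_mean} averages the EI of a promoter's barcodes (computed
#' per barcode first, preserving within-promoter barcode agreement as a QC
#' signal); \code{count_pooled} sums raw counts across a promoter's
#' barcodes (premix likewise) and recomputes the whole chain at promoter
#' resolution.
#'
#' @param ei named per-barcode EI vector (barcode_mean mode), or \code{NULL}
#'   in count_pooled mode.
#' @param kit a [kit_design()].
#' @param mode \code{"barcode_mean"} or \code{"count_pooled"}.
#' @param counts named list with elements \code{premix}, \code{gDNA},
#'   \code{cDNA} of raw barcode counts (required for count_pooled).
#' @param pseudocount pseudocount for the recomputed chain (count_pooled).
#' @return named per-promoter EI vector, in kit construct order.
#' @export
aggregate_promoters <- function(ei, kit, mode = c("barcode_mean",
                                                  "count_pooled"),
                                counts = NULL, pseudocount = 0.5) {
  mode <- match.arg(mode)
  promoters <- kit_constructs(kit)$promoter
  if (mode == "barcode_mean") {
    if (is.null(ei)) stop("barcode_mean mode needs the per-barcode EI vector")
    v <- vapply(promoters,
                function(p) mean(ei[kit$barcode[kit$promoter == p]]),
                numeric(1L))
  } else {
    if (is.null(counts) ||
        !all(c("premix", "gDNA", "cDNA") %in% names(counts)))
      stop("count_pooled mode needs counts$premix, counts$gDNA, counts$cDNA")
    pool <- function(x) vapply(promoters,
                               function(p) sum(x[kit$promoter == p]),
                               numeric(1L))
    p_pre <- proportions(pool(counts$premix), pseudocount)
    R_dna <- premix_normalize(proportions(pool(counts$gDNA), pseudocount),
                              p_pre)
    R_rna <- premix_normalize(proportions(pool(counts$cDNA), pseudocount),
                              p_pre)
    v <- expression_index(R_rna, R_dna)
  }
  stats::setNames(v, promoters)
}

#' Expression Index table for a whole experiment
#'
#' Runs the full normalisation chain for every (model, capsid, replicate)
#' with both fractions: pseudocounted proportions, premix normalisation
#' against that capsid batch's premix library, per-barcode EI, promoter
#' aggregation, and within-replicate EI proportions
#' (\eqn{ei\_proportion = ei / \sum_{promoters} ei}).
#'
#' @param counts barcode x sample count matrix from [count_experiment()].
#' @param sheet the \code{sample_sheet}.
#' @param kit a [kit_design()].
#' @param pseudocount pseudocount for all libraries (default 0.5).
#' @param mode promoter aggregation mode, see [aggregate_promoters()].
#' @return an \code{ei_table} data frame: \code{model}, \code{capsid},
#'   \code{replicate}, \code{promoter}, \code{group}, \code{ei},
#'   \code{ei_proportion}.
#' @export
ei_table <- function(counts, sheet, kit, pseudocount = 0.5,
                     mode = c("barcode_mean", "count_pooled")) {
  mode <- match.arg(mode)
  if (!all(sheet$sample_id %in% colnames(counts)))
    stop("count matrix lacks columns for some samples")
  counts <- counts[kit$barcode, , drop = FALSE]
  cons <- kit_constructs(kit)
  grp <- stats::setNames(cons$group, cons$promoter)

  cdna <- sheet[sheet$fraction == "cDNA", , drop = FALSE]
  rows <- vector("list", nrow(cdna))
  for (i in seq_len(nrow(cdna))) {
    model <- cdna$model[i]; cap <- cdna$capsid[i]; r <- cdna$replicate[i]
    gid <- sheet$sample_id[sheet$fraction == "gDNA" & sheet$model == model &
                             sheet$capsid == cap & sheet$replicate == r]
    if (length(gid) != 1L)
      stop(sprintf("no unique gDNA partner for %s/%s replicate %d", model,
                   cap, r))
    pre <- counts[, premix_sample(sheet, cap)]
    cg <- counts[, gid]
    cc <- counts[, cdna$sample_id[i]]
    if (mode == "barcode_mean") {
      p_pre <- proportions(pre, pseudocount)
      R_dna <- premix_normalize(proportions(cg, pseudocount), p_pre)
      R_rna <- premix_normalize(proportions(cc, pseudocount), p_pre)
      ei_bc <- expression_index(R_rna, R_dna)
      ei_p <- aggregate_promoters(ei_bc, kit, "barcode_mean")
    } else {
      ei_p <- aggregate_promoters(NULL, kit, "count_pooled",
                                  counts = list(premix = pre, gDNA = cg,
                                                cDNA = cc),
                                  pseudocount = pseudocount)
    }
    rows[[i]] <- data.frame(model = model, capsid = cap, replicate = r,
                            promoter = names(ei_p),
                            group = unname(grp[names(ei_p)]),
                            ei = unname(ei_p),
                            ei_proportion = unname(ei_p / sum(ei_p)),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ei_table", "data.frame")
  out
}

#' Write / read an EI table as TSV
#' @param ei an \code{ei_table}.
#' @param path TSV path.
#' @return \code{path} (write) or the \code{ei_table} (read).
#' @export
write_ei <- function(ei, path) {
  utils::write.table(as.data.frame(ei), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_ei
#' @export
read_ei <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("ei_table", "data.frame")
  out
}
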
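#' Construct a promoter--barcode kit design
#'
#' A kit design maps short fixed-length DNA barcodes to promoter constructs,
#' each labelled with a promoter class (\code{ubiquitous},
#' \code{cardiac_specific} or \code{liver_specific}). Every barcode belongs to
#' exactly one promoter; a promoter may carry several barcodes (internal
#' replicates).
#'
#' @param barcode character vector of barcode sequences (A/C/G/T only, all the
#'   same length).
#' @param promoter character vector of promoter names, parallel to
#'   \code{barcode}.
#' @param group character vector of promoter classes, parallel to
#'   \code{barcode}; one of \code{"ubiquitous"}, \code{"cardiac_specific"},
#'   \code{"liver_specific"}. Must be constant within a promoter.
#' @return A \code{kit_design} object: a data frame with columns
#'   \code{barcode}, \code{promoter}, \code{group} and attribute
#'   \code{barcode_length}. Construct order is first-appearance order.
#' @seealso [read_kit()], [default_kit()]
#' @export
kit_design <- function(barcode, promoter, group) {
  barcode <- trimws(as.character(barcode))
  promoter <- trimws(as.character(promoter))
  group <- trimws(as.character(group))
  n <- length(barcode)
  if (length(promoter) != n || length(group) != n)
    stop("barcode, promoter and group must have equal length")
  if (n == 0L) stop("kit has no barcodes")

  lens <- nchar(barcode)
  bad_len <- which(lens != lens[1L])
  if (length(bad_len))
    stop(sprintf("barcode length mismatch at row %d: '%s' (expected %d nt)",
                 bad_len[1L], barcode[bad_len[1L]], lens[1L]))
  bad_alpha <- grep("[^ACGT]", barcode)
  if (length(bad_alpha))
    stop(sprintf("barcode at row %d ('%s') contains characters outside A/C/G/T",
                 bad_alpha[1L], barcode[bad_alpha[1L]]))
  dup <- which(duplicated(barcode))
  if (length(dup)) {
    first <- match(barcode[dup[1L]], barcode)
    stop(sprintf("duplicate barcode '%s' at rows %d and %d (each barcode must map to exactly one promoter)",
                 barcode[dup[1L]], first, dup[1L]))
  }
  valid_groups <- c("ubiquitous", "cardiac_specific", "liver_specific")
  bad_grp <- which(!group %in% valid_groups)
  if (length(bad_grp))
    stop(sprintf("unknown group label '%s' at row %d (expected one of %s)",
                 group[bad_grp[1L]], bad_grp[1L],
                 paste(valid_groups, collapse = ", ")))
  pg <- tapply(group, promoter, function(g) length(unique(g)))
  if (any(pg > 1L))
    stop(sprintf("promoter '%s' is assigned to more than one group",
                 names(pg)[which(pg > 1L)[1L]]))

  out <- data.frame(barcode = barcode, promoter = promoter, group = group,
                    stringsAsFactors = FALSE)
  attr(out, "barcode_length") <- lens[1L]
  class(out) <- c("kit_design", "data.frame")
  out
}

#' @export
print.kit_design <- function(x, ...) {
  cons <- kit_constructs(x)
  cat(sprintf("Promoter kit: %d barcodes (%d nt) across %d constructs\n",
              nrow(x), barcode_length(x), nrow(cons)))
  for (g in unique(cons$group)) {
    p <- cons$promoter[cons$group == g]
    cat(sprintf("  %-16s %s\n", paste0(g, ":"), paste(p, collapse = ", ")))
  }
  invisible(x)
}

#' Barcode length of a kit
#' @param kit a [kit_design()] object.
#' @return integer barcode length in nucleotides.
#' @export
barcode_length <- function(kit) attr(kit, "barcode_length")

#' Construct table of a kit
#'
#' @param kit a [kit_design()] object.
#' @return data frame with one row per promoter construct, in first-appearance
#'   order: \code{promoter}, \code{group}, \code{n_barcodes}.
#' @export
kit_constructs <- function(kit) {
  idx <- !duplicated(kit$promoter)
  data.frame(promoter = kit$promoter[idx],
             group = kit$group[idx],
             n_barcodes = as.integer(table(factor(kit$promoter,
                                                  levels = kit$promoter[idx]))),
             stringsAsFactors = FALSE)
}

#' Read a kit design from TSV
#'
#' Expects a tab-separated file with header columns \code{barcode},
#' \code{promoter}, \code{group}. Extra columns are preserved on read but
#' ignored by the pipeline. Labels are whitespace-trimmed and case-sensitive.
#'
#' @param path path to the TSV file.
#' @return a validated [kit_design()] object.
#' @export
read_kit <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("barcode", "promoter", "group")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(sprintf("kit file %s is missing column(s): %s", path,
                 paste(miss, collapse = ", ")))
  if (nrow(tab) == 0L) stop(sprintf("kit file %s has no rows", path))
  kit_design(tab$barcode, tab$promoter, tab$group)
}

#' Write a kit design to TSV
#'
#' Canonical column order \code{barcode}, \code{promoter}, \code{group};
#' round-trips byte-identically with [read_kit()] for canonical input.
#'
#' @param kit a [kit_design()] object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_kit <- function(kit, path) {
  utils::write.table(as.data.frame(kit)[, c("barcode", "promoter", "group")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Deterministic barcode whitelist: lexicographic greedy scan over all 4^k
# k-mers keeping pairwise Hamming distance >= min_dist. With min_dist 3 a
# single substitution can never move one whitelist barcode within 1 mismatch
# of another, so 1-mismatch assignment is unambiguous by construction.
generate_barcodes <- function(n, k = 6L, min_dist = 3L) {
  alpha <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid,
                  c(rep(list(alpha), k), stringsAsFactors = FALSE))
  # expand.grid varies the first factor fastest; reorder for lexicographic
  grid <- grid[, rev(seq_len(k))]
  all_kmers <- do.call(paste0, grid)
  kept <- character(0)
  kept_mat <- NULL
  for (s in all_kmers) {
    v <- strsplit(s, "")[[1L]]
    if (is.null(kept_mat) ||
        all(colSums(kept_mat != v) >= min_dist)) {
      kept <- c(kept, s)
      kept_mat <- cbind(kept_mat, v)
      if (length(kept) == n) return(kept)
    }
  }
  stop(sprintf("could not find %d barcodes of length %d at distance %d", n, k,
               min_dist))
}

#' Default 18-barcode cardiac promoter kit
#'
#' Eight constructs: six cardiac-specific promoters (aMHC, MLC2v, cTnT, cTnI,
#' NCX, a1c), the ubiquitous CMV benchmark and a liver-specific promoter
#' (LSP). Each promoter carries two 6-nt barcodes and CMV carries two extra
#' (18 barcodes total). Barcodes are generated deterministically with
#' pairwise Hamming distance >= 3 so single-mismatch whitelist assignment is
#' never ambiguous.
#'
#' @param barcodes_per_promoter barcodes per construct (default 2).
#' @param extra_cmv additional CMV barcodes (default 2).
#' @return a [kit_design()] object.
#' @export
default_kit <- function(barcodes_per_promoter = 2L, extra_cmv = 2L) {
  promoters <- c("CMV", "aMHC", "MLC2v", "cTnT", "cTnI", "NCX", "a1c", "LSP")
  groups <- c("ubiquitous", rep("cardiac_specific", 6L), "liver_specific")
  mult <- rep(barcodes_per_promoter, length(promoters))
  mult[1L] <- mult[1L] + extra_cmv
  bcs <- generate_barcodes(sum(mult), k = 6L, min_dist = 3L)
  kit_design(bcs, rep(promoters, times = mult), rep(groups, times = mult))
}

#' Map barcodes to promoters
#' @param kit a [kit_design()] object.
#' @return named character vector promoter-per-barcode, in kit order.
#' @export
barcode_promoters <- function(kit) {
  stats::setNames(kit$promoter, kit$barcode)
}
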
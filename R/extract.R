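#' Anchor specification for barcode excision
#'
#' The barcode is excised immediately 3' of a constant anchor sequence
#' located in each read with bounded mismatches; the excised window is then
#' assigned to the kit whitelist with bounded Hamming distance. Conservative
#' defaults (anchor <= 2 mismatches, barcode <= 1, exact-match priority,
#' ambiguity discarded) make false assignment provably rare for 6-mers at
#' pairwise distance >= 3.
#'
#' @param left_anchor constant anchor sequence 5' of the barcode (>= 12 nt).
#' @param barcode_length barcode length in nt (>= 4).
#' @param max_anchor_mismatches maximum mismatches tolerated when locating
#'   the anchor (default 2).
#' @param max_barcode_mismatches maximum Hamming distance for whitelist
#'   assignment; 0 or 1 (default 1).
#' @param scan_reverse_complement also scan the reverse complement of reads
#'   whose forward strand has no qualifying anchor.
#' @return an \code{anchor_spec} list.
#' @export
anchor_spec <- function(left_anchor, barcode_length = 6L,
                        max_anchor_mismatches = 2L,
                        max_barcode_mismatches = 1L,
                        scan_reverse_complement = FALSE) {
  left_anchor <- toupper(left_anchor)
  if (nchar(left_anchor) < 12L) stop("anchor must be at least 12 nt")
  if (grepl("[^ACGT]", left_anchor)) stop("anchor must be A/C/G/T only")
  if (barcode_length < 4L) stop("barcode_length must be >= 4")
  if (max_barcode_mismatches < 0L || max_barcode_mismatches > 1L)
    stop("max_barcode_mismatches must be 0 or 1")
  if (max_anchor_mismatches < 0L)
    stop("max_anchor_mismatches must be nonnegative")
  structure(list(left_anchor = left_anchor,
                 barcode_length = as.integer(barcode_length),
                 max_anchor_mismatches = as.integer(max_anchor_mismatches),
                 max_barcode_mismatches = as.integer(max_barcode_mismatches),
                 scan_reverse_complement = isTRUE(scan_reverse_complement)),
            class = "anchor_spec")
}

revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s)
    paste(rev(strsplit(s, "")[[1L]]), collapse = ""), character(1L)))
}

#' Locate the anchor in one read
#'
#' Scans every window of the read and returns the 1-based start of the
#' occurrence with the fewest mismatches, provided that minimum is within
#' tolerance; ties are broken by the leftmost position. \code{N} in the read
#' counts as a mismatch. Returns \code{NA} when no window qualifies
#' (absence is a value, not an error).
#'
#' @param read a nucleotide string (may contain N).
#' @param spec an [anchor_spec()].
#' @return integer position or \code{NA_integer_}.
#' @export
locate_anchor <- function(read, spec) {
  al <- nchar(spec$left_anchor)
  n <- nchar(read)
  if (n < al) return(NA_integer_)
  achars <- strsplit(spec$left_anchor, "")[[1L]]
  rchars <- strsplit(toupper(read), "")[[1L]]
  best_pos <- NA_integer_
  best_mm <- spec$max_anchor_mismatches + 1L
  for (s in seq_len(n - al + 1L)) {
    mm <- sum(rchars[s:(s + al - 1L)] != achars)
    if (mm < best_mm) {
      best_mm <- mm
      best_pos <- s
      if (mm == 0L) break
    }
  }
  if (best_mm <= spec$max_anchor_mismatches) best_pos else NA_integer_
}

# vectorised anchor location over many reads; exact occurrences are resolved
# first with fixed-pattern regexpr, the remainder by per-offset mismatch
# counting. Same contract as locate_anchor(), applied elementwise.
locate_anchor_vec <- function(reads, spec) {
  reads <- toupper(reads)
  al <- nchar(spec$left_anchor)
  n <- length(reads)
  pos <- rep(NA_integer_, n)
  if (n == 0L) return(pos)
  exact <- regexpr(spec$left_anchor, reads, fixed = TRUE)
  pos[exact > 0L] <- exact[exact > 0L]
  if (spec$max_anchor_mismatches == 0L) return(pos)

  todo <- which(is.na(pos) & nchar(reads) >= al)
  if (!length(todo)) return(pos)
  achars <- strsplit(spec$left_anchor, "")[[1L]]
  sub <- reads[todo]
  best_mm <- rep(spec$max_anchor_mismatches + 1L, length(todo))
  best_pos <- rep(NA_integer_, length(todo))
  max_off <- max(nchar(sub)) - al + 1L
  for (s in seq_len(max_off)) {
    live <- nchar(sub) - al + 1L >= s
    if (!any(live)) break
    mm <- integer(length(todo))
    for (k in seq_len(al))
      mm <- mm + (substr(sub, s + k - 1L, s + k - 1L) != achars[k])
    upd <- live & mm < best_mm
    best_mm[upd] <- mm[upd]
    best_pos[upd] <- s
  }
  ok <- best_mm <= spec$max_anchor_mismatches
  pos[todo[ok]] <- best_pos[ok]
  pos
}

#' Assign an observed barcode to the kit whitelist
#'
#' Exact whitelist hits win outright. Otherwise, with
#' \code{max_barcode_mismatches = 1}, a unique whitelist barcode at Hamming
#' distance 1 wins; two or more whitelist barcodes at the minimal qualifying
#' distance give \code{"ambiguous"}; nothing within tolerance gives
#' \code{"unmatched"}. \code{N} counts as a mismatch.
#'
#' @param observed barcode-length string excised from a read.
#' @param kit a [kit_design()].
#' @param spec an [anchor_spec()].
#' @return the matched whitelist barcode, \code{"ambiguous"} or
#'   \code{"unmatched"}.
#' @export
assign_barcode <- function(observed, kit, spec) {
  assign_barcode_vec(observed, kit, spec)
}

# vectorised whitelist assignment; returns the whitelist barcode,
# "ambiguous" or "unmatched" per observed window
assign_barcode_vec <- function(observed, kit, spec) {
  bl <- barcode_length(kit)
  observed <- toupper(observed)
  if (any(nchar(observed) != bl))
    stop(sprintf("observed barcode length != %d", bl))
  out <- rep("unmatched", length(observed))
  hit <- match(observed, kit$barcode)
  out[!is.na(hit)] <- kit$barcode[hit[!is.na(hit)]]
  if (spec$max_barcode_mismatches >= 1L) {
    todo <- which(is.na(hit))
    if (length(todo)) {
      obs <- observed[todo]
      dmat <- matrix(0L, length(obs), nrow(kit))
      for (k in seq_len(bl)) {
        oc <- substr(obs, k, k)
        bc <- substr(kit$barcode, k, k)
        dmat <- dmat + (outer(oc, bc, "!="))
      }
      mind <- apply(dmat, 1L, min)
      nmin <- rowSums(dmat == mind)
      one <- mind <= spec$max_barcode_mismatches
      out[todo[one & nmin == 1L]] <-
        kit$barcode[apply(dmat[one & nmin == 1L, , drop = FALSE], 1L,
                          which.min)]
      out[todo[one & nmin > 1L]] <- "ambiguous"
    }
  }
  out
}

#' Count whitelist barcodes in one sample
#'
#' For each read: locate the anchor; if found, excise the barcode-length
#' window immediately 3' of it and assign it to the whitelist. Reads with no
#' qualifying anchor, or too short to hold a full barcode after the anchor,
#' are unmatched. Optionally reads with no forward-strand anchor are
#' re-scanned on the reverse complement.
#'
#' @param path FASTQ(.gz) path (or a data frame of reads as returned by
#'   [read_fastq()]).
#' @param kit a [kit_design()].
#' @param spec an [anchor_spec()].
#' @return list with \code{counts} (named integer vector in kit barcode
#'   order) and \code{stats} (one-row data frame: \code{total_reads},
#'   \code{anchored_reads}, \code{assigned_reads}, \code{ambiguous_reads},
#'   \code{unmatched_reads}).
#' @export
count_sample <- function(path, kit, spec) {
  counts <- stats::setNames(integer(nrow(kit)), kit$barcode)
  tot <- anch <- assn <- ambig <- unm <- 0L
  process <- function(chunk) {
    seqs <- toupper(chunk$sequence)
    n <- length(seqs)
    tot <<- tot + n
    pos <- locate_anchor_vec(seqs, spec)
    if (spec$scan_reverse_complement && any(is.na(pos))) {
      flip <- which(is.na(pos))
      rc <- revcomp(seqs[flip])
      rp <- locate_anchor_vec(rc, spec)
      seqs[flip] <- rc
      pos[flip] <- rp
    }
    found <- !is.na(pos)
    anch <<- anch + sum(found)
    # reads with no qualifying anchor count toward total only
    if (!any(found)) return(invisible(NULL))
    al <- nchar(spec$left_anchor)
    start <- pos[found] + al
    stop_ <- start + spec$barcode_length - 1L
    fits <- stop_ <= nchar(seqs[found])
    unm <<- unm + sum(!fits)
    if (any(fits)) {
      obs <- substr(seqs[found][fits], start[fits], stop_[fits])
      res <- assign_barcode_vec(obs, kit, spec)
      is_amb <- res == "ambiguous"
      is_unm <- res == "unmatched"
      ambig <<- ambig + sum(is_amb)
      unm <<- unm + sum(is_unm)
      good <- res[!is_amb & !is_unm]
      if (length(good)) {
        tab <- table(factor(good, levels = kit$barcode))
        counts <<- counts + as.integer(tab)
        assn <<- assn + length(good)
      }
    }
    invisible(NULL)
  }
  if (is.data.frame(path)) process(path) else stream_fastq(path, process)
  list(counts = counts,
       stats = data.frame(total_reads = tot, anchored_reads = anch,
                          assigned_reads = assn, ambiguous_reads = ambig,
                          unmatched_reads = unm))
}

#' Count barcodes across all samples of an experiment
#'
#' @param sheet a \code{sample_sheet} (reads paths must exist).
#' @param kit a [kit_design()].
#' @param spec an [anchor_spec()].
#' @return list with \code{counts} (barcode x sample integer matrix) and
#'   \code{stats} (one row per sample).
#' @export
count_experiment <- function(sheet, kit, spec) {
  mats <- vector("list", nrow(sheet))
  st <- vector("list", nrow(sheet))
  for (i in seq_len(nrow(sheet))) {
    res <- count_sample(sheet$reads_path[i], kit, spec)
    mats[[i]] <- res$counts
    st[[i]] <- cbind(data.frame(sample_id = sheet$sample_id[i]), res$stats)
  }
  counts <- do.call(cbind, mats)
  colnames(counts) <- sheet$sample_id
  rownames(counts) <- kit$barcode
  list(counts = counts, stats = do.call(rbind, st))
}

#' Write / read a barcode count matrix as TSV
#'
#' Rows are barcodes, columns samples; first column name is \code{barcode}.
#' @param counts barcode x sample integer matrix.
#' @param path TSV path.
#' @return \code{path} (write) or the matrix (read).
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(barcode = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "integer"
  m
}
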
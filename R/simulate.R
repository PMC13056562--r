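# RNG substreams: every stochastic step draws under a seed derived from the
# run seed plus a stage key, so a replicate's cDNA draw can reuse the same
# realised entry vector as its gDNA draw, and whole experiment trees are
# byte-reproducible. Derived seeds are kept inside 32-bit integer range.
substream <- function(seed, key) {
  # seed is folded into the character hash so streams from different run
  # seeds (or keys) never coincide systematically; stays < 2^31
  h <- as.numeric(seed) %% 2147483629
  for (v in utf8ToInt(paste0("|", key))) h <- (h * 131 + v) %% 2147483629
  as.integer(h)
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Default promoter-activity matrix
#'
#' Relative transcriptional activities (arbitrary units, per promoter and
#' model) encoding the qualitative pattern expected of this promoter panel:
#' in cardiomyocyte models the ubiquitous CMV dominates, NCX and cTnT are the
#' strongest cardiac-specific promoters, cTnI the weakest, and the
#' liver-specific promoter is near-silent; in hepatic models LSP outperforms
#' every cardiac-specific promoter and cTnT is the least active of them.
#' Activities span 50-fold, and aMHC is exactly twice a1c, giving a known 2x
#' pair for calibration checks. Exact values are configuration, not claims.
#'
#' @return numeric matrix, promoters x models.
#' @export
default_activity <- function() {
  promoters <- c("CMV", "aMHC", "MLC2v", "cTnT", "cTnI", "NCX", "a1c", "LSP")
  cardiac <- c(CMV = 50, aMHC = 8, MLC2v = 7, cTnT = 18, cTnI = 2, NCX = 20,
               a1c = 4, LSP = 1)
  liver <- c(CMV = 50, aMHC = 6, MLC2v = 3, cTnT = 1, cTnI = 2, NCX = 4,
             a1c = 3, LSP = 25)
  models <- list(hiPSC_CM = cardiac, NRVM = cardiac, HuH7 = liver,
                 mouse_heart = cardiac, mouse_liver = liver,
                 rat_heart = cardiac, rat_liver = liver,
                 sheep_heart = cardiac, pig_heart = cardiac)
  m <- do.call(cbind, models)[promoters, , drop = FALSE]
  rownames(m) <- promoters
  m
}

#' Ground truth for the competitive-transduction simulator
#'
#' Bundles every parameter of the generative model: the promoter-by-model
#' activity matrix, log-scale entry and expression noise, the Dirichlet
#' concentration governing deviation of the vector pool from equimolar, the
#' per-base substitution error rate of sequencing, read depth per library and
#' replicate count.
#'
#' @param activity promoter x model matrix of positive relative activities.
#' @param entry_sd natural-log SD of per-barcode, per-replicate cell-entry
#'   noise (promoter-independent).
#' @param expr_sd natural-log SD of per-barcode expression noise.
#' @param premix_concentration per-component Dirichlet concentration around
#'   the equimolar pool; \code{Inf} disables premix jitter.
#' @param error_rate per-base substitution probability in synthesized reads.
#' @param depth reads per library.
#' @param n_replicates default replicates per model x capsid.
#' @param seed integer run seed.
#' @return a \code{ground_truth} list.
#' @export
ground_truth <- function(activity = default_activity(), entry_sd = 0.3,
                         expr_sd = 0.3, premix_concentration = 200,
                         error_rate = 0.01, depth = 1e5, n_replicates = 5L,
                         seed = 1L) {
  stopifnot(is.matrix(activity), all(activity > 0),
            !is.null(rownames(activity)), !is.null(colnames(activity)))
  if (error_rate < 0 || error_rate >= 0.25)
    stop("error_rate must be in [0, 0.25)")
  if (depth < 0) stop("depth must be nonnegative")
  if (entry_sd < 0 || expr_sd < 0) stop("noise SDs must be nonnegative")
  structure(list(activity = activity, entry_sd = entry_sd, expr_sd = expr_sd,
                 premix_concentration = premix_concentration,
                 error_rate = error_rate, depth = depth,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' Amplicon template around the barcode
#'
#' In the vector cassette the 6-nt barcode sits between the 3' end of the
#' eGFP coding sequence and the WPRE element; reads therefore carry the
#' barcode at a fixed offset between two constant regions. Anchors are
#' validated to be barcode-free: no same-length window of either anchor may
#' lie within Hamming distance 1 of any whitelist barcode, so an anchor can
#' never be mistaken for (or absorb) a barcode.
#'
#' By default both constant regions are built deterministically from the kit
#' so the constraint holds by construction.
#'
#' @param kit a [kit_design()], used to validate (and by default build) the
#'   anchors.
#' @param left_anchor constant region 5' of the barcode (>= 12 nt).
#' @param right_anchor constant region 3' of the barcode (>= 12 nt).
#' @param read_length single-end read length; reads are truncated to it.
#' @return an \code{amplicon_template} list.
#' @export
amplicon_template <- function(kit, left_anchor = NULL, right_anchor = NULL,
                              read_length = 150L) {
  bl <- barcode_length(kit)
  if (is.null(left_anchor) && is.null(right_anchor)) {
    # retry phases until the left anchor is unique within every amplicon
    for (ph in 0:49) {
      left_anchor <- build_anchor(kit, 20L, phase = ph * 7L)
      right_anchor <- build_anchor(kit, max(20L, read_length - 20L - bl),
                                   phase = ph * 7L + 3L)
      if (anchor_unique(left_anchor, right_anchor, kit)) break
      if (ph == 49L) stop("could not build a template with a unique anchor")
    }
  } else if (is.null(left_anchor) || is.null(right_anchor)) {
    stop("supply both anchors or neither")
  }
  for (a in list(left_anchor, right_anchor)) {
    if (nchar(a) < 12L) stop("anchors must be at least 12 nt")
    if (grepl("[^ACGT]", a)) stop("anchors must be A/C/G/T only")
    if (min_window_dist(a, kit$barcode, bl) < 2L)
      stop("anchor contains a window within Hamming distance 1 of a whitelist barcode")
  }
  if (!anchor_unique(left_anchor, right_anchor, kit))
    warning("left anchor recurs (within 4 mismatches) inside the amplicon; mismatch-tolerant location may pick the wrong site")
  if (read_length < nchar(left_anchor) + bl + 4L)
    stop(sprintf("read_length %d too short: barcode would be truncated (need >= %d)",
                 read_length, nchar(left_anchor) + bl + 4L))
  structure(list(left_anchor = left_anchor, right_anchor = right_anchor,
                 read_length = as.integer(read_length)),
            class = "amplicon_template")
}

# minimum Hamming distance between any k-window of seq and any barcode
min_window_dist <- function(seq, barcodes, k) {
  n <- nchar(seq)
  if (n < k) return(k)
  chars <- strsplit(seq, "")[[1L]]
  bmat <- vapply(barcodes, function(b) strsplit(b, "")[[1L]],
                 character(k))
  best <- k
  for (s in seq_len(n - k + 1L)) {
    w <- chars[s:(s + k - 1L)]
    d <- colSums(bmat != w)
    best <- min(best, d)
  }
  best
}

# deterministic constant-region builder: draws candidate sequences under a
# fixed internal seed until every barcode-length window sits at Hamming
# distance >= 2 from the whole whitelist (so an anchor window can never be
# mistaken for a barcode). Different `phase` values give unrelated regions.
build_anchor <- function(kit, len, phase = 0L) {
  bases <- c("A", "C", "G", "T")
  k <- barcode_length(kit)
  bmat <- vapply(kit$barcode, function(b) strsplit(b, "")[[1L]], character(k))
  for (attempt in seq_len(50L)) {
    out <- with_seed(90021L + phase * 1009L + attempt, {
      grown <- character(0)
      for (i in seq_len(len)) {
        ok <- FALSE
        for (cand in sample(bases)) {
          if (length(grown) >= k - 1L) {
            w <- c(grown[(length(grown) - k + 2L):length(grown)], cand)
            if (min(colSums(bmat != w)) < 2L) next
          }
          grown <- c(grown, cand)
          ok <- TRUE
          break
        }
        if (!ok) break  # dead end; restart with a fresh attempt
      }
      if (length(grown) == len) paste(grown, collapse = "") else NULL
    })
    if (!is.null(out)) return(out)
  }
  stop("could not build an anchor away from the barcode whitelist")
}

# TRUE when, for every barcode's amplicon, the only window within 4
# mismatches of the left anchor is its true site (position 1), so the
# mismatch-tolerant scan cannot lock onto a downstream near-copy
anchor_unique <- function(left_anchor, right_anchor, kit) {
  all(vapply(kit$barcode, function(bc)
    min_pattern_dist(paste0(left_anchor, bc, right_anchor), left_anchor,
                     skip = 1L) >= 5L, logical(1L)))
}

# minimum Hamming distance between `pattern` and every same-length window of
# `seq` except the one starting at `skip` (0 = none)
min_pattern_dist <- function(seq, pattern, skip = 0L) {
  m <- nchar(pattern)
  n <- nchar(seq)
  if (n < m) return(m)
  pc <- strsplit(pattern, "")[[1L]]
  sc <- strsplit(seq, "")[[1L]]
  best <- m
  for (s in seq_len(n - m + 1L)) {
    if (s == skip) next
    best <- min(best, sum(sc[s:(s + m - 1L)] != pc))
  }
  best
}

#' Simulate the pre-transduction vector pool
#'
#' The pool is nominally equimolar; batch-to-batch pipetting deviation is
#' modelled as a symmetric Dirichlet draw around the uniform vector with
#' per-component concentration \code{premix_concentration}. Infinite
#' concentration returns the exact equimolar pool.
#'
#' @param kit a [kit_design()].
#' @param truth a [ground_truth()].
#' @param seed seed for this draw (default: run seed).
#' @return named proportion vector over barcodes, summing to 1.
#' @export
simulate_premix <- function(kit, truth, seed = truth$seed) {
  b <- nrow(kit)
  if (!is.finite(truth$premix_concentration))
    return(stats::setNames(rep(1 / b, b), kit$barcode))
  with_seed(substream(seed, "premix"), {
    g <- stats::rgamma(b, shape = truth$premix_concentration, rate = 1)
    stats::setNames(g / sum(g), kit$barcode)
  })
}

# per-replicate realised entry vector (promoter-independent lognormal jitter
# of the premix), shared between the gDNA and cDNA draws of that replicate
realised_entry <- function(kit, truth, premix, model, capsid, replicate) {
  key <- paste("entry", model, capsid, replicate, sep = "|")
  with_seed(substream(truth$seed, key),
            premix * exp(stats::rnorm(nrow(kit), 0, truth$entry_sd)))
}

#' Simulate barcode counts for one library
#'
#' gDNA (cell entry) counts are multinomial draws from the premix distorted
#' by promoter-independent lognormal entry noise; cDNA (expression) counts
#' are multinomial draws from that same replicate's realised entry vector
#' weighted by the promoter's activity in the given model, with additional
#' lognormal expression noise. Calling the function for the gDNA and cDNA
#' fractions of the same (model, capsid, replicate) reuses one realised
#' entry vector.
#'
#' @param kit a [kit_design()].
#' @param truth a [ground_truth()].
#' @param premix premix proportion vector from [simulate_premix()].
#' @param model model/tissue label; must be a column of
#'   \code{truth$activity}.
#' @param fraction \code{"gDNA"} or \code{"cDNA"}.
#' @param replicate replicate number.
#' @param capsid capsid label (part of the replicate's RNG substream).
#' @return named integer count vector over barcodes, summing to
#'   \code{truth$depth}.
#' @export
simulate_sample_counts <- function(kit, truth, premix, model, fraction,
                                   replicate, capsid = "batch") {
  fraction <- match.arg(fraction, c("gDNA", "cDNA"))
  if (!model %in% colnames(truth$activity))
    stop(sprintf("model '%s' has no activity column (known: %s)", model,
                 paste(colnames(truth$activity), collapse = ", ")))
  entry <- realised_entry(kit, truth, premix, model, capsid, replicate)
  if (fraction == "gDNA") {
    probs <- entry / sum(entry)
  } else {
    act <- truth$activity[, model]
    miss <- setdiff(unique(kit$promoter), names(act))
    if (length(miss))
      stop(sprintf("activity matrix lacks promoter '%s'", miss[1L]))
    w <- with_seed(substream(truth$seed,
                             paste("expr", model, capsid, replicate,
                                   sep = "|")),
                   entry * act[kit$promoter] *
                     exp(stats::rnorm(nrow(kit), 0, truth$expr_sd)))
    probs <- w / sum(w)
  }
  counts <- with_seed(substream(truth$seed,
                                paste("counts", fraction, model, capsid,
                                      replicate, sep = "|")),
                      stats::rmultinom(1L, size = truth$depth, prob = probs))
  stats::setNames(as.integer(counts), kit$barcode)
}

#' Synthesize error-bearing amplicon reads from barcode counts
#'
#' Each read is left anchor + barcode + right constant region, truncated to
#' the template read length, with every base independently substituted with
#' probability \code{truth$error_rate} (uniform over the three alternative
#' bases). Read order is shuffled under the run seed; quality strings are
#' constant. The FASTQ header records the true barcode
#' (\code{bc=<barcode>}), which downstream extraction never reads but tests
#' can.
#'
#' @param counts named count vector in kit barcode order.
#' @param kit a [kit_design()].
#' @param template an [amplicon_template()].
#' @param truth a [ground_truth()].
#' @param out output FASTQ path (\code{.gz} to compress).
#' @param seed seed for shuffling and errors (default derived from run seed
#'   and the output file name).
#' @return invisibly, a data frame of \code{read_id}, \code{true_barcode} in
#'   written order.
#' @export
synthesize_reads <- function(counts, kit, template, truth, out,
                             seed = substream(truth$seed,
                                              paste0("reads|",
                                                     basename(out)))) {
  if (length(counts) != nrow(kit))
    stop("counts must align with the kit barcode order")
  bl <- barcode_length(kit)
  L <- template$read_length
  if (L < nchar(template$left_anchor) + bl + 4L)
    stop("read_length too short: barcode would be truncated")
  full <- paste0(template$left_anchor, kit$barcode, template$right_anchor)
  pad <- max(0L, L - min(nchar(full)))
  if (pad > 0L) full <- paste0(full, strrep("A", pad))
  tpl <- substr(full, 1L, L)

  n <- sum(counts)
  truth_bc <- rep(kit$barcode, counts)
  reads <- rep(tpl, counts)
  with_seed(seed, {
    if (n > 1L) {
      perm <- sample.int(n)
      reads <- reads[perm]
      truth_bc <- truth_bc[perm]
    }
    if (truth$error_rate > 0 && n > 0L) {
      hit <- which(stats::runif(n * L) < truth$error_rate)
      if (length(hit)) {
        ri <- (hit - 1L) %/% L + 1L
        pos <- (hit - 1L) %% L + 1L
        bases <- c("A", "C", "G", "T")
        k <- sample.int(3L, length(hit), replace = TRUE)
        # apply errors in rounds so multiple hits in one read all land
        todo <- seq_along(hit)
        while (length(todo)) {
          take <- todo[!duplicated(ri[todo])]
          cur <- match(substr(reads[ri[take]], pos[take], pos[take]), bases)
          alt <- k[take] + (k[take] >= cur)
          str <- reads[ri[take]]
          substr(str, pos[take], pos[take]) <- bases[alt]
          reads[ri[take]] <- str
          todo <- setdiff(todo, take)
        }
      }
    }
  })
  ids <- if (n > 0L) sprintf("sim_%07d bc=%s", seq_len(n), truth_bc)
         else character(0)
  write_fastq(data.frame(read_id = ids, sequence = reads,
                         quality = rep(strrep("I", L), n),
                         stringsAsFactors = FALSE), out)
  invisible(data.frame(read_id = ids, true_barcode = truth_bc,
                       stringsAsFactors = FALSE))
}

#' Default experiment layout
#'
#' The study design of the promoter screen: hiPSC-CM (AAV2, AAV6; n = 4),
#' NRVM (AAV6, AAV9; n = 5), HuH7 (AAV2, AAV6; n = 3), mouse heart and liver
#' (AAV6 n = 8, AAV9 n = 5), rat heart and liver (AAV6 n = 5, AAV9 n = 4),
#' sheep and pig heart (n = 1 per capsid).
#'
#' @return data frame with columns \code{model}, \code{capsid},
#'   \code{n_replicates}.
#' @export
default_layout <- function() {
  rbind(
    data.frame(model = "hiPSC_CM", capsid = c("AAV2", "AAV6"),
               n_replicates = 4L),
    data.frame(model = "NRVM", capsid = c("AAV6", "AAV9"), n_replicates = 5L),
    data.frame(model = "HuH7", capsid = c("AAV2", "AAV6"), n_replicates = 3L),
    data.frame(model = c("mouse_heart", "mouse_liver"), capsid = "AAV6",
               n_replicates = 8L),
    data.frame(model = c("mouse_heart", "mouse_liver"), capsid = "AAV9",
               n_replicates = 5L),
    data.frame(model = c("rat_heart", "rat_liver"), capsid = "AAV6",
               n_replicates = 5L),
    data.frame(model = c("rat_heart", "rat_liver"), capsid = "AAV9",
               n_replicates = 4L),
    data.frame(model = c("sheep_heart", "pig_heart"),
               capsid = rep(c("AAV6", "AAV9"), each = 2L), n_replicates = 1L)
  )
}

#' Simulate an experiment directly at the count level
#'
#' Same generative model as [simulate_experiment()] but skipping read
#' synthesis: returns the barcode x sample count matrix and matching sample
#' sheet (with placeholder read paths) for studies where the sequencing
#' channel itself is not under test, e.g. calibration sweeps.
#'
#' @param kit a [kit_design()].
#' @param truth a [ground_truth()].
#' @param layout data frame (\code{model}, \code{capsid},
#'   \code{n_replicates}).
#' @return list with \code{counts}, \code{samples} and per-capsid
#'   \code{premix} proportion vectors.
#' @export
simulate_count_matrix <- function(kit = default_kit(),
                                  truth = ground_truth(),
                                  layout = default_layout()) {
  rows <- list()
  cols <- list()
  premixes <- list()
  for (cap in unique(layout$capsid)) {
    pm <- simulate_premix(kit, truth, seed = substream(truth$seed,
                                                       paste0("batch|", cap)))
    premixes[[cap]] <- pm
    id <- paste0("premix_", cap)
    cols[[id]] <- with_seed(substream(truth$seed, paste0("premixlib|", cap)),
                            as.integer(stats::rmultinom(1L, truth$depth,
                                                        pm)))
    rows[[length(rows) + 1L]] <-
      data.frame(sample_id = id, model = "premix", capsid = cap,
                 fraction = "premix", replicate = 1L, reads_path = NA_character_,
                 stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(layout))) {
    model <- layout$model[i]; cap <- layout$capsid[i]
    for (r in seq_len(layout$n_replicates[i])) {
      for (frac in c("gDNA", "cDNA")) {
        id <- sprintf("%s_%s_%s_r%d", model, cap, frac, r)
        cols[[id]] <- unname(simulate_sample_counts(kit, truth,
                                                    premixes[[cap]], model,
                                                    frac, r, capsid = cap))
        rows[[length(rows) + 1L]] <-
          data.frame(sample_id = id, model = model, capsid = cap,
                     fraction = frac, replicate = r,
                     reads_path = NA_character_, stringsAsFactors = FALSE)
      }
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- kit$barcode
  list(counts = counts, samples = sample_sheet(do.call(rbind, rows)),
       premix = premixes)
}

#' Simulate a whole competitive-transduction experiment to disk
#'
#' Writes, under \code{outdir}: one premix FASTQ per capsid batch, gDNA and
#' cDNA FASTQs per (model, capsid, replicate), \code{kit.tsv},
#' \code{samples.tsv}, \code{truth.tsv} (activity matrix in long form plus
#' the realised premix proportions) and \code{run_config.txt}. The whole
#' tree is byte-reproducible from the seed.
#'
#' @param kit a [kit_design()]; default [default_kit()].
#' @param truth a [ground_truth()].
#' @param layout data frame (\code{model}, \code{capsid},
#'   \code{n_replicates}); default [default_layout()].
#' @param outdir output directory, created if needed.
#' @param template an [amplicon_template()]; default built from the kit.
#' @param gzip write FASTQ files gzip-compressed.
#' @return invisibly, a list with the validated \code{samples} sheet,
#'   \code{kit}, \code{truth}, per-capsid \code{premix} vectors and
#'   \code{outdir}.
#' @export
simulate_experiment <- function(kit = default_kit(), truth = ground_truth(),
                                layout = default_layout(), outdir,
                                template = amplicon_template(kit),
                                gzip = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop(sprintf("cannot create outdir '%s'", outdir))
  probe <- file.path(outdir, ".write_probe")
  ok <- tryCatch({ file.create(probe, showWarnings = FALSE) },
                 error = function(e) FALSE)
  if (!isTRUE(ok)) stop(sprintf("outdir '%s' is not writable", outdir))
  unlink(probe)

  ext <- if (gzip) ".fastq.gz" else ".fastq"
  rows <- list()
  premixes <- list()
  for (cap in unique(layout$capsid)) {
    pm <- simulate_premix(kit, truth, seed = substream(truth$seed,
                                                       paste0("batch|", cap)))
    premixes[[cap]] <- pm
    pm_counts <- with_seed(substream(truth$seed, paste0("premixlib|", cap)),
                           stats::setNames(as.integer(
                             stats::rmultinom(1L, truth$depth, pm)),
                             kit$barcode))
    f <- file.path(outdir, paste0("premix_", cap, ext))
    synthesize_reads(pm_counts, kit, template, truth, f)
    rows[[length(rows) + 1L]] <-
      data.frame(sample_id = paste0("premix_", cap), model = "premix",
                 capsid = cap, fraction = "premix", replicate = 1L,
                 reads_path = f, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(layout))) {
    model <- layout$model[i]; cap <- layout$capsid[i]
    for (r in seq_len(layout$n_replicates[i])) {
      for (frac in c("gDNA", "cDNA")) {
        cnt <- simulate_sample_counts(kit, truth, premixes[[cap]], model,
                                      frac, r, capsid = cap)
        id <- sprintf("%s_%s_%s_r%d", model, cap, frac, r)
        f <- file.path(outdir, paste0(id, ext))
        synthesize_reads(cnt, kit, template, truth, f)
        rows[[length(rows) + 1L]] <-
          data.frame(sample_id = id, model = model, capsid = cap,
                     fraction = frac, replicate = r, reads_path = f,
                     stringsAsFactors = FALSE)
      }
    }
  }
  sheet <- sample_sheet(do.call(rbind, rows))
  write_kit(kit, file.path(outdir, "kit.tsv"))
  # on disk the sheet refers to reads relative to its own directory, so the
  # tree is relocatable and byte-identical across runs
  rel <- sheet
  rel$reads_path <- basename(rel$reads_path)
  write_sample_sheet(rel, file.path(outdir, "samples.tsv"))

  act <- truth$activity
  tt <- rbind(
    data.frame(kind = "activity",
               name = rep(rownames(act), times = ncol(act)),
               scope = rep(colnames(act), each = nrow(act)),
               value = as.vector(act), stringsAsFactors = FALSE),
    do.call(rbind, lapply(names(premixes), function(cap)
      data.frame(kind = "premix", name = names(premixes[[cap]]), scope = cap,
                 value = as.vector(premixes[[cap]]),
                 stringsAsFactors = FALSE))))
  utils::write.table(tt, file.path(outdir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- c(paste0("seed: ", truth$seed), paste0("depth: ", truth$depth),
           paste0("entry_sd: ", truth$entry_sd),
           paste0("expr_sd: ", truth$expr_sd),
           paste0("premix_concentration: ", truth$premix_concentration),
           paste0("error_rate: ", truth$error_rate),
           paste0("read_length: ", template$read_length),
           paste0("left_anchor: ", template$left_anchor))
  writeLines(cfg, file.path(outdir, "run_config.txt"))
  invisible(list(samples = sheet, kit = kit, truth = truth,
                 premix = premixes, template = template, outdir = outdir))
}
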
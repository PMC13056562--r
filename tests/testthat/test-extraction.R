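make_spec <- function(anchor = "ACGTACGTACGTACGT", ...) {
  anchor_spec(anchor, barcode_length = 6L, ...)
}

test_that("anchor location matches the exhaustive scan oracle", {
  spec <- make_spec()
  a <- spec$left_anchor

  expect_equal(locate_anchor(paste0(a, "AAAAAA", "TTTT"), spec), 1L)

  read <- paste0("GGGGGGG", a, "AAAAAA")
  substr(read, 10L, 10L) <- "T"  # one substitution inside the anchor
  expect_equal(locate_anchor(read, spec), 8L)

  # two exact occurrences: leftmost wins
  expect_equal(locate_anchor(paste0("TT", a, "CC", a), spec), 3L)

  # no qualifying window is a value, not an error
  expect_true(is.na(locate_anchor(strrep("G", 40L), spec)))
  # N counts as a mismatch
  read_n <- paste0(a, "AAAAAA")
  substr(read_n, 3L, 5L) <- "NNN"
  expect_true(is.na(locate_anchor(read_n, make_spec(max_anchor_mismatches = 2))))
  expect_equal(locate_anchor(read_n, make_spec(max_anchor_mismatches = 3)), 1L)

  # randomised agreement with the brute-force oracle, scalar and vector paths
  set.seed(11)
  reads <- rand_seq(300, 28)
  half <- sample(300, 150)  # plant mutated anchors in half the reads
  for (i in half) {
    r <- reads[[i]]
    pos <- sample(28 - 16 + 1, 1)
    aa <- a
    if (i %% 3 == 0) substr(aa, 5, 5) <- "T"
    substr(r, pos, pos + 15) <- aa
    reads[i] <- r
  }
  want <- vapply(reads, bf_locate, integer(1), anchor = a, max_mm = 2L)
  got_scalar <- vapply(reads, locate_anchor, integer(1), spec = spec)
  got_vec <- promEI:::locate_anchor_vec(reads, spec)
  expect_equal(unname(got_scalar), unname(want))
  expect_equal(unname(got_vec), unname(want))
})

test_that("whitelist assignment follows exact-priority, unique-neighbour, ambiguity rules", {
  spec <- make_spec()
  k <- kit_design(c("AAAAAA", "CCCCCC"), c("P1", "P2"),
                  rep("cardiac_specific", 2))
  expect_equal(assign_barcode("AAAAAC", k, spec), "AAAAAA")
  expect_equal(assign_barcode("AAAAAA", k, spec), "AAAAAA")
  expect_equal(assign_barcode("AGGAAC", k, spec), "unmatched")
  expect_equal(assign_barcode("AAAANA", k, spec), "AAAAAA")

  k_tie <- kit_design(c("AAAAAA", "AAAAAT"), c("P1", "P2"),
                      rep("cardiac_specific", 2))
  expect_equal(assign_barcode("AAAAAC", k_tie, spec), "ambiguous")
  # an exact hit wins even with another barcode at distance 1
  expect_equal(assign_barcode("AAAAAT", k_tie, spec), "AAAAAT")

  # randomised agreement with the brute-force whitelist oracle
  set.seed(12)
  wl <- unique(rand_seq(8, 6))
  kk <- kit_design(wl, paste0("P", seq_along(wl)),
                   rep("cardiac_specific", length(wl)))
  obs <- c(wl, rand_seq(300, 6))
  want <- vapply(obs, bf_assign, character(1), whitelist = wl, max_mm = 1L)
  expect_equal(unname(assign_barcode(obs, kk, spec)), unname(want))
  # with mismatches disabled only exact hits survive
  spec0 <- make_spec(max_barcode_mismatches = 0)
  got0 <- assign_barcode(obs, kk, spec0)
  expect_true(all(got0[!obs %in% wl] == "unmatched"))
})

test_that("count_sample is a lossless channel at zero error and keeps its books straight", {
  kit <- default_kit()
  tpl <- amplicon_template(kit)
  tr <- ground_truth(error_rate = 0, depth = 5000, seed = 13L)
  pm <- simulate_premix(kit, tr)
  cnt <- simulate_sample_counts(kit, tr, pm, "hiPSC_CM", "gDNA", 1)
  f <- withr::local_tempfile(fileext = ".fastq")
  synthesize_reads(cnt, kit, tpl, tr, f)
  spec <- anchor_spec(tpl$left_anchor)
  res <- count_sample(f, kit, spec)
  expect_equal(res$stats$assigned_reads, res$stats$total_reads)
  expect_identical(res$counts, cnt)
  expect_equal(sum(res$counts), res$stats$assigned_reads)
  expect_equal(res$stats$anchored_reads,
               res$stats$assigned_reads + res$stats$ambiguous_reads +
                 res$stats$unmatched_reads)

  empty <- withr::local_tempfile(fileext = ".fastq")
  file.create(empty)
  res0 <- count_sample(empty, kit, spec)
  expect_true(all(res0$counts == 0L))
  expect_true(all(unlist(res0$stats) == 0L))
})

test_that("mis-assignment rate under 1% error agrees with the whitelist enumeration oracle", {
  kit <- default_kit()
  tpl <- amplicon_template(kit)
  e <- 0.01
  tr <- ground_truth(error_rate = e, depth = 1e5, seed = 14L)
  pm <- simulate_premix(kit, tr)
  cnt <- simulate_sample_counts(kit, tr, pm, "hiPSC_CM", "gDNA", 1)
  f <- withr::local_tempfile(fileext = ".fastq")
  truth_map <- synthesize_reads(cnt, kit, tpl, tr, f)
  spec <- anchor_spec(tpl$left_anchor)

  # re-extract with per-read truth: which reads landed on the wrong barcode
  fq <- read_fastq(f)
  pos <- promEI:::locate_anchor_vec(fq$sequence, spec)
  ok <- !is.na(pos)
  obs <- substr(fq$sequence[ok], pos[ok] + nchar(spec$left_anchor),
                pos[ok] + nchar(spec$left_anchor) + 5L)
  got <- assign_barcode(obs, kit, spec)
  true_bc <- truth_map$true_barcode[ok]
  assigned <- !got %in% c("ambiguous", "unmatched")
  n_wrong <- sum(got[assigned] != true_bc[assigned])

  # enumeration oracle: P(observed window assigned to a wrong barcode),
  # summing the substitution channel over every 6-mer within distance 2 of
  # the true barcode (3+ errors contribute negligibly at e = 0.01)
  p_wrong_given <- function(bc) {
    chars <- strsplit(bc, "")[[1]]
    bases <- c("A", "C", "G", "T")
    p <- 0
    for (i in 1:6) for (bi in bases[bases != chars[i]]) {
      w1 <- chars; w1[i] <- bi
      for (j in 1:6) {
        if (j < i) next
        if (j == i) {
          w <- paste(w1, collapse = "")
          a <- bf_assign(w, kit$barcode, 1L)
          if (!a %in% c(bc, "ambiguous", "unmatched"))
            p <- p + (e / 3)^1 * (1 - e)^5
        } else {
          for (bj in bases[bases != chars[j]]) {
            w2 <- w1; w2[j] <- bj
            w <- paste(w2, collapse = "")
            a <- bf_assign(w, kit$barcode, 1L)
            if (!a %in% c(bc, "ambiguous", "unmatched"))
              p <- p + (e / 3)^2 * (1 - e)^4
          }
        }
      }
    }
    p
  }
  p_by_bc <- vapply(kit$barcode, p_wrong_given, numeric(1))
  lambda <- sum(p_by_bc * cnt[kit$barcode])
  expect_lt(abs(n_wrong - lambda), 3 * sqrt(lambda) + 3)
})

test_that("raising mismatch tolerances never loses reads", {
  kit <- default_kit()
  tpl <- amplicon_template(kit)
  tr <- ground_truth(error_rate = 0.04, depth = 4000, seed = 15L)
  pm <- simulate_premix(kit, tr)
  cnt <- simulate_sample_counts(kit, tr, pm, "hiPSC_CM", "gDNA", 1)
  f <- withr::local_tempfile(fileext = ".fastq")
  synthesize_reads(cnt, kit, tpl, tr, f)
  prev_anch <- -1L
  for (mm in 0:3) {
    st <- count_sample(f, kit,
                       anchor_spec(tpl$left_anchor,
                                   max_anchor_mismatches = mm))$stats
    expect_gte(st$anchored_reads, prev_anch)
    prev_anch <- st$anchored_reads
  }
  st0 <- count_sample(f, kit,
                      anchor_spec(tpl$left_anchor,
                                  max_barcode_mismatches = 0))$stats
  st1 <- count_sample(f, kit,
                      anchor_spec(tpl$left_anchor,
                                  max_barcode_mismatches = 1))$stats
  expect_gte(st1$assigned_reads + st1$ambiguous_reads,
             st0$assigned_reads + st0$ambiguous_reads)
})

test_that("reverse-complement scanning recovers flipped reads", {
  kit <- default_kit()
  tpl <- amplicon_template(kit)
  tr <- ground_truth(error_rate = 0, depth = 300, seed = 16L)
  pm <- simulate_premix(kit, tr)
  cnt <- simulate_sample_counts(kit, tr, pm, "hiPSC_CM", "gDNA", 1)
  f <- withr::local_tempfile(fileext = ".fastq")
  synthesize_reads(cnt, kit, tpl, tr, f)
  fq <- read_fastq(f)
  fq$sequence <- promEI:::revcomp(fq$sequence)
  fwd <- count_sample(fq, kit, anchor_spec(tpl$left_anchor))
  expect_equal(fwd$stats$anchored_reads, 0L)
  rc <- count_sample(fq, kit,
                     anchor_spec(tpl$left_anchor,
                                 scan_reverse_complement = TRUE))
  expect_identical(rc$counts, cnt)
})
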
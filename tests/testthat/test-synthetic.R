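test_that("premix simulation is seeded, centred on equimolar, and exact in the limit", {
  kit <- default_kit()
  tr_inf <- ground_truth(premix_concentration = Inf)
  expect_equal(unname(simulate_premix(kit, tr_inf)), rep(1 / 18, 18))

  tr <- ground_truth(seed = 9L)
  p1 <- simulate_premix(kit, tr)
  p2 <- simulate_premix(kit, tr)
  expect_identical(p1, p2)
  expect_equal(sum(p1), 1)
  expect_false(identical(p1, simulate_premix(kit, ground_truth(seed = 10L))))

  # Monte-Carlo oracle: mean of many Dirichlet draws is uniform
  draws <- t(vapply(1:10000, function(s)
    simulate_premix(kit, ground_truth(seed = s)), numeric(18)))
  mc_se <- apply(draws, 2, sd) / sqrt(nrow(draws))
  expect_true(all(abs(colMeans(draws) - 1 / 18) <= 3 * mc_se))
})

test_that("count simulation follows the stated generative model", {
  # null model: no noise, equal activities -> cDNA shares match gDNA shares
  kit <- default_kit()
  act <- default_activity(); act[, ] <- 1
  tr <- ground_truth(activity = act, entry_sd = 0, expr_sd = 0,
                     premix_concentration = Inf, depth = 1e5, seed = 2L)
  pm <- simulate_premix(kit, tr)
  g <- simulate_sample_counts(kit, tr, pm, "hiPSC_CM", "gDNA", 1)
  c_ <- simulate_sample_counts(kit, tr, pm, "hiPSC_CM", "cDNA", 1)
  expect_equal(sum(g), 1e5)
  expect_equal(sum(c_), 1e5)
  # both are multinomial around 1/18; 4-SE band since 18 cells are checked
  se <- sqrt((1 / 18) * (17 / 18) / 1e5)
  expect_true(all(abs(g / 1e5 - 1 / 18) <= 4 * se))
  expect_true(all(abs(c_ / 1e5 - 1 / 18) <= 4 * se))

  # two promoters at activities (2, 1): expected cDNA shares (2/3, 1/3)
  k2 <- kit_design(c("AAAAAA", "CCCCCC"), c("P1", "P2"),
                   rep("cardiac_specific", 2))
  a2 <- matrix(c(2, 1), 2, 1, dimnames = list(c("P1", "P2"), "m"))
  t2 <- ground_truth(activity = a2, entry_sd = 0, expr_sd = 0,
                     premix_concentration = Inf, depth = 1e6, seed = 3L)
  pm2 <- simulate_premix(k2, t2)
  cd <- simulate_sample_counts(k2, t2, pm2, "m", "cDNA", 1)
  se2 <- sqrt((2 / 3) * (1 / 3) / 1e6)
  expect_lt(abs(cd[1] / 1e6 - 2 / 3), 3 * se2)

  # depth 0 gives an all-zero vector; unknown model is a hard error
  t0 <- ground_truth(depth = 0, seed = 1L)
  expect_equal(unname(simulate_sample_counts(kit, t0, pm, "NRVM", "gDNA", 1)),
               rep(0L, 18))
  expect_error(simulate_sample_counts(kit, tr, pm, "kidney", "gDNA", 1),
               "no activity column")
})

test_that("gDNA and cDNA of one replicate share the same realised entry vector", {
  kit <- default_kit()
  # entry noise only: expression adds nothing, so cDNA probabilities equal
  # the gDNA probabilities of the same replicate (equal activities)
  act <- default_activity(); act[, ] <- 1
  tr <- ground_truth(activity = act, entry_sd = 0.8, expr_sd = 0,
                     premix_concentration = Inf, depth = 2e5, seed = 4L)
  pm <- simulate_premix(kit, tr)
  g <- simulate_sample_counts(kit, tr, pm, "NRVM", "gDNA", 1)
  c_ <- simulate_sample_counts(kit, tr, pm, "NRVM", "cDNA", 1)
  # entry_sd 0.8 spreads shares over ~5x; agreement implies shared entry
  expect_gt(cor(g, c_), 0.95)
  # a different replicate draws different entry
  g2 <- simulate_sample_counts(kit, tr, pm, "NRVM", "gDNA", 2)
  expect_lt(cor(g, g2), 0.9)
})

test_that("read synthesis is exact at zero error, calibrated at 1%, and seed-stable", {
  kit <- default_kit()
  tpl <- amplicon_template(kit)
  counts <- setNames(integer(18), kit$barcode)
  counts[1L] <- 3L
  tr0 <- ground_truth(error_rate = 0, seed = 5L)
  f <- withr::local_tempfile(fileext = ".fastq")
  synthesize_reads(counts, kit, tpl, tr0, f)
  fq <- read_fastq(f)
  expect_equal(nrow(fq), 3L)
  expect_equal(length(unique(fq$sequence)), 1L)
  al <- nchar(tpl$left_anchor)
  expect_equal(substr(fq$sequence[1], al + 1, al + 6), kit$barcode[1])
  expect_equal(nchar(fq$sequence[1]), tpl$read_length)

  # per-base substitution frequency ~ error_rate (binomial MC oracle)
  tr1 <- ground_truth(error_rate = 0.01, seed = 6L)
  cnt <- setNames(rep(1000L, 18), kit$barcode)
  f2 <- withr::local_tempfile(fileext = ".fastq")
  truth_map <- synthesize_reads(cnt, kit, tpl, tr1, f2)
  fq2 <- read_fastq(f2)
  tpl_of <- function(bc) substr(paste0(tpl$left_anchor, bc,
                                       tpl$right_anchor), 1,
                                tpl$read_length)
  mm <- mapply(function(s, b) bf_hamming(s, tpl_of(b)),
               fq2$sequence, truth_map$true_barcode)
  n_bases <- nrow(fq2) * tpl$read_length
  rate <- sum(mm) / n_bases
  se <- sqrt(0.01 * 0.99 / n_bases)
  expect_lt(abs(rate - 0.01), 3 * se)

  # byte-identical regeneration under the same seed
  f3 <- withr::local_tempfile(fileext = ".fastq")
  synthesize_reads(cnt, kit, tpl, tr1, f3, seed = 123L)
  f4 <- withr::local_tempfile(fileext = ".fastq")
  synthesize_reads(cnt, kit, tpl, tr1, f4, seed = 123L)
  expect_identical(readLines(f3), readLines(f4))

  expect_error(amplicon_template(kit, read_length = 28L), "truncated")
})

test_that("simulate_experiment writes a complete, reproducible directory tree", {
  kit <- default_kit()
  tr <- ground_truth(depth = 400, seed = 8L)
  layout <- data.frame(model = "hiPSC_CM", capsid = "AAV2",
                       n_replicates = 4L)
  d1 <- withr::local_tempdir()
  sim <- simulate_experiment(kit, tr, layout, d1)
  expect_equal(nrow(sim$samples), 9L)  # premix + 4 x (gDNA, cDNA)
  fq <- list.files(d1, pattern = "\\.fastq$")
  expect_length(fq, 9L)
  # FASTQ depth equals the requested depth
  expect_equal(stream_fastq(file.path(d1, fq[1]), function(ch) NULL), 400L)

  # replicate-free layout leaves only the premix library
  d0 <- withr::local_tempdir()
  sim0 <- simulate_experiment(kit, tr,
                              data.frame(model = "hiPSC_CM",
                                         capsid = "AAV2",
                                         n_replicates = 0L), d0)
  expect_equal(sim0$samples$fraction, "premix")

  # same seed, byte-identical tree
  d2 <- withr::local_tempdir()
  simulate_experiment(kit, tr, layout, d2)
  for (f in list.files(d1)) {
    a <- file.path(d1, f); b <- file.path(d2, f)
    expect_identical(readLines(a), readLines(b))
  }

  # truth.tsv carries the activity matrix and realised premix
  tt <- read.delim(file.path(d1, "truth.tsv"))
  expect_setequal(unique(tt$kind), c("activity", "premix"))
  pm <- tt[tt$kind == "premix", ]
  expect_equal(sum(pm$value), 1, tolerance = 1e-12)
})
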
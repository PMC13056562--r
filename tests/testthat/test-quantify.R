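test_that("pseudocounted proportions match hand arithmetic", {
  expect_equal(proportions(c(1, 1, 1, 1), 0), rep(0.25, 4))
  expect_equal(proportions(c(3, 1), 0), c(0.75, 0.25))
  expect_equal(proportions(c(0, 4), 0.5), c(0.1, 0.9))
  expect_error(proportions(c(0, 0), 0), "empty sample")
  expect_error(proportions(c(-1, 2)), "nonnegative")
})

test_that("premix normalisation cancels the pool and renormalises to shares", {
  expect_equal(premix_normalize(c(0.3, 0.7), c(0.5, 0.5)), c(0.3, 0.7))
  expect_equal(premix_normalize(c(0.5, 0.5), c(0.25, 0.75)), c(0.75, 0.25))
  p <- c(0.2, 0.3, 0.5)
  expect_equal(premix_normalize(p, p), rep(1 / 3, 3))
  expect_error(premix_normalize(c(0.5, 0.5), c(1)), "length")
  expect_error(premix_normalize(c(0.5, 0.5), c(0, 1)), "positive")
})

test_that("expression index is the RNA/DNA share ratio and is monotone", {
  expect_equal(expression_index(c(0.5, 0.5), c(0.5, 0.5)), c(1, 1))
  expect_equal(expression_index(c(0.8, 0.2), c(0.5, 0.5)), c(1.6, 0.4))
  # doubling one barcode's RNA share (then renormalising) raises its EI
  dna <- c(0.4, 0.6)
  rna <- c(0.3, 0.7)
  rna2 <- c(0.6, 0.7) / 1.3
  expect_gt(expression_index(rna2, dna)[1], expression_index(rna, dna)[1])
})

test_that("promoter aggregation modes agree where they must", {
  k <- tiny_kit()
  ei <- setNames(c(1.6, 1.4), k$barcode)
  expect_equal(unname(aggregate_promoters(ei, k, "barcode_mean")),
               c(1.6, 1.4))
  k2 <- kit_design(c("AAAAAA", "ACCCCA", "GGGGGG", "GTTTTG"),
                   c("P1", "P1", "P2", "P2"), rep("cardiac_specific", 4))
  ei2 <- setNames(c(1.6, 1.4, 0.5, 0.7), k2$barcode)
  expect_equal(unname(aggregate_promoters(ei2, k2, "barcode_mean")),
               c(1.5, 0.6))
  # count_pooled recomputes the chain on summed counts
  cnts <- list(premix = setNames(c(100, 100, 100, 100), k2$barcode),
               gDNA = setNames(c(50, 50, 100, 100), k2$barcode),
               cDNA = setNames(c(100, 100, 50, 50), k2$barcode))
  pooled <- aggregate_promoters(NULL, k2, "count_pooled", counts = cnts,
                                pseudocount = 0)
  p_pre <- c(0.5, 0.5)
  Rd <- premix_normalize(c(100, 200) / 300, p_pre)
  Rr <- premix_normalize(c(200, 100) / 300, p_pre)
  expect_equal(unname(pooled), unname(Rr / Rd))
  expect_error(aggregate_promoters(NULL, k2, "count_pooled"), "needs")
})

test_that("the EI chain is invariant to library-size rescaling (a = 0)", {
  set.seed(21)
  pre <- rpois(6, 200) + 1
  g <- rpois(6, 150) + 1
  c_ <- rpois(6, 150) + 1
  chain <- function(pre, g, c_) {
    p0 <- proportions(pre, 0)
    expression_index(premix_normalize(proportions(c_, 0), p0),
                     premix_normalize(proportions(g, 0), p0))
  }
  expect_equal(chain(pre, g, c_), chain(pre * 7L, g * 3L, c_ * 11L))
})

test_that("ei_table computes per-replicate promoter EI with shares summing to 1", {
  kit <- default_kit()
  tr <- ground_truth(depth = 5000, seed = 22L)
  layout <- data.frame(model = c("hiPSC_CM", "HuH7"), capsid = "AAV2",
                       n_replicates = c(3L, 2L))
  cm <- simulate_count_matrix(kit, tr, layout)
  for (mode in c("barcode_mean", "count_pooled")) {
    ei <- ei_table(cm$counts, cm$samples, kit, mode = mode)
    expect_s3_class(ei, "ei_table")
    expect_equal(nrow(ei), 5L * 8L)
    sums <- tapply(ei$ei_proportion,
                   paste(ei$model, ei$capsid, ei$replicate), sum)
    expect_equal(as.vector(sums), rep(1, 5), tolerance = 1e-12)
    expect_true(all(ei$ei > 0))
  }
  # with one barcode per promoter the two modes coincide at a = 0
  k1 <- kit_design(c("AAAAAA", "CCCCCC", "GGGGGG"), c("P1", "P2", "P3"),
                   c("ubiquitous", "cardiac_specific", "liver_specific"))
  a1 <- matrix(c(3, 2, 1), 3, 1, dimnames = list(c("P1", "P2", "P3"), "m"))
  t1 <- ground_truth(activity = a1, depth = 4000, seed = 23L)
  cm1 <- simulate_count_matrix(k1, t1,
                               data.frame(model = "m", capsid = "AAV2",
                                          n_replicates = 2L))
  e_bm <- ei_table(cm1$counts, cm1$samples, k1, pseudocount = 0,
                   mode = "barcode_mean")
  e_cp <- ei_table(cm1$counts, cm1$samples, k1, pseudocount = 0,
                   mode = "count_pooled")
  expect_equal(e_bm$ei, e_cp$ei, tolerance = 1e-12)

  # EI tables round-trip through TSV
  f <- withr::local_tempfile(fileext = ".tsv")
  ei <- ei_table(cm$counts, cm$samples, kit)
  write_ei(ei, f)
  back <- read_ei(f)
  expect_equal(back$ei, ei$ei, tolerance = 1e-10)
})

test_that("zero-noise simulation recovers activity shares through the full chain", {
  k2 <- kit_design(c("AAAAAA", "CCCCCC"), c("P1", "P2"),
                   rep("cardiac_specific", 2))
  a2 <- matrix(c(4, 1), 2, 1, dimnames = list(c("P1", "P2"), "m"))
  tz <- ground_truth(activity = a2, entry_sd = 0, expr_sd = 0,
                     premix_concentration = Inf, error_rate = 0,
                     depth = 1e6, seed = 24L)
  cm <- simulate_count_matrix(k2, tz,
                              data.frame(model = "m", capsid = "AAV2",
                                         n_replicates = 1L))
  ei <- ei_table(cm$counts, cm$samples, k2)
  expect_equal(ei$ei_proportion[ei$promoter == "P1"], 0.8, tolerance = 0.01)
  expect_equal(ei$ei_proportion[ei$promoter == "P2"], 0.2, tolerance = 0.04)
})
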
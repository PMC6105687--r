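test_that("CCF formula reproduces hand-computed values", {
  seg <- data.frame(chrom = "1", start = 1L, end = 1e6L, major = 1L,
                    minor = 1L)
  # diploid clonal identity: vaf 0.5, purity 1 -> ccf 1
  m <- data.frame(chrom = "1", pos = 100L, ref_count = 50L, alt_count = 50L)
  cc <- compute_ccf(m, seg, purity = 1, multiplicity = 1L)
  expect_equal(cc$ccf, 1)
  # vaf 0 -> ccf 0
  m0 <- data.frame(chrom = "1", pos = 100L, ref_count = 80L, alt_count = 0L)
  expect_equal(compute_ccf(m0, seg, purity = 1, multiplicity = 1L)$ccf, 0)
  # vaf 0.4, purity 0.8, CNt 3, m 2 -> 0.4 * (2.4 + 0.4) / 1.6 = 0.7
  seg3 <- data.frame(chrom = "1", start = 1L, end = 1e6L, major = 2L,
                     minor = 1L)
  m4 <- data.frame(chrom = "1", pos = 100L, ref_count = 60L, alt_count = 40L)
  cc4 <- compute_ccf(m4, seg3, purity = 0.8, multiplicity = 2L)
  expect_equal(cc4$ccf, 0.7, tolerance = 1e-12)
})

test_that("CCF estimation flags clipping and zero depth, errors off-segment", {
  seg <- data.frame(chrom = "1", start = 1L, end = 1000L, major = 1L,
                    minor = 1L)
  m <- data.frame(chrom = "1", pos = 100L, ref_count = 0L, alt_count = 100L)
  cc <- compute_ccf(m, seg, purity = 0.5, multiplicity = 1L)
  expect_true(cc$ccf_clipped)
  expect_equal(cc$ccf, 1.5)
  m0 <- data.frame(chrom = "1", pos = 100L, ref_count = 0L, alt_count = 0L)
  expect_message(cc0 <- compute_ccf(m0, seg, purity = 1), "zero depth")
  expect_true(cc0$excluded)
  expect_true(is.na(cc0$ccf))
  m_off <- data.frame(chrom = "1", pos = 5000L, ref_count = 10L,
                      alt_count = 10L)
  expect_error(compute_ccf(m_off, seg, purity = 1), "1:5000")
})

test_that("multiplicity is the nearest expected VAF with ties toward 1", {
  expect_equal(estimate_multiplicity(0.5, 2, 1, 1), 1L)
  # expected VAFs 1/3 (m=1) vs 2/3 (m=2): vaf 0.66 is closer to 2/3
  expect_equal(estimate_multiplicity(0.66, 3, 2, 1), 2L)
  # exact tie at vaf 0.75 between m=1 (0.5) and m=2 (1.0): pick m=1
  expect_equal(estimate_multiplicity(0.75, 2, 2, 1), 1L)
})

test_that("DP clustering recovers a single clonal cluster", {
  set.seed(41)
  sim <- sim_dp_input(300, 1.0, 1.0)
  dp <- dp_cluster_2d(sim$input, seed = 5)
  expect_equal(nrow(dp$clusters), 1)
  expect_equal(dp$clusters$center_smm, 1, tolerance = 0.03)
  expect_equal(dp$clusters$center_mm, 1, tolerance = 0.03)
})

test_that("DP clustering separates two planted clusters (ARI >= 0.95)", {
  skip_if_not_installed("mclust")
  set.seed(42)
  sim <- sim_dp_input(c(150, 150), c(1, 0.6), c(1, 0.05))
  dp <- dp_cluster_2d(sim$input, seed = 9)
  expect_equal(nrow(dp$clusters), 2)
  expect_gte(mclust::adjustedRandIndex(dp$hard_assignment, sim$truth), 0.95)
  # assignment mass is conserved
  expect_equal(unname(rowSums(dp$assignments)), rep(1, 300),
               tolerance = 1e-9)
  expect_lte(nrow(dp$clusters), 30)
})

test_that("DP input drops zero-depth mutations and demands 20 usable ones", {
  set.seed(43)
  sim <- sim_dp_input(30, 1, 1)
  sim$input$depth_smm[1] <- 0
  expect_error(dp_cluster_2d(sim$input), "positive depth")
  small <- sim$input[1:10, ]
  expect_error(dp_cluster_2d(small), "at least 20")
})

test_that("dp_input assembles zeta from copy number and purity", {
  seg <- data.frame(chrom = "1", start = 1L, end = 1e6L, major = 1L,
                    minor = 1L)
  mut <- data.frame(chrom = "1", pos = c(10L, 20L),
                    ref_count_smm = c(50L, 60L), alt_count_smm = c(50L, 0L),
                    ref_count_mm = c(40L, 30L), alt_count_mm = c(60L, 30L))
  inp <- dp_input(mut, seg, seg, 0.8, 1.0)
  expect_equal(inp$zeta_smm, rep(0.8 / (0.8 * 2 + 0.4), 2))
  expect_equal(inp$zeta_mm, rep(0.5, 2))
  expect_equal(attr(inp, "n_dropped"), 0L)
})

test_that("CCF estimation inverts the generative model (small bias at high depth)", {
  set.seed(44)
  seg <- data.frame(chrom = "1", start = 1L, end = 1e7L, major = 2L,
                    minor = 1L)
  purity <- 0.8
  ccf_true <- 0.65
  n <- 300
  zeta <- expected_vaf(purity, 3, 2)
  depth <- rpois(n, 10000)
  alt <- rbinom(n, depth, ccf_true * zeta)
  m <- data.frame(chrom = "1", pos = seq_len(n) + 10L,
                  ref_count = depth - alt, alt_count = alt)
  cc <- compute_ccf(m, seg, purity, multiplicity = 2L)
  expect_lt(abs(mean(cc$ccf) - ccf_true), 0.01)
})
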
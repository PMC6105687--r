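diploid_seg <- data.frame(chrom = c("1", "2"), start = 1L, end = 1e8L,
                          major = 1L, minor = 1L)

rr_row <- function(pos1 = 1000L, pos2 = 50000L, chrom1 = "1", chrom2 = "1",
                   support = 10L, total = 40L, sv_type = "deletion",
                   strand1 = "+", strand2 = "-") {
  data.frame(chrom1 = chrom1, pos1 = pos1, strand1 = strand1,
             chrom2 = chrom2, pos2 = pos2, strand2 = strand2,
             sv_type = sv_type, support_reads = support, total_reads = total)
}

test_that("adjusted clonal fraction reproduces hand-computed values", {
  # diploid clonal identity: purity 1, CN 2, vaf 0.5 -> fraction 1
  a <- adjusted_fraction(rr_row(support = 30L, total = 60L), diploid_seg, 1)
  expect_equal(a$adjusted_fraction, 1)
  # purity 0.8, CN 2, raw 0.2 -> 0.2 * 2 / 0.8 = 0.5
  a2 <- adjusted_fraction(rr_row(support = 8L, total = 40L), diploid_seg, 0.8)
  expect_equal(a2$adjusted_fraction, 0.5, tolerance = 1e-12)
  # zero support -> fraction 0
  a3 <- adjusted_fraction(rr_row(support = 0L), diploid_seg, 0.9)
  expect_equal(a3$adjusted_fraction, 0)
})

test_that("diploid identity holds for all raw VAFs at purity 1", {
  set.seed(71)
  for (i in 1:10) {
    tot <- sample(20:80, 1)
    sup <- sample(0:tot, 1)
    a <- adjusted_fraction(rr_row(support = sup, total = tot), diploid_seg, 1)
    expect_equal(a$adjusted_fraction, min(2 * sup / tot, 1.5))
  }
})

test_that("zero total reads are skipped and missing segments error", {
  expect_message(
    a <- adjusted_fraction(rr_row(support = 0L, total = 0L), diploid_seg, 1),
    "skipped")
  expect_true(a$skipped)
  expect_true(is.na(a$adjusted_fraction))
  expect_error(
    adjusted_fraction(rr_row(chrom2 = "9"), diploid_seg, 1),
    "no covering segment")
})

test_that("breakpoint copy number uses the configured summary", {
  seg <- data.frame(chrom = "1", start = c(1L, 40000L), end = c(39999L, 1e8L),
                    major = c(1L, 3L), minor = c(1L, 1L))
  r <- rr_row(pos1 = 1000L, pos2 = 50000L, support = 10L, total = 40L)
  expect_equal(adjusted_fraction(r, seg, 1)$cn_bar, 3)      # mean of 2 and 4
  expect_equal(adjusted_fraction(r, seg, 1, "min")$cn_bar, 2)
  expect_equal(adjusted_fraction(r, seg, 1, "max")$cn_bar, 4)
})

test_that("timepoint matching respects the slop threshold", {
  smm <- rr_row()
  mm499 <- rr_row(pos1 = 1000L + 499L, pos2 = 50000L)
  mm501 <- rr_row(pos1 = 1000L + 501L, pos2 = 50000L)
  m1 <- match_across_timepoints(smm, mm499)
  expect_equal(nrow(m1$matched), 1)
  m2 <- match_across_timepoints(smm, mm501)
  expect_equal(nrow(m2$matched), 0)
  expect_equal(nrow(m2$private_smm), 1)
  expect_equal(nrow(m2$private_mm), 1)
  # type and strand must agree too
  mm_type <- rr_row(sv_type = "inversion", strand1 = "+", strand2 = "+")
  expect_equal(nrow(match_across_timepoints(smm, mm_type)$matched), 0)
})

test_that("matching is symmetric: swapping timepoints transposes pairs and negates deltas", {
  set.seed(72)
  smm <- do.call(rbind, lapply(1:5, function(i) {
    rr_row(pos1 = as.integer(i * 1e6), pos2 = as.integer(i * 1e6 + 5e4),
           support = sample(5:20, 1))
  }))
  mm <- smm
  mm$pos1 <- mm$pos1 + sample(-300:300, 5)
  mm$pos2 <- mm$pos2 + sample(-300:300, 5)
  a1 <- adjusted_fraction(smm, diploid_seg, 0.9)
  a2 <- adjusted_fraction(mm, diploid_seg, 0.8)
  f <- match_across_timepoints(a1, a2)
  r <- match_across_timepoints(a2, a1)
  expect_equal(nrow(f$matched), nrow(r$matched))
  expect_equal(sort(f$matched$delta_fraction), sort(-r$matched$delta_fraction))
})

test_that("a planted subclonal-to-clonal sweep is recovered in the delta", {
  set.seed(73)
  n <- 40
  purity <- 0.9
  frac <- c(smm = 0.1, mm = 0.9)
  raw <- frac * purity / (purity * 2 + (1 - purity) * 2)
  tot1 <- rpois(n, 100); tot2 <- rpois(n, 100)
  smm <- do.call(rbind, lapply(1:n, function(i) {
    rr_row(pos1 = as.integer(i * 1e6), pos2 = as.integer(i * 1e6 + 5e4),
           support = rbinom(1, tot1[i], raw["smm"]), total = tot1[i])
  }))
  mm <- smm
  mm$support_reads <- rbinom(n, tot2, raw["mm"])
  mm$total_reads <- tot2
  a1 <- adjusted_fraction(smm, diploid_seg, purity)
  a2 <- adjusted_fraction(mm, diploid_seg, purity)
  m <- match_across_timepoints(a1, a2)
  expect_equal(nrow(m$matched), n)
  expect_equal(mean(m$matched$delta_fraction), 0.8, tolerance = 0.05)
})
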
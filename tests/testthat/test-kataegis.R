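test_that("kataegis detection finds planted clusters and nothing else", {
  expect_equal(nrow(detect_kataegis(data.frame(chrom = character(0),
                                               pos = integer(0)))), 0)
  set.seed(61)
  cluster_pos <- sort(sample(2000000:2000500, 8))
  background <- seq(1e5, by = 5e4, length.out = 50)
  background <- background[background < 2e6 - 1e4 | background > 2.1e6]
  m <- data.frame(chrom = "1", pos = c(background, cluster_pos))
  regs <- detect_kataegis(m)
  expect_equal(nrow(regs), 1)
  expect_equal(regs$n_mutations, 8)
  expect_equal(regs$start, min(cluster_pos))
  expect_equal(regs$end, max(cluster_pos))
  expect_lte(regs$mean_imd, 1000)
})

test_that("sparse or short runs do not qualify", {
  m <- data.frame(chrom = "1", pos = seq(1e5, by = 1e4, length.out = 5))
  expect_equal(nrow(detect_kataegis(m)), 0)
  # five tightly spaced mutations are below the six-mutation minimum
  m2 <- data.frame(chrom = "1", pos = 1000 + c(0, 50, 100, 150, 200))
  expect_equal(nrow(detect_kataegis(m2)), 0)
})

test_that("detection is translation-invariant", {
  set.seed(62)
  pos <- c(sort(sample(50000:50600, 9)), seq(2e5, by = 6e4, length.out = 30))
  m <- data.frame(chrom = "1", pos = pos)
  r1 <- detect_kataegis(m)
  shift <- 123457L
  r2 <- detect_kataegis(data.frame(chrom = "1", pos = pos + shift))
  expect_equal(r2$start, r1$start + shift)
  expect_equal(r2$end, r1$end + shift)
  expect_equal(r2$n_mutations, r1$n_mutations)
})

test_that("IG annotation requires a one-base overlap", {
  ig <- ig_intervals()
  regs <- data.frame(
    chrom = c("14", "5", "14", "14"),
    start = c(106500000L, 106500000L, 106032514L, 107288052L),
    end = c(106500800L, 106500800L, 106032613L, 107288900L),
    n_mutations = 8L, mean_imd = 100)
  a <- annotate_ig(regs, ig)
  # inside IGH; wrong chromosome; abutting with zero overlap; past the end
  expect_equal(a$is_IG, c(TRUE, FALSE, FALSE, FALSE))
  # one-base overlap at the boundary counts
  regs2 <- data.frame(chrom = "14", start = 106032514L, end = 106032614L,
                      n_mutations = 8L, mean_imd = 100)
  expect_true(annotate_ig(regs2, ig)$is_IG)
})

test_that("planted breakpoint association yields small p; absent rearrangements are untestable", {
  set.seed(63)
  chrom_lengths <- c(`1` = 1e8, `2` = 1e8)
  regs <- data.frame(chrom = rep(c("1", "2"), each = 3),
                     start = as.integer(seq(1e7, 9e7, length.out = 3)),
                     end = as.integer(seq(1e7, 9e7, length.out = 3)) + 1000L)
  near <- function(p) as.integer(p + sample(100:10000, length(p), TRUE))
  rr <- data.frame(chrom1 = regs$chrom, pos1 = near(regs$end),
                   chrom2 = regs$chrom, pos2 = near(regs$end + 2e4),
                   sv_type = "deletion")
  pt <- proximity_test(regs, rr, chrom_lengths, n_permutations = 1000,
                       seed = 3)
  expect_true(pt$testable)
  expect_lte(pt$p_value, 0.01)
  expect_gt(pt$p_value, 0)
  # reproducible given the seed
  pt2 <- proximity_test(regs, rr, chrom_lengths, n_permutations = 1000,
                        seed = 3)
  expect_equal(pt$p_value, pt2$p_value)
  expect_equal(pt$null_quantiles, pt2$null_quantiles)

  nt <- proximity_test(regs, rr[0, ], chrom_lengths)
  expect_false(nt$testable)
  nt2 <- proximity_test(regs[0, ], rr, chrom_lengths)
  expect_false(nt2$testable)
})

test_that("kataegis-restricted extraction recovers a single planted process", {
  set.seed(64)
  L <- 400000
  g <- make_genome(`1` = paste(sample(c("A", "C", "G", "T"), L, TRUE),
                               collapse = ""))
  P <- bundled_signatures(include_caid = TRUE)
  classes <- context_classes()
  # 30 planted regions, members drawn 100% from the canonical-AID process
  regions <- data.frame(chrom = "1",
                        start = as.integer(seq(5000, L - 6000,
                                               length.out = 30)))
  regions$end <- regions$start + 999L
  regions$is_IG <- rep(c(TRUE, FALSE), 15)
  muts <- list()
  for (q in seq_len(nrow(regions))) {
    lab <- sample(classes, 8, replace = TRUE, prob = P["c_aid", ])
    pc <- smmevo:::parse_class(lab)
    pos <- smmevo:::place_in_interval(g[[1]], "1", regions$start[q],
                                      regions$end[q], pc$ctx)
    tri <- substring(as.character(g[[1]]), pos - 1, pos + 1)
    centre <- substr(tri, 2, 2)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    flip <- centre %in% c("A", "G")
    muts[[q]] <- data.frame(chrom = "1", pos = pos,
                            ref = ifelse(flip, comp[pc$ref], pc$ref),
                            alt = ifelse(flip, comp[pc$alt], pc$alt))
  }
  muts <- do.call(rbind, muts)
  ks <- kataegis_signatures(muts, regions, g, k_range = 1:2,
                            n_bootstrap = 20, seed = 7)
  expect_true(ks$extractable)
  expect_equal(ks$result$selected_k, 1)
  expect_gt(smmevo:::cosine_similarity(ks$result$catalog[1, ], P["c_aid", ]),
            0.95)
  expect_equal(sum(ks$ig_exposures), ks$n_pooled, tolerance = 1)
  # too few pooled members -> explicit not-extractable result
  few <- kataegis_signatures(muts[1:50, ], regions, g)
  expect_false(few$extractable)
})
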
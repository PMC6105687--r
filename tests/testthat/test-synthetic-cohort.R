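test_that("configuration invariants are enforced", {
  expect_error(small_config(subclone_tree = data.frame(
    clone = "c1", ccf_smm = 1, ccf_mm = 1, mutation_fraction = 0.9),
    signature_mixtures = rbind(c1 = c(apobec = 1))),
    "sum to 1")
  expect_error(small_config(subclone_tree = data.frame(
    clone = "c1", ccf_smm = 1.2, ccf_mm = 1, mutation_fraction = 1),
    signature_mixtures = rbind(c1 = c(apobec = 1))),
    "CCFs")
  expect_error(small_config(signature_mixtures = rbind(
    clonal = c(not_a_process = 1),
    disappearing = c(apobec = 1),
    appearing = c(apobec = 1))),
    "unknown process")
  expect_error(small_config(purity_range = c(0, 0.9)), "purity")
  expect_error(simulation_config(
    chromosome_lengths = c(`1` = 5000), kataegis_span = 1000,
    ig_intervals = data.frame(locus = "x", chrom = "1", start = 1L,
                              end = 2000L)),
    "10x the kataegis span")
})

test_that("generation is deterministic: identical seeds give byte-identical fixtures", {
  cfg <- small_config(seed = 9, n_patients = 1, n_mut = c(150L, 200L),
                      n_kataegis = 2L, n_rearrangements = 5L)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture(g1, d1)
  write_fixture(g2, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
})

test_that("clonal diploid mutations at purity 1 have mean VAF 1/2", {
  cfg <- small_config(
    seed = 10, n_patients = 1, n_mut = c(2500L, 2500L), depth = 100,
    purity_range = c(1, 1),
    subclone_tree = data.frame(clone = "clonal", ccf_smm = 1, ccf_mm = 1,
                               mutation_fraction = 1),
    signature_mixtures = rbind(clonal = c(apobec = 0.5, nc_aid = 0.5)),
    n_kataegis = 0L, n_rearrangements = 0L)
  g <- generate_cohort(cfg)
  m <- g$cohort$mutations
  vaf <- m$alt_count_smm / (m$ref_count_smm + m$alt_count_smm)
  expect_gte(nrow(m), 2000)
  expect_lt(abs(mean(vaf, na.rm = TRUE) - 0.5), 0.02)
})

test_that("a pure single-process cohort reproduces that process's 96-class spectrum", {
  cfg <- small_config(
    seed = 11, n_patients = 1, n_mut = c(5000L, 5000L),
    subclone_tree = data.frame(clone = "clonal", ccf_smm = 1, ccf_mm = 1,
                               mutation_fraction = 1),
    signature_mixtures = rbind(clonal = c(apobec = 1)),
    n_kataegis = 0L, n_rearrangements = 0L)
  g <- generate_cohort(cfg)
  mat <- build_context_matrix(
    cbind(g$cohort$mutations, sample_id = "P01"), g$cohort$genome)
  p_hat <- mat[1, ] / sum(mat[1, ])
  p <- bundled_signatures()["apobec", ]
  se <- sqrt(p * (1 - p) / sum(mat[1, ]))
  # multinomial sampling: jointly, a few of the 96 classes are expected to
  # stray past 3 SE; none should get anywhere near 5 SE
  z <- abs(p_hat - p) / se
  expect_lte(sum(z > 3), 3)
  expect_true(all(z <= 5))
  expect_gt(smmevo:::cosine_similarity(p_hat, p), 0.99)
})

test_that("empirical VAF concentrates on the copy-number expectation at high depth", {
  cfg <- small_config(
    seed = 12, n_patients = 1, n_mut = c(3000L, 3000L), depth = 10000,
    purity_range = c(0.8, 0.8),
    subclone_tree = data.frame(clone = "clonal", ccf_smm = 1, ccf_mm = 1,
                               mutation_fraction = 1),
    signature_mixtures = rbind(clonal = c(apobec = 1)),
    n_kataegis = 0L, n_rearrangements = 0L,
    cn_events = data.frame(chrom = "2", start = 1L, end = 3000000L,
                           major = 2L, minor = 1L))
  g <- generate_cohort(cfg)
  m <- g$cohort$mutations
  vaf <- m$alt_count_smm / (m$ref_count_smm + m$alt_count_smm)
  rho <- 0.8
  exp_diploid <- rho / (rho * 2 + (1 - rho) * 2)
  exp_tri <- rho / (rho * 3 + (1 - rho) * 2)
  dip <- m$chrom != "2"
  expect_lt(abs(mean(vaf[dip]) - exp_diploid), 0.005)
  expect_lt(abs(mean(vaf[!dip]) - exp_tri), 0.005)
})

test_that("written fixtures list every file and re-read equal to memory", {
  cfg <- small_config(seed = 13, n_patients = 1, n_mut = c(200L, 250L),
                      n_kataegis = 2L, n_rearrangements = 8L)
  g <- generate_cohort(cfg)
  d <- withr::local_tempdir()
  man <- write_fixture(g, d)
  expect_equal(sum(man$type == "vcf"), 2)
  expect_equal(sum(man$type == "bedpe"), 2)
  expect_equal(sum(man$type == "segments"), 2)
  expect_equal(man$n_records[man$type == "vcf"],
               rep(nrow(g$cohort$mutations), 2))
  rt <- read_cohort(d)
  key <- function(x) x[order(x$patient, x$chrom, x$pos), ]
  m1 <- key(g$cohort$mutations); m2 <- key(rt$mutations)
  rownames(m1) <- rownames(m2) <- NULL
  m1$chrom <- as.character(m1$chrom)
  expect_equal(m2[, names(m1)], m1, ignore_attr = TRUE)
  rkey <- function(x) x[order(x$chrom1, x$pos1, x$chrom2, x$pos2), ]
  r1 <- rkey(g$cohort$rearrangements); r2 <- rkey(rt$rearrangements)
  rownames(r1) <- rownames(r2) <- NULL
  expect_equal(r2[, names(r1)], r1, ignore_attr = TRUE)
  expect_identical(as.character(rt$genome), as.character(g$cohort$genome))
  expect_equal(rt$purity$acf, g$cohort$purity$acf, tolerance = 1e-9)
})

test_that("a mutation-free cohort still writes schema-valid zero-record files", {
  cfg <- small_config(seed = 14, n_patients = 1, n_mut = c(0L, 0L),
                      n_kataegis = 0L, n_rearrangements = 0L)
  g <- generate_cohort(cfg)
  expect_equal(nrow(g$cohort$mutations), 0)
  d <- withr::local_tempdir()
  man <- write_fixture(g, d)
  expect_true(all(man$n_records[man$type %in% c("vcf", "bedpe")] == 0))
  m <- read_mutations(file.path(d, "P01_smm.vcf"), "P01", "SMM")
  expect_equal(nrow(m), 0)
  r <- read_rearrangements(file.path(d, "P01_smm.bedpe"), "P01", "SMM")
  expect_equal(nrow(r), 0)
})

test_that("planted kataegis regions hold the configured mutation load", {
  cfg <- small_config(seed = 15, n_patients = 1, n_mut = c(300L, 300L),
                      n_kataegis = 4L, kataegis_n_mutations = 8L,
                      n_rearrangements = 0L)
  g <- generate_cohort(cfg)
  kat <- g$truth$kataegis
  expect_equal(nrow(kat), 4)
  m <- g$cohort$mutations
  for (q in seq_len(nrow(kat))) {
    inside <- m$chrom == kat$chrom[q] & m$pos >= kat$start[q] &
      m$pos <= kat$end[q]
    expect_gte(sum(inside), 8)
  }
  # disjoint per chromosome
  for (ch in unique(kat$chrom)) {
    k <- kat[kat$chrom == ch, ]
    k <- k[order(k$start), ]
    if (nrow(k) > 1) expect_true(all(k$start[-1] > k$end[-nrow(k)]))
  }
})
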
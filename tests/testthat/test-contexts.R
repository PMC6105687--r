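test_that("pyrimidine-context classification maps forward and reverse strands", {
  #           123456789
  g <- make_genome(`1` = "TACAGTGCA")
  # positions 2-4 spell ACA; C>T at pos 3
  m <- data.frame(chrom = "1", pos = 3, ref = "C", alt = "T")
  expect_equal(as.character(classify_mutations(m, g)), "A[C>T]A")
  # positions 6-8 spell TGC; G>A at pos 7 reverse-complements to G[C>T]A
  m2 <- data.frame(chrom = "1", pos = 7, ref = "G", alt = "A")
  expect_equal(as.character(classify_mutations(m2, g)), "G[C>T]A")
})

test_that("classification rejects invalid alleles and mismatched references", {
  g <- make_genome(`1` = "TACAGTGCA")
  expect_error(classify_mutations(
    data.frame(chrom = "1", pos = 3, ref = "C", alt = "C"), g), "differ")
  expect_error(classify_mutations(
    data.frame(chrom = "1", pos = 3, ref = "G", alt = "A"), g),
    "reference mismatch at 1:3")
  expect_error(classify_mutations(
    data.frame(chrom = "1", pos = 1, ref = "T", alt = "A"), g),
    "chromosome end")
})

test_that("contexts containing N are excluded with a logged count", {
  g <- make_genome(`1` = "TANAGTGCA")
  m <- data.frame(chrom = "1", pos = c(2, 7), ref = c("A", "G"),
                  alt = c("G", "A"))
  expect_message(lab <- classify_mutations(m, g), "1 mutation")
  expect_true(is.na(lab[1]))
  expect_false(is.na(lab[2]))
  expect_equal(attr(lab, "n_excluded"), 1L)
})

test_that("classification is strand-involutive", {
  set.seed(42)
  L <- 2000
  fwd <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  rev <- paste(rev(strsplit(chartr("ACGT", "TGCA", fwd), "")[[1]]),
               collapse = "")
  g <- make_genome(`1` = fwd)
  g_rc <- make_genome(`1` = rev)
  pos <- sample(2:(L - 1), 100)
  ref <- substring(fwd, pos, pos)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1))
  lab_fwd <- classify_mutations(
    data.frame(chrom = "1", pos = pos, ref = ref, alt = alt), g)
  lab_rc <- classify_mutations(
    data.frame(chrom = "1", pos = L - pos + 1,
               ref = comp[ref], alt = comp[alt]), g_rc)
  expect_equal(as.character(lab_fwd), as.character(lab_rc))
})

test_that("context matrices always have exactly 96 canonical columns", {
  expect_length(context_classes(), 96)
  expect_equal(context_classes()[1], "A[C>A]A")
  expect_equal(context_classes()[96], "T[T>G]T")
  set.seed(7)
  L <- 5000
  g <- make_genome(`1` = paste(sample(c("A", "C", "G", "T"), L, TRUE),
                               collapse = ""))
  pos <- sample(2:(L - 1), 200)
  ref <- substring(as.character(g[[1]]), pos, pos)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1))
  m <- data.frame(chrom = "1", pos = pos, ref = ref, alt = alt,
                  sample_id = rep(c("a", "b"), each = 100))
  mat <- build_context_matrix(m, g)
  expect_identical(dim(mat), c(2L, 96L))
  expect_identical(colnames(mat), context_classes())
  expect_equal(unname(rowSums(mat)), c(100, 100))
  # a group with no mutations yields a row of zeros
  m$sample_id <- factor(m$sample_id, levels = c("a", "b", "empty"))
  mat3 <- build_context_matrix(m, g, groups = m$sample_id)
  expect_equal(unname(mat3["empty", ]), rep(0L, 96))
})

test_that("coding/noncoding stratification follows BED half-open conventions", {
  m <- data.frame(chrom = "1", pos = c(100, 100, 150, 200), ref = "C",
                  alt = "T")
  # interval (99,100) covers 1-based position 100 only
  s <- stratify_coding_noncoding(m[1, ], data.frame(chrom = "1", start = 99,
                                                    end = 100))
  expect_equal(nrow(s$coding), 1)
  # interval (100,200): position 100 is outside (half-open), 150 inside,
  # 200 inside (end base is 1-based 200)
  bed <- data.frame(chrom = "1", start = 100, end = 200)
  s2 <- stratify_coding_noncoding(m, bed)
  expect_equal(s2$coding$pos, c(150, 200))
  expect_equal(sort(c(s2$coding$pos, s2$noncoding$pos)), sort(m$pos))
  # empty BED puts everything in noncoding
  s3 <- stratify_coding_noncoding(m, data.frame(chrom = character(0),
                                                start = integer(0),
                                                end = integer(0)))
  expect_equal(nrow(s3$coding), 0)
  expect_equal(nrow(s3$noncoding), nrow(m))
})
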
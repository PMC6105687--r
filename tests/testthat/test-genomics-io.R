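vcf_header <- c(
  "##fileformat=VCFv4.2",
  "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
  "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
  paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1"), collapse = "\t"))

vcf_line <- function(chrom, pos, ref, alt, ad) {
  paste(chrom, pos, ".", ref, alt, ".", "PASS", ".", "AD", ad, sep = "\t")
}

test_that("VCF reading keeps biallelic SNVs and counts skipped records", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(vcf_header,
               vcf_line("1", 100, "C", "T", "40,10"),
               vcf_line("1", 200, "A", "G", "35,5"),
               vcf_line("chr2", 300, "G", "C", "20,20"),
               vcf_line("2", 400, "AT", "A", "30,3")), f)
  expect_message(m <- read_mutations(f, "P1", "SMM"), "1 non-SNV")
  expect_equal(nrow(m), 3)
  expect_equal(attr(m, "n_skipped"), 1L)
  expect_equal(m$pos[1], 100)
  expect_equal(m$ref_count[1], 40)
  expect_equal(m$alt_count[1], 10)
  expect_equal(m$chrom[3], "2")  # chr prefix stripped
  expect_equal(m$timepoint, rep("SMM", 3))
})

test_that("empty VCF bodies give empty record sets", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_header, f)
  m <- read_mutations(f, "P1", "MM")
  expect_equal(nrow(m), 0)
  expect_equal(attr(m, "n_skipped"), 0L)
})

test_that("malformed VCF lines are reported with their line number", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(vcf_header, vcf_line("1", 100, "C", "T", "40,10"),
               "1\t200\tbroken"), f)
  expect_error(read_mutations(f, "P1", "SMM"), "line 6")
})

test_that("missing depth fields name the sample in the error", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(vcf_header[-(2:3)],
               paste("1", 100, ".", "C", "T", ".", "PASS", ".", "DP", "50",
                     sep = "\t")), f)
  expect_error(read_mutations(f, "P7", "SMM"), "P7")
})

test_that("BEDPE breakpoints convert from 0-based half-open to 1-based", {
  f <- withr::local_tempfile(fileext = ".bedpe")
  writeLines(paste("1", 99, 100, "1", 499, 500, "deletion", 0, "+", "-",
                   12, 40, sep = "\t"), f)
  r <- read_rearrangements(f, "P1", "SMM")
  expect_equal(r$pos1, 100)
  expect_equal(r$pos2, 500)
  expect_equal(r$sv_type, "deletion")
  expect_equal(r$support_reads, 12)
})

test_that("rearrangement type is inferred from strands when absent", {
  f <- withr::local_tempfile(fileext = ".bedpe")
  writeLines(c(paste("1", 99, 100, "1", 499, 500, ".", 0, "+", "-", 1, 10, sep = "\t"),
               paste("1", 99, 100, "1", 499, 500, ".", 0, "-", "+", 1, 10, sep = "\t"),
               paste("1", 99, 100, "1", 499, 500, ".", 0, "+", "+", 1, 10, sep = "\t"),
               paste("1", 99, 100, "2", 499, 500, ".", 0, "-", "-", 1, 10, sep = "\t")),
             f)
  r <- read_rearrangements(f, "P1", "MM")
  expect_equal(r$sv_type, c("deletion", "tandem_duplication", "inversion",
                            "translocation"))
})

test_that("support exceeding total reads is rejected", {
  f <- withr::local_tempfile(fileext = ".bedpe")
  writeLines(paste("1", 99, 100, "1", 499, 500, "deletion", 0, "+", "-",
                   50, 40, sep = "\t"), f)
  expect_error(read_rearrangements(f, "P1", "SMM"), "support_reads")
})

test_that("overlapping copy-number segments are rejected with the pair", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tmajor\tminor",
               "1\t1\t1000\t1\t1",
               "1\t500\t2000\t2\t1"), f)
  expect_error(read_segments(f, "P1", "SMM"), "overlapping segments")
})

test_that("purity must lie in (0,1]", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\ttimepoint\tacf", "P1\tSMM\t1.0", "P1\tMM\t0.8"), f)
  p <- read_purity(f)
  expect_equal(p$acf, c(1.0, 0.8))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\ttimepoint\tacf", "P1\tSMM\t0"), f2)
  expect_error(read_purity(f2), "P1")
})

test_that("write/read round-trips are exact for all four formats", {
  d <- withr::local_tempdir()
  m <- data.frame(chrom = c("1", "2"), pos = c(150L, 220L),
                  ref = c("C", "T"), alt = c("A", "G"),
                  ref_count = c(30L, 12L), alt_count = c(10L, 0L))
  write_vcf(m, file.path(d, "x.vcf"), "P1_SMM")
  m2 <- read_mutations(file.path(d, "x.vcf"), "P1", "SMM")
  expect_equal(m2[, names(m)], m, ignore_attr = TRUE)

  r <- data.frame(chrom1 = "1", pos1 = 1000L, strand1 = "+",
                  chrom2 = "1", pos2 = 9000L, strand2 = "-",
                  sv_type = "deletion", support_reads = 8L,
                  total_reads = 40L)
  write_bedpe(r, file.path(d, "x.bedpe"))
  r2 <- read_rearrangements(file.path(d, "x.bedpe"), "P1", "SMM")
  expect_equal(r2[, names(r)], r, ignore_attr = TRUE)

  s <- data.frame(chrom = c("1", "1"), start = c(1L, 5001L),
                  end = c(5000L, 9000L), major = c(1L, 2L), minor = c(1L, 1L))
  write_segments(s, file.path(d, "x.tsv"))
  s2 <- read_segments(file.path(d, "x.tsv"), "P1", "SMM")
  expect_equal(s2[, names(s)], s, ignore_attr = TRUE)

  mat <- matrix(0L, 2, 96, dimnames = list(c("a", "b"), context_classes()))
  mat[1, 5] <- 7L
  write_context_matrix(mat, file.path(d, "ctx.tsv"))
  expect_identical(read_context_matrix(file.path(d, "ctx.tsv")), mat)

  cat_mat <- bundled_signatures()
  write_catalog(cat_mat, file.path(d, "cat.tsv"))
  expect_equal(read_catalog(file.path(d, "cat.tsv")), cat_mat,
               tolerance = 1e-12)
})
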
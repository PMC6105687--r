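#' Canonical 96 trinucleotide context classes
#'
#' Six pyrimidine-centred substitution types (C>A, C>G, C>T, T>A, T>C, T>G) in
#' major order; within each type the 5' flank varies first, then the 3' flank,
#' each over A, C, G, T. This matches the conventional catalog column order so
#' extracted signatures can be compared directly against reference catalogs.
#'
#' @return Character vector of the 96 class labels, e.g. `"A[C>A]A"`.
#' @export
context_classes <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (s in subs) for (p5 in bases) for (p3 in bases) {
    out <- c(out, paste0(p5, "[", s, "]", p3))
  }
  out
}

#' Classify substitutions into the 96 trinucleotide context classes
#'
#' Purine-reference mutations are reverse-complemented (substituted base and
#' both flanks) so that the central base of the reported class is a pyrimidine
#' (C or T). Mutations whose trinucleotide context contains an ambiguous base
#' (N) are excluded: they receive an `NA` label and the exclusion count is
#' reported via the `"n_excluded"` attribute and a message.
#'
#' @param mutations data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` (single bases).
#' @param genome a [Biostrings::DNAStringSet] whose names are chromosome names
#'   (without a "chr" prefix).
#' @return Character vector of class labels (`NA` for excluded mutations) with
#'   attribute `n_excluded`.
#' @export
classify_mutations <- function(mutations, genome) {
  stopifnot(is.data.frame(mutations),
            all(c("chrom", "pos", "ref", "alt") %in% names(mutations)))
  n <- nrow(mutations)
  if (n == 0) {
    out <- character(0)
    attr(out, "n_excluded") <- 0L
    return(out)
  }
  chrom <- normalize_chrom(mutations$chrom)
  pos <- as.integer(mutations$pos)
  ref <- toupper(as.character(mutations$ref))
  alt <- toupper(as.character(mutations$alt))
  if (any(ref == alt)) stop("ref and alt alleles must differ")
  bad_allele <- !(ref %in% c("A", "C", "G", "T")) | !(alt %in% c("A", "C", "G", "T"))
  if (any(bad_allele)) stop("alleles must be single bases in {A,C,G,T}")

  glen <- setNames(Biostrings::width(genome), normalize_chrom(names(genome)))
  unknown <- !(chrom %in% names(glen))
  if (any(unknown)) {
    stop("unknown chromosome(s): ", paste(unique(chrom[unknown]), collapse = ", "))
  }
  oob <- pos - 1L < 1L | pos + 1L > glen[chrom]
  if (any(oob)) {
    i <- which(oob)[1]
    stop(sprintf("position %s:%d too close to a chromosome end for context lookup",
                 chrom[i], pos[i]))
  }

  ctx <- character(n)
  names(genome) <- normalize_chrom(names(genome))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    at <- IRanges::IRanges(start = pos[idx] - 1L, width = 3L)
    ctx[idx] <- as.character(Biostrings::extractAt(genome[[ch]], at))
  }
  centre <- substr(ctx, 2, 2)
  mismatch <- centre != ref
  if (any(mismatch)) {
    i <- which(mismatch)[1]
    stop(sprintf("reference mismatch at %s:%d (genome has %s, record says %s)",
                 chrom[i], pos[i], centre[i], ref[i]))
  }

  has_n <- grepl("[^ACGT]", ctx)
  labels <- rep(NA_character_, n)
  ok <- !has_n
  if (any(ok)) {
    c5 <- substr(ctx, 1, 1)
    c3 <- substr(ctx, 3, 3)
    purine <- ref %in% c("A", "G")
    flip <- ok & purine
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    p5 <- ifelse(flip, comp[c3], c5)
    p3 <- ifelse(flip, comp[c5], c3)
    r <- ifelse(flip, comp[ref], ref)
    a <- ifelse(flip, comp[alt], alt)
    labels[ok] <- paste0(p5[ok], "[", r[ok], ">", a[ok], "]", p3[ok])
  }
  n_excluded <- sum(has_n)
  if (n_excluded > 0) {
    message(n_excluded, " mutation(s) excluded: trinucleotide context contains N")
  }
  attr(labels, "n_excluded") <- as.integer(n_excluded)
  labels
}

#' Build a subsets x 96 context count matrix
#'
#' @param mutations data.frame as for [classify_mutations()].
#' @param genome reference [Biostrings::DNAStringSet].
#' @param groups vector (length `nrow(mutations)`) naming the subset each
#'   mutation belongs to; defaults to `sample_id`. Factor levels with no
#'   mutations yield all-zero rows.
#' @return Integer matrix with one row per subset and exactly 96 columns in
#'   [context_classes()] order; attribute `n_excluded` gives per-group counts
#'   of context-ambiguous mutations left out.
#' @export
build_context_matrix <- function(mutations, genome,
                                 groups = mutations$sample_id) {
  classes <- context_classes()
  if (nrow(mutations) == 0) {
    levs <- if (is.factor(groups)) levels(groups) else unique(as.character(groups))
    mat <- matrix(0L, nrow = length(levs), ncol = 96,
                  dimnames = list(levs, classes))
    attr(mat, "n_excluded") <- setNames(integer(length(levs)), levs)
    return(mat)
  }
  stopifnot(length(groups) == nrow(mutations))
  g <- if (is.factor(groups)) groups else factor(groups, levels = unique(as.character(groups)))
  labels <- classify_mutations(mutations, genome)
  keep <- !is.na(labels)
  tab <- table(g[keep], factor(labels[keep], levels = classes))
  mat <- matrix(as.integer(tab), nrow = nlevels(g), ncol = 96,
                dimnames = list(levels(g), classes))
  excl <- table(g[!keep])
  n_excluded <- setNames(integer(nlevels(g)), levels(g))
  n_excluded[names(excl)] <- as.integer(excl)
  attr(mat, "n_excluded") <- n_excluded
  mat
}

#' Split mutations by coding status
#'
#' Membership is positional: a mutation is coding when its (1-based) position
#' overlaps any supplied coding interval. Intervals follow BED conventions
#' (0-based half-open), so a BED interval `(99, 100)` covers 1-based
#' position 100 only.
#'
#' @param mutations data.frame with `chrom` and `pos` columns.
#' @param coding data.frame with BED-style columns `chrom`, `start`, `end`
#'   (0-based half-open), or a [GenomicRanges::GRanges] (taken as 1-based).
#' @return list with elements `coding` and `noncoding`, a disjoint exhaustive
#'   partition of the input rows.
#' @export
stratify_coding_noncoding <- function(mutations, coding) {
  if (is.data.frame(coding)) {
    if (nrow(coding) == 0) {
      return(list(coding = mutations[integer(0), , drop = FALSE],
                  noncoding = mutations))
    }
    coding_gr <- GenomicRanges::GRanges(
      seqnames = normalize_chrom(coding$chrom),
      ranges = IRanges::IRanges(start = coding$start + 1L, end = coding$end))
  } else {
    coding_gr <- coding
    if (length(coding_gr) == 0) {
      return(list(coding = mutations[integer(0), , drop = FALSE],
                  noncoding = mutations))
    }
  }
  if (nrow(mutations) == 0) {
    return(list(coding = mutations, noncoding = mutations))
  }
  mut_gr <- GenomicRanges::GRanges(
    seqnames = normalize_chrom(mutations$chrom),
    ranges = IRanges::IRanges(start = mutations$pos, width = 1L))
  hit <- suppressWarnings(IRanges::overlapsAny(mut_gr, coding_gr))
  list(coding = mutations[hit, , drop = FALSE],
       noncoding = mutations[!hit, , drop = FALSE])
}
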
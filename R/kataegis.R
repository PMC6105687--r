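#' Default immunoglobulin locus intervals (GRCh37)
#'
#' Heavy-chain (IGH, chromosome 14), kappa (IGK, chromosome 2) and lambda
#' (IGL, chromosome 22) loci, 1-based inclusive. These are a replaceable
#' annotation: pass your own table to [annotate_ig()] for other assemblies or
#' toy genomes.
#'
#' @return data.frame with columns `locus`, `chrom`, `start`, `end`.
#' @export
ig_intervals <- function() {
  data.frame(
    locus = c("IGH", "IGK", "IGL"),
    chrom = c("14", "2", "22"),
    start = c(106032614L, 89156874L, 22380474L),
    end = c(107288051L, 90274235L, 23265085L))
}

#' Detect kataegis (localized hypermutation) regions
#'
#' Scans each chromosome's sorted, de-duplicated mutation positions for
#' maximal runs of at least `min_mutations` consecutive mutations whose mean
#' inter-mutation distance is at most `max_imd`; overlapping candidate runs
#' are merged. Region coordinates span the first to the last member mutation.
#'
#' @param mutations data.frame with `chrom` and `pos` (one sample).
#' @param min_mutations minimum run length W (default 6).
#' @param max_imd maximum mean inter-mutation distance D in bp (default 1000).
#' @return data.frame of regions: `chrom`, `start`, `end` (1-based
#'   inclusive), `n_mutations`, `mean_imd`.
#' @export
detect_kataegis <- function(mutations, min_mutations = 6, max_imd = 1000) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_mutations = integer(0),
                      mean_imd = numeric(0))
  if (is.null(mutations) || nrow(mutations) == 0) return(empty)
  w <- as.integer(min_mutations)
  out <- list()
  for (ch in unique(normalize_chrom(mutations$chrom))) {
    pos <- sort(unique(mutations$pos[normalize_chrom(mutations$chrom) == ch]))
    n <- length(pos)
    if (n < w) next
    # run [i, j] has mean IMD (pos[j]-pos[i])/(j-i) <= D  iff
    # f(j) <= f(i) with f(x) = pos[x] - D*x; so the maximal end for start i
    # is the last index whose f does not exceed f(i)
    f <- pos - max_imd * seq_len(n)
    ord <- order(f, seq_len(n))
    prefmax <- cummax(ord)                  # largest index among the r smallest f
    r <- rank(f, ties.method = "max")
    jmax <- prefmax[r]
    starts <- which(jmax - seq_len(n) + 1L >= w)
    if (length(starts) == 0) next
    ends <- jmax[starts]
    # drop runs contained in an earlier (longer) one: starts increase, so a
    # run is redundant when an earlier run already reaches at least as far
    keep <- ends > cummax(c(0L, ends[-length(ends)]))
    starts <- starts[keep]; ends <- ends[keep]
    ms <- starts[1]; me <- ends[1]
    flush <- function(i0, i1) {
      data.frame(chrom = ch, start = pos[i0], end = pos[i1],
                 n_mutations = i1 - i0 + 1L,
                 mean_imd = (pos[i1] - pos[i0]) / (i1 - i0))
    }
    for (q in seq_along(starts)[-1]) {
      if (starts[q] <= me) {
        me <- max(me, ends[q])
      } else {
        out[[length(out) + 1]] <- flush(ms, me)
        ms <- starts[q]; me <- ends[q]
      }
    }
    out[[length(out) + 1]] <- flush(ms, me)
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Flag kataegis regions overlapping immunoglobulin loci
#'
#' `is_IG` is set when the region overlaps any supplied interval by at least
#' one base (both in 1-based inclusive coordinates).
#'
#' @param regions output of [detect_kataegis()].
#' @param ig data.frame with `chrom`, `start`, `end`; defaults to the bundled
#'   GRCh37 [ig_intervals()].
#' @return `regions` with an added logical `is_IG` column.
#' @export
annotate_ig <- function(regions, ig = ig_intervals()) {
  if (nrow(regions) == 0) {
    regions$is_IG <- logical(0)
    return(regions)
  }
  if (nrow(ig) == 0) {
    regions$is_IG <- FALSE
    return(regions)
  }
  reg_gr <- GenomicRanges::GRanges(
    seqnames = normalize_chrom(regions$chrom),
    ranges = IRanges::IRanges(start = regions$start, end = regions$end))
  ig_gr <- GenomicRanges::GRanges(
    seqnames = normalize_chrom(ig$chrom),
    ranges = IRanges::IRanges(start = ig$start, end = ig$end))
  regions$is_IG <- suppressWarnings(IRanges::overlapsAny(reg_gr, ig_gr))
  regions
}

#' Signature extraction restricted to kataegis regions
#'
#' Pools the member mutations of the supplied regions, applies the
#' same strict >`min_mutations` subset filter used for per-cluster signature
#' analysis, and runs [extract_signatures()] on a per-region context matrix.
#' Exposures are refit per region and summed by immunoglobulin status, giving
#' the IG versus non-IG contribution of each extracted process.
#'
#' @param mutations data.frame of all mutations of the sample(s) with `chrom`,
#'   `pos`, `ref`, `alt`.
#' @param regions annotated regions ([annotate_ig()] output); an `is_IG`
#'   column is required.
#' @param genome reference [Biostrings::DNAStringSet].
#' @param min_mutations strict pooled-count filter (default 100).
#' @param ... passed to [extract_signatures()].
#' @return list: `extractable` flag; when extractable also `result`
#'   (an `extraction_result`), `region_exposures` and `ig_exposures`
#'   (absolute exposures summed over IG and non-IG regions).
#' @export
kataegis_signatures <- function(mutations, regions, genome,
                                min_mutations = 100, ...) {
  stopifnot("is_IG" %in% names(regions))
  if (nrow(regions) == 0) {
    return(list(extractable = FALSE, reason = "no kataegis regions"))
  }
  mut_gr <- GenomicRanges::GRanges(
    seqnames = normalize_chrom(mutations$chrom),
    ranges = IRanges::IRanges(start = mutations$pos, width = 1L))
  reg_gr <- GenomicRanges::GRanges(
    seqnames = normalize_chrom(regions$chrom),
    ranges = IRanges::IRanges(start = regions$start, end = regions$end))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(mut_gr, reg_gr, select = "first"))
  member <- !is.na(hits)
  pooled <- sum(member)
  if (length(filter_subsets_for_signatures(
    setNames(pooled, "kataegis"), min_mutations)) == 0) {
    return(list(extractable = FALSE,
                reason = sprintf("only %d pooled kataegis mutations (need > %d)",
                                 pooled, min_mutations)))
  }
  members <- mutations[member, , drop = FALSE]
  region_id <- paste0("region_", hits[member])
  mat <- build_context_matrix(members, genome, groups = region_id)
  mat <- mat[rowSums(mat) > 0, , drop = FALSE]
  res <- extract_signatures(mat, ...)
  reg_idx <- as.integer(sub("region_", "", rownames(res$exposures$absolute)))
  is_ig <- regions$is_IG[reg_idx]
  abs_exp <- res$exposures$absolute
  ig_exposures <- rbind(
    IG = colSums(abs_exp[is_ig, , drop = FALSE]),
    non_IG = colSums(abs_exp[!is_ig, , drop = FALSE]))
  list(extractable = TRUE, result = res,
       region_exposures = abs_exp, ig_exposures = ig_exposures,
       n_pooled = pooled)
}

#' Permutation test of kataegis-breakpoint proximity
#'
#' The observed statistic is the median over regions of the distance to the
#' nearest rearrangement breakpoint on the same chromosome (0 when a
#' breakpoint falls inside the region). The null re-places every breakpoint
#' uniformly on its own chromosome (preserving per-chromosome breakpoint
#' counts) `n_permutations` times; the empirical p-value is
#' `(1 + #[null <= observed]) / (n_permutations + 1)`, so it is never 0. Both
#' breakpoints of every rearrangement enter the pool.
#'
#' @param regions kataegis regions (`chrom`, `start`, `end`).
#' @param rearrangements data.frame with `chrom1`, `pos1`, `chrom2`, `pos2`
#'   and optionally `sv_type`.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param n_permutations default 1000.
#' @param seed integer seed.
#' @return list of class `proximity_test`: `testable`, `observed` (bp),
#'   `p_value`, `null_quantiles`, `n_permutations`, `per_type` (observed
#'   median by breakpoint type).
#' @export
proximity_test <- function(regions, rearrangements, chrom_lengths,
                           n_permutations = 1000, seed = 1) {
  if (is.null(rearrangements) || nrow(rearrangements) == 0) {
    return(structure(list(testable = FALSE, reason = "no rearrangements"),
                     class = "proximity_test"))
  }
  if (is.null(regions) || nrow(regions) == 0) {
    return(structure(list(testable = FALSE, reason = "no kataegis regions"),
                     class = "proximity_test"))
  }
  set.seed(seed)
  names(chrom_lengths) <- normalize_chrom(names(chrom_lengths))
  bp <- data.frame(
    chrom = normalize_chrom(c(rearrangements$chrom1, rearrangements$chrom2)),
    pos = c(rearrangements$pos1, rearrangements$pos2),
    type = rep(if (!is.null(rearrangements$sv_type)) rearrangements$sv_type
               else "unknown", 2))
  regions$chrom <- normalize_chrom(regions$chrom)

  region_dist <- function(pos_by_chrom) {
    vapply(seq_len(nrow(regions)), function(i) {
      p <- pos_by_chrom[[regions$chrom[i]]]
      if (is.null(p) || length(p) == 0) return(Inf)
      d <- pmax(0, pmax(regions$start[i] - p, p - regions$end[i]))
      min(d)
    }, numeric(1))
  }
  obs_pos <- split(bp$pos, bp$chrom)
  obs_d <- region_dist(obs_pos)
  observed <- median(obs_d)

  per_type <- vapply(split(seq_len(nrow(bp)), bp$type), function(idx) {
    median(region_dist(split(bp$pos[idx], bp$chrom[idx])))
  }, numeric(1))

  # vectorized null: per chromosome, a (breakpoints x permutations) matrix of
  # uniform re-placements; per region take the column minima
  null_median <- rep(NA_real_, n_permutations)
  chroms <- unique(bp$chrom)
  perm_pos <- lapply(chroms, function(ch) {
    nb <- sum(bp$chrom == ch)
    L <- chrom_lengths[[ch]]
    if (is.null(L) || is.na(L)) stop("missing length for chromosome ", ch)
    matrix(ceiling(runif(nb * n_permutations) * L), nrow = nb)
  })
  names(perm_pos) <- chroms
  dmat <- matrix(Inf, nrow = nrow(regions), ncol = n_permutations)
  for (i in seq_len(nrow(regions))) {
    P <- perm_pos[[regions$chrom[i]]]
    if (is.null(P) || nrow(P) == 0) next
    D <- pmax(pmax(regions$start[i] - P, P - regions$end[i]), 0)
    dmat[i, ] <- apply(D, 2, min)
  }
  null_median <- apply(dmat, 2, median)
  p <- (1 + sum(null_median <= observed)) / (n_permutations + 1)

  structure(list(testable = TRUE, observed = observed, p_value = p,
                 null_quantiles = quantile(null_median,
                                           c(0.025, 0.25, 0.5, 0.75, 0.975)),
                 n_permutations = n_permutations, per_type = per_type,
                 seed = seed),
            class = "proximity_test")
}

#' @export
print.proximity_test <- function(x, ...) {
  if (!isTRUE(x$testable)) {
    cat("Proximity test: not testable (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf("Proximity test: observed median distance %.0f bp, p = %.4g (%d permutations)\n",
                x$observed, x$p_value, x$n_permutations))
  }
  invisible(x)
}
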
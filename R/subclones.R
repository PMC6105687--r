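#' Expected variant allele fraction at full clonality
#'
#' For a mutation on `m` of `cnt` tumor copies in a sample of purity `rho`,
#' the expected VAF of a fully clonal mutation (CCF 1) is
#' `rho * m / (rho * cnt + (1 - rho) * 2)`; the VAF at CCF `c` is `c` times
#' this value.
#'
#' @param purity aberrant cell fraction in (0, 1].
#' @param cnt total tumor copy number at the site.
#' @param m mutation multiplicity (mutated copies).
#' @return numeric expected VAF at CCF 1.
#' @export
expected_vaf <- function(purity, cnt, m = 1) {
  purity * m / (purity * cnt + (1 - purity) * 2)
}

#' Estimate mutation multiplicity from observed VAF
#'
#' Chooses `m` in `1..major` minimizing the distance between the observed VAF
#' and the expected VAF of a clonal mutation on `m` copies; exact ties break
#' toward `m = 1` (the lower multiplicity).
#'
#' @param vaf observed variant allele fraction.
#' @param cnt total copy number at the site.
#' @param major major allele copy number (upper bound on `m`).
#' @param purity sample purity.
#' @return integer multiplicity (vectorized over the inputs).
#' @export
estimate_multiplicity <- function(vaf, cnt, major, purity) {
  if (length(vaf) == 0) return(integer(0))
  n <- length(vaf)
  cnt <- rep_len(cnt, n)
  major <- rep_len(major, n); purity <- rep_len(purity, n)
  vapply(seq_len(n), function(i) {
    ms <- seq_len(max(1L, major[i]))
    d <- abs(vaf[i] - expected_vaf(purity[i], cnt[i], ms))
    ms[which.min(d)]  # which.min takes the first minimum: ties go to lower m
  }, integer(1))
}

match_segment <- function(chrom, pos, segments) {
  chrom <- normalize_chrom(chrom)
  seg_gr <- GenomicRanges::GRanges(
    seqnames = normalize_chrom(segments$chrom),
    ranges = IRanges::IRanges(start = segments$start, end = segments$end))
  mut_gr <- GenomicRanges::GRanges(
    seqnames = chrom, ranges = IRanges::IRanges(start = pos, width = 1L))
  # disjoint seqlevels between query and segments are legitimate here
  suppressWarnings(
    GenomicRanges::findOverlaps(mut_gr, seg_gr, select = "first"))
}

#' Convert read counts to cancer cell fractions
#'
#' Applies the standard purity/copy-number correction
#' `ccf = vaf * (rho * CNt + (1 - rho) * 2) / (rho * m)` with `CNt` the total
#' copy number of the covering segment and `rho` the sample purity. When
#' `multiplicity` is `NULL` it is estimated per mutation with
#' [estimate_multiplicity()]. CCFs are clipped to `[0, 1.5]` with clipping
#' flagged (values above 1.5 usually indicate a multiplicity misestimate).
#' Mutations with zero depth get `NA` CCF and are flagged `excluded`.
#'
#' @param mutations data.frame with `chrom`, `pos`, `ref_count`, `alt_count`.
#' @param segments data.frame of copy-number segments (`chrom`, `start`,
#'   `end` 1-based inclusive, `major`, `minor`) for the same sample.
#' @param purity scalar purity in (0, 1].
#' @param multiplicity integer vector or `NULL` to estimate.
#' @return the input with added columns `vaf`, `cnt`, `major`, `minor`,
#'   `multiplicity`, `ccf`, `ccf_clipped`, `excluded`.
#' @export
compute_ccf <- function(mutations, segments, purity, multiplicity = NULL) {
  stopifnot(purity > 0, purity <= 1)
  n <- nrow(mutations)
  hit <- match_segment(mutations$chrom, mutations$pos, segments)
  if (anyNA(hit)) {
    i <- which(is.na(hit))
    stop("no covering copy-number segment for mutation(s): ",
         paste(sprintf("%s:%d", mutations$chrom[i], mutations$pos[i])[
           seq_len(min(5, length(i)))], collapse = ", "))
  }
  major <- segments$major[hit]
  minor <- segments$minor[hit]
  cnt <- major + minor
  depth <- mutations$ref_count + mutations$alt_count
  vaf <- ifelse(depth > 0, mutations$alt_count / depth, NA_real_)
  if (is.null(multiplicity)) {
    multiplicity <- rep(1L, n)
    ok <- !is.na(vaf)
    multiplicity[ok] <- estimate_multiplicity(vaf[ok], cnt[ok], major[ok], purity)
  }
  ccf_raw <- vaf * (purity * cnt + (1 - purity) * 2) / (purity * multiplicity)
  clipped <- !is.na(ccf_raw) & ccf_raw > 1.5
  ccf <- pmin(ccf_raw, 1.5)
  excluded <- is.na(vaf)
  if (any(excluded)) {
    message(sum(excluded), " mutation(s) with zero depth excluded from CCF estimation")
  }
  out <- mutations
  out$vaf <- vaf
  out$cnt <- cnt
  out$major <- major
  out$minor <- minor
  out$multiplicity <- multiplicity
  out$ccf <- ccf
  out$ccf_clipped <- clipped
  out$excluded <- excluded
  out
}

#' Assemble the paired-timepoint input for DP clustering
#'
#' Joins per-timepoint read counts with copy-number and purity context and
#' computes, per mutation and axis, the expected VAF at CCF 1 (`zeta`).
#' Mutations private to one timepoint should be supplied with alt count 0 at
#' the depth observed (or imputed) on the absent axis, so they enter the
#' mixture at CCF 0 on that axis.
#'
#' @param mutations data.frame with `chrom`, `pos`, and per-timepoint counts
#'   `ref_count_smm`, `alt_count_smm`, `ref_count_mm`, `alt_count_mm`.
#' @param segments_smm,segments_mm copy-number segment tables per timepoint.
#' @param purity_smm,purity_mm scalar purities.
#' @return data.frame with alt/depth/zeta per axis; attribute `n_dropped`
#'   counts mutations removed for zero depth on either axis.
#' @export
dp_input <- function(mutations, segments_smm, segments_mm,
                     purity_smm, purity_mm) {
  m1 <- data.frame(chrom = mutations$chrom, pos = mutations$pos,
                   ref_count = mutations$ref_count_smm,
                   alt_count = mutations$alt_count_smm)
  m2 <- data.frame(chrom = mutations$chrom, pos = mutations$pos,
                   ref_count = mutations$ref_count_mm,
                   alt_count = mutations$alt_count_mm)
  c1 <- suppressMessages(compute_ccf(m1, segments_smm, purity_smm))
  c2 <- suppressMessages(compute_ccf(m2, segments_mm, purity_mm))
  # multiplicity for the pair: prefer the axis with the higher VAF, so a
  # mutation absent at one timepoint still gets a defensible multiplicity
  mult <- ifelse(!is.na(c1$vaf) & (is.na(c2$vaf) | c1$vaf >= c2$vaf),
                 c1$multiplicity, c2$multiplicity)
  out <- data.frame(
    chrom = mutations$chrom, pos = mutations$pos,
    alt_smm = m1$alt_count, depth_smm = m1$ref_count + m1$alt_count,
    alt_mm = m2$alt_count, depth_mm = m2$ref_count + m2$alt_count,
    multiplicity = mult,
    zeta_smm = expected_vaf(purity_smm, c1$cnt, mult),
    zeta_mm = expected_vaf(purity_mm, c2$cnt, mult))
  keep <- out$depth_smm > 0 & out$depth_mm > 0
  dropped <- sum(!keep)
  if (dropped > 0) {
    message(dropped, " mutation(s) dropped from DP input: zero depth on one axis")
  }
  out <- out[keep, , drop = FALSE]
  attr(out, "n_dropped") <- dropped
  out
}

#' Cluster paired cancer cell fractions with a Dirichlet-process mixture
#'
#' Truncated stick-breaking DP with binomial emission on each timepoint axis:
#' the per-mutation likelihood is the product over the two timepoints of
#' `Binom(alt | depth, zeta * pi_k)` where `zeta` is the mutation's expected
#' VAF at CCF 1 and `pi_k` the cluster CCF on that axis. Cluster CCFs are
#' resampled each sweep on a uniform grid over `[0, 1.2]` (griddy Gibbs); the
#' concentration parameter carries a Gamma(1,1) hyperprior. Components
#' occupying more than `min_occupancy` of mutations after burn-in are
#' reported, with centers and 95% credible intervals from the posterior
#' draws. A split-chain diagnostic flags center disagreement above 0.1.
#'
#' @param input data.frame from [dp_input()] (or with the same columns).
#' @param sweeps,burnin,thin Gibbs controls.
#' @param truncation maximum number of mixture components.
#' @param min_occupancy minimum mean fraction of mutations for a component to
#'   be reported (default 0.01).
#' @param merge_distance reported components whose posterior centers lie
#'   within this Euclidean distance are merged into one cluster (the
#'   truncated sampler can spread one mutation cluster over two component
#'   labels); default 0.1.
#' @param grid_step resolution of the CCF grid.
#' @param seed integer seed.
#' @return object of class `subclone_clusters`: `clusters` (data.frame with
#'   id, centers, n, credible intervals), `assignments` (mutations x clusters
#'   posterior probabilities), `density` (posterior CCF-pair histogram),
#'   `convergence_warning`, `n_mutations`.
#' @export
dp_cluster_2d <- function(input, sweeps = 2000, burnin = 500, thin = 5,
                          truncation = 30, min_occupancy = 0.01,
                          merge_distance = 0.1, grid_step = 0.005, seed = 1) {
  if (nrow(input) < 20) {
    stop("DP clustering needs at least 20 mutations with defined CCF at both timepoints")
  }
  if (any(input$depth_smm <= 0) || any(input$depth_mm <= 0)) {
    stop("all mutations must have positive depth at both timepoints")
  }
  set.seed(seed)
  grid <- seq(0, 1.2, by = grid_step)
  z1 <- factor(signif(input$zeta_smm, 12))
  z2 <- factor(signif(input$zeta_mm, 12))
  fit <- .dp_gibbs_2d(
    as.integer(input$alt_smm), as.integer(input$depth_smm),
    as.integer(z1) - 1L, as.numeric(levels(z1)),
    as.integer(input$alt_mm), as.integer(input$depth_mm),
    as.integer(z2) - 1L, as.numeric(levels(z2)),
    as.integer(truncation), grid, as.integer(sweeps), as.integer(burnin),
    as.integer(thin), 1.0, 1.0)

  n <- nrow(input)
  S <- fit$n_kept
  occ <- rowMeans(fit$n[, seq_len(S), drop = FALSE]) / n
  kept <- which(occ > min_occupancy)
  if (length(kept) == 0) kept <- which.max(occ)

  all_cols <- seq_len(S)

  # pooled draws of a group, trimmed to the neighbourhood of its center so
  # sweeps where a component label briefly held a different cluster do not
  # contaminate the center or the credible interval
  group_draws <- function(ks, cols) {
    p1 <- c(); p2 <- c(); ww <- c()
    for (k in ks) {
      use <- fit$n[k, cols] > 0
      p1 <- c(p1, fit$pi1[k, cols][use])
      p2 <- c(p2, fit$pi2[k, cols][use])
      ww <- c(ww, fit$n[k, cols][use])
    }
    if (length(ww) == 0) return(NULL)
    c1 <- sum(p1 * ww) / sum(ww); c2 <- sum(p2 * ww) / sum(ww)
    keep <- sqrt((p1 - c1)^2 + (p2 - c2)^2) <= 2 * merge_distance
    if (!any(keep)) keep <- rep(TRUE, length(ww))
    list(p1 = p1[keep], p2 = p2[keep], w = ww[keep])
  }
  group_summary <- function(ks, cols) {
    g <- group_draws(ks, cols)
    if (is.null(g)) return(c(NA_real_, NA_real_))
    c(sum(g$p1 * g$w) / sum(g$w), sum(g$p2 * g$w) / sum(g$w))
  }

  # merge components whose (trimmed) posterior centers nearly coincide: the
  # truncated sampler can park two labels on one mutation cluster, and a tiny
  # component riding the super-clonal binomial tail (center above 1 on both
  # axes) belongs to the clonal cluster, so centers are compared capped at 1
  prov <- t(vapply(kept, group_summary, numeric(2), cols = all_cols))
  groups <- as.list(seq_along(kept))
  if (length(kept) > 1) {
    hc <- hclust(dist(pmin(prov, 1)), method = "single")
    gl <- cutree(hc, h = merge_distance)
    groups <- split(seq_along(kept), gl)
  }
  groups <- lapply(groups, function(g) kept[g])

  summarize <- function(cols) {
    t(vapply(groups, group_summary, numeric(2), cols = cols))
  }
  centers <- summarize(all_cols)

  weighted_ci <- function(x, w) {
    o <- order(x)
    cw <- cumsum(w[o]) / sum(w)
    c(x[o][which(cw >= 0.025)[1]], x[o][which(cw >= 0.975)[1]])
  }
  ci <- t(vapply(groups, function(ks) {
    g <- group_draws(ks, all_cols)
    c(weighted_ci(g$p1, g$w), weighted_ci(g$p2, g$w))
  }, numeric(4)))

  assign_prob <- matrix(0, nrow = n, ncol = length(groups))
  zmat <- fit$z[, all_cols, drop = FALSE]
  for (j in seq_along(groups)) {
    for (k in groups[[j]]) assign_prob[, j] <- assign_prob[, j] + rowMeans(zmat == k)
  }
  tot <- rowSums(assign_prob)
  tot[tot == 0] <- 1
  assign_prob <- assign_prob / tot
  hard <- max.col(assign_prob, ties.method = "first")

  # the occupancy rule is about mutations: drop merged groups that no
  # mutation is actually assigned to (transient posterior mass), then
  # renormalize and reassign
  counts <- tabulate(hard, nbins = length(groups))
  keep_grp <- counts > min_occupancy * n
  if (!any(keep_grp)) keep_grp[which.max(counts)] <- TRUE
  if (!all(keep_grp)) {
    groups <- groups[keep_grp]
    centers <- centers[keep_grp, , drop = FALSE]
    ci <- ci[keep_grp, , drop = FALSE]
    assign_prob <- assign_prob[, keep_grp, drop = FALSE]
    tot <- rowSums(assign_prob)
    tot[tot == 0] <- 1
    assign_prob <- assign_prob / tot
    hard <- max.col(assign_prob, ties.method = "first")
  }

  clusters <- data.frame(
    cluster = seq_along(groups),
    center_smm = centers[, 1], center_mm = centers[, 2],
    n_mutations = as.integer(tabulate(hard, nbins = length(groups))),
    ci_smm_lo = ci[, 1], ci_smm_hi = ci[, 2],
    ci_mm_lo = ci[, 3], ci_mm_hi = ci[, 4],
    occupancy = vapply(groups, function(ks) sum(occ[ks]), numeric(1)))
  ord <- order(-clusters$n_mutations)
  clusters <- clusters[ord, ]
  clusters$cluster <- seq_along(groups)
  assign_prob <- assign_prob[, ord, drop = FALSE]
  hard <- max.col(assign_prob, ties.method = "first")
  rownames(clusters) <- NULL

  # posterior density over CCF pairs (draws of the assigned cluster's CCFs)
  breaks <- seq(0, 1.2, by = 0.02)
  dens <- matrix(0, nrow = length(breaks) - 1, ncol = length(breaks) - 1)
  for (s in seq_len(S)) {
    x <- fit$pi1[zmat[, s], s]; y <- fit$pi2[zmat[, s], s]
    ix <- pmin(findInterval(x, breaks, rightmost.closed = TRUE), length(breaks) - 1)
    iy <- pmin(findInterval(y, breaks, rightmost.closed = TRUE), length(breaks) - 1)
    for (q in seq_along(ix)) dens[ix[q], iy[q]] <- dens[ix[q], iy[q]] + 1
  }
  dens <- dens / sum(dens)

  # split-chain diagnostic on kept-cluster centers
  half <- all_cols <= S / 2
  c1 <- summarize(all_cols[half]); c2 <- summarize(all_cols[!half])
  disagreement <- suppressWarnings(max(abs(c1 - c2), na.rm = TRUE))
  convergence_warning <- is.finite(disagreement) && disagreement > 0.1
  if (convergence_warning) {
    warning(sprintf("split-chain cluster centers disagree by %.3f (> 0.1)",
                    disagreement))
  }

  structure(list(clusters = clusters, assignments = assign_prob,
                 hard_assignment = hard, density = dens,
                 convergence_warning = convergence_warning,
                 center_disagreement = disagreement,
                 n_mutations = n, seed = seed),
            class = "subclone_clusters")
}

#' @export
print.subclone_clusters <- function(x, ...) {
  cat("DP subclonal clustering:", nrow(x$clusters), "cluster(s) over",
      x$n_mutations, "mutations\n")
  print(x$clusters, row.names = FALSE)
  invisible(x)
}
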
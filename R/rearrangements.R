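#' Purity/copy-number-adjusted clonal fraction of rearrangements
#'
#' For each rearrangement the raw VAF (supporting / total reads) is scaled by
#' `(rho * CNbar + (1 - rho) * 2) / rho`, where `CNbar` summarizes the total
#' copy number of the two breakpoint segments (mean by default) and one
#' derivative-allele copy is assumed. Fractions are clipped to `[0, 1.5]`
#' with a flag. Records with zero total reads are skipped with a log message.
#'
#' @param rearrangements data.frame with `chrom1`, `pos1`, `chrom2`, `pos2`,
#'   `support_reads`, `total_reads`.
#' @param segments copy-number segments of the same sample.
#' @param purity scalar purity in (0, 1].
#' @param cn_summary how to combine the two breakpoint copy numbers:
#'   `"mean"` (default), `"min"` or `"max"`.
#' @return input with added `raw_vaf`, `cn_bar`, `adjusted_fraction`,
#'   `fraction_clipped`, `skipped` columns.
#' @export
adjusted_fraction <- function(rearrangements, segments, purity,
                              cn_summary = c("mean", "min", "max")) {
  stopifnot(purity > 0, purity <= 1)
  cn_summary <- match.arg(cn_summary)
  n <- nrow(rearrangements)
  hit1 <- match_segment(rearrangements$chrom1, rearrangements$pos1, segments)
  hit2 <- match_segment(rearrangements$chrom2, rearrangements$pos2, segments)
  if (anyNA(hit1) || anyNA(hit2)) {
    i <- which(is.na(hit1) | is.na(hit2))[1]
    stop(sprintf("no covering segment for breakpoint of rearrangement %s:%d-%s:%d",
                 rearrangements$chrom1[i], rearrangements$pos1[i],
                 rearrangements$chrom2[i], rearrangements$pos2[i]))
  }
  cn1 <- segments$major[hit1] + segments$minor[hit1]
  cn2 <- segments$major[hit2] + segments$minor[hit2]
  cn_bar <- switch(cn_summary,
                   mean = (cn1 + cn2) / 2,
                   min = pmin(cn1, cn2),
                   max = pmax(cn1, cn2))
  skipped <- rearrangements$total_reads == 0
  if (any(skipped)) {
    message(sum(skipped), " rearrangement(s) skipped: zero total reads")
  }
  raw <- ifelse(skipped, NA_real_,
                rearrangements$support_reads / rearrangements$total_reads)
  adj <- raw * (purity * cn_bar + (1 - purity) * 2) / purity
  clipped <- !is.na(adj) & adj > 1.5
  out <- rearrangements
  out$raw_vaf <- raw
  out$cn_bar <- cn_bar
  out$adjusted_fraction <- pmin(adj, 1.5)
  out$fraction_clipped <- clipped
  out$skipped <- skipped
  out
}

#' Match rearrangements across the two timepoints
#'
#' Two rearrangements match when their type and strand pair agree and both
#' breakpoints lie within `slop` bp. Matching is greedy nearest-first on the
#' summed breakpoint distance, ties broken toward the lower coordinate.
#'
#' @param smm,mm data.frames of rearrangements of the same patient at the two
#'   timepoints, carrying `adjusted_fraction` columns if deltas are wanted.
#' @param slop maximum per-breakpoint distance in bp (default 500).
#' @return list: `matched` (pairs with `delta_fraction` = MM - SMM when
#'   fractions are present), `private_smm`, `private_mm`.
#' @export
match_across_timepoints <- function(smm, mm, slop = 500) {
  has_frac <- "adjusted_fraction" %in% names(smm) &&
    "adjusted_fraction" %in% names(mm)
  if (nrow(smm) == 0 || nrow(mm) == 0) {
    return(list(matched = data.frame(), private_smm = smm, private_mm = mm))
  }
  cand <- list()
  for (i in seq_len(nrow(smm))) {
    same <- normalize_chrom(mm$chrom1) == normalize_chrom(smm$chrom1[i]) &
      normalize_chrom(mm$chrom2) == normalize_chrom(smm$chrom2[i]) &
      mm$sv_type == smm$sv_type[i] &
      mm$strand1 == smm$strand1[i] & mm$strand2 == smm$strand2[i] &
      abs(mm$pos1 - smm$pos1[i]) <= slop & abs(mm$pos2 - smm$pos2[i]) <= slop
    js <- which(same)
    if (length(js)) {
      cand[[length(cand) + 1]] <- data.frame(
        i = i, j = js,
        dist = abs(mm$pos1[js] - smm$pos1[i]) + abs(mm$pos2[js] - smm$pos2[i]),
        pos = pmin(mm$pos1[js], smm$pos1[i]))
    }
  }
  used_i <- logical(nrow(smm)); used_j <- logical(nrow(mm))
  pairs <- data.frame(i = integer(0), j = integer(0))
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand$dist, cand$pos, cand$i, cand$j), , drop = FALSE]
    for (q in seq_len(nrow(cand))) {
      i <- cand$i[q]; j <- cand$j[q]
      if (!used_i[i] && !used_j[j]) {
        used_i[i] <- TRUE; used_j[j] <- TRUE
        pairs <- rbind(pairs, data.frame(i = i, j = j))
      }
    }
  }
  if (nrow(pairs)) {
    matched <- data.frame(
      chrom1 = smm$chrom1[pairs$i], pos1_smm = smm$pos1[pairs$i],
      pos1_mm = mm$pos1[pairs$j],
      chrom2 = smm$chrom2[pairs$i], pos2_smm = smm$pos2[pairs$i],
      pos2_mm = mm$pos2[pairs$j],
      sv_type = smm$sv_type[pairs$i],
      strand1 = smm$strand1[pairs$i], strand2 = smm$strand2[pairs$i])
    if (has_frac) {
      matched$fraction_smm <- smm$adjusted_fraction[pairs$i]
      matched$fraction_mm <- mm$adjusted_fraction[pairs$j]
      matched$delta_fraction <- matched$fraction_mm - matched$fraction_smm
    }
  } else {
    matched <- data.frame()
  }
  list(matched = matched,
       private_smm = smm[!used_i, , drop = FALSE],
       private_mm = mm[!used_j, , drop = FALSE])
}
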
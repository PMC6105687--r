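#!/usr/bin/env Rscript
# Localized hypermutation and rearrangement dynamics: kataegis detection per
# sample, immunoglobulin-locus annotation, cross-timepoint conservation,
# kataegis-restricted signature extraction split by IG status, the
# breakpoint-proximity permutation test, and purity/copy-number-adjusted
# rearrangement clonality changes between timepoints.
#
# Reads results/fixture/; writes tables under results/kataegis/.

suppressPackageStartupMessages(library(smmevo))

stopifnot(dir.exists("results/fixture"))
dir.create("results/kataegis", recursive = TRUE, showWarnings = FALSE)

cohort <- read_cohort("results/fixture")
genome <- cohort$genome
glen <- setNames(Biostrings::width(genome), names(genome))
ig <- data.frame(locus = c("IGH_toy", "IGK_toy", "IGL_toy"),
                 chrom = c("1", "2", "3"),
                 start = c(10000001L, 20000001L, 30000001L),
                 end = c(10050000L, 20050000L, 30050000L))

regions <- list(); prox <- list(); members <- list()
for (pt in cohort$patients) {
  m <- cohort$mutations[cohort$mutations$patient == pt, ]
  rr <- cohort$rearrangements[cohort$rearrangements$patient == pt, ]
  per_tp <- list()
  for (tp in c("SMM", "MM")) {
    suf <- tolower(tp)
    obs <- m[m[[paste0("alt_count_", suf)]] > 0, ]
    regs <- annotate_ig(detect_kataegis(obs), ig)
    per_tp[[tp]] <- regs
    if (nrow(regs)) {
      regions[[paste(pt, tp)]] <- cbind(patient = pt, timepoint = tp, regs)
      members[[paste(pt, tp)]] <- obs
    }
    pt_res <- proximity_test(regs, rr, glen, n_permutations = 1000,
                             seed = 20260923L + match(pt, cohort$patients))
    prox[[paste(pt, tp)]] <- data.frame(
      patient = pt, timepoint = tp,
      observed = if (pt_res$testable) pt_res$observed else NA,
      p_value = if (pt_res$testable) pt_res$p_value else NA)
  }
  ## cross-timepoint conservation of kataegis calls
  if (nrow(per_tp$SMM) && nrow(per_tp$MM)) {
    shared <- sum(vapply(seq_len(nrow(per_tp$SMM)), function(q) {
      any(per_tp$MM$chrom == per_tp$SMM$chrom[q] &
            per_tp$MM$start <= per_tp$SMM$end[q] &
            per_tp$MM$end >= per_tp$SMM$start[q])
    }, logical(1)))
    message(sprintf("%s: %d SMM regions, %d MM regions, %d conserved",
                    pt, nrow(per_tp$SMM), nrow(per_tp$MM), shared))
  }
}
regions_all <- do.call(rbind, regions)
write.table(regions_all, "results/kataegis/regions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, prox), "results/kataegis/proximity.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("total kataegis regions: %d (%d in IG loci)",
                nrow(regions_all), sum(regions_all$is_IG)))

## kataegis-restricted signatures, pooled over the cohort (SMM calls)
smm_regs <- regions_all[regions_all$timepoint == "SMM", ]
smm_muts <- unique(do.call(rbind, members[paste(cohort$patients, "SMM")]))
ks <- kataegis_signatures(
  smm_muts[, c("chrom", "pos", "ref", "alt")],
  smm_regs, genome, k_range = 1:4, n_bootstrap = 50, seed = 20260924L)
if (ks$extractable) {
  message("kataegis-restricted extraction: k = ", ks$result$selected_k,
          " over ", ks$n_pooled, " pooled mutations")
  ref <- bundled_signatures(include_caid = TRUE)
  for (i in seq_len(nrow(ks$result$catalog))) {
    mm <- match_to_catalog(ks$result$catalog[i, ], ref)
    message(sprintf("  signature %d ~ %s (cosine %.3f)", i, mm$best_name,
                    mm$best_cosine))
  }
  ig_tab <- round(ks$ig_exposures, 1)
  message("absolute exposure split by IG status:")
  print(ig_tab)
  write.table(data.frame(status = rownames(ig_tab), ig_tab,
                         check.names = FALSE),
              "results/kataegis/ig_exposures.tsv", sep = "\t", quote = FALSE,
              row.names = FALSE)
} else {
  message("kataegis-restricted extraction not possible: ", ks$reason)
}

## rearrangement clonality dynamics
dyn <- list()
for (pt in cohort$patients) {
  rr <- cohort$rearrangements[cohort$rearrangements$patient == pt, ]
  seg <- cohort$segments[cohort$segments$patient == pt, ]
  pur <- cohort$purity
  rho <- setNames(pur$acf[pur$patient == pt], pur$timepoint[pur$patient == pt])
  mk <- function(suf) data.frame(
    chrom1 = rr$chrom1, pos1 = rr$pos1, strand1 = rr$strand1,
    chrom2 = rr$chrom2, pos2 = rr$pos2, strand2 = rr$strand2,
    sv_type = rr$sv_type, support_reads = rr[[paste0("support_", suf)]],
    total_reads = rr[[paste0("total_", suf)]])
  a1 <- suppressMessages(adjusted_fraction(mk("smm"), seg, rho[["SMM"]]))
  a2 <- suppressMessages(adjusted_fraction(mk("mm"), seg, rho[["MM"]]))
  mt <- match_across_timepoints(a1, a2)
  if (nrow(mt$matched)) dyn[[pt]] <- cbind(patient = pt, mt$matched)
}
dyn_all <- do.call(rbind, dyn)
write.table(dyn_all, "results/kataegis/rearrangement_dynamics.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
sweeps <- dyn_all[!is.na(dyn_all$delta_fraction) &
                    abs(dyn_all$delta_fraction) > 0.4, ]
message(sprintf("%d matched rearrangements; %d changed clonal fraction by > 0.4",
                nrow(dyn_all), nrow(sweeps)))
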
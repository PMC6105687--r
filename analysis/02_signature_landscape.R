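#!/usr/bin/env Rscript
# Mutational-signature landscape of the simulated cohort: 96-class context
# matrix per sample, de novo NNMF extraction with bootstrap model selection,
# matching of the extracted processes against the bundled reference catalog,
# NNLS exposure refitting, coding/noncoding stratification and the
# noncoding-enrichment contrast of the nc-AID process (Wilcoxon rank-sum).
#
# Reads results/fixture/ (run 01_simulate_cohort.R first); writes tables
# under results/signatures/.

suppressPackageStartupMessages(library(smmevo))

stopifnot(dir.exists("results/fixture"))
dir.create("results/signatures", recursive = TRUE, showWarnings = FALSE)

cohort <- read_cohort("results/fixture")
genome <- cohort$genome

## per-sample 96-class counts (a mutation must be observed at the timepoint)
sample_contexts <- function(ch, tag) {
  long <- do.call(rbind, lapply(c("SMM", "MM"), function(tp) {
    suf <- tolower(tp)
    m <- ch$mutations[ch$mutations[[paste0("alt_count_", suf)]] > 0, ]
    data.frame(chrom = m$chrom, pos = m$pos, ref = m$ref, alt = m$alt,
               subset = paste0(tag, m$patient, "_", tp))
  }))
  list(long = long,
       mat = build_context_matrix(long, ch$genome, groups = long$subset))
}
paired <- sample_contexts(cohort, "")
ctx <- paired$mat
long <- paired$long
write_context_matrix(ctx, "results/signatures/context_matrix.tsv")

## extraction cohort: the paired samples plus the supplementary cohort
## (factorization wants many samples, so the extraction runs on 40)
extra <- sample_contexts(read_cohort("results/fixture_extra"), "X")
ctx_nnmf <- rbind(ctx, extra$mat)
message("context matrix: ", nrow(ctx), " paired samples (+",
        nrow(extra$mat), " supplementary) x ", ncol(ctx), " classes")

## de novo extraction with model selection; processes contributing ~10% or
## less can hover around the stability threshold at this cohort size, so the
## per-k table is the result to read, not just the selected k
ext <- extract_signatures(ctx_nnmf, k_range = 2:6, n_bootstrap = 100,
                          seed = 20260921L)
print(ext)
write_catalog(ext$catalog, "results/signatures/denovo_catalog.tsv")

## match against the bundled reference processes
ref <- bundled_signatures(include_caid = TRUE)
matches <- do.call(rbind, lapply(seq_len(nrow(ext$catalog)), function(i) {
  m <- match_to_catalog(ext$catalog[i, ], ref)
  data.frame(signature = rownames(ext$catalog)[i], best_match = m$best_name,
             cosine = round(m$best_cosine, 4))
}))
message("catalog matches:")
print(matches, row.names = FALSE)
write.table(matches, "results/signatures/catalog_matches.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

## exposures (absolute counts and relative fractions)
expo <- fit_exposures(ctx, ext$catalog)
write.table(data.frame(subset = rownames(expo$absolute), expo$absolute,
                       check.names = FALSE),
            "results/signatures/exposures_absolute.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

## coding vs noncoding: toy coding intervals tile 2% of the genome
glen <- setNames(Biostrings::width(genome), names(genome))
coding <- do.call(rbind, lapply(names(glen), function(ch) {
  starts <- seq(0, glen[[ch]] - 50000, by = 50000)
  data.frame(chrom = ch, start = starts, end = starts + 1000)
}))
split_sets <- stratify_coding_noncoding(long, coding)
frac_coding <- nrow(split_sets$coding) / nrow(long)
message(sprintf("%.1f%% of substitutions fall in (toy) coding regions",
                100 * frac_coding))
message("(the generator places mutations independent of annotation, so the")
message(" coding/noncoding exposure contrast below is a negative control)")

strat <- rbind(cbind(split_sets$coding, status = "coding"),
               cbind(split_sets$noncoding, status = "noncoding"))
strat$grp <- paste(strat$subset, strat$status, sep = ".")
ctx_strat <- build_context_matrix(strat, genome, groups = strat$grp)
ctx_strat <- ctx_strat[rowSums(ctx_strat) > 0, , drop = FALSE]
expo_strat <- fit_exposures(ctx_strat, ref)
rel <- expo_strat$relative
is_coding <- grepl("\\.coding$", rownames(rel))
wt <- compare_exposure_distributions(rel[!is_coding, "nc_aid"],
                                     rel[is_coding, "nc_aid"])
message(sprintf("nc-AID fraction, noncoding vs coding: W = %g, p = %.3g (%s)",
                wt$statistic, wt$p_value,
                if (wt$exact) "exact" else "normal approximation"))

## hierarchical clustering of relative exposures
cl <- cluster_exposures(expo$relative, k = 2)
write.table(data.frame(subset = names(cl$groups), group = cl$groups),
            "results/signatures/exposure_clusters.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("exposure dendrogram groups at k = 2: ",
        paste(table(cl$groups), collapse = " / "))
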
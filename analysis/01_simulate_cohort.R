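#!/usr/bin/env Rscript
# Simulate the study cohort: ten patients, each sampled at a smoldering
# (SMM) and a symptomatic (MM) timepoint, with a three-clone subclone tree
# (one clonal cluster, one disappearing and one appearing subclone),
# clone-specific signature mixtures (nc-AID-dominated early, APOBEC/broad-C>A
# late), six kataegis regions per patient (three inside toy immunoglobulin
# loci with a canonical-AID-heavy spectrum) and 35 rearrangements per patient
# of which 60% fall near a kataegis region.
#
# The toy genome is 3 chromosomes x 3 Mb so the whole workflow runs on a
# laptop in minutes; coordinates, depths, purities and clone CCFs follow the
# defaults documented in ?simulation_config. Writes the fixture (VCF / BEDPE
# / TSV / FASTA + manifest) under results/fixture/.

suppressPackageStartupMessages(library(smmevo))

# 4 x 60 Mb keeps the background mutation density below ~1/30 kb at
# study-scale per-sample totals, so kataegis stays a local anomaly rather
# than the genome-wide norm
ig <- data.frame(locus = c("IGH_toy", "IGK_toy", "IGL_toy"),
                 chrom = c("1", "2", "3"),
                 start = c(10000001L, 20000001L, 30000001L),
                 end = c(10050000L, 20050000L, 30050000L))

cfg <- simulation_config(
  seed = 20260920L,
  n_patients = 10,
  chromosome_lengths = c(`1` = 6e7, `2` = 6e7, `3` = 6e7, `4` = 6e7),
  n_mutations_range = c(2400L, 7300L),
  depth = 60,
  ig_intervals = ig)

message("simulating ", cfg$n_patients, " paired patients ...")
gen <- generate_cohort(cfg)

dir.create("results", showWarnings = FALSE)
manifest <- write_fixture(gen, "results/fixture")
saveRDS(gen$truth, "results/fixture_truth.rds")

message("wrote ", nrow(manifest), " files")
message(sprintf("cohort totals: %d substitutions, %d rearrangements, %d planted kataegis regions",
                nrow(gen$cohort$mutations),
                nrow(gen$cohort$rearrangements),
                nrow(gen$truth$kataegis)))

# Factorization wants many samples: like the study design, which added
# further whole genomes to its paired cases for signature extraction, a
# supplementary cohort contributes 20 extra samples that only enter the NNMF
# stage (02_signature_landscape.R).
cfg_extra <- cfg
cfg_extra$seed <- cfg$seed + 1L
message("simulating the supplementary extraction cohort ...")
gen_extra <- generate_cohort(cfg_extra)
write_fixture(gen_extra, "results/fixture_extra")
message("supplementary cohort: ", nrow(gen_extra$cohort$mutations),
        " substitutions across ", 2 * cfg_extra$n_patients, " samples")
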
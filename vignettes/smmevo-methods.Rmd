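---
title: "Models and methods behind smmevo"
author: "smmevo authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smmevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Smoldering multiple myeloma (SMM) is an asymptomatic plasma-cell malignancy
that progresses to symptomatic multiple myeloma (MM). Whole-genome sequencing
of the *same patient* at both stages makes four questions tractable:

1. Which mutational processes (signatures) shaped the genome, and when?
2. How is the tumor subdivided into subclones, and how do their cancer cell
   fractions (CCFs) change at progression?
3. Where did localized hypermutation (kataegis) occur, and is it physically
   associated with rearrangement breakpoints?
4. How do the clonal fractions of structural rearrangements evolve?

`smmevo` implements this analysis stack end to end, together with a seeded
synthetic-cohort generator that plants known subclone trees, signature
mixtures, kataegis regions and rearrangement clonality so that every stage
can be validated against ground truth without access to patient genomes
(which are controlled-access for the real cohorts this design mirrors).

# The synthetic cohort generator

`simulation_config()` / `generate_cohort()` encode the generative model:

* **Toy genome.** Chromosomes are i.i.d. uniform A/C/G/T, drawn from the
  seed. A uniform composition guarantees every pyrimidine-centred
  trinucleotide occurs about once per 32 bp per strand, so any 96-class
  signature can be realized at usable density. This is the one deliberate
  departure from real genomes (no CpG depletion, no repeats); consequences
  are discussed under *Limitations*.
* **Subclone tree.** Each clone has a CCF pair (SMM, MM) and a mutation
  fraction. The default tree is one clonal cluster at (1, 1), a disappearing
  subclone at (0.5, 0) and an appearing one at (0, 0.6) — the canonical
  branching pattern seen in paired-sample density plots.
* **Signature mixtures.** Each clone draws its mutations' 96 classes from a
  mixture of the bundled processes. Defaults put 47% of clonal (early)
  mutations on the noncanonical-AID process and shift subclonal (late)
  mutations toward APOBEC and the broad C>A process, reproducing the
  early/late asymmetry that motivates per-cluster signature analysis. Each
  patient realizes its own clone mixtures as Dirichlet draws around the
  configured ones (`mixture_concentration`, default 10, calibrated so
  per-process contributions spread severalfold across a cohort, the order
  reported for real cohorts): without between-patient variation all samples
  share one aggregate spectrum and factorization has nothing to separate.
* **Read counts.** A site's total depth is Poisson at the configured mean
  (default 38.7, the whole-genome average the study design targets); alt
  counts are binomial with success probability `ccf * rho * m / (rho * CNt +
  (1 - rho) * 2)` — the expected VAF given clone CCF, purity `rho`, local
  total copy number `CNt` and multiplicity `m` (fixed to 1 when simulating).
  Both timepoints of a mutation are written to both VCFs (alt count 0 where
  the clone is absent), so fixtures round-trip exactly.
* **Kataegis.** Eight mutations (configurable) are planted within a 1 kb
  span per region, in the clonal clone. A region is one enzymatic storm: a
  single process drives all of its mutations, drawn once per region from a
  mixture (canonical-AID-heavy for the first three regions per patient,
  which sit inside toy immunoglobulin loci; an APOBEC/nc-AID blend
  elsewhere). Drawing the process per mutation instead would make every
  region's expected spectrum identical and the planted multi-process
  structure unrecoverable in principle. Regions are disjoint per chromosome
  and the driving process is recorded in the ground truth.
* **Rearrangements.** 35 per patient; each is assigned to a clone, so its
  true clonal fraction per timepoint equals the clone CCF. 60% of
  rearrangements place one breakpoint near a kataegis region, at an
  exponential offset with mean 10 kb — this plants the proximity signal the
  permutation test is designed to detect. Supporting read counts are binomial
  at the raw VAF implied by the clone fraction, purity and local copy number.

Default per-patient mutation totals (2,400–7,300) and kataegis counts
(6/patient) match the ranges the study design reports; purity is drawn from
(0.7, 0.95). Scaled-down chromosomes (a few Mb) are used throughout the
tests and the analysis scripts purely as a problem-size choice; all rates
that matter (per-base mutation densities inside/outside kataegis, depths,
CCFs) are preserved or made more conservative.

# Trinucleotide contexts

`classify_mutations()` maps every substitution to one of 96 classes
(6 pyrimidine substitutions x 16 flank combinations, in the conventional
catalog column order). Purine-reference mutations are reverse-complemented
together with both flanks. Mutations whose context contains an ambiguous
base are excluded and counted rather than imputed. Classification is
strand-involutive: describing the same genomic event from the other strand
yields the identical label (tested).

# Signature extraction and model selection

The count matrix `V` (subsets x 96) is factorized as `V ~ W H` with
multiplicative Kullback–Leibler updates (implemented in C++; random
initialization from R's RNG so a seed fixes the result). Model selection
follows the resample–factorize–cluster paradigm:

* For each candidate `k`, every row of `V` is multinomially resampled
  `n_bootstrap` times (default 100) and factorized once per replicate
  (`bootstrap_restarts = 1`; the resampling already diversifies replicates
  and the consensus step absorbs occasional local minima — raising restarts
  multiplies cost roughly linearly with little stability gain). Replicate
  fits get their own convergence controls (`bootstrap_tol = 1e-5`,
  `bootstrap_max_iter = 2000`): under-converged replicates depress the
  stability of a genuinely supported `k` when between-sample contrast is
  modest, so if selection looks conservative the remedy is tightening these,
  never lowering the stability threshold. On well-separated processes a
  looser `1e-4`/1000 gives identical selections at a third of the cost.
* The pooled replicate signatures are partitioned into `k` groups. Three
  partitioners are tried — k-means on the unit sphere, average-linkage and
  Ward-linkage agglomeration on cosine distance — and the cut with the best
  silhouette is kept: k-means occasionally merges two tight groups, Ward
  occasionally splits one, and the silhouette arbitrates between these
  complementary failure modes.
* **Stability** is the *minimum* per-group mean silhouette width. The
  minimum, rather than the grand mean, is what actually separates a correct
  `k` from an overfactorized one: the extra component of an overfactorized
  solution appears as a single diffuse group while the true signatures stay
  tight, and a grand mean dilutes that signal below detectability.
* **Eligibility** additionally requires each step in `k` to reduce the
  relative Frobenius reconstruction error by at least 10%
  (`min_error_improvement`). On cohorts of 40 samples x ~5,000 mutations the
  step to the true `k` cuts the error by 25% or more while any further step
  only chips at the multinomial noise floor (a few percent), so 0.10 sits in
  the middle of a wide gap. This quantifies the otherwise vacuous
  requirement that the error "still be decreasing".
* The selected `k` is the largest eligible candidate; consensus signatures
  are the normalized group centroids.

Exposures are *refit* on the original counts by nonnegative least squares
(`fit_exposures()`), rescaled so each subset's absolute exposures sum to its
classified-mutation total — conservation by construction, and relative
contributions that refer to real mutation counts rather than NNMF loadings.

The bundled reference catalog (`bundled_signatures()`) is **synthetic**: five
stylized 96-class vectors standing in for the processes relevant here
(age-related NpCpG deamination, APOBEC at TpCpW, noncanonical AID, a broad
C>A process, and a constructed novel process kept at cosine < 0.85 from all
others), plus an optional canonical-AID-like process for kataegis work. They
encode each process's documented context preferences but are not any
published catalog's numbers; they serve as simulation inputs and matching
references so the pipeline runs without external data.

Subsets entering per-cluster signature analysis must have **more than 100**
substitutions (strict inequality; a cluster of exactly 100 is excluded).

# CCFs and Dirichlet-process clustering

`compute_ccf()` applies the standard purity/copy-number correction
`ccf = vaf (rho CNt + 2(1 - rho)) / (rho m)`; multiplicity is the value in
`1..major` whose expected clonal VAF is nearest the observation, ties toward
1. CCFs are clipped at 1.5 *with a flag* — values that far above 1 almost
always mean a multiplicity misestimate, and silently truncating at 1 would
hide that diagnostic.

`dp_cluster_2d()` is a truncated stick-breaking Dirichlet-process mixture
over paired CCFs. Per mutation and timepoint the likelihood is
`Binom(alt | depth, zeta * pi_k)`, with `zeta` the expected VAF at CCF 1 for
that mutation's copy-number/purity context, so differing depths and copy
numbers are handled exactly rather than by normalizing the data. Numerical
choices:

* truncation at 30 components; concentration alpha with a Gamma(1,1)
  hyperprior resampled each sweep;
* cluster CCFs live on a uniform grid over [0, 1.2] (step 0.005) and are
  resampled by griddy Gibbs — no tuning parameters, exact conditional draws,
  and the 1.2 ceiling leaves room for multiplicity artifacts;
* 2,000 sweeps, 500 burn-in, thinning 5 (defaults; arguments of the
  function);
* mutations private to one timepoint enter at alt count 0 on the absent axis
  at an observed or sample-median depth, i.e. at CCF 0 — this is what makes
  appearing/disappearing subclones visible as clusters on an axis;
* reported clusters are components with posterior occupancy above 1%;
  components whose posterior centers lie within 0.1 of each other are merged
  (the truncated sampler sometimes parks two labels on one mutation
  cluster), and center/interval summaries use draws trimmed to the
  neighbourhood of the merged center so transient label swaps do not inflate
  credible intervals;
* a split-chain diagnostic flags center disagreement above 0.1.

# Progression classification

`classify_progression()` operationalizes the static-versus-spontaneous
dichotomy: a non-clonal cluster is *changed* when its CCF moved by more than
`delta = 0.1` **and** its two per-axis 95% credible intervals are disjoint
(effect size and significance); it is *appearing*/*disappearing* when one
axis center is below 0.05 and the other above 0.2. Any such cluster makes
the patient *spontaneous*; otherwise *static*. The clonal cluster (within
0.15 of (1,1)) is exempt — its CCF is pinned at 1 by definition. Subtypes
are best-effort: gain + loss = branching, only gains = linear, reciprocal
significant shifts = differential clonal response; the dichotomy itself is
symmetric under relabeling the timepoints. The numeric rule (0.1 / interval
disjointness) is this package's own, since "significant genomic change" is
not a formula; both knobs are arguments.

`compare_burden()` is the paired Wilcoxon signed-rank test (exact for up to
15 informative pairs without ties, normal approximation with corrections
otherwise; zero differences dropped and counted). `wilcox.test()` does the
computation; the test suite checks it against brute-force enumeration over
sign patterns and group assignments.

# Kataegis and breakpoint proximity

`detect_kataegis()` emits maximal runs of at least `W = 6` consecutive
mutations whose mean inter-mutation distance is at most `D = 1000` bp
(the field-standard convention; both arguments exposed), merging overlapping
candidate runs. The scan uses the equivalence *run [i, j] passes iff
f(j) <= f(i)* for `f(x) = pos[x] - D x`, which gives an O(n log n)
implementation exact against the definition.

`annotate_ig()` flags regions overlapping immunoglobulin loci by at least
1 bp; the bundled GRCh37 intervals (IGH 14:106,032,614–107,288,051, IGK
2:89,156,874–90,274,235, IGL 22:22,380,474–23,265,085) are a replaceable
data table, and toy-genome analyses pass their own intervals.

`proximity_test()` measures the median distance from each kataegis region to
the nearest rearrangement breakpoint (both breakpoints of every
rearrangement enter the pool; 0 when a breakpoint falls inside the region).
The null re-places every breakpoint uniformly *on its own chromosome*,
preserving per-chromosome breakpoint counts — chromosome-level rearrangement
burden is a confounder worth controlling. The empirical p-value
`(1 + #{null <= obs}) / (B + 1)` can never be 0. Distance computation over
permutations is vectorized (a breakpoints x permutations matrix per
chromosome), keeping 1,000 permutations per sample cheap.

`kataegis_signatures()` pools region members (subject to the same >100
filter), builds a per-region context matrix and reuses the extraction stack,
then splits refitted absolute exposures by IG status — the IG/non-IG
contrast is where canonical-AID activity shows up.

# Rearrangement clonality

`adjusted_fraction()` scales the raw VAF (supporting/total reads) by
`(rho CNbar + 2(1 - rho)) / rho`, with `CNbar` the mean total copy number of
the two breakpoint segments (mean/min/max selectable) and one derivative
copy assumed — deliberately a rough estimate, as rearrangement multiplicity
is not identifiable from these counts. `match_across_timepoints()` pairs
records with equal type and strand pair whose breakpoints agree within 500 bp
(greedy nearest-first, ties to the lower coordinate) and reports the clonal
fraction change of matched pairs alongside the privates.

# Pipeline

`run_pipeline()` executes the stages in dependency order from a manifest,
isolates per-patient failures, skips progression for single-timepoint
patients with a note, warns when the cohort context matrix has fewer than 10
rows (factorization wants many samples), and writes each stage's tables
before the next stage starts plus a `run_metadata.json` with all parameters,
seeds and a config hash (the hash also appears as a column of
`summary.tsv`). The numbered scripts under `analysis/` drive the same
functions one stage at a time and are the command-line surface of the
package.

# Problem sizes used in validation

The test suite and `scripts/acceptance.R` run everything on scaled problems
chosen once: 3 x 2–3 Mb toy chromosomes, 600–3,600 mutations per patient,
depths 60–100 for clustering work (10,000 where an asymptotic claim is
checked), 40-sample x 5,000-mutation cohorts for model selection, 50 planted
datasets for kataegis sensitivity, 200 null datasets for permutation-test
calibration, and 20 patients per arm for progression accuracy. These sizes
keep every property measurable with comfortable statistical margins; the
claims they check (unbiasedness, recovery rates, calibration) are
size-stable by construction.

# Limitations

* The toy genome's uniform base composition means context opportunities are
  flat; real genomes weight the 96 classes by trinucleotide abundance, so
  passing recovery tests here demonstrates the machinery, not robustness to
  compositional bias.
* The generator plants multiplicity-1 mutations on clonal copy-number
  segments; subclonal copy number enters only as input segments, never as a
  deconvolution target.
* Progression subtypes beyond the static/spontaneous dichotomy
  (linear / differential clonal response / branching) are heuristic labels
  on cluster dynamics and are flagged as best-effort in the output.
* No indels, doublet substitutions, sequencing error, germline variation or
  transcription-strand effects are simulated or classified.
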
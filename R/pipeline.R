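#' Parameters for a full pipeline run
#'
#' Bundles every stage's tunables with the defaults used throughout the
#' package; all seeds derive from the single `seed`.
#'
#' @param seed master seed.
#' @param k_range,n_bootstrap,n_restarts,stability_threshold signature
#'   extraction controls ([extract_signatures()]).
#' @param min_cohort_for_nnmf warn when the context matrix has fewer rows
#'   than this (factorization quality degrades on small cohorts).
#' @param sweeps,burnin,thin,truncation DP clustering controls
#'   ([dp_cluster_2d()]).
#' @param kataegis_min_mutations,kataegis_max_imd detection rule
#'   ([detect_kataegis()]).
#' @param delta,clonal_radius progression classification
#'   ([classify_progression()]).
#' @param n_permutations proximity test ([proximity_test()]).
#' @param slop rearrangement matching ([match_across_timepoints()]).
#' @param ig immunoglobulin intervals for [annotate_ig()].
#' @param cluster_min_mutations strict per-cluster substitution filter for
#'   per-cluster signature analysis.
#' @return list of class `pipeline_params`.
#' @export
pipeline_params <- function(seed = 1, k_range = 2:6, n_bootstrap = 100,
                            n_restarts = 10, stability_threshold = 0.8,
                            min_cohort_for_nnmf = 10,
                            sweeps = 2000, burnin = 500, thin = 5,
                            truncation = 30,
                            kataegis_min_mutations = 6,
                            kataegis_max_imd = 1000,
                            delta = 0.1, clonal_radius = 0.15,
                            n_permutations = 1000, slop = 500,
                            ig = ig_intervals(),
                            cluster_min_mutations = 100) {
  structure(as.list(environment()), class = "pipeline_params")
}

config_hash <- function(params) {
  txt <- jsonlite::toJSON(params[!vapply(params, is.function, logical(1))],
                          auto_unbox = TRUE, digits = NA, force = TRUE)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

read_manifest <- function(path) {
  manifest <- data.table::fread(path, data.table = FALSE)
  need <- c("patient", "timepoint", "vcf", "bedpe", "segments", "purity",
            "fasta")
  if (!all(need %in% names(manifest))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(manifest$timepoint %in% .tp_levels)) {
    stop("manifest timepoints must be SMM or MM")
  }
  manifest
}

#' Run the full paired-sample analysis over a cohort
#'
#' Orchestrates, in dependency order: reading the fixture, per-sample context
#' matrices, cohort-level signature extraction and catalog matching, coding
#' versus noncoding exposure contrast, per-patient DP subclonal clustering and
#' progression classification, per-cluster signature refitting (clusters with
#' more than `cluster_min_mutations` substitutions only), kataegis detection
#' with IG annotation and breakpoint-proximity testing, rearrangement
#' clonality dynamics, and the paired burden comparison. A patient whose
#' stage fails is logged and skipped without aborting the cohort; a patient
#' with a single timepoint skips the progression stages with a note. Each
#' stage's tables are written under `out_dir` before the next stage starts,
#' along with a `run_metadata.json` carrying the parameters, seeds and config
#' hash.
#'
#' @param manifest path to a `manifest.tsv` (see [write_fixture()]) or an
#'   equivalent data.frame; file paths are resolved relative to `input_dir`.
#' @param out_dir output directory.
#' @param params a [pipeline_params()] object.
#' @param input_dir directory the manifest's relative paths live in; defaults
#'   to the manifest's own directory.
#' @return list of class `pipeline_result` with all stage outputs (invisibly
#'   also written as TSVs).
#' @export
run_pipeline <- function(manifest, out_dir, params = pipeline_params(),
                         input_dir = NULL) {
  if (is.character(manifest)) {
    if (is.null(input_dir)) input_dir <- dirname(manifest)
    manifest <- read_manifest(manifest)
  } else {
    manifest <- read_manifest_df(manifest)
    if (is.null(input_dir)) input_dir <- "."
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  hash <- config_hash(params)
  notes <- character(0)
  failures <- list()
  rp <- function(f) file.path(input_dir, f)

  genome <- Biostrings::readDNAStringSet(rp(manifest$fasta[1]))
  names(genome) <- sub("\\s.*$", "", names(genome))
  purity <- read_purity(rp(manifest$purity[1]))

  ## ---- per-sample data ----
  samples <- list()
  for (q in seq_len(nrow(manifest))) {
    pt <- manifest$patient[q]; tp <- manifest$timepoint[q]
    key <- paste0(pt, "_", tp)
    res <- tryCatch({
      list(mutations = suppressMessages(read_mutations(rp(manifest$vcf[q]), pt, tp)),
           rearrangements = read_rearrangements(rp(manifest$bedpe[q]), pt, tp),
           segments = read_segments(rp(manifest$segments[q]), pt, tp),
           acf = purity$acf[purity$sample_id == pt & purity$timepoint == tp])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[key]] <- conditionMessage(res)
      next
    }
    if (length(res$acf) != 1) {
      failures[[key]] <- "missing or duplicated purity entry"
      next
    }
    samples[[key]] <- res
  }

  ## ---- context matrices ----
  all_mut <- do.call(rbind, lapply(names(samples), function(k) {
    m <- samples[[k]]$mutations
    m <- m[m$alt_count > 0, , drop = FALSE]
    if (nrow(m) > 0) m$subset <- k
    m
  }))
  ctx_mat <- build_context_matrix(all_mut, genome, groups = all_mut$subset)
  write_context_matrix(ctx_mat, file.path(out_dir, "context_matrix.tsv"))

  ## ---- cohort signature extraction ----
  if (nrow(ctx_mat) < params$min_cohort_for_nnmf) {
    warning("only ", nrow(ctx_mat), " samples for NNMF; factorization works ",
            "best when a large number of samples is used")
  }
  nz_mat <- ctx_mat[rowSums(ctx_mat) > 0, , drop = FALSE]
  k_range <- params$k_range[params$k_range <= nrow(nz_mat)]
  if (length(k_range) < length(params$k_range)) {
    warning("k_range truncated to 1..", nrow(nz_mat),
            " (cannot search more processes than samples)")
  }
  extraction <- extract_signatures(
    nz_mat,
    k_range = k_range, n_bootstrap = params$n_bootstrap,
    n_restarts = params$n_restarts,
    stability_threshold = params$stability_threshold,
    seed = params$seed)
  write_catalog(extraction$catalog, file.path(out_dir, "signatures.tsv"))
  matches <- lapply(seq_len(nrow(extraction$catalog)), function(i) {
    m <- match_to_catalog(extraction$catalog[i, ], bundled_signatures(TRUE))
    data.frame(signature = rownames(extraction$catalog)[i],
               best_match = m$best_name, cosine = m$best_cosine)
  })
  matches <- do.call(rbind, matches)
  data.table::fwrite(matches, file.path(out_dir, "signature_matches.tsv"),
                     sep = "\t")
  exp_abs <- data.frame(subset = rownames(extraction$exposures$absolute),
                        extraction$exposures$absolute, check.names = FALSE)
  data.table::fwrite(exp_abs, file.path(out_dir, "exposures_absolute.tsv"),
                     sep = "\t")

  ## ---- per-patient progression ----
  patients <- unique(manifest$patient)
  calls <- list(); cluster_tabs <- list(); cluster_sig <- list()
  burden <- data.frame(patient = patients, n_smm = NA_integer_,
                       n_mm = NA_integer_)
  for (pt in patients) {
    k_smm <- paste0(pt, "_SMM"); k_mm <- paste0(pt, "_MM")
    have <- c(k_smm, k_mm) %in% names(samples)
    tps <- manifest$timepoint[manifest$patient == pt]
    if (!all(c("SMM", "MM") %in% tps) || !all(have)) {
      notes <- c(notes, paste0(pt, ": single timepoint; progression stage skipped"))
      next
    }
    res <- tryCatch({
      s1 <- samples[[k_smm]]; s2 <- samples[[k_mm]]
      key <- c("chrom", "pos", "ref", "alt")
      wide <- merge(s1$mutations[, c(key, "ref_count", "alt_count")],
                    s2$mutations[, c(key, "ref_count", "alt_count")],
                    by = key, all = TRUE, suffixes = c("_smm", "_mm"))
      # sites unreported at one timepoint enter at alt 0 with an imputed
      # (sample-median) depth so they sit at CCF 0 on the absent axis
      med1 <- max(1L, round(median(s1$mutations$ref_count + s1$mutations$alt_count)))
      med2 <- max(1L, round(median(s2$mutations$ref_count + s2$mutations$alt_count)))
      miss1 <- is.na(wide$alt_count_smm)
      wide$alt_count_smm[miss1] <- 0L
      wide$ref_count_smm[miss1] <- med1
      miss2 <- is.na(wide$alt_count_mm)
      wide$alt_count_mm[miss2] <- 0L
      wide$ref_count_mm[miss2] <- med2
      inp <- dp_input(wide, s1$segments, s2$segments, s1$acf, s2$acf)
      dp <- dp_cluster_2d(inp, sweeps = params$sweeps, burnin = params$burnin,
                          thin = params$thin, truncation = params$truncation,
                          seed = params$seed + match(pt, patients))
      call <- classify_progression(dp$clusters, delta = params$delta,
                                   clonal_radius = params$clonal_radius)
      ## per-cluster signature refit (strict > cluster_min_mutations filter)
      counts <- setNames(dp$clusters$n_mutations,
                         paste0(pt, "_cluster", dp$clusters$cluster))
      keep <- filter_subsets_for_signatures(counts, params$cluster_min_mutations)
      cs <- NULL
      if (length(keep) > 0) {
        lab <- paste0(pt, "_cluster", dp$hard_assignment)
        sel <- lab %in% keep
        cmat <- build_context_matrix(
          data.frame(chrom = inp$chrom[sel], pos = inp$pos[sel],
                     ref = wide$ref[match(paste(inp$chrom, inp$pos),
                                          paste(wide$chrom, wide$pos))][sel],
                     alt = wide$alt[match(paste(inp$chrom, inp$pos),
                                          paste(wide$chrom, wide$pos))][sel]),
          genome, groups = lab[sel])
        cs <- fit_exposures(cmat, extraction$catalog)$relative
      }
      list(dp = dp, call = call, cluster_sig = cs,
           n_smm = sum(s1$mutations$alt_count > 0),
           n_mm = sum(s2$mutations$alt_count > 0))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[pt]] <- conditionMessage(res)
      next
    }
    burden$n_smm[burden$patient == pt] <- res$n_smm
    burden$n_mm[burden$patient == pt] <- res$n_mm
    cluster_tabs[[pt]] <- cbind(patient = pt, res$dp$clusters)
    calls[[pt]] <- data.frame(patient = pt, call = res$call$call,
                              subtype = res$call$subtype,
                              n_clusters = nrow(res$dp$clusters),
                              has_clonal = res$call$has_clonal)
    if (!is.null(res$cluster_sig)) {
      cluster_sig[[pt]] <- data.frame(subset = rownames(res$cluster_sig),
                                      res$cluster_sig, check.names = FALSE)
    }
  }
  clusters_all <- if (length(cluster_tabs)) do.call(rbind, cluster_tabs) else NULL
  calls_all <- if (length(calls)) do.call(rbind, calls) else NULL
  if (!is.null(clusters_all)) {
    data.table::fwrite(clusters_all, file.path(out_dir, "subclones.tsv"),
                       sep = "\t")
  }
  if (!is.null(calls_all)) {
    data.table::fwrite(calls_all, file.path(out_dir, "progression_calls.tsv"),
                       sep = "\t")
  }
  if (length(cluster_sig)) {
    data.table::fwrite(do.call(rbind, cluster_sig),
                       file.path(out_dir, "cluster_exposures.tsv"), sep = "\t")
  }

  ## ---- kataegis and proximity ----
  kat_tabs <- list(); prox_tabs <- list()
  chrom_lengths <- setNames(Biostrings::width(genome), names(genome))
  for (key in names(samples)) {
    s <- samples[[key]]
    m <- s$mutations[s$mutations$alt_count > 0, , drop = FALSE]
    regs <- detect_kataegis(m, params$kataegis_min_mutations,
                            params$kataegis_max_imd)
    regs <- annotate_ig(regs, params$ig)
    if (nrow(regs) > 0) kat_tabs[[key]] <- cbind(sample = key, regs)
    pr <- proximity_test(regs, s$rearrangements, chrom_lengths,
                         n_permutations = params$n_permutations,
                         seed = params$seed + 1000 + match(key, names(samples)))
    prox_tabs[[key]] <- data.frame(
      sample = key, testable = pr$testable,
      observed = if (pr$testable) pr$observed else NA_real_,
      p_value = if (pr$testable) pr$p_value else NA_real_)
  }
  kataegis_all <- if (length(kat_tabs)) do.call(rbind, kat_tabs) else NULL
  proximity_all <- do.call(rbind, prox_tabs)
  if (!is.null(kataegis_all)) {
    data.table::fwrite(kataegis_all, file.path(out_dir, "kataegis.tsv"),
                       sep = "\t")
  }
  data.table::fwrite(proximity_all, file.path(out_dir, "proximity.tsv"),
                     sep = "\t")

  ## ---- rearrangement dynamics ----
  rr_tabs <- list()
  for (pt in patients) {
    k_smm <- paste0(pt, "_SMM"); k_mm <- paste0(pt, "_MM")
    if (!all(c(k_smm, k_mm) %in% names(samples))) next
    res <- tryCatch({
      s1 <- samples[[k_smm]]; s2 <- samples[[k_mm]]
      a1 <- suppressMessages(
        adjusted_fraction(s1$rearrangements, s1$segments, s1$acf))
      a2 <- suppressMessages(
        adjusted_fraction(s2$rearrangements, s2$segments, s2$acf))
      mt <- match_across_timepoints(a1, a2, slop = params$slop)
      if (nrow(mt$matched) > 0) cbind(patient = pt, mt$matched) else NULL
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[paste0(pt, "_rearrangements")]] <- conditionMessage(res)
    } else if (!is.null(res)) {
      rr_tabs[[pt]] <- res
    }
  }
  rearr_all <- if (length(rr_tabs)) do.call(rbind, rr_tabs) else NULL
  if (!is.null(rearr_all)) {
    data.table::fwrite(rearr_all, file.path(out_dir, "rearrangement_dynamics.tsv"),
                       sep = "\t")
  }

  ## ---- burden comparison ----
  paired <- !is.na(burden$n_smm) & !is.na(burden$n_mm)
  burden_test <- if (sum(paired) >= 2) {
    compare_burden(burden$n_smm[paired], burden$n_mm[paired])
  } else NULL

  ## ---- summary ----
  kat_count <- function(key) {
    if (is.null(kataegis_all)) 0L else sum(kataegis_all$sample == key)
  }
  summary <- data.frame(
    patient = patients,
    n_substitutions_smm = burden$n_smm[match(patients, burden$patient)],
    n_substitutions_mm = burden$n_mm[match(patients, burden$patient)],
    n_clusters = if (is.null(calls_all)) NA_integer_ else
      calls_all$n_clusters[match(patients, calls_all$patient)],
    call = if (is.null(calls_all)) NA_character_ else
      calls_all$call[match(patients, calls_all$patient)],
    kataegis_smm = vapply(paste0(patients, "_SMM"), kat_count, integer(1)),
    kataegis_mm = vapply(paste0(patients, "_MM"), kat_count, integer(1)),
    config_hash = hash)
  data.table::fwrite(summary, file.path(out_dir, "summary.tsv"), sep = "\t")

  meta <- list(config_hash = hash, seed = params$seed,
               params = params[!vapply(params, is.function, logical(1))],
               notes = notes, failures = failures)
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  structure(list(context_matrix = ctx_mat, extraction = extraction,
                 matches = matches, clusters = clusters_all,
                 calls = calls_all, kataegis = kataegis_all,
                 proximity = proximity_all, rearrangements = rearr_all,
                 burden = burden, burden_test = burden_test,
                 summary = summary, notes = notes, failures = failures,
                 config_hash = hash),
            class = "pipeline_result")
}

read_manifest_df <- function(manifest) {
  need <- c("patient", "timepoint", "vcf", "bedpe", "segments", "purity",
            "fasta")
  if (!all(need %in% names(manifest))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(manifest$timepoint %in% .tp_levels)) {
    stop("manifest timepoints must be SMM or MM")
  }
  manifest
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline run", x$config_hash, "\n")
  print(x$summary, row.names = FALSE)
  if (length(x$notes)) cat("Notes:\n", paste(" -", x$notes, collapse = "\n"), "\n")
  if (length(x$failures)) {
    cat("Failures:\n")
    for (k in names(x$failures)) cat(" -", k, ":", x$failures[[k]], "\n")
  }
  invisible(x)
}
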
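#' Classify a patient's progression pattern from subclone dynamics
#'
#' A cluster counts as significantly changed when the absolute difference
#' between its two timepoint CCFs exceeds `delta` *and* its per-axis 95%
#' credible intervals are disjoint; it is appearing (or disappearing) when
#' one axis center is below 0.05 and the other above 0.2. Any changed or
#' appearing/disappearing non-clonal cluster makes the call "spontaneous",
#' otherwise "static". The clonal cluster (center within `clonal_radius` of
#' (1, 1)) is exempt: its CCF is 1 at both timepoints by definition, and the
#' dichotomy concerns the subclonal composition.
#'
#' Spontaneous calls get a best-effort subtype: an appearing cluster together
#' with a disappearing one is "branching"; only gains is "linear"; reciprocal
#' significant shifts without gain/loss is "differential_clonal_response".
#'
#' @param clusters data.frame as in the `clusters` element of
#'   [dp_cluster_2d()] output (columns `cluster`, `center_smm`, `center_mm`,
#'   `ci_*`).
#' @param delta minimum CCF change (default 0.1).
#' @param clonal_radius Euclidean distance from (1,1) within which a cluster
#'   is considered clonal (default 0.15).
#' @return object of class `progression_call`: `call` ("static" or
#'   "spontaneous"), `subtype`, `evidence` (per-cluster table), `has_clonal`.
#' @export
classify_progression <- function(clusters, delta = 0.1, clonal_radius = 0.15) {
  if (is.null(clusters) || nrow(clusters) == 0) stop("empty cluster list")
  d_clonal <- sqrt((clusters$center_smm - 1)^2 + (clusters$center_mm - 1)^2)
  clonal <- d_clonal <= clonal_radius
  has_clonal <- any(clonal)
  if (!has_clonal) {
    warning("no clonal cluster (center near (1,1)) found")
  }
  dccf <- clusters$center_mm - clusters$center_smm
  disjoint <- clusters$ci_smm_hi < clusters$ci_mm_lo |
    clusters$ci_mm_hi < clusters$ci_smm_lo
  changed <- abs(dccf) > delta & disjoint
  appearing <- clusters$center_smm < 0.05 & clusters$center_mm > 0.2
  disappearing <- clusters$center_mm < 0.05 & clusters$center_smm > 0.2
  evidence <- data.frame(cluster = clusters$cluster,
                         delta_ccf = dccf,
                         interval_disjoint = disjoint,
                         changed = changed,
                         appearing = appearing,
                         disappearing = disappearing,
                         clonal = clonal)
  active <- !clonal & (changed | appearing | disappearing)
  call <- if (any(active)) "spontaneous" else "static"
  subtype <- NA_character_
  if (call == "spontaneous") {
    gains <- active & (appearing | (changed & dccf > 0))
    losses <- active & (disappearing | (changed & dccf < 0))
    subtype <- if (any(appearing & active) && any(disappearing & active)) {
      "branching"
    } else if (any(gains) && !any(losses)) {
      "linear"
    } else if (any(gains) && any(losses)) {
      "differential_clonal_response"
    } else {
      "unassigned"
    }
  }
  structure(list(call = call, subtype = subtype, evidence = evidence,
                 has_clonal = has_clonal),
            class = "progression_call")
}

#' @export
print.progression_call <- function(x, ...) {
  cat("Progression call:", x$call,
      if (!is.na(x$subtype)) paste0("(", x$subtype, ")") else "", "\n")
  print(x$evidence, row.names = FALSE)
  invisible(x)
}

#' Compare paired mutation burdens by Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on the paired differences (MM - SMM). Zero
#' differences are dropped (count reported); the exact null is enumerated for
#' up to 15 informative pairs without tied absolute differences, otherwise
#' the normal approximation with corrections is used. With no informative
#' pairs the p-value is 1 with a warning.
#'
#' @param smm,mm numeric vectors of per-patient totals, same order.
#' @return list: `statistic` (V), `p_value`, `n_zero` (dropped pairs),
#'   `exact` flag.
#' @export
compare_burden <- function(smm, mm) {
  stopifnot(length(smm) == length(mm))
  if (length(smm) < 2) stop("need at least 2 pairs")
  d <- mm - smm
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  if (length(d) == 0) {
    warning("all paired differences are zero")
    return(list(statistic = NA_real_, p_value = 1, n_zero = n_zero,
                exact = TRUE))
  }
  ties <- anyDuplicated(abs(d)) > 0
  exact <- length(d) <= 15 && !ties
  ht <- suppressWarnings(
    wilcox.test(d, alternative = "two.sided", exact = exact, correct = !exact))
  list(statistic = unname(ht$statistic), p_value = min(ht$p.value, 1),
       n_zero = n_zero, exact = exact)
}
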
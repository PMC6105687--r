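#' Bundled synthetic reference signature catalog
#'
#' A constructed stand-in catalog of 96-class probability vectors for the
#' mutational processes relevant to plasma-cell disorders: an age-related
#' process (pooled clock-like deamination at NpCpG), APOBEC (C>T/C>G at
#' TpCpW), noncanonical AID (T>C/T>G in an A-rich context, acting
#' genome-wide), a broad C>A-dominated process of unknown aetiology
#' ("sig8_like"), and a distinct "mm1_like" process constructed to be
#' dissimilar (cosine < 0.85) from all the others. With
#' `include_caid = TRUE` a sixth, canonical-AID-like process (C>T/C>G at
#' WpCpY, the spectrum expected at immunoglobulin loci) is appended; it is
#' used by kataegis-restricted analyses.
#'
#' These vectors are synthetic: they are stylized encodings of the context
#' preferences described for each process, not any published catalog's
#' numerical values. They serve as simulation inputs and matching references
#' so the whole pipeline runs without external data.
#'
#' @param include_caid append the canonical-AID-like process.
#' @return matrix, processes x 96; each row sums to 1.
#' @export
bundled_signatures <- function(include_caid = FALSE) {
  classes <- context_classes()
  put <- function(v, labels, mass) {
    v[labels] <- v[labels] + mass / length(labels)
    v
  }
  blank <- setNames(rep(0, 96), classes)
  bases <- c("A", "C", "G", "T")

  # age-related: C>T at NpCpG plus a diffuse clock-like background
  age <- blank + 0.30 / 96
  age <- put(age, paste0(bases, "[C>T]G"), 0.50)
  age <- put(age, paste0("A[T>C]", bases), 0.20)

  # APOBEC: C>T and C>G at TpCpA / TpCpT
  apobec <- blank + 0.06 / 96
  apobec <- put(apobec, c("T[C>T]A", "T[C>T]T"), 0.46)
  apobec <- put(apobec, c("T[C>G]A", "T[C>G]T"), 0.48)

  # noncanonical AID: T>C and T>G with a strong A 5' flank, genome-wide
  nc_aid <- blank + 0.10 / 96
  nc_aid <- put(nc_aid, paste0("A[T>C]", bases), 0.40)
  nc_aid <- put(nc_aid, paste0("A[T>G]", bases), 0.30)
  nc_aid <- put(nc_aid, paste0("T[T>C]", bases), 0.20)

  # broad C>A process of unknown aetiology
  sig8 <- blank + 0.20 / 96
  for (p5 in bases) sig8 <- put(sig8, paste0(p5, "[C>A]", bases), 0.70 / 4)
  sig8 <- put(sig8, paste0(bases, "[T>A]A"), 0.10)

  # constructed novel process, far from all the above
  mm1 <- blank + 0.10 / 96
  mm1 <- put(mm1, paste0("G[T>A]", bases), 0.45)
  mm1 <- put(mm1, paste0("C[T>G]", bases), 0.30)
  mm1 <- put(mm1, c("G[C>G]C", "C[C>G]G"), 0.15)

  rows <- list(age_related = age, apobec = apobec, nc_aid = nc_aid,
               sig8_like = sig8, mm1_like = mm1)
  if (include_caid) {
    # canonical AID: C>T/C>G at WRCY-like contexts (A/G 5', C/T 3')
    caid <- blank + 0.08 / 96
    caid <- put(caid, c("A[C>T]C", "A[C>T]T", "G[C>T]C", "G[C>T]T"), 0.52)
    caid <- put(caid, c("A[C>G]C", "A[C>G]T", "G[C>G]C", "G[C>G]T"), 0.40)
    rows$c_aid <- caid
  }
  cat <- do.call(rbind, rows)
  cat / rowSums(cat)
}

cosine_similarity <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# stability of a replicate-signature partition: silhouette widths under
# cosine distance, averaged within each group, reporting the weakest group.
# The minimum (rather than the grand mean) is what separates a correctly
# factorized k from an overfactorized one: an extra component shows up as a
# single diffuse group while the real signatures stay tight.
cosine_silhouette <- function(X, cl) {
  n <- nrow(X)
  if (length(unique(cl)) < 2) return(1)
  Xn <- X / sqrt(rowSums(X^2))
  D <- 1 - Xn %*% t(Xn)
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- cl == cl[i]
    same[i] <- FALSE
    a <- if (any(same)) mean(D[i, same]) else NA_real_
    b <- min(vapply(setdiff(unique(cl), cl[i]),
                    function(k) mean(D[i, cl == k]), numeric(1)))
    s[i] <- if (is.na(a)) 0 else (b - a) / max(a, b)
  }
  min(tapply(s, cl, mean))
}

run_nmf <- function(V, k, n_restarts, max_iter, tol) {
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- .nmf_kl(V, k, max_iter, tol)
    if (is.null(best) || fit$divergence < best$divergence) best <- fit
  }
  best
}

multinomial_resample <- function(mat) {
  res <- mat
  for (i in seq_len(nrow(mat))) {
    tot <- sum(mat[i, ])
    if (tot > 0) res[i, ] <- as.numeric(rmultinom(1, tot, mat[i, ] / tot))
  }
  res
}

#' De novo signature extraction with bootstrap model selection
#'
#' For each candidate number of processes `k`, the count matrix is repeatedly
#' perturbed by multinomial resampling of each row, factorized by
#' KL-divergence multiplicative-update NNMF (best of `n_restarts` random
#' starts), and the pooled replicate signatures are partitioned into `k`
#' groups; stability is the weakest group's mean silhouette width under
#' cosine distance (per-signature stability: one diffuse group is what an
#' overfactorized k looks like). The selected `k` is the largest candidate whose stability
#' reaches `stability_threshold` while the reconstruction error is still
#' decreasing along the searched range. Consensus signatures are the
#' normalized group centroids; exposures are refit on the original counts by
#' nonnegative least squares (see [fit_exposures()]) so per-subset absolute
#' exposures conserve mutation totals.
#'
#' @param mat subsets x 96 count matrix ([build_context_matrix()]).
#' @param k_range integer candidates, within `[1, min(nrow, 96)]`.
#' @param n_bootstrap resampled replicates per `k`.
#' @param n_restarts random NNMF restarts for the deterministic fits (the
#'   per-k reconstruction error and the final catalog).
#' @param bootstrap_restarts random starts per bootstrap replicate (default
#'   1: the multinomial resampling already diversifies the replicates, and
#'   the consensus clustering absorbs occasional local minima).
#' @param stability_threshold minimum per-signature stability to accept a `k`.
#' @param min_error_improvement minimum relative drop in reconstruction error
#'   a step in `k` must deliver to stay eligible (default 0.1): adding a
#'   component beyond the true factorization rank only chips at the sampling
#'   noise floor (a few percent), while a genuine process cuts the error by a
#'   quarter or more.
#' @param max_iter,tol NNMF convergence controls for the deterministic fits.
#' @param bootstrap_max_iter,bootstrap_tol convergence controls for the
#'   resampled replicate fits, looser than the deterministic fits'.
#'   Under-converged replicates depress the stability of a genuinely
#'   supported `k` when between-sample contrast is modest, so tighten these
#'   (and pay the proportional runtime) rather than lowering the stability
#'   threshold if selection looks conservative; on well-separated cohorts
#'   `1e-4` / 1000 already suffices.
#' @param seed integer seed; extraction is stochastic.
#' @return object of class `extraction_result`: `selected_k`, `stats`
#'   (per-k stability and relative reconstruction error), `catalog`
#'   (k x 96 probability rows), `exposures` (see [fit_exposures()]),
#'   `n_bootstrap`, `seed`.
#' @export
extract_signatures <- function(mat, k_range = 2:6, n_bootstrap = 100,
                               n_restarts = 10, bootstrap_restarts = 1,
                               stability_threshold = 0.8,
                               min_error_improvement = 0.1,
                               max_iter = 10000, tol = 1e-6,
                               bootstrap_max_iter = 2000,
                               bootstrap_tol = 1e-5, seed = 1) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop("signature extraction needs at least 2 subsets")
  rs <- rowSums(mat)
  if (any(rs <= 0)) {
    stop("all-zero count row(s): ",
         paste(rownames(mat)[rs <= 0], collapse = ", "))
  }
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 1 || max(k_range) > min(nrow(mat), ncol(mat))) {
    stop("k_range must lie within [1, min(subsets, classes)]")
  }
  set.seed(seed)

  stats <- data.frame(k = k_range, stability = NA_real_,
                      recon_error = NA_real_)
  catalogs <- list()
  total_norm <- sqrt(sum(mat^2))
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    pool <- matrix(0, nrow = n_bootstrap * k, ncol = ncol(mat))
    for (b in seq_len(n_bootstrap)) {
      Vb <- multinomial_resample(mat)
      fit <- run_nmf(Vb, k, bootstrap_restarts, bootstrap_max_iter,
                     bootstrap_tol)
      H <- fit$H
      H <- H / pmax(rowSums(H), 1e-12)
      pool[(b - 1) * k + seq_len(k), ] <- H
    }
    if (k == 1) {
      centroid <- colMeans(pool)
      catalogs[[ki]] <- matrix(centroid / sum(centroid), nrow = 1)
      stats$stability[ki] <- 1
    } else {
      # partition the pooled replicate signatures with three complementary
      # partitioners and keep the most coherent cut: k-means restarts can
      # merge two tight groups, Ward can split one; the silhouette arbitrates
      Xn <- pool / sqrt(rowSums(pool^2))
      D <- as.dist(1 - Xn %*% t(Xn))
      h <- hclust(D, method = "average")
      hw <- hclust(D, method = "ward.D2")
      cands <- list(kmeans(Xn, centers = k, nstart = 10,
                           iter.max = 100)$cluster,
                    cutree(h, k), cutree(hw, k))
      sils <- vapply(cands, function(cl) cosine_silhouette(pool, cl),
                     numeric(1))
      cl <- cands[[which.max(sils)]]
      stats$stability[ki] <- max(sils)
      cent <- matrix(0, nrow = k, ncol = ncol(mat))
      for (g in seq_len(k)) {
        cg <- colMeans(pool[cl == g, , drop = FALSE])
        cent[g, ] <- cg / sum(cg)
      }
      catalogs[[ki]] <- cent
    }
    fit0 <- run_nmf(mat, k, n_restarts, max_iter, tol)
    stats$recon_error[ki] <- sqrt(sum((mat - fit0$W %*% fit0$H)^2)) / total_norm
  }

  # eligible: stability reached and the reconstruction error still genuinely
  # decreasing -- each step must cut the error by at least
  # min_error_improvement (relatively); past the true k the improvement
  # collapses to the multinomial noise floor
  prev_err <- stats$recon_error[-nrow(stats)]
  rel_improve <- c(Inf, -diff(stats$recon_error) / pmax(prev_err, 1e-12))
  improving <- cumprod(rel_improve >= min_error_improvement) > 0
  eligible <- stats$stability >= stability_threshold & improving
  if (any(eligible)) {
    selected_k <- max(stats$k[eligible])
  } else {
    selected_k <- stats$k[which.max(stats$stability)]
    warning("no k reached the stability threshold; reporting the most stable k")
  }
  ki <- match(selected_k, k_range)
  catalog <- catalogs[[ki]]
  colnames(catalog) <- colnames(mat) %||% context_classes()
  rownames(catalog) <- paste0("S", seq_len(selected_k))
  exposures <- fit_exposures(mat, catalog)
  structure(list(selected_k = selected_k, stats = stats, catalog = catalog,
                 exposures = exposures, n_bootstrap = n_bootstrap,
                 seed = seed),
            class = "extraction_result")
}

#' @export
print.extraction_result <- function(x, ...) {
  cat("Signature extraction: selected k =", x$selected_k, "\n")
  print(x$stats, row.names = FALSE)
  invisible(x)
}

#' Match a candidate signature against a reference catalog
#'
#' @param candidate numeric 96-vector summing to 1 (tolerance 1e-6).
#' @param reference catalog matrix (processes x 96) with row names.
#' @param threshold cosine similarity below which the candidate is declared
#'   novel.
#' @return list: `best_name` (or `"novel"`), `best_cosine`, `novel` flag and
#'   the full `similarity` table.
#' @export
match_to_catalog <- function(candidate, reference, threshold = 0.85) {
  if (is.null(dim(reference)) || nrow(reference) == 0) {
    stop("empty reference catalog")
  }
  if (abs(sum(candidate) - 1) > 1e-6) {
    stop("candidate must be a probability vector (sum 1)")
  }
  sims <- apply(reference, 1, cosine_similarity, b = candidate)
  best <- which.max(sims)
  novel <- sims[best] < threshold
  list(best_name = if (novel) "novel" else rownames(reference)[best],
       best_cosine = unname(sims[best]),
       novel = novel,
       similarity = sims)
}

#' Refit signature exposures by nonnegative least squares
#'
#' Each count row is projected onto the catalog by NNLS and the fitted
#' loadings rescaled so their sum equals the row's classified-mutation total,
#' conserving mutation counts. All-zero rows yield all-zero exposures.
#'
#' @param mat subsets x 96 count matrix.
#' @param catalog processes x 96 probability matrix.
#' @return list of class `exposure_matrix`: `absolute` (counts),
#'   `relative` (row-normalized fractions; zero rows stay zero) and
#'   `residual` (per-row NNLS residual norm).
#' @export
fit_exposures <- function(mat, catalog) {
  mat <- as.matrix(mat)
  catalog <- as.matrix(catalog)
  stopifnot(ncol(mat) == ncol(catalog))
  k <- nrow(catalog)
  C <- t(catalog)
  absolute <- matrix(0, nrow = nrow(mat), ncol = k,
                     dimnames = list(rownames(mat), rownames(catalog)))
  residual <- numeric(nrow(mat))
  for (i in seq_len(nrow(mat))) {
    y <- mat[i, ]
    tot <- sum(y)
    if (tot == 0) next
    fit <- pracma::lsqnonneg(C, y)
    e <- fit$x
    residual[i] <- sqrt(max(fit$resid.norm, 0))
    if (sum(e) > 0) e <- e * tot / sum(e)
    absolute[i, ] <- e
  }
  rel <- absolute
  nz <- rowSums(absolute) > 0
  rel[nz, ] <- absolute[nz, , drop = FALSE] / rowSums(absolute)[nz]
  structure(list(absolute = absolute, relative = rel, residual = residual),
            class = "exposure_matrix")
}

#' Retain mutation subsets large enough for signature analysis
#'
#' A subset qualifies only with strictly more than `min_mutations`
#' substitutions (a subset of exactly 100 is excluded under the default).
#'
#' @param counts named numeric vector of per-subset mutation counts.
#' @param min_mutations strict lower bound (default 100).
#' @return names of the retained subsets.
#' @export
filter_subsets_for_signatures <- function(counts, min_mutations = 100) {
  names(counts)[counts > min_mutations]
}

#' Hierarchically cluster relative exposure profiles
#'
#' Average-linkage agglomeration on Euclidean distances between relative
#' exposure rows; deterministic for a given row order.
#'
#' @param relative subsets x processes matrix of relative exposures.
#' @param k number of flat groups to cut (default 2).
#' @return list: `hclust` (dendrogram) and `groups` (flat assignment from
#'   [stats::cutree()]).
#' @export
cluster_exposures <- function(relative, k = 2) {
  relative <- as.matrix(relative)
  if (nrow(relative) < 2) {
    stop("only one exposure row: no clustering needed")
  }
  h <- hclust(dist(relative, method = "euclidean"), method = "average")
  list(hclust = h, groups = cutree(h, k = min(k, nrow(relative))))
}

#' Compare two groups of exposure fractions by Wilcoxon rank-sum test
#'
#' Two-sided; the exact null distribution is enumerated when both groups have
#' at most 10 observations and there are no ties, otherwise the normal
#' approximation with tie correction (and continuity correction) is used.
#'
#' @param a,b numeric vectors of exposure fractions.
#' @return list: `statistic` (rank-sum W), `p_value`, `exact` flag.
#' @export
compare_exposure_distributions <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("both groups must be nonempty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- length(a) <= 10 && length(b) <= 10 && !ties
  ht <- wilcox.test(a, b, alternative = "two.sided", exact = exact,
                    correct = !exact)
  list(statistic = unname(ht$statistic), p_value = ht$p.value, exact = exact)
}
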
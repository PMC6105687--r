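# shared fixture builders and independent oracles

make_genome <- function(...) {
  seqs <- c(...)
  g <- Biostrings::DNAStringSet(unname(seqs))
  names(g) <- names(seqs)
  g
}

# toy immunoglobulin loci that fit 3 Mb chromosomes
toy_ig <- function() {
  data.frame(locus = c("IGH_toy", "IGK_toy", "IGL_toy"),
             chrom = c("1", "2", "3"),
             start = c(1000001L, 1500001L, 2000001L),
             end = c(1050000L, 1550000L, 2050000L))
}

small_config <- function(seed = 1, n_patients = 2, n_mut = c(800L, 1200L),
                         depth = 60, ...) {
  simulation_config(
    seed = seed, n_patients = n_patients,
    chromosome_lengths = c(`1` = 3e6, `2` = 3e6, `3` = 3e6),
    n_mutations_range = as.integer(n_mut), depth = depth,
    ig_intervals = toy_ig(), ...)
}

# samples x 96 counts drawn from a mixture of reference processes; the
# independent multinomial oracle for the signature stack
sim_context_matrix <- function(n_samples, processes, n_mut = 5000,
                               loadings = NULL) {
  K <- nrow(processes)
  if (is.null(loadings)) {
    loadings <- matrix(rexp(n_samples * K), n_samples, K)
    loadings <- loadings / rowSums(loadings)
  }
  V <- matrix(0, n_samples, ncol(processes))
  for (i in seq_len(n_samples)) {
    p <- as.numeric(loadings[i, , drop = FALSE] %*% processes)
    V[i, ] <- as.numeric(rmultinom(1, n_mut, p))
  }
  colnames(V) <- colnames(processes)
  rownames(V) <- paste0("s", seq_len(n_samples))
  attr(V, "loadings") <- loadings
  V
}

# brute-force two-sided rank-sum p-value by enumerating all group assignments
enum_ranksum_p <- function(a, b) {
  n <- length(a); m <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(n + m, n)
  stats <- apply(combs, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  centre <- n * m / 2
  mean(abs(stats - centre) >= abs(obs - centre) - 1e-12)
}

# brute-force two-sided signed-rank p-value by enumerating all sign patterns
enum_signedrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  centre <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  stats <- as.numeric(signs %*% r)
  mean(abs(stats - centre) >= abs(obs - centre) - 1e-12)
}

# greedy best cosine match of each truth row among recovered rows
min_truth_cosine <- function(truth, recovered) {
  min(apply(truth, 1, function(t) {
    max(apply(recovered, 1, function(r) sum(t * r) / sqrt(sum(t^2) * sum(r^2))))
  }))
}

# simulate paired read counts for clusters of mutations at given CCF pairs;
# the binomial oracle feeding dp_cluster_2d directly
sim_dp_input <- function(n_per_cluster, centers_smm, centers_mm, depth = 100,
                         zeta = 0.5) {
  truth <- rep(seq_along(centers_smm), n_per_cluster)
  n <- length(truth)
  dep1 <- rpois(n, depth); dep2 <- rpois(n, depth)
  dep1 <- pmax(dep1, 1L); dep2 <- pmax(dep2, 1L)
  alt1 <- rbinom(n, dep1, centers_smm[truth] * zeta)
  alt2 <- rbinom(n, dep2, centers_mm[truth] * zeta)
  list(input = data.frame(chrom = "1", pos = seq_len(n),
                          alt_smm = alt1, depth_smm = dep1,
                          alt_mm = alt2, depth_mm = dep2,
                          zeta_smm = zeta, zeta_mm = zeta),
       truth = truth)
}

# cluster table builder for classify_progression tests
cluster_row <- function(id, smm, mm, half_width = 0.02, n = 200) {
  data.frame(cluster = id, center_smm = smm, center_mm = mm, n_mutations = n,
             ci_smm_lo = smm - half_width, ci_smm_hi = smm + half_width,
             ci_mm_lo = mm - half_width, ci_mm_hi = mm + half_width,
             occupancy = 0.2)
}
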
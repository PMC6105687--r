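test_that("a rank-1 count matrix selects k = 1 with near-zero reconstruction error", {
  P <- bundled_signatures()
  V <- outer(c(120, 260, 340, 500), P["apobec", ]) * 10
  colnames(V) <- context_classes()
  rownames(V) <- paste0("s", 1:4)
  r <- extract_signatures(V, k_range = 1:2, n_bootstrap = 20, seed = 11,
                          tol = 1e-9)
  expect_equal(r$selected_k, 1)
  expect_lt(r$stats$recon_error[r$stats$k == 1], 1e-6)
  expect_gt(smmevo:::cosine_similarity(r$catalog[1, ], P["apobec", ]), 0.999)
})

test_that("catalog matching finds identical rows, argmax rows, and novelty", {
  P <- bundled_signatures()
  m <- match_to_catalog(P["nc_aid", ], P)
  expect_equal(m$best_name, "nc_aid")
  expect_equal(m$best_cosine, 1, tolerance = 1e-12)

  u <- rep(1 / 96, 96)
  m2 <- match_to_catalog(u, P, threshold = 0)
  brute <- which.max(apply(P, 1, function(r) {
    sum(r * u) / sqrt(sum(r^2) * sum(u^2))
  }))
  expect_equal(m2$best_name, rownames(P)[brute])

  # a vector far from every catalog row is reported as novel
  novel <- setNames(rep(0, 96), context_classes())
  novel[c("C[T>A]C", "C[T>A]G")] <- 0.5
  m3 <- match_to_catalog(novel, P)
  expect_true(m3$novel)
  expect_equal(m3$best_name, "novel")

  expect_error(match_to_catalog(u, P[0, , drop = FALSE]), "empty")
  expect_error(match_to_catalog(u * 2, P), "probability")
})

test_that("NNLS exposure refitting is exact on pure rows and conserves totals", {
  P <- bundled_signatures()
  V <- rbind(pure = 100 * P["apobec", ],
             zero = rep(0, 96))
  e <- fit_exposures(V, P)
  expect_equal(unname(e$absolute["pure", "apobec"]), 100, tolerance = 1e-6)
  expect_equal(sum(e$absolute["pure", ]) - 100, 0, tolerance = 1e-6)
  expect_equal(unname(e$absolute["zero", ]), rep(0, 5))
  expect_equal(e$residual[2], 0)
  expect_true(all(e$absolute >= 0))
})

test_that("a 60/40 two-process mixture is recovered within 0.03 at 10k mutations", {
  set.seed(21)
  P <- bundled_signatures()
  p <- 0.6 * P["apobec", ] + 0.4 * P["nc_aid", ]
  V <- matrix(as.numeric(rmultinom(1, 10000, p)), nrow = 1)
  colnames(V) <- context_classes()
  e <- fit_exposures(V, P)
  expect_equal(unname(e$relative[1, "apobec"]), 0.6, tolerance = 0.03)
  expect_equal(unname(e$relative[1, "nc_aid"]), 0.4, tolerance = 0.03)
  expect_equal(sum(e$absolute[1, ]), 10000, tolerance = 0.5)
})

test_that("the per-cluster filter is strictly greater than 100", {
  counts <- c(a = 100, b = 101, c = 0, d = 5000)
  expect_identical(filter_subsets_for_signatures(counts), c("b", "d"))
})

test_that("exposure clustering separates simplex corners and is deterministic", {
  rel <- rbind(a = c(1, 0, 0), b = c(0.98, 0.02, 0),
               c = c(0, 0, 1), d = c(0.02, 0, 0.98))
  cl <- cluster_exposures(rel, k = 2)
  expect_equal(unname(cl$groups["a"]), unname(cl$groups["b"]))
  expect_equal(unname(cl$groups["c"]), unname(cl$groups["d"]))
  expect_false(unname(cl$groups["a"]) == unname(cl$groups["c"]))
  # identical rows merge at height zero
  h <- cluster_exposures(rbind(x = c(0.5, 0.5), y = c(0.5, 0.5)))$hclust
  expect_equal(h$height[1], 0)
  expect_error(cluster_exposures(rel[1, , drop = FALSE]), "one exposure row")
})

test_that("rank-sum comparison matches brute-force enumeration", {
  r <- compare_exposure_distributions(c(1, 2, 3), c(4, 5, 6))
  expect_true(r$exact)
  expect_equal(r$p_value, 0.1)
  expect_equal(r$p_value, enum_ranksum_p(c(1, 2, 3), c(4, 5, 6)))

  set.seed(5)
  for (i in 1:5) {
    a <- rnorm(4); b <- rnorm(5) + 0.5
    r2 <- compare_exposure_distributions(a, b)
    expect_equal(r2$p_value, enum_ranksum_p(a, b), tolerance = 1e-12)
  }

  # identical groups: symmetric case, no evidence of a shift
  r3 <- compare_exposure_distributions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r3$p_value, 1)
  expect_error(compare_exposure_distributions(numeric(0), 1:3), "nonempty")
})

test_that("label equivariance: permuting input rows permutes exposures", {
  set.seed(31)
  P <- bundled_signatures()
  V <- sim_context_matrix(6, P[c("apobec", "nc_aid"), ], n_mut = 2000)
  e1 <- fit_exposures(V, P)
  perm <- c(3, 1, 6, 2, 5, 4)
  e2 <- fit_exposures(V[perm, ], P)
  expect_equal(e2$absolute, e1$absolute[perm, ], tolerance = 1e-9)
})

test_that("extraction rejects degenerate inputs", {
  P <- bundled_signatures()
  V <- rbind(a = 100 * P[1, ], b = rep(0, 96))
  expect_error(extract_signatures(V, k_range = 1:2, seed = 1), "all-zero")
  expect_error(extract_signatures(V[1, , drop = FALSE], k_range = 1,
                                  seed = 1), "at least 2")
  expect_error(extract_signatures(rbind(a = 100 * P[1, ], b = 90 * P[2, ]),
                                  k_range = 1:50, seed = 1), "k_range")
})
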
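test_that("hybrid profile concatenates sign-fixed PC blocks", {
  set.seed(2)
  H_rna <- matrix(rnorm(80 * 50), 80, 50)
  H_img <- matrix(rnorm(80 * 20), 80, 20)
  hy <- build_hybrid_profile(H_rna, H_img, p_rna = 30, p_img = 5)
  expect_equal(ncol(hy), 35)
  expect_equal(unname(attr(hy, "pcs")), c(30, 5))

  # p_img = 0: expression-only profile equals the RNA block alone
  hy_rna <- build_hybrid_profile(H_rna, H_img, p_rna = 30, p_img = 0)
  expect_equal(unname(hy_rna), unname(hy[, 1:30]), ignore_attr = TRUE)
  expect_error(build_hybrid_profile(H_rna, NULL, p_rna = 0, p_img = 0),
               "at least one")

  # shifting every row by a constant vector leaves the profile unchanged
  shift <- matrix(rnorm(50), 80, 50, byrow = TRUE)
  hy2 <- build_hybrid_profile(H_rna + shift, H_img, p_rna = 30, p_img = 5)
  expect_equal(hy2, hy, tolerance = 1e-8)
})

test_that("requesting more PCs than the rank supports is clipped, with low-rank tails flat", {
  set.seed(3)
  base <- matrix(rnorm(40 * 2), 40, 2) %*% matrix(rnorm(2 * 12), 2, 12)
  expect_warning(hy <- build_hybrid_profile(base, NULL, p_rna = 5, p_img = 0),
                 regexp = NA)        # 5 <= 12 columns: no clipping warning
  expect_true(all(apply(hy[, 3:5, drop = FALSE], 2, var) < 1e-10))
  expect_warning(build_hybrid_profile(matrix(rnorm(12), 4, 3), NULL,
                                      p_rna = 10, p_img = 0), "clipped")
})

test_that("the mixture model recovers well-separated blobs", {
  set.seed(7)
  n <- 60
  X <- rbind(cbind(rnorm(n), rnorm(n)), cbind(rnorm(n) + 10, rnorm(n) + 10))
  truth <- rep(1:2, each = n)
  labs <- cluster_gmm(X, 2, seed = 1)
  expect_equal(adjusted_rand_index(labs, truth), 1)
  # labels renumbered by decreasing size -> both present
  expect_setequal(unique(labs), 1:2)
  # duplicated points always co-assign
  Xd <- rbind(X, X[1:5, ])
  labs_d <- cluster_gmm(Xd, 2, seed = 1)
  expect_equal(labs_d[(2 * n + 1):(2 * n + 5)], labs_d[1:5])
  # determinism
  expect_identical(cluster_gmm(X, 2, seed = 9), cluster_gmm(X, 2, seed = 9))
})

test_that("boundary cluster counts run without error", {
  set.seed(8)
  X <- matrix(rnorm(12 * 2), 12, 2) * 5
  labs <- cluster_gmm(X, 11, seed = 2)
  expect_lte(length(unique(labs)), 11)
  expect_error(cluster_gmm(X, 1, seed = 1), "at least 2")
  expect_error(cluster_gmm(X[1:3, ], 3, seed = 1), "more observations")
})

test_that("refinement follows majority, keeps coherent maps, honours ties", {
  # 12 spots on a line; spot 1 carries label 1, its 10 nearest all label 2
  co <- cbind(pixel_row = rep(0, 12), pixel_col = 1:12)
  labs <- c(1, rep(2, 11))
  ref <- refine_labels(labs, co, r = 10)
  expect_equal(ref[1], 2)

  # two coherent half-planes are a fixed point away from the boundary
  sim <- tiny_sim(seed = 1)
  co2 <- sim$dataset$coords
  half <- ifelse(co2[, "pixel_row"] <= median(co2[, "pixel_row"]), 1L, 2L)
  ref2 <- refine_labels(half, co2, r = 4)
  interior <- abs(co2[, "pixel_row"] - median(co2[, "pixel_row"])) > 100
  expect_equal(ref2[interior], half[interior])
  # idempotence on locally constant labelings
  expect_equal(refine_labels(ref2, co2, r = 4), ref2)

  # constructed 5-5 tie between own and other label keeps the current label
  co3 <- cbind(pixel_row = rep(0, 11), pixel_col = c(0, 1:10))
  labs3 <- c(1, rep(1, 5), rep(2, 5))
  expect_equal(refine_labels(labs3, co3, r = 10)[1], 1)
  # 5-5 tie between two labels neither of which is the spot's own: smallest id
  labs4 <- c(3, rep(1, 5), rep(2, 5))
  expect_equal(refine_labels(labs4, co3, r = 10)[1], 1)

  expect_error(refine_labels(labs3, co3, r = 0), "positive")
  expect_error(refine_labels(labs3, co3, r = 11), "smaller")
})

test_that("silhouette selection finds the true cluster count", {
  set.seed(5)
  n <- 40
  X <- rbind(cbind(rnorm(n), rnorm(n)),
             cbind(rnorm(n) + 12, rnorm(n)),
             cbind(rnorm(n) + 6, rnorm(n) + 10))
  sel <- select_k_by_silhouette(X, 2:5, seed = 3)
  expect_equal(sel$k_best, 3L)
  expect_equal(names(sel$silhouette_by_k), as.character(2:5))

  # a single Gaussian blob has weak 2-cluster structure
  X1 <- matrix(rnorm(150 * 4), 150, 4)
  sel1 <- select_k_by_silhouette(X1, 2, seed = 3)
  expect_lt(sel1$silhouette_by_k[["2"]], 0.3)
  expect_error(select_k_by_silhouette(X1, integer(0), seed = 1), "non-empty")
})

test_that("call_domains wires profile, clustering and refinement together", {
  set.seed(9)
  n <- 50
  H_rna <- rbind(matrix(rnorm(n * 10), n, 10),
                 matrix(rnorm(n * 10, mean = 8), n, 10))
  co <- cbind(pixel_row = c(rep(0, n), rep(1000, n)) + runif(2 * n, 0, 300),
              pixel_col = runif(2 * n, 0, 300))
  res <- call_domains(H_rna, NULL, coords = co, k = 2, p_rna = 5, p_img = 0,
                      seed = 4)
  expect_s3_class(res, "proust_domains")
  expect_equal(res$k, 2)
  expect_equal(adjusted_rand_index(res$labels, rep(1:2, each = n)), 1)
  expect_length(res$refined_labels, 2 * n)
})
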
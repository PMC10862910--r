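line_graph <- function(n = 3) {
  build_knn_graph(cbind(pixel_row = rep(0, n), pixel_col = seq_len(n)), k = 1)
}

test_that("gcn_layer evaluates the propagation recurrence", {
  co <- cbind(pixel_row = c(0, 5), pixel_col = c(0, 0))
  g <- build_knn_graph(co, k = 1)               # L = [[1,1],[1,1]]
  out <- gcn_layer(matrix(c(1, 2), 2, 1), g$L, matrix(1, 1, 1), 0)
  expect_equal(out, matrix(3, 2, 1), ignore_attr = TRUE)

  # ReLU clamps negative pre-activations to exactly zero
  out2 <- gcn_layer(matrix(c(1, 2), 2, 1), g$L, matrix(-1, 1, 1), 0)
  expect_equal(out2, matrix(0, 2, 1), ignore_attr = TRUE)

  z <- gcn_layer(matrix(0, 2, 3), g$L, diag(3), numeric(3))
  expect_true(all(z == 0))
  expect_error(gcn_layer(matrix(0, 2, 3), g$L, diag(2), numeric(2)), "shape")
})

test_that("corruption permutes rows, preserves the multiset, leaves the graph", {
  set.seed(1)
  X <- matrix(rnorm(12), 4, 3)
  Xc <- corrupt_features(X, seed = 7)
  expect_equal(X[order(X[, 1]), ], Xc[order(Xc[, 1]), ])
  expect_identical(corrupt_features(X, seed = 7), Xc)   # seeded determinism

  X2 <- matrix(1:4, 2, 2)
  c2 <- corrupt_features(X2, seed = 1)
  expect_true(identical(c2, X2) || identical(c2, X2[2:1, ]))

  g <- line_graph(4)
  A_before <- as.matrix(g$A)
  invisible(corrupt_features(X, seed = 3))
  expect_identical(as.matrix(g$A), A_before)
})

test_that("readout matches hand evaluation", {
  g <- line_graph(3)
  Z0 <- matrix(0, 3, 2)
  expect_true(all(readout(Z0, g, k = 1) == 0.5))        # sigmoid(0)

  z <- c(1.5, -0.5)
  Zc <- rbind(z, z, z)
  expect_equal(readout(Zc, g, k = 1)[1, ], 1 / (1 + exp(-2 * z)),
               ignore_attr = TRUE)

  # 3-spot line, k = 1: neighbour of spot 1 is spot 2, of spot 2 is spot 1
  # (tie with spot 3 broken by index), of spot 3 is spot 2
  Z <- rbind(c(1, 0), c(0, 2), c(-1, 1))
  S <- readout(Z, g, k = 1)
  expect_equal(S[1, ], 1 / (1 + exp(-(Z[2, ] + Z[1, ]))), ignore_attr = TRUE)
  expect_equal(S[2, ], 1 / (1 + exp(-(Z[1, ] + Z[2, ]))), ignore_attr = TRUE)
  expect_equal(S[3, ], 1 / (1 + exp(-(Z[2, ] + Z[3, ]))), ignore_attr = TRUE)
  expect_error(readout(Z, g, k = 5), "exceeds")
})

test_that("discriminator is the sigmoid bilinear form", {
  expect_equal(discriminate(c(1, 2), c(3, 4), matrix(0, 2, 2)), 0.5)
  expect_equal(discriminate(c(1, 0), c(0, 1), diag(2)), 0.5)
  expect_equal(discriminate(c(1, 2), c(3, 4), diag(2)), 1 / (1 + exp(-11)))
})

test_that("contrastive losses reproduce hand-computed values", {
  n <- 4
  Z <- matrix(0, n, 2)
  S <- matrix(0.3, n, 2)
  out <- csl_losses(Z, Z, S, S, matrix(0, 2, 2))        # all scores 0.5
  expect_equal(unname(out["csl"]), log(2), tolerance = 1e-12)
  expect_equal(unname(out["csl_corrupt"]), log(2), tolerance = 1e-12)

  # N = 1 with engineered scores: positive 0.8, negative 0.3
  w <- log(0.8 / 0.2)                                   # logit(0.8)
  Z1 <- matrix(1, 1, 1); S1 <- matrix(1, 1, 1)
  Zc <- matrix(log(0.3 / 0.7) / w, 1, 1)                # gives sigmoid = 0.3
  out2 <- csl_losses(Z1, Zc, S1, S1, matrix(w, 1, 1))
  expect_equal(unname(out2["csl"]), -(log(0.8) + log(0.7)) / 2, tolerance = 1e-10)
  expect_equal(round(unname(out2["csl"]), 4), 0.2899)

  # saturated discriminator: losses collapse to ~0
  big <- matrix(1e4, 1, 1)
  out3 <- csl_losses(matrix(1, 1, 1), matrix(-1, 1, 1),
                     matrix(1, 1, 1), matrix(1, 1, 1), big)
  expect_lt(unname(out3["csl"]), 1e-3)
})

test_that("with beta = 0 the trainer matches an independent plain autoencoder", {
  # independent oracle: a from-scratch two-layer GCN autoencoder with the
  # same seeding protocol (Glorot init order, per-iteration permutation
  # draw) and Adam updates, no contrastive terms anywhere
  plain_gae <- function(X, L, iters, seed, d1 = 8, d2 = 4, lr = 1e-3) {
    n <- nrow(X); p <- ncol(X)
    set.seed(seed)
    gl <- function(fi, fo) {
      lim <- sqrt(6 / (fi + fo))
      matrix(runif(fi * fo, -lim, lim), fi, fo)
    }
    th <- list(We1 = gl(p, d1), be1 = numeric(d1), We2 = gl(d1, d2),
               be2 = numeric(d2), Wd1 = gl(d2, d1), bd1 = numeric(d1),
               Wd2 = gl(d1, p), bd2 = numeric(p), Wdisc = matrix(0, d2, d2))
    m <- lapply(th, function(x) x * 0); v <- m; tt <- 0
    Ld <- as.matrix(L)
    hist <- numeric(iters)
    for (it in seq_len(iters)) {
      perm <- sample.int(n)                      # keep RNG stream aligned
      Xc <- X[perm, , drop = FALSE]
      fwd <- function(Xi) {
        p1 <- Ld %*% Xi %*% th$We1 + rep(1, n) %o% th$be1
        h1 <- pmax(p1, 0)
        p2 <- Ld %*% h1 %*% th$We2 + rep(1, n) %o% th$be2
        list(p1 = p1, h1 = h1, p2 = p2, Z = pmax(p2, 0))
      }
      fe <- fwd(X); fc <- fwd(Xc)
      pd1 <- Ld %*% fe$Z %*% th$Wd1 + rep(1, n) %o% th$bd1
      hd1 <- pmax(pd1, 0)
      H <- Ld %*% hd1 %*% th$Wd2 + rep(1, n) %o% th$bd2
      hist[it] <- sum((H - X)^2)
      dH <- 2 * (H - X)
      g <- list()
      g$Wd2 <- t(Ld %*% hd1) %*% dH; g$bd2 <- colSums(dH)
      dpd1 <- (t(Ld) %*% dH %*% t(th$Wd2)) * (pd1 > 0)
      g$Wd1 <- t(Ld %*% fe$Z) %*% dpd1; g$bd1 <- colSums(dpd1)
      dZ <- t(Ld) %*% dpd1 %*% t(th$Wd1)
      bk <- function(f, Xi, dZv) {
        dp2 <- dZv * (f$p2 > 0)
        w2 <- t(Ld %*% f$h1) %*% dp2
        dh1 <- t(Ld) %*% dp2 %*% t(th$We2)
        dp1 <- dh1 * (f$p1 > 0)
        list(We1 = t(Ld %*% Xi) %*% dp1, be1 = colSums(dp1),
             We2 = w2, be2 = colSums(dp2))
      }
      ge <- bk(fe, X, dZ)
      # corrupted path carries no gradient when beta = 0, but the encoder is
      # still evaluated on it; weight grads from that path are zero
      g$We1 <- ge$We1; g$be1 <- ge$be1; g$We2 <- ge$We2; g$be2 <- ge$be2
      g$Wdisc <- th$Wdisc * 0
      tt <- tt + 1
      for (nm in names(th)) {
        gr <- g[[nm]]
        if (is.null(gr)) gr <- th[[nm]] * 0
        m[[nm]] <- 0.9 * m[[nm]] + 0.1 * gr
        v[[nm]] <- 0.999 * v[[nm]] + 0.001 * gr * gr
        th[[nm]] <- th[[nm]] - lr * (m[[nm]] / (1 - 0.9^tt)) /
          (sqrt(v[[nm]] / (1 - 0.999^tt)) + 1e-8)
      }
    }
    hist
  }

  sim <- simulate_spots(n_rows = 3, k_domains = 2, n_cols = 4, n_genes = 12, seed = 6)
  expr <- preprocess_expression(sim$dataset, n_top_hvg = 12)
  g <- build_knn_graph(sim$dataset$coords, k = 2)
  emb <- train_modality(expr$values, g, alpha = 1, beta = 0, iters = 40,
                        seed = 9, latent_dims = c(8, 4))
  oracle <- plain_gae(expr$values, g$L, iters = 40, seed = 9)
  expect_equal(emb$loss_history$recon, oracle, tolerance = 1e-6)
  # Eq.-6 limit: total loss is exactly alpha * recon at every iteration
  expect_equal(emb$loss_history$total, emb$loss_history$recon, tolerance = 1e-9)
})

test_that("training is seed-deterministic and mirrors identical subgraphs", {
  sim <- tiny_sim(seed = 4)
  expr <- preprocess_expression(sim$dataset, n_top_hvg = 30)
  g <- build_knn_graph(sim$dataset$coords, k = 3)
  e1 <- train_modality(expr$values, g, iters = 25, seed = 3,
                       latent_dims = c(16, 8))
  e2 <- train_modality(expr$values, g, iters = 25, seed = 3,
                       latent_dims = c(16, 8))
  expect_identical(e1$loss_history, e2$loss_history)
  expect_identical(e1$Z, e2$Z)

  # two far-apart copies of the same 4-spot square with identical features:
  # mirrored spots get identical embeddings (the encoder has no cross-copy
  # terms once the graph is disconnected)
  sq <- cbind(pixel_row = c(0, 0, 1, 1), pixel_col = c(0, 1, 0, 1))
  co <- rbind(sq, sq + 1000)
  Xh <- matrix(rnorm(4 * 6), 4, 6)
  X <- rbind(Xh, Xh)
  gg <- build_knn_graph(co, k = 2)
  emb <- train_modality(X, gg, iters = 30, seed = 2, latent_dims = c(5, 3))
  expect_equal(emb$Z[1:4, ], emb$Z[5:8, ], tolerance = 1e-10)
  expect_equal(emb$H[1:4, ], emb$H[5:8, ], tolerance = 1e-10)
})

test_that("embeddings separate two feature-distinct domains", {
  set.seed(21)
  n <- 100
  co <- cbind(pixel_row = rep(1:10, each = 10) * 10,
              pixel_col = rep(1:10, times = 10) * 10)
  dom <- rep(c(1, 2), each = 50)
  X <- matrix(rnorm(n * 20), n, 20) + outer(dom == 2, rep(3, 20)) * 1
  g <- build_knn_graph(co, k = 3)
  emb <- train_modality(X, g, iters = 150, seed = 5, latent_dims = c(16, 8))
  Z <- emb$Z
  cs <- Z / sqrt(rowSums(Z^2) + 1e-12)
  sim_mat <- cs %*% t(cs)
  within <- mean(sim_mat[dom %o% rep(1, n) == rep(1, n) %o% dom])
  between <- mean(sim_mat[dom %o% rep(1, n) != rep(1, n) %o% dom])
  expect_gt(within, between)
})

test_that("image-modality trainer reduces to the flat trainer for C = 1", {
  sim <- simulate_spots(n_rows = 2, k_domains = 2, n_cols = 4, n_genes = 10,
                        image_channels = 1, seed = 12)
  gt <- extract_spot_grids(sim$dataset$images, sim$dataset$coords,
                           sim$dataset$spot_diameter_px)
  gt <- normalize_grid_range(gt, matrix(c(-2, 8), 1))
  gt <- train_image_autoencoder(gt, iters = 10, seed = 3)
  g <- build_knn_graph(sim$dataset$coords, k = 2)
  e_img <- train_image_modality(gt, g, iters = 20, seed = 4,
                                latent_dims = c(8, 4))
  flat <- matrix(gt$features[, 1, ], dim(gt$features)[1], 576)
  e_ref <- train_modality(flat, g, iters = 20, seed = 4, latent_dims = c(8, 4))
  expect_equal(e_img$Z, e_ref$Z)
  expect_equal(drop(e_img$H_tensor[, 1, ]), unname(e_ref$H), ignore_attr = TRUE)

  # channel-major flatten/reshape round-trips
  expect_equal(e_img$H_tensor[, 1, ], e_img$H[, 1:576], ignore_attr = TRUE)
})

test_that("an all-zero feature channel is reconstructed towards zero", {
  set.seed(30)
  n <- 24
  co <- cbind(pixel_row = rep(1:4, each = 6) * 10,
              pixel_col = rep(1:6, times = 4) * 10)
  g <- build_knn_graph(co, k = 3)
  # informative channel is low-rank so the latent space can represent it
  f <- array(0, dim = c(n, 2, 20))
  f[, 1, ] <- tcrossprod(matrix(rnorm(n * 2, sd = 3), n, 2),
                         matrix(rnorm(20 * 2), 20, 2))
  gt <- structure(list(grids = array(0, c(n, 2, 48, 48)), features = f,
                       channel_names = c("a", "b"), grid_px = 48L, d = 89L),
                  class = "image_grid_tensor")
  emb <- train_image_modality(gt, g, iters = 4000, seed = 6,
                              latent_dims = c(8, 4))
  n1 <- sqrt(sum(emb$H_tensor[, 1, ]^2))
  n2 <- sqrt(sum(emb$H_tensor[, 2, ]^2))
  # converges towards zero; a fixed-step Adam cannot drive the block to
  # machine zero, so assert a small relative floor rather than exact decay
  expect_lt(n2, 0.05 * n1)
})
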
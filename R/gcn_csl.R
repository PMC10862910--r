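# Graph convolutional autoencoder with Deep-Graph-Infomax-style contrastive
# self-supervised learning. One trainer per modality (expression / image
# features); manual backpropagation through the GCN layers, read-out,
# bilinear discriminator and reconstruction, optimised with Adam.

#' One graph convolution layer
#'
#' Computes `ReLU(L %*% features %*% W + b)` (bias broadcast over spots),
#' the layer recurrence used by both encoder and decoder.
#'
#' @param features N × p input matrix.
#' @param L propagation matrix (from [build_knn_graph()]).
#' @param W p × q weight matrix.
#' @param b length-q bias.
#' @param activation `"relu"` or `"linear"` (final reconstruction layer).
#' @return N × q output matrix.
#' @export
gcn_layer <- function(features, L, W, b, activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  if (ncol(features) != nrow(W) || length(b) != ncol(W))
    stop_proust("gcn_layer: shape mismatch (features ", ncol(features),
                " cols, W ", nrow(W), "x", ncol(W), ", b ", length(b), ")")
  pre <- as.matrix(L %*% features %*% W)
  pre <- sweep(pre, 2, b, "+")
  if (activation == "relu") relu(pre) else pre
}

#' Corrupt a feature matrix by row shuffling
#'
#' Negative-sample generation for contrastive learning: rows (spots) of the
#' feature matrix are permuted uniformly at random while the spatial graph
#' is left untouched, so corrupted features sit in the true neighbourhood
#' structure.
#'
#' @param X N × p feature matrix.
#' @param seed optional seed; if supplied the permutation is drawn from a
#'   fresh RNG stream seeded with it, otherwise from the ambient stream.
#' @return the row-permuted matrix.
#' @export
corrupt_features <- function(X, seed = NULL) {
  if (nrow(X) < 2) stop_proust("need at least 2 rows to corrupt")
  if (!is.null(seed)) set.seed(seed)
  X[sample.int(nrow(X)), , drop = FALSE]
}

# Sparse row-mean operator over each spot's k nearest neighbours.
readout_operator <- function(graph, k = graph$k) {
  if (k > ncol(graph$knn))
    stop_proust("read-out k = ", k, " exceeds stored neighbours (", ncol(graph$knn), ")")
  n <- nrow(graph$knn)
  Matrix::sparseMatrix(i = rep(seq_len(n), each = k),
                       j = as.vector(t(graph$knn[, seq_len(k), drop = FALSE])),
                       x = 1 / k, dims = c(n, n))
}

#' Neighbourhood read-out
#'
#' Summarises each spot's local context as
#' `S_i = sigmoid(mean(Z over the k nearest neighbours of i) + Z_i)`,
#' with neighbours taken by the same Euclidean rule as the spatial graph.
#'
#' @param Z N × q latent matrix, row-aligned with the graph.
#' @param graph a `spatial_graph`.
#' @param k number of neighbours to average (default: the graph's k).
#' @return N × q matrix of neighbourhood summaries in (0, 1).
#' @export
readout <- function(Z, graph, k = graph$k) {
  M <- readout_operator(graph, k)
  sigmoid(as.matrix(M %*% Z) + Z)
}

#' Bilinear discriminator score
#'
#' `sigmoid(Z_i' W S_i)`: the probability that a (spot embedding,
#' neighbourhood summary) pair is a true pair rather than a corrupted one.
#'
#' @param Z_i latent vector (or N × q matrix for row-wise scoring).
#' @param S_i summary vector (or matrix, row-aligned with `Z_i`).
#' @param W q × q trainable scoring matrix.
#' @return scalar (or vector) in (0, 1).
#' @export
discriminate <- function(Z_i, S_i, W) {
  if (is.null(dim(Z_i))) Z_i <- matrix(Z_i, 1)
  if (is.null(dim(S_i))) S_i <- matrix(S_i, 1)
  drop(sigmoid(rowSums((Z_i %*% W) * S_i)))
}

#' Contrastive losses for true and corrupted views
#'
#' Binary-cross-entropy-style objectives over positive pairs (embedding with
#' its own neighbourhood summary) and negative pairs (embedding with the
#' other view's summary), each averaged over 2N terms:
#' `L_CSL = -(1/2N) (sum log D(Z_i, S_i) + sum log(1 - D(Z'_j, S_j)))` and
#' `L_CSL_corrupt = -(1/2N) (sum log D(Z'_i, S'_i) + sum log(1 - D(Z_j, S'_j)))`.
#' Scores are clamped to `(1e-7, 1 - 1e-7)` to keep the logs finite.
#'
#' @param Z,Z_corrupt latent matrices of the true and corrupted views.
#' @param S,S_corrupt the corresponding read-out summaries.
#' @param W discriminator scoring matrix.
#' @return named numeric vector `c(csl = ..., csl_corrupt = ...)`.
#' @export
csl_losses <- function(Z, Z_corrupt, S, S_corrupt, W) {
  eps <- 1e-7
  cl <- function(p) pmin(pmax(p, eps), 1 - eps)
  n <- nrow(Z)
  d_pos <- cl(discriminate(Z, S, W))
  d_neg <- cl(discriminate(Z_corrupt, S, W))
  d_pos_c <- cl(discriminate(Z_corrupt, S_corrupt, W))
  d_neg_c <- cl(discriminate(Z, S_corrupt, W))
  c(csl = -(sum(log(d_pos)) + sum(log(1 - d_neg))) / (2 * n),
    csl_corrupt = -(sum(log(d_pos_c)) + sum(log(1 - d_neg_c))) / (2 * n))
}

#' Train one modality's graph autoencoder with contrastive learning
#'
#' Fits a two-layer GCN encoder (input → `latent_dims[1]` → `latent_dims[2]`,
#' ReLU) and mirrored decoder (ReLU inner layer, linear reconstruction
#' layer) on features `X` over the spatial graph, minimising
#' `alpha * L_recon + beta * (L_CSL + L_CSL_corrupt)` with Adam, where
#' `L_recon` is the squared Frobenius error between `X` and its
#' reconstruction. Each iteration draws a fresh row-shuffling corruption
#' from the seeded stream; the real and corrupted views share the encoder.
#' The discriminator matrix starts at zero (all scores 0.5, both
#' contrastive losses log 2) and weight matrices are Glorot-uniform.
#'
#' @param X N × p preprocessed feature matrix.
#' @param graph a `spatial_graph` on the same spots.
#' @param alpha reconstruction-loss weight (default 1).
#' @param beta contrastive-loss weight (default 1; 0 gives a plain graph
#'   autoencoder).
#' @param lr Adam learning rate.
#' @param iters full-batch iterations (default 600).
#' @param seed integer seed covering initialisation and the corruption
#'   stream; equal seeds give equal loss histories.
#' @param latent_dims encoder layer widths, input → first → latent.
#' @return a `modality_embedding`: list with `Z`, `Z_corrupt`, `H`
#'   (reconstruction), `S`, `loss_history` (data.frame: iter, recon, csl,
#'   csl_corrupt, total) and `state` (an autoencoder-state list of encoder/
#'   decoder weights, the discriminator matrix, `alpha`, `beta`,
#'   `layer_dims`).
#' @export
train_modality <- function(X, graph, alpha = 1, beta = 1, lr = 1e-3,
                           iters = 600, seed = 1, latent_dims = c(64, 32)) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(inherits(graph, "spatial_graph"), length(graph$D) == n, iters >= 1)
  d1 <- latent_dims[1]; d2 <- latent_dims[2]
  L <- graph$L
  Lt <- Matrix::t(L)
  R <- readout_operator(graph) + Matrix::Diagonal(n)   # summary = mean(kNN) + self
  Rt <- Matrix::t(R)

  set.seed(seed)
  params <- list(
    We1 = glorot(p, d1), be1 = numeric(d1),
    We2 = glorot(d1, d2), be2 = numeric(d2),
    Wd1 = glorot(d2, d1), bd1 = numeric(d1),
    Wd2 = glorot(d1, p), bd2 = numeric(p),
    Wdisc = matrix(0, d2, d2))
  st <- adam_init(params)
  hist <- matrix(NA_real_, iters, 4,
                 dimnames = list(NULL, c("recon", "csl", "csl_corrupt", "total")))

  encode <- function(Xin) {
    pre1 <- as.matrix(L %*% Xin %*% params$We1)
    pre1 <- sweep(pre1, 2, params$be1, "+")
    h1 <- relu(pre1)
    pre2 <- as.matrix(L %*% h1 %*% params$We2)
    pre2 <- sweep(pre2, 2, params$be2, "+")
    list(pre1 = pre1, h1 = h1, pre2 = pre2, Z = relu(pre2))
  }

  for (it in seq_len(iters)) {
    perm <- sample.int(n)
    Xc <- X[perm, , drop = FALSE]
    fe <- encode(X)
    fc <- encode(Xc)
    Z <- fe$Z; Zc <- fc$Z

    preS <- as.matrix(R %*% Z); S <- sigmoid(preS)
    preSc <- as.matrix(R %*% Zc); Sc <- sigmoid(preSc)

    # decoder on the real view only
    pd1 <- sweep(as.matrix(L %*% Z %*% params$Wd1), 2, params$bd1, "+")
    hd1 <- relu(pd1)
    H <- sweep(as.matrix(L %*% hd1 %*% params$Wd2), 2, params$bd2, "+")

    diff <- H - X
    recon <- sum(diff * diff)
    ZW <- Z %*% params$Wdisc
    ZcW <- Zc %*% params$Wdisc
    d_pos <- sigmoid(rowSums(ZW * S))
    d_neg <- sigmoid(rowSums(ZcW * S))
    d_pos_c <- sigmoid(rowSums(ZcW * Sc))
    d_neg_c <- sigmoid(rowSums(ZW * Sc))
    eps <- 1e-7
    cl <- function(x) pmin(pmax(x, eps), 1 - eps)
    csl <- -(sum(log(cl(d_pos))) + sum(log(1 - cl(d_neg)))) / (2 * n)
    cslc <- -(sum(log(cl(d_pos_c))) + sum(log(1 - cl(d_neg_c)))) / (2 * n)
    total <- alpha * recon + beta * (csl + cslc)
    if (!is.finite(total))
      stop_proust("non-finite training loss at iteration ", it)
    hist[it, ] <- c(recon, csl, cslc, total)

    # --- backward ---
    dH <- 2 * alpha * diff
    gWd2 <- crossprod(as.matrix(L %*% hd1), dH)
    gbd2 <- colSums(dH)
    dhd1 <- as.matrix(Lt %*% dH) %*% t(params$Wd2)
    dpd1 <- dhd1 * (pd1 > 0)
    gWd1 <- crossprod(as.matrix(L %*% Z), dpd1)
    gbd1 <- colSums(dpd1)
    dZ <- as.matrix(Lt %*% dpd1) %*% t(params$Wd1)

    sc <- beta / (2 * n)
    g1 <- sc * (d_pos - 1)          # -log D(Z, S)
    g2 <- sc * d_neg                # -log(1 - D(Zc, S))
    g3 <- sc * (d_pos_c - 1)        # -log D(Zc, Sc)
    g4 <- sc * d_neg_c              # -log(1 - D(Z, Sc))
    gWdisc <- crossprod(Z, g1 * S) + crossprod(Zc, g2 * S) +
      crossprod(Zc, g3 * Sc) + crossprod(Z, g4 * Sc)
    SWt <- S %*% t(params$Wdisc)
    ScWt <- Sc %*% t(params$Wdisc)
    dZ <- dZ + g1 * SWt + g4 * ScWt
    dZc <- g2 * SWt + g3 * ScWt
    dS <- g1 * ZW + g2 * ZcW
    dSc <- g3 * ZcW + g4 * ZW
    dZ <- dZ + as.matrix(Rt %*% (dS * S * (1 - S)))
    dZc <- dZc + as.matrix(Rt %*% (dSc * Sc * (1 - Sc)))

    back_encoder <- function(f, Xin, dZv) {
      dpre2 <- dZv * (f$pre2 > 0)
      gWe2 <- crossprod(as.matrix(L %*% f$h1), dpre2)
      gbe2 <- colSums(dpre2)
      dh1 <- as.matrix(Lt %*% dpre2) %*% t(params$We2)
      dpre1 <- dh1 * (f$pre1 > 0)
      gWe1 <- crossprod(as.matrix(L %*% Xin), dpre1)
      gbe1 <- colSums(dpre1)
      list(We1 = gWe1, be1 = gbe1, We2 = gWe2, be2 = gbe2)
    }
    ge <- back_encoder(fe, X, dZ)
    gc <- back_encoder(fc, Xc, dZc)

    grads <- list(We1 = ge$We1 + gc$We1, be1 = ge$be1 + gc$be1,
                  We2 = ge$We2 + gc$We2, be2 = ge$be2 + gc$be2,
                  Wd1 = gWd1, bd1 = gbd1, Wd2 = gWd2, bd2 = gbd2,
                  Wdisc = gWdisc)
    upd <- adam_step(params, grads, st, lr = lr)
    params <- upd$params; st <- upd$state
  }

  # final forward pass with trained weights (fresh corruption for Z_corrupt)
  perm <- sample.int(n)
  fe <- encode(X)
  fc <- encode(X[perm, , drop = FALSE])
  Z <- fe$Z
  S <- sigmoid(as.matrix(R %*% Z))
  hd1 <- relu(sweep(as.matrix(L %*% Z %*% params$Wd1), 2, params$bd1, "+"))
  H <- sweep(as.matrix(L %*% hd1 %*% params$Wd2), 2, params$bd2, "+")

  state <- list(encoder_weights = list(list(W = params$We1, b = params$be1),
                                       list(W = params$We2, b = params$be2)),
                decoder_weights = list(list(W = params$Wd1, b = params$bd1),
                                       list(W = params$Wd2, b = params$bd2)),
                discriminator_W = params$Wdisc,
                alpha = alpha, beta = beta,
                layer_dims = c(p, d1, d2))
  structure(list(Z = Z, Z_corrupt = fc$Z, H = H, S = S,
                 loss_history = data.frame(iter = seq_len(iters), hist),
                 state = state),
            class = "modality_embedding")
}

#' Train the image modality's graph autoencoder
#'
#' Flattens the three-dimensional image-feature tensor (spots × channels ×
#' features) into an N × (C·F) matrix by channel-major concatenation, trains
#' it exactly as [train_modality()], and reshapes the reconstruction back to
#' (N, C, F).
#'
#' @param features an `image_grid_tensor` with `features` filled.
#' @param graph a `spatial_graph`.
#' @param ... passed to [train_modality()].
#' @return a `modality_embedding` with an extra element `H_tensor`
#'   (reconstruction reshaped to N × C × F).
#' @export
train_image_modality <- function(features, graph, ...) {
  stopifnot(inherits(features, "image_grid_tensor"))
  f <- features$features
  if (is.null(f)) stop_proust("run train_image_autoencoder() first")
  dm <- dim(f)                        # N x C x F
  Xflat <- matrix(aperm(f, c(1, 3, 2)), dm[1], dm[2] * dm[3])
  emb <- train_modality(Xflat, graph, ...)
  emb$H_tensor <- aperm(array(emb$H, c(dm[1], dm[3], dm[2])), c(1, 3, 2))
  emb
}

#' @export
print.modality_embedding <- function(x, ...) {
  lh <- x$loss_history
  cat(sprintf("modality_embedding: %d spots, latent dim %d; loss %.4g -> %.4g over %d iters\n",
              nrow(x$Z), ncol(x$Z), lh$total[1], lh$total[nrow(lh)], nrow(lh)))
  invisible(x)
}
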
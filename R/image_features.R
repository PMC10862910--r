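# Image-channel enhancement, per-spot grid extraction, area-weighted
# resizing, range normalisation, and the CNN autoencoder driver that turns
# resized grids into spot-level image features.

#' Enhance an immunofluorescence channel
#'
#' Noise suppression for sparse, bright IF stains: pixels below
#' `mean + sd_multiplier * SD` of the channel are zeroed, then a sliding
#' maximum filter of `max_filter_size × max_filter_size` (reflected edges)
#' dilates the surviving signal so protein-rich regions cover whole spots.
#' With a constant image (SD = 0) every pixel meets the threshold and the
#' channel passes through unchanged.
#'
#' @param image 2-D non-negative intensity matrix.
#' @param sd_multiplier threshold multiplier (default 6).
#' @param max_filter_size max-filter box side (default 10).
#' @return the enhanced channel, same dimensions.
#' @export
enhance_channel <- function(image, sd_multiplier = 6, max_filter_size = 10) {
  if (!all(is.finite(image))) stop_proust("image contains non-finite pixels")
  thr <- mean(image) + sd_multiplier * sd(as.vector(image))
  out <- image
  out[out < thr] <- 0
  max_filter(out, max_filter_size)
}

# Separable sliding-window maximum with reflected edges. For an even window
# size m the window spans offsets -floor((m-1)/2) .. ceil((m-1)/2).
max_filter <- function(x, size) {
  if (size <= 1) return(x)
  lo <- floor((size - 1) / 2)
  hi <- size - 1 - lo
  run <- function(m) {                  # max over rows within the window
    n <- nrow(m)
    idx <- c(rev(seq_len(lo)), seq_len(n), n + 1 - seq_len(hi))  # reflect
    pad <- m[idx, , drop = FALSE]
    out <- pad[seq_len(n) + lo, , drop = FALSE]
    for (o in c(-(lo:1), seq_len(hi)))
      out <- pmax(out, pad[seq_len(n) + lo + o, , drop = FALSE])
    out
  }
  t(run(t(run(x))))
}

# Area-overlap averaging weights mapping n_in cells onto n_out cells;
# rows sum to 1. Exact block-mean preservation when n_in %% n_out == 0.
resize_weights <- function(n_in, n_out) {
  W <- matrix(0, n_out, n_in)
  step <- n_in / n_out
  for (o in seq_len(n_out)) {
    a <- (o - 1) * step
    b <- o * step
    i0 <- floor(a) + 1
    i1 <- ceiling(b)
    for (i in i0:min(i1, n_in)) {
      ov <- min(b, i) - max(a, i - 1)
      if (ov > 0) W[o, i] <- ov / step
    }
  }
  W
}

#' Extract and resize per-spot image grids
#'
#' Cuts a `d × d` window centred on each spot centroid from every channel
#' (`d = ceiling(spot_diameter_px)`), zero-padding windows that overhang the
#' image border, and resizes each window to `grid_px × grid_px` by
#' area-weighted averaging (each output pixel is the overlap-weighted mean
#' of the input pixels it covers).
#'
#' @param images named list of 2-D channel matrices.
#' @param coords N × 2 matrix with columns `pixel_row`, `pixel_col`.
#' @param spot_diameter_px spot diameter in pixels.
#' @param grid_px resized grid side (default 48).
#' @return an `image_grid_tensor`: list with `grids` (N × C × grid_px ×
#'   grid_px array), `features` (`NULL` until [train_image_autoencoder()]),
#'   `channel_names`, `grid_px`, and `d`.
#' @export
extract_spot_grids <- function(images, coords, spot_diameter_px, grid_px = 48) {
  if (grid_px <= 0 || spot_diameter_px <= 0)
    stop_proust("grid_px and spot_diameter_px must be positive")
  stopifnot(length(images) >= 1)
  d <- as.integer(ceiling(spot_diameter_px))
  n <- nrow(coords)
  C <- length(images)
  lo <- floor((d - 1) / 2)
  Wr <- resize_weights(d, grid_px)     # grid_px x d
  grids <- array(0, dim = c(n, C, grid_px, grid_px))
  h <- nrow(images[[1]]); w <- ncol(images[[1]])
  for (i in seq_len(n)) {
    r0 <- round(coords[i, 1]) - lo
    c0 <- round(coords[i, 2]) - lo
    rr <- r0:(r0 + d - 1)
    cc <- c0:(c0 + d - 1)
    rok <- rr >= 1 & rr <= h
    cok <- cc >= 1 & cc <= w
    for (ch in seq_len(C)) {
      win <- matrix(0, d, d)
      win[rok, cok] <- images[[ch]][rr[rok], cc[cok]]
      grids[i, ch, , ] <- Wr %*% win %*% t(Wr)
    }
  }
  structure(list(grids = grids, features = NULL,
                 channel_names = names(images) %||% sprintf("CH%d", seq_len(C)),
                 grid_px = grid_px, d = d),
            class = "image_grid_tensor")
}

#' Normalise grid pixel values to the preprocessed-expression range
#'
#' Per channel, pixel values are affinely mapped from
#' `[channel min, channel max]` (over all grids of that channel) to
#' `[min(expr values), max(expr values)]`, so both modalities enter model
#' training on the same scale. A constant channel maps to the midpoint of
#' the target range.
#'
#' @param grids an `image_grid_tensor`.
#' @param expr an `expression_matrix` (or any numeric matrix/vector whose
#'   range defines the target).
#' @return the `image_grid_tensor` with rescaled grids.
#' @export
normalize_grid_range <- function(grids, expr) {
  vals <- if (inherits(expr, "expression_matrix")) expr$values else expr
  tgt <- range(vals)
  for (ch in seq_len(dim(grids$grids)[2])) {
    g <- grids$grids[, ch, , ]
    rg <- range(g)
    # a numerically constant channel must not be stretched across the target
    if (rg[2] - rg[1] > 1e-10 * max(1, abs(rg[1]), abs(rg[2]))) {
      grids$grids[, ch, , ] <- tgt[1] + (g - rg[1]) / (rg[2] - rg[1]) * (tgt[2] - tgt[1])
    } else {
      grids$grids[, ch, , ] <- array(mean(tgt), dim = dim(g))
    }
  }
  grids
}

#' Train the convolutional autoencoder on spot image grids
#'
#' Learns spot-level image features by minimising the summed squared
#' Frobenius reconstruction error of the resized grids. The encoder is two
#' 5×5 "same" convolutions (1→8 and 8→4 feature maps), each followed by
#' ReLU and 2×2 average pooling (48 → 24 → 12); the decoder mirrors it with
#' two 2×2 stride-2 transposed convolutions (ReLU after the first, linear
#' output). Every image channel is encoded independently with shared
#' weights; the per-spot, per-channel feature vector is the flattened 12×12×4
#' encoder output (F = 576). Optimised with Adam; fully deterministic given
#' `seed`.
#'
#' @param grids a normalised `image_grid_tensor`.
#' @param lr Adam learning rate.
#' @param iters number of full-batch iterations (default 800).
#' @param seed integer seed for weight initialisation.
#' @return the `image_grid_tensor` with `features` filled (N × C × 576
#'   array), plus attributes-like elements `state` (trained weights) and
#'   `loss_history` (per-iteration reconstruction loss).
#' @export
train_image_autoencoder <- function(grids, lr = 1e-3, iters = 800, seed = 1) {
  stopifnot(inherits(grids, "image_grid_tensor"), iters >= 1)
  dims <- dim(grids$grids)
  n <- dims[1]; C <- dims[2]; px <- dims[3]
  if (px != 48) stop_proust("the CNN autoencoder expects 48x48 grids")
  # columns: spot-major, channel fastest
  X <- matrix(aperm(grids$grids, c(3, 4, 2, 1)), px * px, C * n)
  set.seed(seed)
  params <- list(
    W1 = glorot(25, 8, c(25, 8)), b1 = numeric(8),
    W2 = glorot(25 * 8, 4, c(200, 4)), b2 = numeric(4),
    W3 = glorot(4, 4 * 8, c(4, 32)), b3 = numeric(8),
    W4 = glorot(8, 4, c(8, 4)), b4 = numeric(1))
  st <- adam_init(params)
  loss_history <- numeric(iters)
  for (it in seq_len(iters)) {
    ps <- .cnn_ae_pass(X, params$W1, params$b1, params$W2, params$b2,
                       params$W3, params$b3, params$W4, params$b4,
                       TRUE, FALSE)
    if (!is.finite(ps$loss))
      stop_proust("non-finite image-autoencoder loss at iteration ", it)
    loss_history[it] <- ps$loss
    upd <- adam_step(params, ps$grads, st, lr = lr)
    params <- upd$params; st <- upd$state
  }
  fin <- .cnn_ae_pass(X, params$W1, params$b1, params$W2, params$b2,
                      params$W3, params$b3, params$W4, params$b4,
                      FALSE, TRUE)
  feats <- array(aperm(array(fin$features, c(576, C, n)), c(3, 2, 1)),
                 dim = c(n, C, 576))
  grids$features <- feats
  grids$state <- params
  grids$loss_history <- loss_history
  grids$final_loss <- fin$loss
  grids
}

#' @export
print.image_grid_tensor <- function(x, ...) {
  d <- dim(x$grids)
  cat(sprintf("image_grid_tensor: %d spots x %d channel(s), %dx%d grids%s\n",
              d[1], d[2], d[3], d[4],
              if (is.null(x$features)) "" else sprintf(", F = %d features", dim(x$features)[3])))
  invisible(x)
}
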
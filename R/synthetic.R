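# Synthetic Visium-like data: honeycomb spot lattice, layered ground-truth
# domains, negative-binomial counts with domain-specific means, and image
# channels with domain-dependent base intensity inside spot-sized discs.

#' Simulate a Visium-like tissue section with known spatial domains
#'
#' Generates a honeycomb lattice of spots (alternate rows offset by half the
#' centre-to-centre spacing, emulating the Visium geometry where each interior
#' spot has six equidistant neighbours), assigns each spot to one of
#' `k_domains` ground-truth domains, draws spot-by-gene counts from a
#' negative-binomial model in which a `de_fraction` of genes carries a
#' domain-specific log2 fold change, and renders image channels at full
#' resolution with per-domain base intensity inside spot-sized discs plus
#' Gaussian pixel noise.
#'
#' Defaults describe the reference validation fixture: a ~600-spot lattice
#' with 4 layered domains, 300 genes of which 20% are differentially
#' expressed at a 1 log2-fold effect, and 2 domain-contrasting image
#' channels.
#'
#' @param n_rows,n_cols lattice dimensions (rows × columns of spots).
#' @param k_domains number of ground-truth domains (≥ 2).
#' @param layout `"horizontal_layers"` (contiguous row bands) or
#'   `"concentric"` (rings of increasing distance from the lattice centre).
#' @param n_genes number of genes.
#' @param de_fraction fraction of genes with a domain-specific mean shift.
#' @param log2_fc log2 fold change applied to a DE gene in its marked domain.
#' @param image_channels number of image channels.
#' @param channel_means optional `image_channels × k_domains` matrix of
#'   per-domain disc intensities; by default each channel is a linear ramp
#'   across domains (alternate channels reversed) so every pair of adjacent
#'   domains contrasts in every channel.
#' @param image_noise_sd Gaussian pixel-noise standard deviation.
#' @param expr_domain_map optional integer vector of length `k_domains`
#'   mapping true domains to expression domains; e.g. `c(1, 2, 3, 3)` makes
#'   domains 3 and 4 share expression means so they are distinguishable only
#'   through the image channels.
#' @param spot_spacing centre-to-centre spot distance in pixels.
#' @param spot_diameter_px spot diameter in pixels.
#' @param out_of_tissue number of randomly chosen spots flagged as outside
#'   the tissue (kept in the files/matrices, filtered on load).
#' @param seed integer seed; the dataset is a deterministic function of the
#'   arguments and this seed.
#' @return a list with elements `dataset` (a `spot_dataset`), `truth`
#'   (integer domain per spot, aligned with `dataset$spot_ids`), and
#'   `params` (the resolved simulation parameters).
#' @examples
#' sim <- simulate_spots(n_rows = 6, n_cols = 8, n_genes = 40, seed = 1)
#' table(sim$truth)
#' @export
simulate_spots <- function(n_rows = 20, n_cols = 30, k_domains = 4,
                           layout = c("horizontal_layers", "concentric"),
                           n_genes = 300, de_fraction = 0.2, log2_fc = 1,
                           image_channels = 2, channel_means = NULL,
                           image_noise_sd = 8, expr_domain_map = NULL,
                           spot_spacing = 100, spot_diameter_px = 89,
                           out_of_tissue = 0, seed = 1) {
  layout <- match.arg(layout)
  stopifnot(n_rows >= 2, n_cols >= 2, n_genes >= 1,
            de_fraction >= 0, de_fraction <= 1,
            spot_spacing > 0, spot_diameter_px > 0, image_noise_sd >= 0)
  if (k_domains < 2) stop_proust("k_domains must be at least 2")
  if (layout == "horizontal_layers" && k_domains > n_rows)
    stop_proust("k_domains exceeds the number of representable row layers")

  set.seed(seed)
  margin <- ceiling(spot_spacing)
  ri <- rep(seq_len(n_rows), each = n_cols) - 1L
  ci <- rep(seq_len(n_cols), times = n_rows) - 1L
  px_col <- round(margin + ci * spot_spacing + (ri %% 2L) * spot_spacing / 2)
  px_row <- round(margin + ri * spot_spacing * sqrt(3) / 2)
  n <- n_rows * n_cols
  coords <- cbind(pixel_row = px_row, pixel_col = px_col)

  truth <- switch(layout,
    horizontal_layers = as.integer(cut(ri, breaks = k_domains, labels = FALSE)),
    concentric = {
      d <- sqrt((px_row - mean(px_row))^2 + (px_col - mean(px_col))^2)
      as.integer(cut(rank(d, ties.method = "first"),
                     breaks = k_domains, labels = FALSE))
    })

  if (is.null(expr_domain_map)) expr_domain_map <- seq_len(k_domains)
  stopifnot(length(expr_domain_map) == k_domains)
  expr_dom <- expr_domain_map[truth]

  # Negative-binomial expression: lognormal baseline means, gamma-distributed
  # gene-level dispersion, lognormal per-spot size factors; DE genes get a
  # multiplicative 2^log2_fc bump in their marked (expression) domain.
  base_mu <- rlnorm(n_genes, meanlog = log(2), sdlog = 1)
  phi <- rgamma(n_genes, shape = 2, rate = 4)        # dispersion, size = 1/phi
  size_g <- 1 / pmax(phi, 1e-3)
  n_de <- round(de_fraction * n_genes)
  de_genes <- if (n_de > 0) sort(sample.int(n_genes, n_de)) else integer(0)
  de_domain <- integer(n_genes)
  k_expr <- length(unique(expr_domain_map))
  if (n_de > 0)
    de_domain[de_genes] <- rep_len(sort(unique(expr_domain_map)), n_de)
  sf <- rlnorm(n, meanlog = 0, sdlog = 0.15)

  counts <- matrix(0L, n, n_genes)
  for (g in seq_len(n_genes)) {
    mu <- base_mu[g] * sf
    if (de_domain[g] > 0)
      mu[expr_dom == de_domain[g]] <- mu[expr_dom == de_domain[g]] * 2^log2_fc
    counts[, g] <- rnbinom(n, mu = mu, size = size_g[g])
  }
  gene_ids <- sprintf("GENE%04d", seq_len(n_genes))
  colnames(counts) <- gene_ids
  spot_ids <- sprintf("SPOT%05d", seq_len(n))
  rownames(counts) <- spot_ids

  if (is.null(channel_means)) {
    ramp <- seq(20, 20 + 40 * (k_domains - 1), length.out = k_domains)
    channel_means <- t(vapply(seq_len(image_channels), function(c) {
      if (c %% 2L == 1L) ramp else rev(ramp)
    }, numeric(k_domains)))
  }
  stopifnot(nrow(channel_means) == image_channels,
            ncol(channel_means) == k_domains)

  height <- max(px_row) + margin
  width <- max(px_col) + margin
  radius <- spot_diameter_px / 2
  images <- vector("list", image_channels)
  names(images) <- sprintf("CH%d", seq_len(image_channels))
  for (c in seq_len(image_channels)) {
    img <- matrix(5, height, width)                  # faint background
    for (i in seq_len(n)) {
      rr <- max(1, px_row[i] - ceiling(radius)):min(height, px_row[i] + ceiling(radius))
      cc <- max(1, px_col[i] - ceiling(radius)):min(width, px_col[i] + ceiling(radius))
      disc <- outer((rr - px_row[i])^2, (cc - px_col[i])^2, "+") <= radius^2
      blk <- img[rr, cc]
      blk[disc] <- channel_means[c, truth[i]]
      img[rr, cc] <- blk
    }
    if (image_noise_sd > 0)
      img <- img + matrix(rnorm(height * width, 0, image_noise_sd), height, width)
    images[[c]] <- pmax(img, 0)
  }

  in_tissue <- rep(TRUE, n)
  if (out_of_tissue > 0)
    in_tissue[sample.int(n, min(out_of_tissue, n - 1L))] <- FALSE

  dataset <- new_spot_dataset(
    spot_ids = spot_ids, coords = coords, in_tissue = in_tissue,
    counts = counts, gene_ids = gene_ids, images = images,
    spot_diameter_px = spot_diameter_px)

  list(dataset = dataset, truth = truth,
       params = list(n_rows = n_rows, n_cols = n_cols, k_domains = k_domains,
                     layout = layout, n_genes = n_genes,
                     de_fraction = de_fraction, log2_fc = log2_fc,
                     image_channels = image_channels,
                     channel_means = channel_means,
                     image_noise_sd = image_noise_sd,
                     expr_domain_map = expr_domain_map,
                     spot_spacing = spot_spacing,
                     spot_diameter_px = spot_diameter_px, seed = seed))
}

#' Write a simulated dataset to the standard on-disk input layout
#'
#' Emits the MatrixMarket counts triplet (`matrix.mtx`, `barcodes.tsv`,
#' `features.tsv`), a `positions.csv` spot-positions table, one 16-bit TIFF
#' per image channel, and `truth.csv` with ground-truth domain labels, so the
#' output can be read back unchanged by [load_spot_dataset()].
#'
#' Image intensities are rounded to integers before writing (16-bit range).
#'
#' @param sim result of [simulate_spots()].
#' @param dir output directory (created if missing).
#' @return invisibly, a named list of the written file paths.
#' @export
write_spot_dataset <- function(sim, dir) {
  stopifnot(is.list(sim), inherits(sim$dataset, "spot_dataset"))
  ds <- sim$dataset
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mtx <- file.path(dir, "matrix.mtx")
  # 10x convention: features × barcodes
  Matrix::writeMM(Matrix::Matrix(t(ds$counts), sparse = TRUE), mtx)
  writeLines(ds$spot_ids, file.path(dir, "barcodes.tsv"))
  writeLines(ds$gene_ids, file.path(dir, "features.tsv"))
  pos <- data.frame(
    barcode = ds$spot_ids,
    in_tissue = as.integer(ds$in_tissue),
    array_row = NA_integer_, array_col = NA_integer_,
    pixel_row = ds$coords[, "pixel_row"],
    pixel_col = ds$coords[, "pixel_col"])
  write.csv(pos, file.path(dir, "positions.csv"), row.names = FALSE)
  img_paths <- character(0)
  for (nm in names(ds$images)) {
    p <- file.path(dir, paste0(nm, ".tiff"))
    img <- round(ds$images[[nm]])
    img[img > 65535] <- 65535
    tiff::writeTIFF(img / 65535, p, bits.per.sample = 16L)
    img_paths <- c(img_paths, p)
  }
  truth <- data.frame(barcode = ds$spot_ids, domain = sim$truth)
  write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(list(counts = mtx,
                 positions = file.path(dir, "positions.csv"),
                 images = img_paths,
                 truth = file.path(dir, "truth.csv")))
}
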
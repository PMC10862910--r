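# Gene-expression preprocessing: gene filtering, median library-size
# normalisation, log1p, dispersion-based HVG selection, unit-variance
# scaling with upper-tail clipping.

#' Filter genes by prefix and minimum expressing-spot count
#'
#' Removes mitochondrial/spike-in genes (by id prefix) and genes detected in
#' fewer than `min_spots` spots; the order of surviving genes is preserved.
#'
#' @param dataset a `spot_dataset`.
#' @param min_spots minimum number of spots with a nonzero count.
#' @param exclude_patterns character vector of gene-id prefixes to drop.
#' @return the filtered `spot_dataset`.
#' @export
filter_genes <- function(dataset, min_spots = 3,
                         exclude_patterns = c("MT-", "mt-", "ERCC-")) {
  stopifnot(inherits(dataset, "spot_dataset"))
  genes <- dataset$gene_ids
  drop_prefix <- rep(FALSE, length(genes))
  for (p in exclude_patterns)
    drop_prefix <- drop_prefix | startsWith(genes, p)
  nz <- Matrix::colSums(dataset$counts > 0)
  keep <- !drop_prefix & nz >= min_spots
  if (!any(keep)) stop_proust("gene filtering removed all genes")
  dataset$counts <- dataset$counts[, keep, drop = FALSE]
  dataset$gene_ids <- genes[keep]
  dataset
}

# Median library-size normalisation followed by log1p. Returns the dense
# log-normalised matrix; errors on zero-count spots.
lognormalize <- function(counts, spot_ids = rownames(counts)) {
  lib <- Matrix::rowSums(counts)
  if (any(lib <= 0)) {
    bad <- if (is.null(spot_ids)) which(lib <= 0) else spot_ids[lib <= 0]
    stop_proust("spot(s) with zero total counts: ",
                paste(utils::head(bad, 5), collapse = ", "))
  }
  target <- median(lib)
  log1p(as.matrix(counts) * (target / lib))
}

#' Select highly variable genes by normalised dispersion
#'
#' Seurat-flavour HVG selection on a log-normalised matrix: per-gene
#' dispersion (variance/mean of the de-logged values) is z-scored within 20
#' equal-frequency mean bins and the `n_top` genes with the highest
#' normalised dispersion are retained (all genes if fewer than `n_top`).
#'
#' @param lognorm spots × genes log-normalised matrix.
#' @param n_top number of genes to keep.
#' @return integer indices (columns of `lognorm`) of the selected genes, in
#'   their original column order.
#' @export
select_hvg <- function(lognorm, n_top = 3000) {
  if (n_top <= 0) stop_proust("n_top must be positive")
  g <- ncol(lognorm)
  if (g <= n_top) return(seq_len(g))
  x <- expm1(lognorm)
  mu <- colMeans(x)
  v <- apply(x, 2, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  bins <- cut(rank(mu, ties.method = "first"), breaks = 20, labels = FALSE)
  zdisp <- disp
  for (b in unique(bins)) {
    i <- bins == b
    m <- mean(disp[i]); s <- sd(disp[i])
    zdisp[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - m) / s
  }
  sort(order(zdisp, decreasing = TRUE)[seq_len(n_top)])
}

#' Preprocess expression counts into the model input matrix
#'
#' The full chain on in-tissue counts: (1) normalise each spot to the median
#' library size, (2) log1p-transform, (3) select the top `n_top_hvg` highly
#' variable genes, (4) centre each gene and scale to unit variance, clipping
#' scaled values above `clip` (upper tail only). Scaling statistics are
#' computed after HVG subsetting.
#'
#' @param dataset a filtered `spot_dataset` (see [filter_genes()]).
#' @param n_top_hvg number of highly variable genes to retain.
#' @param clip upper clip bound in scaled units.
#' @return an `expression_matrix` object: list with `values` (spots × HVGs),
#'   `gene_subset`, and `scaling_stats` (per-gene mean/sd used for scaling).
#' @export
normalize_log_scale <- function(dataset, n_top_hvg = 3000, clip = 10) {
  stopifnot(inherits(dataset, "spot_dataset"))
  ln <- lognormalize(dataset$counts, dataset$spot_ids)
  hvg <- select_hvg(ln, n_top_hvg)
  ln <- ln[, hvg, drop = FALSE]
  mu <- colMeans(ln)
  s <- apply(ln, 2, sd)
  s[s == 0] <- 1                                   # constant genes stay at 0
  vals <- sweep(sweep(ln, 2, mu), 2, s, "/")
  vals[vals > clip] <- clip
  structure(list(values = vals,
                 gene_subset = dataset$gene_ids[hvg],
                 scaling_stats = list(mean = mu, sd = s),
                 clip = clip),
            class = "expression_matrix")
}

#' One-call expression preprocessing
#'
#' [filter_genes()] followed by [normalize_log_scale()].
#'
#' @inheritParams filter_genes
#' @inheritParams normalize_log_scale
#' @return an `expression_matrix`.
#' @export
preprocess_expression <- function(dataset, min_spots = 3,
                                  exclude_patterns = c("MT-", "mt-", "ERCC-"),
                                  n_top_hvg = 3000, clip = 10) {
  normalize_log_scale(filter_genes(dataset, min_spots, exclude_patterns),
                      n_top_hvg = n_top_hvg, clip = clip)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d spots x %d genes (clip = %g)\n",
              nrow(x$values), ncol(x$values), x$clip))
  invisible(x)
}
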
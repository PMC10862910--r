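# Hybrid PC profile, Gaussian-mixture clustering, spatial refinement, and
# silhouette-based selection of the cluster count.

# Top-p PC scores with a deterministic sign convention: for each component
# the loading with the largest magnitude is made positive.
pc_scores <- function(M, p, what = "matrix") {
  M <- as.matrix(M)
  pmax_avail <- min(nrow(M) - 1L, ncol(M))
  if (p > pmax_avail) {
    warning("requested ", p, " PCs for the ", what, " block; clipped to ", pmax_avail)
    p <- pmax_avail
  }
  if (p == 0) return(matrix(0, nrow(M), 0))
  pr <- prcomp(M, center = TRUE, scale. = FALSE, rank. = p)
  flip <- vapply(seq_len(ncol(pr$rotation)), function(j) {
    l <- pr$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  sweep(pr$x[, seq_len(p), drop = FALSE], 2, flip[seq_len(p)], "*")
}

#' Build the hybrid principal-component profile
#'
#' Mean-centres each modality's reconstructed feature matrix, extracts its
#' top principal components (sign-fixed so the largest-magnitude loading of
#' each component is positive), and concatenates the transcriptomic and
#' image score blocks column-wise. The PC counts set the relative weight of
#' the two modalities: defaults are 30 (transcriptomics) and 5 (image); to
#' emphasise protein information use e.g. 10 and 10. `p_img = 0` (or a
#' missing image block) yields an expression-only profile.
#'
#' @param H_rna N × p reconstructed expression matrix.
#' @param H_img optional N × q reconstructed image-feature matrix.
#' @param p_rna,p_img numbers of PCs per modality (clipped with a warning if
#'   they exceed what the block supports).
#' @return N × (p_rna + p_img) matrix with attribute `pcs = c(p_rna, p_img)`
#'   (as used after clipping).
#' @export
build_hybrid_profile <- function(H_rna, H_img = NULL, p_rna = 30, p_img = 5) {
  if (p_rna < 0 || p_img < 0) stop_proust("PC counts must be non-negative")
  if (p_rna == 0 && (is.null(H_img) || p_img == 0))
    stop_proust("at least one modality must contribute PCs")
  rna <- pc_scores(H_rna, p_rna, "transcriptomics")
  img <- if (!is.null(H_img) && p_img > 0) pc_scores(H_img, p_img, "image") else
    matrix(0, nrow(rna), 0)
  hybrid <- cbind(rna, img)
  colnames(hybrid) <- c(sprintf("RNA_PC%d", seq_len(ncol(rna))),
                        if (ncol(img)) sprintf("IMG_PC%d", seq_len(ncol(img))))
  attr(hybrid, "pcs") <- c(p_rna = ncol(rna), p_img = ncol(img))
  hybrid
}

#' Cluster the hybrid profile with a Gaussian mixture model
#'
#' Model-based clustering with a fixed number of components: EM (via the
#' mclust engine) started from seeded k-means partitions, best of
#' `restarts` by log-likelihood. Components are renumbered 1..k by
#' decreasing cluster size. If the requested covariance model cannot be
#' fitted, progressively simpler families are tried (`"VVI"`, `"EII"`),
#' each also with a conjugate-prior regularisation pass that guards
#' against degenerate covariances; total failure is an error.
#'
#' @param hybrid N × P profile matrix.
#' @param k number of clusters (2 ≤ k < N).
#' @param seed integer seed covering the k-means restarts.
#' @param model_names mclust covariance family to try first (default
#'   `"EEE"`: ellipsoidal, equal volume/shape/orientation).
#' @param restarts number of seeded k-means initialisations.
#' @return integer label vector in `1..k` (at most k distinct values).
#' @export
cluster_gmm <- function(hybrid, k, seed = 1, model_names = "EEE",
                        restarts = 10) {
  hybrid <- as.matrix(hybrid)
  n <- nrow(hybrid)
  if (k < 2) stop_proust("k must be at least 2")
  if (n <= k) stop_proust("need more observations than clusters")
  set.seed(seed)
  inits <- lapply(seq_len(restarts), function(r) {
    km <- tryCatch(suppressWarnings(stats::kmeans(hybrid, k, nstart = 1)),
                   error = function(e) NULL)
    if (is.null(km)) sample.int(k, n, replace = TRUE) else km$cluster
  })
  best <- NULL
  for (m in unique(c(model_names, "VVI", "EII"))) {
    me_fn <- get(paste0("me", m), envir = asNamespace("mclust"))
    for (prior in list(NULL, mclust::priorControl())) {
      for (cl0 in inits) {
        z0 <- mclust::unmap(cl0, groups = seq_len(k))
        fit <- tryCatch(suppressWarnings(me_fn(data = hybrid, z = z0,
                                               prior = prior)),
                        error = function(e) NULL)
        if (is.null(fit) || is.null(fit$loglik) || !is.finite(fit$loglik) ||
            anyNA(fit$z)) next
        if (is.null(best) || fit$loglik > best$loglik) best <- fit
      }
      if (!is.null(best)) break
    }
    if (!is.null(best)) break
  }
  if (is.null(best)) stop_proust("Gaussian-mixture clustering failed for k = ", k)
  labs <- apply(best$z, 1, which.max)
  sizes <- table(factor(labs, levels = sort(unique(labs))))
  remap <- setNames(seq_along(sizes), names(sizes)[order(-as.vector(sizes),
                                                         as.integer(names(sizes)))])
  as.integer(remap[as.character(labs)])
}

#' Spatially refine domain labels by neighbourhood majority vote
#'
#' Relabels each spot to the most common domain among its `r` nearest
#' surrounding spots (Euclidean distance on centroid coordinates, self
#' excluded), in a single synchronous pass over the original labels. Ties
#' are resolved in favour of the spot's current label, else the smallest
#' label id.
#'
#' @param labels integer label vector.
#' @param coords N × 2 centroid coordinates.
#' @param r neighbourhood size (default 10).
#' @return the refined integer label vector.
#' @export
refine_labels <- function(labels, coords, r = 10) {
  n <- length(labels)
  if (r <= 0) stop_proust("r must be positive")
  if (r >= n) stop_proust("r must be smaller than the number of spots")
  stopifnot(nrow(coords) == n)
  d2 <- as.matrix(stats::dist(as.matrix(coords)))^2
  out <- integer(n)
  for (i in seq_len(n)) {
    o <- order(d2[i, ], seq_len(n))
    nb <- o[o != i][seq_len(r)]
    tab <- table(labels[nb])
    winners <- as.integer(names(tab)[tab == max(tab)])
    out[i] <- if (labels[i] %in% winners) labels[i] else min(winners)
  }
  out
}

#' Select the number of domains by silhouette score
#'
#' Clusters the hybrid profile at each candidate `k`, computes the mean
#' silhouette width (Euclidean) of the pre-refinement labels, and returns
#' the `k` with the highest score (ties: smallest `k`).
#'
#' @param hybrid N × P profile matrix.
#' @param k_range integer vector of candidate cluster counts.
#' @param seed seed passed to [cluster_gmm()].
#' @param model_names covariance family passed to [cluster_gmm()].
#' @return list with `k_best` and `silhouette_by_k` (named numeric vector).
#' @export
select_k_by_silhouette <- function(hybrid, k_range, seed = 1,
                                   model_names = "EEE") {
  if (length(k_range) == 0) stop_proust("k_range must be non-empty")
  k_range <- sort(unique(as.integer(k_range)))
  dmat <- stats::dist(as.matrix(hybrid))
  scores <- vapply(k_range, function(k) {
    labs <- cluster_gmm(hybrid, k, seed = seed, model_names = model_names)
    if (length(unique(labs)) < 2) return(-1)
    mean(cluster::silhouette(labs, dmat)[, "sil_width"])
  }, numeric(1))
  names(scores) <- k_range
  list(k_best = k_range[which.max(scores)], silhouette_by_k = scores)
}

#' Call spatial domains from modality reconstructions
#'
#' Convenience wrapper: [build_hybrid_profile()] → (optional
#' [select_k_by_silhouette()]) → [cluster_gmm()] → optional
#' [refine_labels()].
#'
#' @param H_rna,H_img reconstructions from the modality trainers.
#' @param coords spot centroid coordinates (for refinement).
#' @param k cluster count; if `NULL`, selected from `k_range` by silhouette.
#' @param k_range candidate cluster counts when `k` is `NULL`.
#' @param p_rna,p_img PCs per modality.
#' @param refine logical; apply the spatial majority-vote refinement.
#' @param r refinement neighbourhood size.
#' @param seed integer seed.
#' @param model_names mclust covariance family.
#' @return a `proust_domains` object: list with `hybrid`, `labels`,
#'   `refined_labels`, `k`, `pcs`, `silhouette_by_k` (NULL when `k` was
#'   given).
#' @export
call_domains <- function(H_rna, H_img = NULL, coords = NULL, k = NULL,
                         k_range = 2:8, p_rna = 30, p_img = 5,
                         refine = TRUE, r = 10, seed = 1,
                         model_names = "EEE") {
  hybrid <- build_hybrid_profile(H_rna, H_img, p_rna, p_img)
  sil <- NULL
  if (is.null(k)) {
    sel <- select_k_by_silhouette(hybrid, k_range, seed = seed,
                                  model_names = model_names)
    k <- sel$k_best
    sil <- sel$silhouette_by_k
  }
  labels <- cluster_gmm(hybrid, k, seed = seed, model_names = model_names)
  refined <- if (refine && !is.null(coords)) refine_labels(labels, coords, r)
             else labels
  structure(list(hybrid = hybrid, labels = labels, refined_labels = refined,
                 k = k, pcs = attr(hybrid, "pcs"), silhouette_by_k = sil),
            class = "proust_domains")
}

#' @export
print.proust_domains <- function(x, ...) {
  cat(sprintf("proust_domains: %d spots, k = %d (%d PCs: %d RNA + %d image)\n",
              length(x$labels), x$k, sum(x$pcs), x$pcs[1], x$pcs[2]))
  if (!is.null(x$ari)) cat(sprintf("  ARI vs reference: %.3f (refined %.3f)\n",
                                   x$ari, x$ari_refined))
  invisible(x)
}
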
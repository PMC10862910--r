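# Pipeline orchestration: configuration object, stage sequencing with a
# single fanned-out seed, artifact persistence and a reproducibility
# manifest.

#' Build a pipeline configuration
#'
#' Collects every tunable of the pipeline with its default. Unknown keys
#' are rejected. In `"rna_only"` mode image-specific settings cannot affect
#' the result (`p_img` is forced to 0 and no image model is trained).
#'
#' @param counts_path,positions_path,image_paths,spot_diameter_px input
#'   locations for [load_spot_dataset()] (may stay `NULL` when a dataset is
#'   passed to [run_pipeline()] directly).
#' @param modality_mode `"rna_plus_image"` or `"rna_only"`.
#' @param channels_used optional character subset of image channel names to
#'   use (default: all).
#' @param min_spots_per_gene,exclude_patterns,n_top_hvg,clip_value
#'   expression preprocessing settings (see [preprocess_expression()]).
#' @param enhance list: `enabled`, `sd_multiplier`, `max_filter` (see
#'   [enhance_channel()]; off by default, intended for sparse IF stains).
#' @param grid_px,image_lr,image_iters image autoencoder settings.
#' @param n_neighbors spatial-graph k.
#' @param alpha,beta,latent_dims,gcn_lr,gcn_iters modality-trainer settings.
#' @param n_clusters cluster count k; `NULL` selects from `k_range` by
#'   silhouette.
#' @param k_range candidate cluster counts.
#' @param p_rna,p_img PCs per modality in the hybrid profile.
#' @param refine list: `enabled`, `r`.
#' @param gmm_model mclust covariance family.
#' @param output_dir optional directory for labels, embeddings, loss curves
#'   and the manifest.
#' @param seed global seed; per-stage seeds are derived from it with
#'   [derive_seed()].
#' @return a `proust_config` list.
#' @export
proust_config <- function(counts_path = NULL, positions_path = NULL,
                          image_paths = character(), spot_diameter_px = NULL,
                          modality_mode = c("rna_plus_image", "rna_only"),
                          channels_used = NULL,
                          min_spots_per_gene = 3,
                          exclude_patterns = c("MT-", "mt-", "ERCC-"),
                          n_top_hvg = 3000, clip_value = 10,
                          enhance = list(enabled = FALSE, sd_multiplier = 6,
                                         max_filter = 10),
                          grid_px = 48, image_lr = 1e-3, image_iters = 800,
                          n_neighbors = 3,
                          alpha = 1, beta = 1, latent_dims = c(64, 32),
                          gcn_lr = 1e-3, gcn_iters = 600,
                          n_clusters = NULL, k_range = 2:8,
                          p_rna = 30, p_img = 5,
                          refine = list(enabled = TRUE, r = 10),
                          gmm_model = "EEE",
                          output_dir = NULL, seed = 1) {
  modality_mode <- match.arg(modality_mode)
  cfg <- list(counts_path = counts_path, positions_path = positions_path,
              image_paths = image_paths, spot_diameter_px = spot_diameter_px,
              modality_mode = modality_mode, channels_used = channels_used,
              min_spots_per_gene = min_spots_per_gene,
              exclude_patterns = exclude_patterns,
              n_top_hvg = n_top_hvg, clip_value = clip_value,
              enhance = utils::modifyList(list(enabled = FALSE, sd_multiplier = 6,
                                               max_filter = 10), enhance),
              grid_px = grid_px, image_lr = image_lr, image_iters = image_iters,
              n_neighbors = n_neighbors, alpha = alpha, beta = beta,
              latent_dims = latent_dims, gcn_lr = gcn_lr, gcn_iters = gcn_iters,
              n_clusters = n_clusters, k_range = k_range,
              p_rna = p_rna, p_img = p_img, refine = utils::modifyList(
                list(enabled = TRUE, r = 10), refine),
              gmm_model = gmm_model, output_dir = output_dir, seed = seed)
  if (modality_mode == "rna_only") cfg$p_img <- 0
  structure(cfg, class = "proust_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys present in the file override [proust_config()] defaults; unknown
#' keys are an error.
#'
#' @param path YAML file path.
#' @return a `proust_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(proust_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop_proust("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(proust_config, y)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop_proust("stage '", stage, "' failed: ", conditionMessage(e)))
}

#' Run the full domain-detection pipeline
#'
#' Executes load → expression preprocessing → spatial graph → image feature
#' extraction and CNN autoencoder (unless `rna_only`) → per-modality GCN +
#' contrastive training → hybrid PC profile → GMM clustering → spatial
#' refinement, with per-stage seeds derived from the single config seed.
#' Identical config and seed give identical refined labels.
#'
#' @param config a `proust_config`.
#' @param dataset optional in-memory `spot_dataset` (skips the load stage;
#'   out-of-tissue spots, if any, are filtered here).
#' @param truth optional reference domain labels aligned with the in-tissue
#'   spots; when given, ARIs before and after refinement are recorded.
#' @return a `proust_domains` object extended with `spot_ids`, `coords`,
#'   `loss_history` (per modality), `ari`/`ari_refined` (when `truth` is
#'   given), and `config`. When `config$output_dir` is set, labels,
#'   embeddings, loss curves and a manifest of all resolved parameters are
#'   written there.
#' @export
run_pipeline <- function(config, dataset = NULL, truth = NULL) {
  stopifnot(inherits(config, "proust_config"))
  seed <- config$seed
  if (is.null(dataset)) {
    dataset <- with_stage("load", load_spot_dataset(
      config$counts_path, config$positions_path, config$image_paths,
      config$spot_diameter_px))
  }
  keep <- dataset$in_tissue
  dataset <- filter_tissue(dataset)
  if (!is.null(truth) && length(truth) != length(dataset$spot_ids))
    truth <- truth[keep]

  expr <- with_stage("preprocess", preprocess_expression(
    dataset, config$min_spots_per_gene, config$exclude_patterns,
    config$n_top_hvg, config$clip_value))
  graph <- with_stage("graph", build_knn_graph(dataset$coords,
                                               config$n_neighbors))
  rna <- with_stage("gcn_rna", train_modality(
    expr$values, graph, alpha = config$alpha, beta = config$beta,
    lr = config$gcn_lr, iters = config$gcn_iters,
    seed = derive_seed(seed, "gcn_rna"), latent_dims = config$latent_dims))

  img <- NULL
  use_image <- config$modality_mode == "rna_plus_image" &&
    length(dataset$images) > 0
  if (use_image) {
    images <- dataset$images
    if (!is.null(config$channels_used)) {
      missing_ch <- setdiff(config$channels_used, names(images))
      if (length(missing_ch))
        stop_proust("channels_used not present: ", paste(missing_ch, collapse = ", "))
      images <- images[config$channels_used]
    }
    if (isTRUE(config$enhance$enabled))
      images <- lapply(images, enhance_channel,
                       sd_multiplier = config$enhance$sd_multiplier,
                       max_filter_size = config$enhance$max_filter)
    grids <- with_stage("image_grids", {
      g <- extract_spot_grids(images, dataset$coords,
                              dataset$spot_diameter_px, config$grid_px)
      normalize_grid_range(g, expr)
    })
    grids <- with_stage("image_cnn", train_image_autoencoder(
      grids, lr = config$image_lr, iters = config$image_iters,
      seed = derive_seed(seed, "image_cnn")))
    img <- with_stage("gcn_image", train_image_modality(
      grids, graph, alpha = config$alpha, beta = config$beta,
      lr = config$gcn_lr, iters = config$gcn_iters,
      seed = derive_seed(seed, "gcn_image"), latent_dims = config$latent_dims))
  }

  result <- with_stage("domains", call_domains(
    H_rna = rna$H, H_img = if (use_image) img$H else NULL,
    coords = dataset$coords, k = config$n_clusters, k_range = config$k_range,
    p_rna = config$p_rna, p_img = if (use_image) config$p_img else 0,
    refine = isTRUE(config$refine$enabled), r = config$refine$r,
    seed = derive_seed(seed, "cluster"), model_names = config$gmm_model))

  result$spot_ids <- dataset$spot_ids
  result$coords <- dataset$coords
  result$loss_history <- list(rna = rna$loss_history,
                              image = if (use_image) img$loss_history else NULL)
  result$config <- config
  if (!is.null(truth)) {
    result$truth <- truth
    result$ari <- adjusted_rand_index(result$labels, truth)
    result$ari_refined <- adjusted_rand_index(result$refined_labels, truth)
  }

  if (!is.null(config$output_dir)) {
    out <- config$output_dir
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write_results(dataset, result, out)
    write.csv(rna$loss_history, file.path(out, "loss_rna.csv"), row.names = FALSE)
    if (use_image)
      write.csv(img$loss_history, file.path(out, "loss_image.csv"),
                row.names = FALSE)
    manifest <- list(
      package_version = as.character(utils::packageVersion("proust")),
      seed = seed,
      stage_seeds = list(gcn_rna = derive_seed(seed, "gcn_rna"),
                         image_cnn = derive_seed(seed, "image_cnn"),
                         gcn_image = derive_seed(seed, "gcn_image"),
                         cluster = derive_seed(seed, "cluster")),
      parameters = unclass(config))
    yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  }
  result
}
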
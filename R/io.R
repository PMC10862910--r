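# Visium-style input/output: the spot_dataset container, loaders for
# MTX/CSV counts + positions CSV + TIFF/PNG image channels, result writers.

#' Construct and validate a spot_dataset
#'
#' The in-memory container for one tissue section: spot identifiers, spot
#' centroid pixel coordinates, tissue flags, a spots × genes count matrix,
#' and zero or more full-resolution image channels.
#'
#' @param spot_ids character vector of barcodes.
#' @param coords numeric matrix with columns `pixel_row`, `pixel_col`
#'   (0- or 1-based full-resolution pixel coordinates of spot centroids; the
#'   positions file's pixel columns map directly).
#' @param in_tissue logical vector, one flag per spot.
#' @param counts spots × genes matrix of non-negative integer counts (dense
#'   or `Matrix` sparse).
#' @param gene_ids character vector of gene identifiers.
#' @param images named list of 2-D non-negative intensity matrices, all with
#'   identical dimensions.
#' @param spot_diameter_px positive scalar spot diameter in pixels.
#' @return an object of class `spot_dataset`.
#' @export
new_spot_dataset <- function(spot_ids, coords, in_tissue, counts, gene_ids,
                             images = list(), spot_diameter_px) {
  n <- length(spot_ids)
  if (nrow(counts) != n || nrow(coords) != n || length(in_tissue) != n)
    stop_proust("spot_ids, coords, in_tissue and counts rows must all have length ", n)
  if (ncol(counts) != length(gene_ids))
    stop_proust("counts columns (", ncol(counts), ") != gene_ids (", length(gene_ids), ")")
  cx <- if (inherits(counts, "Matrix")) counts@x else counts
  if (length(cx) && (min(cx) < 0 || any(abs(cx - round(cx)) > 1e-9)))
    stop_proust("counts must be non-negative and integer-valued on ingest")
  if (length(images)) {
    dims <- vapply(images, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop_proust("all image channels must share identical height/width")
  }
  stopifnot(spot_diameter_px > 0)
  structure(list(spot_ids = as.character(spot_ids),
                 coords = coords, in_tissue = as.logical(in_tissue),
                 counts = counts, gene_ids = as.character(gene_ids),
                 images = images, spot_diameter_px = spot_diameter_px),
            class = "spot_dataset")
}

#' @export
print.spot_dataset <- function(x, ...) {
  cat(sprintf("spot_dataset: %d spots (%d in tissue), %d genes, %d image channel(s)\n",
              length(x$spot_ids), sum(x$in_tissue), length(x$gene_ids),
              length(x$images)))
  invisible(x)
}

#' @export
dim.spot_dataset <- function(x) c(length(x$spot_ids), length(x$gene_ids))

# Subset a dataset to its in-tissue spots (stable positions-file order).
filter_tissue <- function(dataset) {
  keep <- which(dataset$in_tissue)
  new_spot_dataset(dataset$spot_ids[keep],
                   dataset$coords[keep, , drop = FALSE],
                   rep(TRUE, length(keep)),
                   dataset$counts[keep, , drop = FALSE],
                   dataset$gene_ids, dataset$images,
                   dataset$spot_diameter_px)
}

read_image_channels <- function(image_paths) {
  images <- list()
  for (p in image_paths) {
    if (!file.exists(p)) stop_proust("unreadable image file: ", p)
    ext <- tolower(tools::file_ext(p))
    arr <- tryCatch(switch(ext,
      tif = , tiff = tiff::readTIFF(p, as.is = TRUE),
      png = png::readPNG(p) * 255,
      stop_proust("unsupported image format: ", p)),
      error = function(e) stop_proust("unreadable image: ", p, " (", conditionMessage(e), ")"))
    base <- tools::file_path_sans_ext(basename(p))
    if (length(dim(arr)) == 3L) {        # RGB(A): split into channels
      nch <- min(dim(arr)[3], 3L)
      for (c in seq_len(nch))
        images[[paste0(base, "_", c("R", "G", "B")[c])]] <- arr[, , c]
    } else {
      images[[base]] <- arr
    }
  }
  images
}

read_counts_any <- function(counts_path) {
  if (dir.exists(counts_path)) {
    mtx <- file.path(counts_path, "matrix.mtx")
    bc <- file.path(counts_path, "barcodes.tsv")
    ft <- file.path(counts_path, "features.tsv")
    if (!all(file.exists(mtx, bc, ft)))
      stop_proust("MTX folder must contain matrix.mtx, barcodes.tsv, features.tsv")
    m <- Matrix::t(Matrix::readMM(mtx))            # features×barcodes -> spots×genes
    barcodes <- readLines(bc)
    feats <- read.delim(ft, header = FALSE)[[1]]
    list(counts = m, barcodes = barcodes, genes = as.character(feats))
  } else if (grepl("\\.mtx$", counts_path)) {
    read_counts_any(dirname(counts_path))
  } else {
    df <- read.csv(counts_path, check.names = FALSE)
    barcodes <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    list(counts = m, barcodes = barcodes, genes = colnames(m))
  }
}

#' Load a Visium-style dataset from disk
#'
#' Reads a counts matrix (MatrixMarket triplet folder or dense CSV,
#' auto-detected), a spot-positions CSV with columns
#' `barcode, in_tissue, array_row, array_col, pixel_row, pixel_col`, and any
#' number of TIFF/PNG image channels (an RGB image is split into three
#' channels), restricts to in-tissue spots, and returns a validated
#' [new_spot_dataset()] object. Spot order is the positions-file order after
#' tissue filtering and is stable across the whole pipeline; gene names are
#' deduplicated deterministically with [make.unique()].
#'
#' @param counts_path MTX folder (or its `matrix.mtx`) or dense CSV
#'   (first column barcode, remaining columns genes).
#' @param positions_path positions CSV as above.
#' @param image_paths character vector of image files (possibly empty).
#' @param spot_diameter_px spot diameter in full-resolution pixels.
#' @return a `spot_dataset` restricted to in-tissue spots.
#' @export
load_spot_dataset <- function(counts_path, positions_path, image_paths = character(),
                              spot_diameter_px) {
  if (!file.exists(positions_path)) stop_proust("positions file not found: ", positions_path)
  cc <- read_counts_any(counts_path)
  pos <- read.csv(positions_path)
  need <- c("barcode", "in_tissue", "pixel_row", "pixel_col")
  if (!all(need %in% names(pos)))
    stop_proust("positions file must have columns: ", paste(need, collapse = ", "))
  if (!setequal(pos$barcode, cc$barcodes))
    stop_proust(sprintf(
      "barcode sets differ between counts (%d barcodes) and positions (%d barcodes); %d shared",
      length(cc$barcodes), nrow(pos), length(intersect(pos$barcode, cc$barcodes))))

  keep <- pos$in_tissue == 1
  pos <- pos[keep, , drop = FALSE]
  idx <- match(pos$barcode, cc$barcodes)
  counts <- cc$counts[idx, , drop = FALSE]
  genes <- make.unique(ifelse(nchar(cc$genes) == 0, "GENE", cc$genes))
  images <- read_image_channels(image_paths)
  coords <- cbind(pixel_row = pos$pixel_row, pixel_col = pos$pixel_col)
  if (length(images)) {
    h <- nrow(images[[1]]); w <- ncol(images[[1]])
    out <- coords[, 1] < 1 | coords[, 1] > h | coords[, 2] < 1 | coords[, 2] > w
    if (any(out))
      warning(sum(out), " retained spot centroid(s) fall outside the image bounds")
  }
  new_spot_dataset(pos$barcode, coords, rep(TRUE, nrow(pos)), counts, genes,
                   images, spot_diameter_px)
}

#' Write domain-calling results to disk
#'
#' Writes `labels.csv` (`spot_id, x, y, domain_label, refined_label`; `x` is
#' the pixel column, `y` the pixel row) and `embeddings.csv` (the hybrid
#' profile, one row per spot). Both round-trip losslessly through
#' [read.csv()].
#'
#' @param dataset a `spot_dataset` (in-tissue spots).
#' @param result a `proust_domains` object from [call_domains()] or
#'   [run_pipeline()].
#' @param out_dir output directory.
#' @return invisibly, the two file paths.
#' @export
write_results <- function(dataset, result, out_dir) {
  n <- length(dataset$spot_ids)
  if (n == 0) stop_proust("empty dataset: nothing to write")
  if (length(result$labels) != n)
    stop_proust("result labels length (", length(result$labels),
                ") != number of spots (", n, ")")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0)
    stop_proust("output directory is not writable: ", out_dir)
  lab_path <- file.path(out_dir, "labels.csv")
  emb_path <- file.path(out_dir, "embeddings.csv")
  write.csv(data.frame(spot_id = dataset$spot_ids,
                       x = dataset$coords[, "pixel_col"],
                       y = dataset$coords[, "pixel_row"],
                       domain_label = result$labels,
                       refined_label = result$refined_labels %||% result$labels),
            lab_path, row.names = FALSE)
  emb <- as.data.frame(result$hybrid)
  names(emb) <- paste0("PC", seq_along(emb))
  write.csv(cbind(data.frame(spot_id = dataset$spot_ids), emb),
            emb_path, row.names = FALSE)
  invisible(list(labels = lab_path, embeddings = emb_path))
}
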
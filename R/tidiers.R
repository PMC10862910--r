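# broom-style accessors and plotting for domain results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a domain result into one row per spot
#'
#' @param x a `proust_domains` object (from [run_pipeline()] or
#'   [call_domains()]).
#' @param ... unused.
#' @return a tibble with columns `spot_id` (if known), `x`, `y` (pixel
#'   column/row, if known), `domain` and `refined_domain`.
#' @export
tidy.proust_domains <- function(x, ...) {
  n <- length(x$labels)
  tb <- tibble::tibble(
    spot_id = x$spot_ids %||% sprintf("spot%d", seq_len(n)),
    domain = x$labels,
    refined_domain = x$refined_labels)
  if (!is.null(x$coords)) {
    tb$x <- x$coords[, "pixel_col"]
    tb$y <- x$coords[, "pixel_row"]
    tb <- tb[, c("spot_id", "x", "y", "domain", "refined_domain")]
  }
  tb
}

#' One-row summary of a domain result
#'
#' @param x a `proust_domains` object.
#' @param ... unused.
#' @return a tibble with the spot count, k, PCs per modality, best
#'   silhouette (if k was selected), and ARIs when a reference was given.
#' @export
glance.proust_domains <- function(x, ...) {
  tibble::tibble(
    n_spots = length(x$labels),
    k = x$k,
    p_rna = unname(x$pcs[1]),
    p_img = unname(x$pcs[2]),
    silhouette = if (is.null(x$silhouette_by_k)) NA_real_ else
      max(x$silhouette_by_k),
    ari = x$ari %||% NA_real_,
    ari_refined = x$ari_refined %||% NA_real_)
}

#' Plot predicted spatial domains
#'
#' Spots at their tissue coordinates coloured by (refined) domain; the y
#' axis is reversed to match image pixel conventions.
#'
#' @param object a `proust_domains` with coordinates.
#' @param refined plot refined (default) or raw labels.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.proust_domains <- function(object, refined = TRUE, ...) {
  if (is.null(object$coords))
    stop_proust("no coordinates attached; run via run_pipeline()")
  df <- tidy(object)
  df$shown <- factor(if (refined) df$refined_domain else df$domain)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$shown)) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = "domain", x = "pixel col", y = "pixel row") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
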
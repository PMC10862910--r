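# Adjusted Rand index from the contingency table of two partitions.

#' Adjusted Rand index between two labelings
#'
#' Builds the l × s contingency table `N_ls` of co-occurrence counts between
#' predicted and reference partitions and evaluates the chance-corrected
#' Rand index
#' \deqn{ARI = \frac{\sum_{ls}\binom{N_{ls}}{2} - \sum_l\binom{N_l}{2}\sum_s\binom{N_s}{2}/\binom{N}{2}}
#'             {[\sum_l\binom{N_l}{2} + \sum_s\binom{N_s}{2}]/2 - \sum_l\binom{N_l}{2}\sum_s\binom{N_s}{2}/\binom{N}{2}}}
#'
#' A perfect match gives 1; the expected value under random labeling is 0.
#' Although often described as ranging from 0 to 1, the adjusted index is
#' negative for worse-than-chance partitions; values are not clipped here.
#' When the denominator is 0 (both partitions trivial, e.g. each a single
#' cluster) the function returns 1 if the partitions are identical as
#' partitions, else 0.
#'
#' @param pred_labels,true_labels equal-length label vectors (any type
#'   coercible to factor).
#' @return scalar ARI.
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1: same partition
#' adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2))  # worse than chance
#' @export
adjusted_rand_index <- function(pred_labels, true_labels) {
  if (length(pred_labels) != length(true_labels))
    stop_proust("label vectors must have equal length")
  n <- length(pred_labels)
  if (n < 2) stop_proust("need at least 2 observations")
  tab <- table(pred_labels, true_labels)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ls <- sum(ch2(tab))
  sum_l <- sum(ch2(rowSums(tab)))
  sum_s <- sum(ch2(colSums(tab)))
  expected <- sum_l * sum_s / ch2(n)
  denom <- (sum_l + sum_s) / 2 - expected
  if (denom == 0) {
    same <- identical(unname(as.integer(factor(pred_labels, unique(pred_labels)))),
                      unname(as.integer(factor(true_labels, unique(true_labels)))))
    return(if (same) 1 else 0)
  }
  (sum_ls - expected) / denom
}
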
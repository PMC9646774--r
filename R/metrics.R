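# Partition agreement measures used for consensus-run selection.

#' Adjusted Rand Index
#'
#' Chance-corrected pair-counting agreement between two partitions of the
#' same items: (Index - Expected) / (Max - Expected) over the contingency
#' table of joint label counts. Equals 1 iff the partitions are identical
#' up to relabeling; 0 in expectation for independent partitions.
#'
#' @param u,v label vectors of equal length (>= 2 items); any atomic type.
#' @return scalar ARI.
#' @export
adjusted_rand_index <- function(u, v) {
  if (length(u) != length(v)) stop("label vectors must have equal length")
  n <- length(u)
  if (n < 2L) stop("need at least 2 items")
  tab <- table(u, v)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_i <- sum(choose2(rowSums(tab)))
  sum_j <- sum(choose2(colSums(tab)))
  total <- choose2(n)
  expected <- sum_i * sum_j / total
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Normalized Mutual Information
#'
#' Mutual information between two partitions normalized by their entropies
#' (natural log). The default "sqrt" variant divides by
#' `sqrt(H(u) * H(v))`; "max" and "arithmetic" variants are available. When
#' exactly one partition has a single cluster (zero entropy) the score is
#' defined as 0; when both do, as 1.
#'
#' @param u,v label vectors of equal length.
#' @param variant normalization: "sqrt", "max" or "arithmetic".
#' @return scalar in [0, 1].
#' @export
normalized_mutual_information <- function(u, v,
                                          variant = c("sqrt", "max", "arithmetic")) {
  variant <- match.arg(variant)
  if (length(u) != length(v)) stop("label vectors must have equal length")
  n <- length(u)
  tab <- table(u, v) / n
  pu <- rowSums(tab)
  pv <- colSums(tab)
  hu <- -sum(pu[pu > 0] * log(pu[pu > 0]))
  hv <- -sum(pv[pv > 0] * log(pv[pv > 0]))
  if (hu == 0 && hv == 0) return(1)
  if (hu == 0 || hv == 0) return(0)
  nz <- tab > 0
  mi <- sum(tab[nz] * log(tab[nz] / outer(pu, pv)[nz]))
  denom <- switch(variant, sqrt = sqrt(hu * hv), max = max(hu, hv),
                  arithmetic = (hu + hv) / 2)
  min(max(mi / denom, 0), 1)
}
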
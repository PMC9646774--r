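# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: pair counting and direct entropy sums for ARI/NMI, exact
# integer binomial coefficients (Pascal's triangle, exact in doubles for
# N <= 30) for the hypergeometric model, exhaustive set enumeration for
# kNN Jaccard weights, and a grid search for NNLS KKT checks.

# All set partitions of n items as label vectors (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, next_max) {
    i <- length(labels) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (v in seq_len(next_max + 1L) - 1L) {
      recurse(c(labels, v), max(next_max, v + 1L))
    }
  }
  recurse(integer(0L), 0L)
  out
}

# ARI by explicit iteration over all item pairs.
oracle_ari <- function(u, v) {
  n <- length(u)
  a <- b <- c_ <- d <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      su <- u[i] == u[j]
      sv <- v[i] == v[j]
      if (su && sv) a <- a + 1
      else if (su && !sv) b <- b + 1
      else if (!su && sv) c_ <- c_ + 1
      else d <- d + 1
    }
  }
  total <- a + b + c_ + d
  expected <- (a + b) * (a + c_) / total
  max_index <- ((a + b) + (a + c_)) / 2
  if (max_index == expected) return(1)
  (a - expected) / (max_index - expected)
}

# NMI (sqrt normalization) from joint counts by direct summation.
oracle_nmi <- function(u, v) {
  n <- length(u)
  hu <- hv <- mi <- 0
  for (cu in unique(u)) {
    p <- sum(u == cu) / n
    hu <- hu - p * log(p)
  }
  for (cv in unique(v)) {
    p <- sum(v == cv) / n
    hv <- hv - p * log(p)
  }
  if (hu == 0 && hv == 0) return(1)
  if (hu == 0 || hv == 0) return(0)
  for (cu in unique(u)) {
    for (cv in unique(v)) {
      pj <- sum(u == cu & v == cv) / n
      if (pj > 0) {
        mi <- mi + pj * log(pj / ((sum(u == cu) / n) * (sum(v == cv) / n)))
      }
    }
  }
  min(max(mi / sqrt(hu * hv), 0), 1)
}

# Exact binomial coefficients via Pascal's triangle (integer-exact in
# doubles up to C(30, 15) << 2^53).
pascal_choose <- local({
  cache <- list()
  function(n, k) {
    if (k < 0 || k > n) return(0)
    key <- as.character(n)
    if (is.null(cache[[key]])) {
      row <- 1
      for (m in seq_len(n)) row <- c(0, row) + c(row, 0)
      cache[[key]] <<- row
    }
    cache[[key]][k + 1L]
  }
})

oracle_hyper <- function(N, N1, N2, j) {
  pascal_choose(N1, j) * pascal_choose(N - N1, N2 - j) / pascal_choose(N, N2)
}

# Jaccard weight of two cells' kNN sets by explicit set enumeration on a
# full distance matrix (ties broken by index, matching the package).
oracle_knn_sets <- function(X, k) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  diag(D) <- Inf
  lapply(seq_len(n), function(i) order(D[i, ])[seq_len(k)])
}

oracle_jaccard <- function(sets, i, j) {
  length(intersect(sets[[i]], sets[[j]])) / length(union(sets[[i]], sets[[j]]))
}

# Chi-square closed form n(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)).
oracle_chi2 <- function(a, b, c_, d) {
  n <- a + b + c_ + d
  n * (a * d - b * c_)^2 / ((a + b) * (c_ + d) * (a + c_) * (b + d))
}

# Best nonnegative solution of min ||t(S) x - y|| over a grid (KKT oracle).
oracle_nnls_grid <- function(S, y, upper, steps = 60L) {
  A <- t(S)
  grid <- seq(0, upper, length.out = steps)
  best <- NULL
  best_obj <- Inf
  for (x1 in grid) {
    for (x2 in grid) {
      obj <- sum((A %*% c(x1, x2) - y)^2)
      if (obj < best_obj) {
        best_obj <- obj
        best <- c(x1, x2)
      }
    }
  }
  best
}
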
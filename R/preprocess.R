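# Raw intensities -> analysis scale: spillover compensation by nonnegative
# least squares (negative values would be artifacts of ordinary
# least-squares unmixing), arcsinh variance stabilization, and
# control-anchored cross-batch normalization.

# Lawson-Hanson active-set NNLS: argmin_{x >= 0} ||A x - b||_2.
nnls_solve <- function(A, b, tol = 1e-10, max_iter = NULL) {
  n <- ncol(A)
  if (is.null(max_iter)) max_iter <- 3L * n
  P <- logical(n)
  x <- numeric(n)
  w <- crossprod(A, b - A %*% x)
  iter <- 0L
  while (any(!P) && any(w[!P] > tol) && iter < max_iter) {
    iter <- iter + 1L
    j <- which(!P)[which.max(w[!P])]
    P[j] <- TRUE
    repeat {
      Ap <- A[, P, drop = FALSE]
      s <- numeric(n)
      s[P] <- qr.solve(Ap, b)
      if (all(s[P] > tol)) { x <- s; break }
      neg <- P & (s <= tol)
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      P[P & (x <= tol)] <- FALSE
      x[!P] <- 0
    }
    w <- crossprod(A, b - A %*% x)
  }
  pmax(x, 0)
}

#' Spillover compensation by nonnegative least squares
#'
#' Per cell, solves `argmin_{x >= 0} || t(S) x - y ||` where `y` is the
#' observed intensity row and `S[i, j]` is the fraction of channel i signal
#' read in channel j. Cells whose unconstrained solution is already
#' nonnegative are solved in one matrix inversion; the remainder go through
#' a Lawson-Hanson active-set solver, so the constrained solutions satisfy
#' the KKT conditions exactly (to the solver tolerance).
#'
#' @param cells raw-scale `cell_table`.
#' @param S spillover matrix matching the table's markers (unit diagonal,
#'   off-diagonals in [0, 1)).
#' @param tol active-set tolerance.
#' @param max_condition maximum acceptable condition number of S.
#' @return compensated raw-scale `cell_table`.
#' @export
compensate_nnls <- function(cells, S, tol = 1e-10, max_condition = 1e8) {
  stopifnot(inherits(cells, "cell_table"))
  if (cells$scale != "raw") stop("compensation expects raw-scale data")
  S <- as.matrix(S)
  M <- ncol(cells$values)
  if (!all(dim(S) == M)) stop("spillover matrix must be ", M, " x ", M)
  if (any(abs(diag(S) - 1) > 1e-12)) stop("spillover diagonal must be 1")
  kap <- kappa(S, exact = TRUE)
  if (kap > max_condition) {
    stop(sprintf("spillover matrix ill-conditioned (condition number %.3g)", kap))
  }
  # unconstrained unmix: y = x S  =>  x = y S^{-1}
  X <- cells$values %*% solve(S)
  bad <- which(apply(X, 1L, function(r) any(r < 0)))
  if (length(bad)) {
    A <- t(S)
    for (i in bad) X[i, ] <- nnls_solve(A, cells$values[i, ], tol = tol)
  }
  X[X < 0] <- 0
  colnames(X) <- colnames(cells$values)
  out <- cells
  out$values <- X
  out
}

#' Arcsinh transform
#'
#' Elementwise `asinh(scale_a * x)`, the standard variance-stabilizing
#' transform for mass cytometry (`scale_a = 0.2` is cofactor 5).
#'
#' @param cells raw-scale `cell_table`.
#' @param scale_a positive scale constant a in asinh(a * x).
#' @return `cell_table` on the arcsinh scale.
#' @export
arcsinh_transform <- function(cells, scale_a = 0.2) {
  stopifnot(inherits(cells, "cell_table"))
  if (cells$scale != "raw") stop("input already transformed")
  if (!is.numeric(scale_a) || length(scale_a) != 1L || scale_a <= 0) {
    stop("scale_a must be a positive scalar")
  }
  out <- cells
  out$values <- asinh(scale_a * cells$values)
  out$scale <- "arcsinh"
  out
}

#' Estimate control-anchored batch normalization factors
#'
#' Each batch acquires an aliquot of one pooled control; for every channel,
#' the factor of batch b is the control median in b divided by the weakest
#' (smallest) control median across batches. Factors are therefore >= 1
#' with a per-channel minimum of exactly 1, and dividing by them aligns all
#' batches onto the weakest batch's signal level.
#'
#' @param controls a `cell_table` of control cells only (any scale); every
#'   batch must contribute at least one cell.
#' @param batches optional character vector of all batch ids that must be
#'   covered (defaults to the batches present in `controls`).
#' @return object of class `batch_norm_factors`: list with `factors`
#'   (batches x channels matrix, rownames = batch ids) and `scale`.
#' @export
estimate_batch_factors <- function(controls, batches = NULL) {
  stopifnot(inherits(controls, "cell_table"))
  present <- unique(controls$batch_id)
  if (is.null(batches)) batches <- present
  missing <- setdiff(batches, present)
  if (length(missing)) {
    stop("batches without control cells: ", paste(missing, collapse = ", "))
  }
  res <- vapply(batches, function(b) {
    apply(controls$values[controls$batch_id == b, , drop = FALSE], 2L, stats::median)
  }, numeric(ncol(controls$values)))
  med <- if (is.matrix(res)) t(res) else matrix(res, ncol = 1L)
  weakest <- apply(med, 2L, min)
  if (any(weakest <= 0)) {
    stop("degenerate channel(s) with zero minimum control median: ",
         paste(colnames(controls$values)[weakest <= 0], collapse = ", "))
  }
  f <- sweep(med, 2L, weakest, "/")
  rownames(f) <- batches
  colnames(f) <- colnames(controls$values)
  structure(list(factors = f, scale = controls$scale),
            class = "batch_norm_factors")
}

#' Apply batch normalization factors
#'
#' Divides every cell's intensity vector by its batch's per-channel factor.
#' After application, per-channel control medians agree across batches up
#' to median-estimator granularity.
#'
#' @param cells a `cell_table` on the same scale the factors were estimated
#'   on.
#' @param f a `batch_norm_factors` object.
#' @return normalized `cell_table`.
#' @export
apply_batch_normalization <- function(cells, f) {
  stopifnot(inherits(cells, "cell_table"), inherits(f, "batch_norm_factors"))
  unknown <- setdiff(unique(cells$batch_id), rownames(f$factors))
  if (length(unknown)) {
    stop("unknown batch id(s): ", paste(unknown, collapse = ", "))
  }
  if (!identical(cells$scale, f$scale)) {
    stop(sprintf("factors were estimated on %s-scale data but cells are %s-scale",
                 f$scale, cells$scale))
  }
  out <- cells
  out$values <- cells$values / f$factors[cells$batch_id, , drop = FALSE]
  out
}

#' Synthesize the combined light-chain channel
#'
#' Adds a "KL" channel holding the per-cell maximum of the kappa and lambda
#' intensities. Clustering uses KL in place of the two chains so clonal
#' populations read as uniformly light-chain-positive; the original
#' channels are retained for clonality analysis.
#'
#' @param cells a `cell_table` containing both light-chain channels.
#' @param panel a `marker_panel`.
#' @return `cell_table` with an appended KL column.
#' @export
synthesize_kl <- function(cells, panel) {
  stopifnot(inherits(cells, "cell_table"), inherits(panel, "marker_panel"))
  kn <- panel$marker_names[panel$kappa_index]
  ln <- panel$marker_names[panel$lambda_index]
  miss <- setdiff(c(kn, ln), colnames(cells$values))
  if (length(miss)) stop("light-chain channel(s) missing: ",
                         paste(miss, collapse = ", "))
  out <- cells
  out$values <- cbind(cells$values,
                      KL = pmax(cells$values[, kn], cells$values[, ln]))
  out
}
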
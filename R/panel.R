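#' Marker-panel description
#'
#' Describes the antibody panel: marker names, which two channels carry the
#' immunoglobulin kappa and lambda light chains, and which markers enter
#' clustering. For clustering, the two light-chain channels are replaced by
#' a single combined "KL" channel (the per-cell maximum of kappa and
#' lambda), so a clonal population reads as uniformly light-chain-high
#' regardless of which chain it expresses.
#'
#' @param marker_names character vector of unique marker identifiers.
#' @param kappa_index,lambda_index integer positions of the kappa and
#'   lambda light-chain channels in `marker_names`.
#' @param clustering_mask logical per marker; markers used for clustering.
#'   Defaults to all markers.
#' @return an object of class `marker_panel`.
#' @export
marker_panel <- function(marker_names, kappa_index, lambda_index,
                         clustering_mask = rep(TRUE, length(marker_names))) {
  marker_names <- as.character(marker_names)
  if (anyDuplicated(marker_names)) stop("marker names must be unique")
  M <- length(marker_names)
  kappa_index <- as.integer(kappa_index)
  lambda_index <- as.integer(lambda_index)
  if (kappa_index == lambda_index) stop("kappa_index must differ from lambda_index")
  if (kappa_index < 1L || kappa_index > M || lambda_index < 1L || lambda_index > M) {
    stop("light-chain indices out of range")
  }
  if (length(clustering_mask) != M) stop("clustering_mask length must equal panel size")
  # KL replaces kappa+lambda, so effective clustering markers exclude the two
  # light chains; require at least 3 besides them.
  n_clust <- sum(clustering_mask[-c(kappa_index, lambda_index)])
  if (n_clust + any(clustering_mask[c(kappa_index, lambda_index)]) < 3L) {
    stop("need at least 3 clustering markers")
  }
  structure(list(marker_names = marker_names,
                 kappa_index = kappa_index, lambda_index = lambda_index,
                 clustering_mask = as.logical(clustering_mask)),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("marker_panel: %d markers (%d clustering), kappa = %s, lambda = %s\n",
              length(x$marker_names), sum(x$clustering_mask),
              x$marker_names[x$kappa_index], x$marker_names[x$lambda_index]))
  invisible(x)
}

#' Default synthetic B-cell panel
#'
#' A compact stand-in for a ~39-marker CyTOF B-cell panel. It keeps the
#' markers that drive the downstream biology -- lineage (CD19/CD20/CD22),
#' BCR components (IgM, IgG, CD79B, kappa, lambda), MHC (HLA-DR), the
#' signaling modulators CD24/CD44, and germinal-center/memory/plasma-cell
#' markers -- and pads with generic phenotyping channels up to `M` markers.
#' Entirely synthetic: the template means attached by
#' [default_templates()] are chosen to reproduce the qualitative contrasts
#' between germinal-center-like and memory-like tumor phenotypes, not any
#' measured panel.
#'
#' @param M total number of markers (>= 14).
#' @return a `marker_panel`.
#' @export
default_panel <- function(M = 39L) {
  core <- c("CD19", "CD20", "CD22", "CD79B", "IgM", "IgG", "IgD",
            "HLA-DR", "CD24", "CD44", "CD38", "CD27", "kappa", "lambda")
  if (M < length(core)) stop("M must be at least ", length(core))
  extra <- if (M > length(core)) sprintf("P%02d", seq_len(M - length(core))) else character(0L)
  names <- c(core, extra)
  marker_panel(names,
               kappa_index = match("kappa", names),
               lambda_index = match("lambda", names))
}
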
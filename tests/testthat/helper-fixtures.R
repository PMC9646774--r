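# Small in-code fixtures shared across test files.

small_panel <- function() default_panel(14L)

# Tiny two-template cohort: one polytypic normal and one monotypic clone.
tiny_config <- function(n_samples = 3L, cells = 200L, seed = 7L,
                        spill = 0, batches = 1L, control_cells = cells) {
  panel <- small_panel()
  tpl <- default_templates(panel)[c("naive", "clonalB")]
  comp <- matrix(rep(c(0.5, 0.5), n_samples), nrow = n_samples, byrow = TRUE,
                 dimnames = list(sprintf("S%d", seq_len(n_samples)),
                                 c("naive", "clonalB")))
  S <- if (spill > 0) make_spillover_matrix(14L, spill, seed = seed) else NULL
  cohort_config(panel, tpl, comp, n_batches = batches,
                cells_per_sample = cells, spillover = S,
                control_cells = control_cells, seed = seed)
}

# Arcsinh-scale cell table built directly from a matrix (single sample).
table_from_matrix <- function(X, sample_id = NULL, scale = "arcsinh") {
  if (is.null(colnames(X))) colnames(X) <- sprintf("m%d", seq_len(ncol(X)))
  if (is.null(sample_id)) sample_id <- rep("S1", nrow(X))
  cell_table(X, sample_id, rep("batch1", nrow(X)), scale = scale)
}

# Three well-separated Gaussian blobs in 2-D with truth labels.
blob_data <- function(n_per = 60L, sep = 10, sd = 1, seed = 42L) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(sep, 0), c(0, sep))
  X <- do.call(rbind, lapply(1:3, function(k) {
    cbind(rnorm(n_per, centers[k, 1], sd), rnorm(n_per, centers[k, 2], sd))
  }))
  list(X = X, truth = rep(1:3, each = n_per))
}
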
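#' Demonstration cohort configuration with planted structure
#'
#' The canonical validation cohort used by the test suite and worked
#' examples: 12 samples across 2 batches -- 4 type-A-like (dominated by
#' the germinal-center-like clonalA template with a minor clonalC
#' component), 4 type-B-like (dominated by the memory-like clonalB
#' template), and 4 divergent (dominated by clonalD with minor clonalA and
#' clonalC components) -- each mixed with residual normal B-cell subsets.
#' Per-channel batch drift (factors ramping 1.1-1.6 on batch 2) and 5%
#' sparse spillover are on by default, and each batch carries one pooled
#' normal-mix control aliquot. The layout plants a positive MC-A/MC-C
#' co-occurrence (present together in 8/12 samples) and MC-A/MC-B mutual
#' exclusivity (8 vs 4 samples, zero overlap) at margins that are
#' significant under the exact co-occurrence model at alpha 0.05.
#'
#' @param cells_per_sample cells per sample (default 500, a desk-scale
#'   stand-in for the ~5000-cell-per-sample cohorts of real studies).
#' @param n_each samples per planted type (total 3 * n_each).
#' @param spill off-diagonal spillover fraction (0 disables).
#' @param batch_effects apply per-channel drift to batch 2.
#' @param seed root seed.
#' @param panel a `marker_panel`.
#' @param sd template arcsinh-scale standard deviation (template mean
#'   contrasts are >= 4 sd apart at the default 0.35).
#' @return a `cohort_config`.
#' @export
demo_cohort_config <- function(cells_per_sample = 500L, n_each = 4L,
                               spill = 0.05, batch_effects = TRUE,
                               seed = 1L, panel = default_panel(),
                               sd = 0.35) {
  templates <- default_templates(panel, sd = sd)
  tn <- names(templates)
  comp_row <- function(w) {
    full <- stats::setNames(numeric(length(tn)), tn)
    full[names(w)] <- w
    full / sum(full)
  }
  rows <- list()
  for (i in seq_len(n_each)) {
    rows[[paste0("A", i)]] <- comp_row(c(clonalA = 0.60, clonalC = 0.15,
                                         naive = 0.10, memory = 0.10, gc = 0.05))
  }
  for (i in seq_len(n_each)) {
    rows[[paste0("B", i)]] <- comp_row(c(clonalB = 0.65, naive = 0.15,
                                         memory = 0.15, gc = 0.05))
  }
  for (i in seq_len(n_each)) {
    rows[[paste0("N", i)]] <- comp_row(c(clonalD = 0.50, clonalA = 0.15,
                                         clonalC = 0.15, naive = 0.10,
                                         memory = 0.10))
  }
  composition <- do.call(rbind, rows)
  colnames(composition) <- tn
  M <- length(panel$marker_names)
  bf <- matrix(1, 2L, M)
  if (batch_effects) bf[2L, ] <- seq(1.1, 1.6, length.out = M)
  S <- if (spill > 0) make_spillover_matrix(M, spill, seed = seed) else NULL
  cohort_config(panel, templates, composition, n_batches = 2L,
                cells_per_sample = cells_per_sample, batch_factors = bf,
                spillover = S, control_cells = cells_per_sample,
                seed = seed)
}
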
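# End-to-end orchestration: preprocessing -> consensus clustering ->
# metaclustering -> clonality/typing -> entropy -> co-occurrence, with a
# cohort-level report. All stage randomness derives from one root seed via
# fixed offsets.

stage_log <- function(verbose, stage, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full cohort analysis pipeline
#'
#' @param x a `cohort_config` (the cohort is simulated first) or a
#'   raw-scale `cell_table` with control cells flagged.
#' @param panel a `marker_panel`; taken from the config when `x` is one.
#' @param spillover spillover matrix for compensation; taken from the
#'   config when available, identity otherwise.
#' @param cofactor arcsinh scale constant a.
#' @param k_neighbors kNN size for clustering (scaled down from the
#'   cohort-scale default of 100 for small cohorts: capped at a tenth of
#'   the cell count, with a warning when capped).
#' @param R consensus runs.
#' @param min_fraction per-sample rare-cluster pruning threshold.
#' @param k_max,gap_B metacluster gap-statistic scan parameters.
#' @param typing_rule "most-abundant" or "majority-50"; both are computed,
#'   this one populates `type`.
#' @param cooccur_threshold presence threshold over the clonal-B-cell
#'   composition.
#' @param alpha co-occurrence significance level per tail.
#' @param max_cells_per_sample optional seeded per-sample subsampling cap.
#' @param seed root seed for all stage substreams.
#' @param out_dir optional directory for stage outputs (CSV/JSON).
#' @param verbose emit per-stage log lines.
#' @return object of class `cohort_report`: `samples` (per-sample type,
#'   clonal fraction, intratumoral entropy, dominant MC, both rules'
#'   types), `mc_composition` (clonal-cell composition over metaclusters),
#'   `cooccurrence`, `consensus` (mean ARI/NMI), `metacluster` model,
#'   `mc_names`, `clonality` calls, `marker_ranking` (NULL when fewer than
#'   two types have two samples), and the processed `cells` + `labels`.
#' @export
run_pipeline <- function(x, panel = NULL, spillover = NULL, cofactor = 0.2,
                         k_neighbors = 100L, R = 25L, min_fraction = 0.01,
                         k_max = 10L, gap_B = 50L,
                         typing_rule = c("most-abundant", "majority-50"),
                         cooccur_threshold = 0.01, alpha = 0.05,
                         max_cells_per_sample = NULL, seed = 1L,
                         out_dir = NULL, verbose = FALSE) {
  typing_rule <- match.arg(typing_rule)
  if (inherits(x, "cohort_config")) {
    if (is.null(panel)) panel <- x$panel
    if (is.null(spillover)) spillover <- x$spillover
    cofactor <- x$cofactor
    stage_log(verbose, "simulate", "%d samples x %d cells",
              nrow(x$composition), x$cells_per_sample)
    cohort <- simulate_cohort(x)
    cells <- cohort$cells
  } else {
    stopifnot(inherits(x, "cell_table"))
    if (is.null(panel)) stop("panel required for cell_table input")
    cells <- x
  }
  M <- ncol(cells$values)
  if (is.null(spillover)) spillover <- diag(M)

  # preprocessing: compensate on the raw scale, normalize batches on raw
  # control medians, then transform and synthesize KL
  stage_log(verbose, "preprocess", "%d cells x %d markers", nrow(cells$values), M)
  cells <- compensate_nnls(cells, spillover)
  factors <- NULL
  if (length(unique(cells$batch_id)) > 1L) {
    if (!any(cells$is_control)) stop("multi-batch input without control cells")
    factors <- estimate_batch_factors(subset_cells(cells, cells$is_control),
                                      batches = unique(cells$batch_id))
    cells <- apply_batch_normalization(cells, factors)
  }
  cells <- arcsinh_transform(cells, scale_a = cofactor)
  cells <- synthesize_kl(cells, panel)
  if (!is.null(max_cells_per_sample)) {
    cells <- subsample_cells(cells, max_cells_per_sample, seed = seed + 17L)
  }

  analysis <- subset_cells(cells, !cells$is_control)
  n <- nrow(analysis$values)
  k_nn <- k_neighbors
  if (k_nn > n %/% 10L) {
    k_nn <- max(5L, n %/% 10L)
    warning(sprintf("k_neighbors reduced from %d to %d for %d cells",
                    k_neighbors, k_nn, n))
  }
  stage_log(verbose, "cluster", "kNN = %d, R = %d runs", k_nn, R)
  cons <- consensus_cluster(analysis, k_nn, R = R, seed = seed + 101L,
                            panel = panel)
  pruned <- prune_rare_clusters(cons$labels, analysis, min_fraction)
  labels <- pruned$labels
  stage_log(verbose, "cluster", "%d clusters, %d/%d cells retained",
            length(unique(stats::na.omit(labels))), sum(pruned$retained), n)

  model <- metacluster_model(analysis, labels, panel = panel, k_max = k_max,
                             B = gap_B, seed = seed + 211L)
  mcs <- assign_metaclusters(model, labels)
  mc_names <- annotate_metaclusters(model)
  stage_log(verbose, "metacluster", "chosen k = %d", model$chosen_k)

  calls <- call_clonality(analysis, labels, panel)
  # clusters carrying a polytypic population in any sample are treated as
  # having a normal-phenotype counterpart; the rest are tumor-only
  normal_map <- local({
    poly <- unique(calls$cluster[calls$call == "polytypic"])
    stats::setNames(rep("normal-like", length(poly)), as.character(poly))
  })
  calls <- flag_abnormal(calls, normal_map)
  typing <- lapply(c("most-abundant", "majority-50"), function(rule)
    assign_tumor_type(calls, analysis, labels, mcs, mc_names, rule = rule))
  names(typing) <- c("most-abundant", "majority-50")

  monotypic <- calls[calls$call %in% c("monotypic-kappa", "monotypic-lambda"), ]
  clonal <- paste(analysis$sample_id, labels) %in%
    paste(monotypic$sample_id, monotypic$cluster) & !is.na(labels)
  samples <- unique(analysis$sample_id)
  intratumoral <- vapply(samples, function(s) {
    idx <- clonal & analysis$sample_id == s
    if (!any(idx)) return(NA_real_)
    intratumoral_entropy(as.numeric(table(labels[idx]) / sum(idx)))
  }, numeric(1L))

  main <- typing[[typing_rule]]
  report_samples <- data.frame(
    sample_id = main$sample_id, type = main$type,
    type_most_abundant = typing[["most-abundant"]]$type,
    type_majority_50 = typing[["majority-50"]]$type,
    clonal_fraction = main$clonal_fraction,
    dominant_mc = main$dominant_mc, dominant_share = main$dominant_share,
    intratumoral_entropy = intratumoral[main$sample_id],
    stringsAsFactors = FALSE)

  # co-occurrence over metaclusters among clonal B-cells
  cooc <- NULL; mc_comp <- NULL
  if (any(clonal)) {
    mc_named <- mc_names[as.character(mcs)]
    mc_comp <- sample_composition(analysis$sample_id[clonal], mc_named[clonal])
    if (ncol(mc_comp) >= 2L && nrow(mc_comp) >= 3L) {
      cooc <- cooccurrence_analysis(
        presence_matrix(mc_comp, cooccur_threshold), alpha = alpha)
    }
  }

  ranking <- NULL
  type_tab <- table(main$type[main$type != "rLN-like"])
  if (sum(type_tab >= 2L) >= 2L) {
    ok_types <- names(type_tab)[type_tab >= 2L]
    use <- main$type %in% ok_types
    prof <- t(vapply(main$sample_id[use], function(s) {
      idx <- clonal & analysis$sample_id == s
      apply(analysis$values[idx, , drop = FALSE], 2L, stats::median)
    }, numeric(ncol(analysis$values))))
    ranking <- rank_markers(prof, main$type[use])
  }

  report <- structure(
    list(samples = report_samples, mc_composition = mc_comp,
         cooccurrence = cooc, consensus = list(mean_ari = cons$mean_ari,
                                               mean_nmi = cons$mean_nmi),
         metacluster = model, mc_names = mc_names, clonality = calls,
         marker_ranking = ranking, batch_factors = factors,
         cells = analysis, labels = labels, metaclusters = mcs,
         typing = typing, seed = seed),
    class = "cohort_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("cohort_report: %d samples (consensus ARI %.3f / NMI %.3f)\n",
              nrow(x$samples), x$consensus$mean_ari, x$consensus$mean_nmi))
  print(table(x$samples$type))
  invisible(x)
}

#' Write a cohort report to disk
#'
#' Emits per-sample typing CSV, clonality CSV, metacluster map CSV,
#' composition CSV, co-occurrence CSV, network edge list, and a summary
#' JSON.
#'
#' @param report a `cohort_report`.
#' @param dir output directory (created).
#' @return invisibly, `dir`.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "cohort_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$samples, file.path(dir, "samples.csv"),
                   row.names = FALSE)
  utils::write.csv(report$clonality, file.path(dir, "clonality.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(cluster = names(report$metacluster$mc_map),
               metacluster = unname(report$metacluster$mc_map),
               mc_name = report$mc_names[as.character(report$metacluster$mc_map)]),
    file.path(dir, "metacluster_map.csv"), row.names = FALSE)
  if (!is.null(report$mc_composition)) {
    utils::write.csv(as.data.frame(report$mc_composition),
                     file.path(dir, "mc_composition.csv"))
  }
  if (!is.null(report$cooccurrence)) {
    utils::write.csv(report$cooccurrence$pairs,
                     file.path(dir, "cooccurrence.csv"), row.names = FALSE)
    export_network(report$cooccurrence, file.path(dir, "network_edges.tsv"))
  }
  if (!is.null(report$marker_ranking)) {
    utils::write.csv(report$marker_ranking$ranking,
                     file.path(dir, "marker_ranking.csv"), row.names = FALSE)
  }
  summary <- list(
    n_samples = nrow(report$samples),
    types = as.list(table(report$samples$type)),
    consensus = report$consensus,
    chosen_k = report$metacluster$chosen_k,
    seed = report$seed)
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
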
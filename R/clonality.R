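# Light-chain clonality: per sample-level cluster, compare kappa vs lambda
# positivity; ratios above 7 or below 0.3 mark a monotypic (clonal)
# population, the interval [0.3, 7] is read as polytypic (inclusive).

#' Call light-chain clonality per sample-level cluster
#'
#' For every (sample, cluster) pair, counts kappa-positive and
#' lambda-positive cells (arcsinh intensity above `positive_cutoff`) and
#' forms the kappa:lambda ratio. Ratios > 7 call monotypic-kappa, < 0.3
#' monotypic-lambda, and the closed interval [0.3, 7] polytypic. A zero
#' denominator with a positive numerator gives an infinite ratio (no
#' pseudocount) and the corresponding monotypic call. Clusters of at least
#' `min_informative` cells with no positive cells on either chain are
#' reported as "indeterminate" rather than errored.
#'
#' @param cells arcsinh-scale `cell_table`.
#' @param labels per-cell cluster ids (NA = pruned, skipped).
#' @param panel a `marker_panel`.
#' @param positive_cutoff arcsinh intensity above which a cell counts as
#'   positive for a chain.
#' @param ratio_high,ratio_low monotypic thresholds (inclusive bounds are
#'   polytypic).
#' @param basis "counts" (positive-cell counts, default) or "median"
#'   (ratio of per-cluster median intensities).
#' @param min_informative cluster size above which an all-negative cluster
#'   is flagged indeterminate.
#' @return data.frame with one row per (sample, cluster): sample_id,
#'   cluster, n_cells, kappa_level, lambda_level, ratio, call.
#' @export
call_clonality <- function(cells, labels, panel, positive_cutoff = 1,
                           ratio_high = 7, ratio_low = 0.3,
                           basis = c("counts", "median"),
                           min_informative = 50L) {
  stopifnot(inherits(cells, "cell_table"), inherits(panel, "marker_panel"))
  basis <- match.arg(basis)
  kn <- panel$marker_names[panel$kappa_index]
  ln <- panel$marker_names[panel$lambda_index]
  miss <- setdiff(c(kn, ln), colnames(cells$values))
  if (length(miss)) stop("light-chain channel(s) missing: ",
                         paste(miss, collapse = ", "))
  keep <- !is.na(labels) & !cells$is_control
  df <- data.frame(sample_id = cells$sample_id[keep],
                   cluster = labels[keep],
                   kappa = cells$values[keep, kn],
                   lambda = cells$values[keep, ln],
                   stringsAsFactors = FALSE)
  groups <- split(df, list(df$sample_id, df$cluster), drop = TRUE)
  rows <- lapply(groups, function(g) {
    if (basis == "counts") {
      k_lev <- sum(g$kappa > positive_cutoff)
      l_lev <- sum(g$lambda > positive_cutoff)
    } else {
      k_lev <- stats::median(g$kappa)
      l_lev <- stats::median(g$lambda)
    }
    ratio <- if (l_lev == 0 && k_lev == 0) NA_real_ else k_lev / l_lev
    call <- if (is.na(ratio)) {
      if (nrow(g) >= min_informative) "indeterminate" else "polytypic"
    } else if (ratio > ratio_high) "monotypic-kappa"
      else if (ratio < ratio_low) "monotypic-lambda"
      else "polytypic"
    data.frame(sample_id = g$sample_id[1L], cluster = g$cluster[1L],
               n_cells = nrow(g), kappa_level = k_lev, lambda_level = l_lev,
               ratio = ratio, call = call, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$sample_id, out$cluster), ]
}

#' Flag monotypic versions of normal phenotypes ("Ab" clusters)
#'
#' Clusters that map to normal B-cell phenotype groups but show monotypic
#' light chains are flagged with `ab_flag` -- the aberrant counterpart of
#' an otherwise normal phenotype. For each sample, the dominant monotypic
#' light chain across its tumor-only clusters is recorded, and a warning is
#' emitted when an Ab cluster's chain disagrees with it (the chains are
#' expected to match within a sample).
#'
#' @param calls data.frame from [call_clonality()].
#' @param normal_phenotype_map named character vector or list mapping
#'   cluster id -> phenotype group name, with "tumor-only" (or absence from
#'   the map) marking clusters with no normal counterpart.
#' @return `calls` with added columns `ab_flag`, `phenotype_group`,
#'   `dominant_chain` (per sample) and `chain_mismatch`.
#' @export
flag_abnormal <- function(calls, normal_phenotype_map) {
  map <- unlist(normal_phenotype_map)
  grp <- map[as.character(calls$cluster)]
  grp[is.na(grp)] <- "tumor-only"
  monotypic <- calls$call %in% c("monotypic-kappa", "monotypic-lambda")
  calls$phenotype_group <- unname(grp)
  calls$ab_flag <- monotypic & grp != "tumor-only"
  chain <- ifelse(calls$call == "monotypic-kappa", "kappa",
                  ifelse(calls$call == "monotypic-lambda", "lambda", NA))
  dom <- vapply(unique(calls$sample_id), function(s) {
    idx <- calls$sample_id == s & monotypic & grp == "tumor-only"
    if (!any(idx)) idx <- calls$sample_id == s & monotypic
    if (!any(idx)) return(NA_character_)
    tab <- table(chain[idx])
    names(tab)[which.max(tab)]
  }, character(1L))
  calls$dominant_chain <- dom[calls$sample_id]
  calls$chain_mismatch <- calls$ab_flag & !is.na(calls$dominant_chain) &
    chain != calls$dominant_chain
  if (any(calls$chain_mismatch)) {
    bad <- calls[calls$chain_mismatch, ]
    warning("Ab cluster light chain disagrees with the sample's dominant ",
            "monotypic chain in: ",
            paste(sprintf("%s/cluster %s", bad$sample_id, bad$cluster),
                  collapse = ", "))
  }
  calls
}

#' Assign a tumor type to each sample
#'
#' Cells in monotypic clusters are the sample's clonal B-cells. Their
#' metacluster composition determines the type: under the "most-abundant"
#' rule the sample takes type A (or B) when its most abundant metacluster
#' among clonal cells is MC-A (or MC-B), otherwise NOS; under the
#' "majority-50" rule type A/B additionally requires that metacluster to
#' hold more than 50% of clonal cells. Samples with no monotypic cluster
#' are called "rLN-like". Ties for the dominant metacluster give NOS.
#'
#' @param calls data.frame from [call_clonality()].
#' @param cells the `cell_table` the calls were made on.
#' @param labels per-cell cluster ids aligned to `cells`.
#' @param metaclusters per-cell metacluster ids (from
#'   [assign_metaclusters()]).
#' @param mc_names named character vector metacluster id -> display name
#'   (from [annotate_metaclusters()]); names "MC-A"/"MC-B" drive typing.
#' @param rule "most-abundant" or "majority-50".
#' @return data.frame per sample: sample_id, type, rule, clonal_fraction,
#'   dominant_mc, dominant_share, plus per-metacluster composition columns.
#' @export
assign_tumor_type <- function(calls, cells, labels, metaclusters, mc_names,
                              rule = c("most-abundant", "majority-50")) {
  rule <- match.arg(rule)
  stopifnot(inherits(cells, "cell_table"))
  monotypic <- calls[calls$call %in% c("monotypic-kappa", "monotypic-lambda"), ]
  key <- paste(cells$sample_id, labels)
  clonal <- key %in% paste(monotypic$sample_id, monotypic$cluster) &
    !is.na(labels) & !cells$is_control
  samples <- unique(cells$sample_id[!cells$is_control])
  mc_levels <- sort(unique(metaclusters[!is.na(metaclusters)]))
  rows <- lapply(samples, function(s) {
    in_s <- cells$sample_id == s & !is.na(labels)
    if (!any(in_s)) stop("sample has no labelled cells: ", s)
    cl <- clonal & in_s
    clonal_fraction <- sum(cl) / sum(in_s)
    if (!any(cl)) {
      return(data.frame(sample_id = s, type = "rLN-like", rule = rule,
                        clonal_fraction = 0, dominant_mc = NA_character_,
                        dominant_share = NA_real_, stringsAsFactors = FALSE))
    }
    comp <- table(factor(metaclusters[cl], levels = mc_levels)) / sum(cl)
    top <- which(comp == max(comp))
    if (length(top) > 1L) {
      dom <- NA_character_; share <- max(comp); type <- "NOS"
    } else {
      dom <- mc_names[as.character(mc_levels[top])]
      share <- as.numeric(comp[top])
      type <- if (dom %in% c("MC-A", "MC-B") &&
                  (rule == "most-abundant" || share > 0.5)) {
        if (dom == "MC-A") "A" else "B"
      } else "NOS"
    }
    data.frame(sample_id = s, type = type, rule = rule,
               clonal_fraction = clonal_fraction, dominant_mc = dom,
               dominant_share = share, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
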
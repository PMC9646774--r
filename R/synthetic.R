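# Synthetic multi-sample, multi-batch cytometry cohorts with planted
# population structure: canonical normal B-cell subsets, monotypic clonal
# populations, per-batch channel drift, and linear spillover. Everything
# downstream of the simulator treats its output like real acquisition data.

local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Population template
#'
#' A cell population is modelled as an independent Gaussian on the arcsinh
#' scale, one mean/sd per marker, with the two light-chain channels handled
#' separately: polytypic populations draw a per-cell chain (kappa with
#' probability `kappa_frac`), monotypic populations put every cell on one
#' chain. Cells express `lc_pos` on their own chain and `lc_neg` on the
#' other.
#'
#' @param name template label.
#' @param mean named numeric vector of arcsinh-scale means; markers not
#'   named fall back to `baseline`.
#' @param panel a `marker_panel` giving the full marker set.
#' @param sd positive scalar or per-marker vector of arcsinh-scale standard
#'   deviations.
#' @param light_chain "polytypic", "kappa" or "lambda". Clonal kinds must be
#'   monotypic.
#' @param kind population kind: one of "normal-naive", "normal-memory",
#'   "normal-GC", "normal-PBPC", "clonal-A", "clonal-B", "clonal-divergent".
#' @param baseline arcsinh-scale mean for unnamed markers.
#' @param lc_pos,lc_neg arcsinh-scale mean on the expressed / unexpressed
#'   light chain.
#' @param kappa_frac P(kappa) per cell for polytypic populations.
#' @return an object of class `population_template`.
#' @export
population_template <- function(name, mean, panel, sd = 0.35,
                                light_chain = c("polytypic", "kappa", "lambda"),
                                kind = c("normal-naive", "normal-memory",
                                         "normal-GC", "normal-PBPC",
                                         "clonal-A", "clonal-B",
                                         "clonal-divergent"),
                                baseline = 0.5, lc_pos = 4, lc_neg = 0.3,
                                kappa_frac = 0.6) {
  light_chain <- match.arg(light_chain)
  kind <- match.arg(kind)
  M <- length(panel$marker_names)
  mu <- rep(baseline, M)
  names(mu) <- panel$marker_names
  if (length(mean)) {
    known <- intersect(names(mean), panel$marker_names)
    mu[known] <- mean[known]
  }
  sdv <- rep_len(sd, M)
  if (any(sdv <= 0)) stop("sd must be positive")
  if (startsWith(kind, "clonal") && light_chain == "polytypic") {
    stop("clonal templates must be monotypic (light_chain kappa or lambda)")
  }
  structure(list(name = name, mean = mu, sd = sdv, light_chain = light_chain,
                 kind = kind, lc_pos = lc_pos, lc_neg = lc_neg,
                 kappa_frac = kappa_frac),
            class = "population_template")
}

#' Default population templates
#'
#' Synthetic arcsinh-scale profiles for four canonical normal B-cell
#' subsets (naive, pre-switch memory, germinal center, plasmablast/plasma
#' cell) and five monotypic clonal templates: a germinal-center-like
#' "clonal-A" (IgG+/HLA-DR+/CD22+), a memory-like "clonal-B"
#' (IgM+/CD79B+/CD24+/CD44+), and three phenotypically divergent clones.
#' Profile values are invented (high ~ 4, mid ~ 2, baseline 0.5 on the
#' arcsinh scale, sd 0.35) so that templates are well separated; they
#' emulate the qualitative marker contrasts of the two recurrent lymphoma
#' phenotypes, not any measured data.
#'
#' @param panel a `marker_panel`; markers absent from the panel are
#'   silently dropped from a template's profile.
#' @param sd arcsinh-scale standard deviation shared by all templates.
#' @return named list of `population_template` objects.
#' @export
default_templates <- function(panel = default_panel(), sd = 0.35) {
  t <- function(name, mean, lc, kind)
    population_template(name, mean, panel, sd = sd, light_chain = lc, kind = kind)
  list(
    naive = t("naive",
      c(CD19 = 4, CD20 = 4, IgM = 4, IgD = 4, CD27 = 0.5, CD24 = 2,
        CD79B = 3, `HLA-DR` = 3, CD44 = 2, CD38 = 1, CD22 = 2, IgG = 0.5),
      "polytypic", "normal-naive"),
    memory = t("memory",
      c(CD19 = 4, CD20 = 4, IgM = 3.5, IgD = 1, CD27 = 4, CD44 = 3.5,
        CD24 = 2.5, CD79B = 3, `HLA-DR` = 3, CD38 = 1, CD22 = 2, IgG = 1),
      "polytypic", "normal-memory"),
    gc = t("gc",
      c(CD19 = 4, CD20 = 4, CD38 = 4, CD22 = 3, `HLA-DR` = 4, IgM = 2,
        IgD = 0.5, CD27 = 1, CD24 = 0.5, IgG = 1.5, CD44 = 1, CD79B = 2),
      "polytypic", "normal-GC"),
    pbpc = t("pbpc",
      c(CD19 = 2, CD20 = 1, CD38 = 5.5, CD27 = 4, `HLA-DR` = 1, IgM = 1,
        IgG = 1, CD24 = 0.5, CD22 = 0.5, CD44 = 2),
      "polytypic", "normal-PBPC"),
    clonalA = t("clonalA",
      c(CD19 = 4, CD20 = 4, IgG = 4, `HLA-DR` = 4.5, CD22 = 4, IgM = 0.5,
        IgD = 0.5, CD24 = 0.5, CD44 = 1, CD38 = 3, CD79B = 2, CD27 = 1),
      "kappa", "clonal-A"),
    clonalB = t("clonalB",
      c(CD19 = 4, CD20 = 4, IgM = 4.5, CD79B = 4, CD24 = 4, CD44 = 4.5,
        IgG = 0.5, `HLA-DR` = 1.5, CD22 = 1, CD38 = 1, CD27 = 2, IgD = 1),
      "lambda", "clonal-B"),
    clonalC = t("clonalC",
      c(CD19 = 4, CD20 = 4, CD38 = 4.5, IgG = 3, CD22 = 3.5, `HLA-DR` = 3,
        CD44 = 3, P01 = 4, P02 = 4),
      "kappa", "clonal-divergent"),
    clonalD = t("clonalD",
      c(CD19 = 4, CD20 = 4, IgD = 3.5, CD27 = 3.5, CD24 = 3, IgM = 2,
        `HLA-DR` = 2, P03 = 4, P04 = 4),
      "lambda", "clonal-divergent"),
    clonalE = t("clonalE",
      c(CD19 = 4, CD20 = 4, CD44 = 4, CD22 = 2.5, IgG = 2, CD38 = 2,
        P05 = 4, P06 = 4),
      "kappa", "clonal-divergent")
  )
}

#' Cohort configuration
#'
#' @param panel a `marker_panel`.
#' @param templates named list of `population_template`s.
#' @param composition samples x templates matrix of mixture weights; rows
#'   must sum to 1 (tolerance 1e-9). Row names become sample ids.
#' @param n_batches number of acquisition batches; samples are assigned
#'   round-robin. Each batch additionally acquires one pooled-control
#'   aliquot simulated from `control_mix`.
#' @param cells_per_sample cells drawn per sample.
#' @param batch_factors n_batches x M matrix of positive multiplicative
#'   per-channel drift factors applied on the raw scale; default all 1.
#' @param spillover M x M spillover matrix (see [make_spillover_matrix()]);
#'   default identity.
#' @param control_mix weights over templates for the pooled control
#'   aliquot, identical across batches; default an even mix of the normal
#'   templates.
#' @param control_cells cells per control aliquot.
#' @param cofactor arcsinh cofactor scale a: raw = sinh(z)/a.
#' @param seed integer root seed.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(panel, templates, composition, n_batches = 1L,
                          cells_per_sample = 1000L, batch_factors = NULL,
                          spillover = NULL, control_mix = NULL,
                          control_cells = cells_per_sample, cofactor = 0.2,
                          seed = 1L) {
  M <- length(panel$marker_names)
  composition <- as.matrix(composition)
  if (is.null(rownames(composition)))
    rownames(composition) <- sprintf("S%02d", seq_len(nrow(composition)))
  if (is.null(colnames(composition)))
    colnames(composition) <- names(templates)
  if (!all(colnames(composition) %in% names(templates)))
    stop("composition columns must name templates")
  if (any(composition < 0)) stop("composition weights must be nonnegative")
  if (any(abs(rowSums(composition) - 1) > 1e-9))
    stop("composition rows must sum to 1")
  if (is.null(batch_factors)) batch_factors <- matrix(1, n_batches, M)
  batch_factors <- as.matrix(batch_factors)
  if (!all(dim(batch_factors) == c(n_batches, M)))
    stop("batch_factors must be n_batches x n_markers")
  if (any(batch_factors <= 0)) stop("batch_factors must be positive")
  if (is.null(spillover)) spillover <- make_spillover_matrix(M, 0)
  if (!all(dim(spillover) == c(M, M))) stop("spillover must be M x M")
  if (is.null(control_mix)) {
    normals <- names(templates)[vapply(templates, function(t)
      startsWith(t$kind, "normal"), logical(1L))]
    if (!length(normals)) stop("control_mix required when no normal templates")
    control_mix <- stats::setNames(rep(1 / length(normals), length(normals)), normals)
  }
  if (abs(sum(control_mix) - 1) > 1e-9) stop("control_mix must sum to 1")
  if (cells_per_sample < 1L || n_batches < 1L) stop("sizes must be positive")
  if (cofactor <= 0) stop("cofactor must be positive")
  structure(list(panel = panel, templates = templates,
                 composition = composition, n_batches = as.integer(n_batches),
                 cells_per_sample = as.integer(cells_per_sample),
                 batch_factors = batch_factors, spillover = spillover,
                 control_mix = control_mix,
                 control_cells = as.integer(control_cells),
                 cofactor = cofactor, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Sparse spillover matrix
#'
#' Builds an M x M spillover matrix with unit diagonal and `n_spill`
#' directed off-diagonal entries of magnitude `off_diag`, mimicking the
#' handful of adjacent-mass crosstalk channels seen on a CyTOF panel.
#'
#' @param M number of channels.
#' @param off_diag spill fraction in [0, 0.5); 0 gives the identity.
#' @param seed integer seed picking which channel pairs spill.
#' @param n_spill number of directed spilling pairs (default ~15% of M,
#'   at least 1 when `off_diag > 0`).
#' @return M x M numeric matrix S with S[i, j] the fraction of channel i
#'   signal read in channel j.
#' @export
make_spillover_matrix <- function(M, off_diag, seed = 1L, n_spill = NULL) {
  if (off_diag < 0 || off_diag >= 0.5) stop("off_diag must be in [0, 0.5)")
  S <- diag(M)
  if (off_diag == 0 || M == 1L) return(S)
  if (is.null(n_spill)) n_spill <- max(1L, round(0.15 * M))
  n_spill <- min(n_spill, M * (M - 1L))
  local_seed(seed, {
    pairs <- sample.int(M * (M - 1L), n_spill)
    for (p in pairs) {
      i <- ((p - 1L) %/% (M - 1L)) + 1L
      j <- ((p - 1L) %% (M - 1L)) + 1L
      if (j >= i) j <- j + 1L
      S[i, j] <- off_diag
    }
  })
  S
}

draw_template_cells <- function(tpl, n, panel, cofactor) {
  M <- length(tpl$mean)
  z <- matrix(stats::rnorm(n * M, mean = rep(tpl$mean, each = n),
                           sd = rep(tpl$sd, each = n)), n, M)
  colnames(z) <- names(tpl$mean)
  chain <- switch(tpl$light_chain,
    polytypic = ifelse(stats::runif(n) < tpl$kappa_frac, "kappa", "lambda"),
    kappa = rep("kappa", n),
    lambda = rep("lambda", n))
  ki <- panel$kappa_index; li <- panel$lambda_index
  mu_k <- ifelse(chain == "kappa", tpl$lc_pos, tpl$lc_neg)
  mu_l <- ifelse(chain == "lambda", tpl$lc_pos, tpl$lc_neg)
  z[, ki] <- stats::rnorm(n, mu_k, tpl$sd[ki])
  z[, li] <- stats::rnorm(n, mu_l, tpl$sd[li])
  raw <- pmax(sinh(z) / cofactor, 0)
  list(raw = raw, chain = chain)
}

sample_truth_type <- function(weights, templates) {
  kinds <- vapply(templates[names(weights)], `[[`, character(1L), "kind")
  clonal <- startsWith(kinds, "clonal")
  if (!any(clonal & weights > 0)) return("rLN")
  dom <- names(weights)[clonal][which.max(weights[clonal])]
  switch(templates[[dom]]$kind,
         "clonal-A" = "A", "clonal-B" = "B", "NOS")
}

#' Simulate a cytometry cohort
#'
#' Forward model, per cell: draw a template from the sample's mixture
#' weights; draw arcsinh-scale expression from the template Gaussian (light
#' chains per the template's clonality); map to the raw scale via
#' `sinh(z)/cofactor`, truncating at zero; multiply by the batch's
#' per-channel drift factor; mix across channels with the spillover matrix.
#' One pooled-control aliquot with a fixed template mix is acquired per
#' batch, so control-anchored batch factors are identifiable downstream.
#' Fully reproducible from `config$seed`.
#'
#' @param config a `cohort_config`.
#' @return a list of class `synthetic_cohort` with elements `cells` (a
#'   raw-scale `cell_table` whose `truth` records template, light chain and
#'   intended sample type) and `truth_samples` (per-sample intended type
#'   A/B/NOS/rLN and planted clonal-population count).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  panel <- config$panel
  S <- config$spillover
  comp_row <- function(s) {
    stats::setNames(as.numeric(config$composition[s, ]),
                    colnames(config$composition))
  }
  local_seed(config$seed, {
    tabs <- list()
    samples <- rownames(config$composition)
    batches <- sprintf("batch%d", ((seq_along(samples) - 1L) %% config$n_batches) + 1L)
    truth_samples <- data.frame(
      sample_id = samples, batch_id = batches,
      type = vapply(samples, function(s)
        sample_truth_type(comp_row(s), config$templates),
        character(1L)),
      n_clonal_populations = vapply(samples, function(s) {
        w <- comp_row(s)
        kinds <- vapply(config$templates[names(w)], `[[`, character(1L), "kind")
        sum(w > 0 & startsWith(kinds, "clonal"))
      }, integer(1L)),
      row.names = NULL, stringsAsFactors = FALSE)
    draw_sample <- function(id, batch, weights, n, is_control) {
      counts <- as.vector(stats::rmultinom(1L, n, weights))
      raws <- list(); tpls <- character(0L); chains <- character(0L)
      for (k in seq_along(weights)) {
        if (counts[k] == 0L) next
        tpl <- config$templates[[names(weights)[k]]]
        d <- draw_template_cells(tpl, counts[k], panel, config$cofactor)
        raws[[length(raws) + 1L]] <- d$raw
        tpls <- c(tpls, rep(names(weights)[k], counts[k]))
        chains <- c(chains, d$chain)
      }
      raw <- do.call(rbind, raws)
      b <- match(batch, sprintf("batch%d", seq_len(config$n_batches)))
      raw <- raw * rep(config$batch_factors[b, ], each = nrow(raw))
      raw <- raw %*% S
      colnames(raw) <- panel$marker_names
      cell_table(raw, rep(id, nrow(raw)), rep(batch, nrow(raw)),
                 rep(is_control, nrow(raw)), scale = "raw",
                 truth = data.frame(template = tpls, light_chain = chains,
                                    stringsAsFactors = FALSE))
    }
    for (i in seq_along(samples)) {
      tabs[[length(tabs) + 1L]] <- draw_sample(
        samples[i], batches[i], comp_row(samples[i]),
        config$cells_per_sample, FALSE)
    }
    for (b in seq_len(config$n_batches)) {
      tabs[[length(tabs) + 1L]] <- draw_sample(
        sprintf("control_b%d", b), sprintf("batch%d", b), config$control_mix,
        config$control_cells, TRUE)
    }
    cells <- do.call(bind_cells, tabs)
    idx <- match(cells$sample_id, truth_samples$sample_id)
    cells$truth$sample_type <- ifelse(is.na(idx), "control",
                                      truth_samples$type[idx])
    structure(list(cells = cells, truth_samples = truth_samples,
                   config = config),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d samples in %d batches\n",
              nrow(x$truth_samples), x$config$n_batches))
  print(x$cells)
  invisible(x)
}

#' Write a cohort to disk
#'
#' One CSV per sample (cells x markers, header = marker names) plus a JSON
#' manifest recording the sample -> batch map, control flags and per-sample
#' truth labels.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory, created if absent.
#' @return invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cells <- cohort$cells
  ids <- unique(cells$sample_id)
  entries <- list()
  for (id in ids) {
    idx <- cells$sample_id == id
    path <- file.path(dir, paste0(id, ".csv"))
    utils::write.csv(as.data.frame(cells$values[idx, , drop = FALSE]),
                     path, row.names = FALSE)
    entries[[id]] <- list(file = basename(path),
                          batch = cells$batch_id[which(idx)[1L]],
                          is_control = cells$is_control[which(idx)[1L]])
  }
  manifest <- list(samples = entries,
                   truth = cohort$truth_samples,
                   cofactor = cohort$config$cofactor)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing per-sample CSVs and `manifest.json`.
#' @return a raw-scale `cell_table`.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  tabs <- lapply(names(manifest$samples), function(id) {
    e <- manifest$samples[[id]]
    vals <- as.matrix(utils::read.csv(file.path(dir, e$file), check.names = FALSE))
    cell_table(vals, rep(id, nrow(vals)), rep(e$batch, nrow(vals)),
               rep(isTRUE(e$is_control), nrow(vals)), scale = "raw")
  })
  do.call(bind_cells, tabs)
}
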
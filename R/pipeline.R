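#' Pipeline configuration
#'
#' Collects every stage parameter with its default (QC minimum area 11 px,
#' 70 % training split, 2000 variable genes, 15 PCs, 0.25 log-fold-change and
#' 10 % minimum-fraction DE thresholds, 9214 events per sample, smoothing
#' gamma 2) plus stage toggles and the master seed. Unknown keys are
#' rejected. The configuration round-trips losslessly through YAML.
#'
#' @param ... Overrides of the defaults listed above (see
#'   [default_pipeline_config()] for all keys).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- default_pipeline_config()
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  structure(utils::modifyList(defaults, override), class = "pipeline_config")
}

#' All pipeline parameters with their defaults
#' @return Named list.
#' @export
default_pipeline_config <- function() {
  list(seed = 1L,
       stages = c("cytof", "imc", "spatial", "spots"),
       n_donors = 3L,
       n_events = 4000L,
       n_per_sample = 3000L,
       k_nodes = 60L,
       k_density = 15L,
       n_roi = 4L,
       imc_cells_per_roi = 2000L,
       min_area_px = 11L,
       split = 0.7,
       b_clusters = 12L,
       spot_nrow = 24L, spot_ncol = 24L,
       n_hvg = 2000L, n_pcs = 15L,
       gamma = 2, q = NULL,
       potts_iterations = 300L, potts_burn_in = 100L,
       logfc_min = 0.25, min_fraction = 0.10,
       sle_genes = c("C1QB", "C1QA", "C1R", "C1S", "C3", "DNASE1L3"))
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config (seed", x$seed, "), stages:",
      paste(x$stages, collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the demonstration pipeline end to end on synthetic tissue
#'
#' Simulates the inputs, then executes the enabled stages in dependency
#' order: suspension cytometry (subsampling, SPADE-style tree, bubbles,
#' paired proportions), imaging cytometry (QC, compensation, gating,
#' propagation, B subsets), spatial statistics (distance to epithelium,
#' subset contrasts), and spot transcriptomics (clustering, region DE,
#' correlation matrix). Fails fast on the first stage error. Reruns with the
#' same configuration reproduce the same report.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; stage outputs and the report are
#'   written there as CSV/JSON.
#' @return Object of class `report_bundle` with one element per stage plus
#'   `config` and collected `warnings`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  warn <- character(0)
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  report <- list(config = unclass(config))
  sim <- sim_config(seed = config$seed,
                    imc = list(n_cells = config$imc_cells_per_roi),
                    spots = list(nrow = config$spot_nrow,
                                 ncol = config$spot_ncol))

  if ("cytof" %in% config$stages) {
    pair <- simulate_suspension_pair(sim, n_donors = config$n_donors,
                                     n_events = config$n_events)
    stage <- collect(run_cytof_stage(
      pair, n_per_sample = config$n_per_sample, k_nodes = config$k_nodes,
      k_density = config$k_density, seed = config$seed))
    report$cytof <- list(
      proportions = stage$report$proportions,
      tests = stage$report$report,
      n_nodes = nrow(stage$tree$nodes))
  }

  imc_stage <- NULL
  if (any(c("imc", "spatial") %in% config$stages)) {
    cohort <- simulate_imc_cohort(sim, n_roi = config$n_roi)
    imc_stage <- collect(run_imc_stage(
      cohort, S = default_spillover(), min_area_px = config$min_area_px,
      split = config$split, k = config$b_clusters, seed = config$seed))
    report$imc <- list(
      qc = imc_stage$qc_log,
      propagation = imc_stage$propagation,
      lineage_counts = as.list(table(imc_stage$cells$meta$lineage_full)),
      b_subset_counts = as.list(table(imc_stage$cells$meta$b_subset)))
  }

  if ("spatial" %in% config$stages && !is.null(imc_stage)) {
    meta <- imc_stage$cells$meta
    dist <- collect(nearest_epithelial_distance(meta))
    bsel <- meta$lineage_full == "B" & meta$b_subset != "none"
    med <- stats::aggregate(dist[bsel],
                            by = list(subset = meta$b_subset[bsel],
                                      roi = meta$roi[bsel]),
                            FUN = stats::median)
    report$spatial <- list(median_distance = med)
  }

  if ("spots" %in% config$stages) {
    sa <- simulate_spot_sample(sim, "STA")
    pp <- collect(preprocess_spots(sa$counts, n_hvg = config$n_hvg,
                                   n_pcs = config$n_pcs))
    graph <- build_spot_graph(sa$spots)
    q_use <- config$q
    tuning <- NULL
    if (is.null(q_use)) {
      tuning <- tune_q(pp$pcs, graph, q_range = 2:10, gamma = config$gamma,
                       seed = config$seed)
      q_use <- if (is.na(tuning$suggested_q)) 7L else tuning$suggested_q
    }
    fit <- potts_cluster(pp$pcs, graph, q = q_use, gamma = config$gamma,
                         iterations = config$potts_iterations,
                         burn_in = config$potts_burn_in, seed = config$seed)
    region <- ifelse(sa$ground_truth$zone %in% c("SED", "FAE"), "SED",
                     ifelse(sa$ground_truth$zone %in% c("mantle", "GC"),
                            "Follicle", "none"))
    de <- region_de(sa$counts, pp$norm, region,
                    logfc_min = config$logfc_min,
                    min_fraction = config$min_fraction)
    lymph <- sa$ground_truth$zone %in% c("mantle", "GC", "SED", "T_zone")
    cm <- gene_correlation_matrix(pp$norm[, lymph, drop = FALSE],
                                  config$sle_genes)
    sed_up <- de[de$tested & de$logFC > 0, , drop = FALSE]
    report$spots <- list(q = q_use,
                         tuning = if (is.null(tuning)) NULL else tuning$curve,
                         cluster_sizes = tabulate(fit$labels, q_use),
                         de_top = utils::head(de, 10L),
                         de_top_sed = utils::head(sed_up, 10L),
                         correlation = cm$rho)
  }

  report$warnings <- warn
  bundle <- structure(report, class = "report_bundle")
  if (!is.null(out_dir)) write_report_bundle(bundle, out_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("report_bundle with stages:",
      paste(setdiff(names(x), c("config", "warnings")), collapse = ", "),
      "\n")
  if (length(x$warnings)) {
    cat("  warnings collected:", length(x$warnings), "\n")
  }
  invisible(x)
}

write_report_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(bundle$cytof)) {
    utils::write.csv(bundle$cytof$proportions,
                     file.path(out_dir, "cytof_proportions.csv"),
                     row.names = FALSE)
    utils::write.csv(bundle$cytof$tests,
                     file.path(out_dir, "cytof_tests.csv"),
                     row.names = FALSE)
  }
  if (!is.null(bundle$spots)) {
    utils::write.csv(bundle$spots$de_top,
                     file.path(out_dir, "spots_de_top.csv"),
                     row.names = FALSE)
  }
  keep <- !vapply(bundle, is.null, logical(1))
  jsonlite::write_json(
    lapply(bundle[keep], function(el) {
      if (is.data.frame(el)) el else el
    }),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = 8,
    force = TRUE)
  invisible(out_dir)
}

# --- file formats -----------------------------------------------------------

#' Write / read a spot sample as MTX + TSV + positions CSV
#'
#' The matrix goes to `matrix.mtx`, gene names to `features.tsv`, spot
#' barcodes to `barcodes.tsv` and array/physical coordinates to
#' `positions.csv`.
#'
#' @param sample Output of [simulate_spot_sample()] (or a list with
#'   `counts` and `spots`).
#' @param dir Output directory.
#' @export
write_spot_table <- function(sample, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(sample$counts, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(sample$counts), file.path(dir, "features.tsv"))
  writeLines(colnames(sample$counts), file.path(dir, "barcodes.tsv"))
  utils::write.csv(sample$spots, file.path(dir, "positions.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_spot_table
#' @export
read_spot_table <- function(dir) {
  counts <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  rownames(counts) <- readLines(file.path(dir, "features.tsv"))
  colnames(counts) <- readLines(file.path(dir, "barcodes.tsv"))
  spots <- utils::read.csv(file.path(dir, "positions.csv"),
                           stringsAsFactors = FALSE)
  list(counts = counts, spots = spots)
}

#' Write / read a cell table as CSV (metadata + one column per channel)
#'
#' Layers are suffixed (`raw_CD20`, `compensated_CD20`, ...); reading
#' restores the [cell_table()] structure.
#'
#' @param cells A [cell_table()].
#' @param path CSV file path.
#' @export
write_cell_table <- function(cells, path) {
  stopifnot(inherits(cells, "cell_table"))
  df <- cells$meta
  for (ly in names(cells$layers)) {
    m <- cells$layers[[ly]]
    colnames(m) <- paste0(ly, "_", cells$channels)
    df <- cbind(df, as.data.frame(m))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  layer_cols <- grep("^(raw|true|compensated|transformed)_", names(df),
                     value = TRUE)
  meta <- df[, setdiff(names(df), layer_cols), drop = FALSE]
  layers <- list()
  for (ly in unique(sub("_.*", "", layer_cols))) {
    cols <- grep(paste0("^", ly, "_"), names(df), value = TRUE)
    m <- as.matrix(df[, cols, drop = FALSE])
    colnames(m) <- sub(paste0("^", ly, "_"), "", cols)
    layers[[ly]] <- m
  }
  raw <- layers$raw
  cell_table(meta, raw, layers = layers[setdiff(names(layers), "raw")])
}
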
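#' Quality-control filter on segmented cells
#'
#' Removes cells smaller than `min_area_px` pixels (default 11) or with low
#' DNA-channel counts. "Low DNA" defaults to the mean DNA intensity falling
#' below the 1st percentile of its per-ROI distribution or below an absolute
#' floor of 1 count, whichever is higher.
#'
#' @param cells A [cell_table()].
#' @param min_area_px Minimum cell area in pixels.
#' @param dna_channels DNA channel names; `NULL` disables the DNA rule.
#' @param dna_quantile Per-ROI quantile defining the low-DNA threshold.
#' @param dna_floor Absolute lower floor on mean DNA counts.
#' @return List with the filtered `cells` and a `log` data.frame of removal
#'   counts per reason and ROI.
#' @export
qc_filter <- function(cells, min_area_px = 11L,
                      dna_channels = c("DNA1", "DNA2"),
                      dna_quantile = 0.01, dna_floor = 1) {
  stopifnot(inherits(cells, "cell_table"))
  raw <- intensity_layer(cells, "raw")
  small <- cells$meta$area_px < min_area_px
  low_dna <- rep(FALSE, nrow(raw))
  if (!is.null(dna_channels)) {
    miss <- setdiff(dna_channels, cells$channels)
    if (length(miss)) stop("DNA channel(s) missing: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    dna <- rowMeans(raw[, dna_channels, drop = FALSE])
    for (r in unique(cells$meta$roi)) {
      i <- cells$meta$roi == r
      thr <- max(stats::quantile(dna[i], dna_quantile, names = FALSE),
                 dna_floor)
      low_dna[i] <- dna[i] < thr
    }
  }
  drop_row <- small | low_dna
  log <- do.call(rbind, lapply(unique(cells$meta$roi), function(r) {
    i <- cells$meta$roi == r
    data.frame(roi = r,
               n_total = sum(i),
               n_small = sum(small & i),
               n_low_dna = sum(low_dna & !small & i),
               n_kept = sum(i & !drop_row), stringsAsFactors = FALSE)
  }))
  if (all(drop_row)) {
    warning("QC removed every cell; downstream stages will refuse",
            call. = FALSE)
  }
  keep <- which(!drop_row)
  out <- cell_table(cells$meta[keep, , drop = FALSE],
                    raw[keep, , drop = FALSE],
                    layers = lapply(cells$layers[-1L], function(m)
                      m[keep, , drop = FALSE]))
  list(cells = out, log = log)
}

#' Spillover compensation by non-negative least squares
#'
#' Recovers per-cell true intensities from observed = true %*% S by solving
#' the non-negative least-squares problem per cell. Cells whose unconstrained
#' solution is already non-negative use the exact linear solve; only the
#' remainder go through the active-set solver, so compensation never produces
#' negative intensities.
#'
#' @param x Observed matrix (cells x channels), vector, or a [cell_table()]
#'   (which gains a `"compensated"` layer).
#' @param S Spillover matrix as in [apply_spillover()].
#' @return Compensated intensities in the same form as the input.
#' @export
compensate_spillover <- function(x, S) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S)) stop("spillover matrix must be square", call. = FALSE)
  kappa <- tryCatch(kappa(S, exact = TRUE), error = function(e) Inf)
  if (!is.finite(kappa) || kappa > 1e8) {
    stop("spillover matrix is singular or ill-conditioned (channels: ",
         paste(colnames(S), collapse = ", "), ")", call. = FALSE)
  }
  if (inherits(x, "cell_table")) {
    comp <- compensate_spillover(intensity_layer(x, "raw")[, rownames(S),
                                                           drop = FALSE], S)
    x$layers$compensated <- comp
    return(x)
  }
  vec <- is.null(dim(x))
  obs <- if (vec) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(obs) != nrow(S)) stop("dimension mismatch between x and S",
                                 call. = FALSE)
  ## unconstrained solve first; x_true = obs %*% inv(S) since obs = true %*% S
  Sinv <- solve(S)
  est <- obs %*% Sinv
  neg <- which(apply(est, 1L, function(r) any(r < -1e-10)))
  if (length(neg)) {
    St <- t(S)                          # solve S' z = obs' per cell
    for (i in neg) {
      est[i, ] <- pracma::lsqnonneg(St, obs[i, ])$x
    }
  }
  est[est < 0] <- 0
  dimnames(est) <- dimnames(obs)
  if (vec) drop(est) else est
}

#' Default lineage gating scheme
#'
#' The mutually exclusive per-image gates: B cells (CD20+), T cells (CD3+),
#' Macrophage/DC (CD11c+ or CD11b+ or CD68+), Endothelial (CD31+) and
#' Epithelial (E-cadherin+). CD20+CD3+ cells are "B-T neighbours" and are
#' never given an assignment, and any cell matching more than one gate is
#' left unassigned.
#'
#' @return Object of class `gating_scheme`: ordered list of gates with
#'   `any_of` channel sets.
#' @export
default_gating_scheme <- function() {
  structure(list(
    B = list(any_of = "CD20"),
    T = list(any_of = "CD3"),
    MacDC = list(any_of = c("CD11c", "CD11b", "CD68")),
    Endothelial = list(any_of = "CD31"),
    Epithelial = list(any_of = "Ecad")),
    class = "gating_scheme")
}

#' Gate cells per image with mutual exclusion
#'
#' Every cell is evaluated against every gate on its arcsinh-transformed
#' (compensated) intensities with per-image thresholds — fitted by
#' two-component mixtures unless supplied. A cell matching exactly one gate
#' receives that lineage; zero or two-plus matches (including the B-T
#' neighbour combination) leave it `"unassigned"`. Because each gate is
#' evaluated independently, the labelling is invariant to gate order.
#'
#' @param cells A [cell_table()] with a `compensated` (or `raw`) layer.
#' @param scheme A [default_gating_scheme()]-style object.
#' @param thresholds Optional list per ROI of named threshold vectors
#'   (transformed scale); `NULL` fits mixtures per image.
#' @param cofactor Arcsinh cofactor for the transformed layer.
#' @return The cell table with `meta$lineage` and a `transformed` layer.
#' @export
gate_cells <- function(cells, scheme = default_gating_scheme(),
                       thresholds = NULL, cofactor = 5) {
  stopifnot(inherits(cells, "cell_table"))
  layer <- if ("compensated" %in% names(cells$layers)) "compensated" else "raw"
  tf <- arcsinh_transform(intensity_layer(cells, layer), cofactor)
  cells$layers$transformed <- tf
  gate_ch <- unique(unlist(lapply(scheme, function(g) g$any_of)))
  miss <- setdiff(gate_ch, cells$channels)
  if (length(miss)) stop("gating scheme names missing channel(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  lineage <- rep("unassigned", nrow(tf))
  fitted_thr <- list()
  for (r in unique(cells$meta$roi)) {
    i <- which(cells$meta$roi == r)
    thr <- if (!is.null(thresholds)) thresholds[[r]] else
      marker_thresholds(tf[i, , drop = FALSE], markers = gate_ch)
    fitted_thr[[r]] <- thr
    hits <- vapply(scheme, function(g) {
      m <- tf[i, g$any_of, drop = FALSE] >=
        matrix(thr[g$any_of], length(i), length(g$any_of), byrow = TRUE)
      rowSums(m) > 0
    }, logical(length(i)))
    if (length(i) == 1L) hits <- matrix(hits, nrow = 1L,
                                        dimnames = list(NULL, names(scheme)))
    nhit <- rowSums(hits)
    one <- nhit == 1L
    lineage[i[one]] <- names(scheme)[max.col(hits[one, , drop = FALSE])]
  }
  cells$meta$lineage <- lineage
  attr(cells, "gate_thresholds") <- fitted_thr
  cells
}

#' Propagate gated lineage labels to unassigned cells
#'
#' A random-forest classifier is trained on the gated cells' transformed
#' intensities (70%/30% train/test split by default), its held-out accuracy
#' is reported, and the unassigned cells receive predicted labels. Gated
#' labels are never overwritten.
#'
#' @param cells A gated [cell_table()] (output of [gate_cells()]).
#' @param channels Feature channels; default all non-DNA channels.
#' @param split Training fraction of gated cells.
#' @param min_class_size Classes smaller than this are dropped from training
#'   with a warning.
#' @param ntree Forest size.
#' @param seed Integer seed.
#' @return List with the fully labelled `cells` (`meta$lineage_full`) and a
#'   `report` (split, held-out overall and per-class accuracy, number of
#'   cells labelled by propagation).
#' @export
propagate_labels <- function(cells, channels = NULL, split = 0.7,
                             min_class_size = 10L, ntree = 500L, seed = 1L) {
  stopifnot(inherits(cells, "cell_table"))
  if (split <= 0 || split >= 1) stop("split must be in (0, 1)", call. = FALSE)
  if (is.null(channels)) {
    channels <- setdiff(cells$channels, c("DNA1", "DNA2"))
  }
  tf <- intensity_layer(cells, "transformed")[, channels, drop = FALSE]
  lab <- cells$meta$lineage
  gated <- which(lab != "unassigned")
  sizes <- table(lab[gated])
  small <- names(sizes)[sizes < min_class_size]
  if (length(small)) {
    warning("class(es) below min_class_size dropped from training: ",
            paste(small, collapse = ", "), call. = FALSE)
    gated <- gated[!lab[gated] %in% small]
    sizes <- sizes[!names(sizes) %in% small]
  }
  if (length(sizes) < 2L) stop("need at least 2 labelled classes",
                               call. = FALSE)
  with_stream(seed, "propagate_labels", {
    y <- factor(lab[gated])
    tr <- unlist(lapply(split(seq_along(gated), y), function(idx) {
      sample(idx, max(1L, round(split * length(idx))))
    }), use.names = FALSE)
    fit <- randomForest::randomForest(tf[gated[tr], , drop = FALSE], y[tr],
                                      ntree = ntree)
    te <- setdiff(seq_along(gated), tr)
    pred_te <- stats::predict(fit, tf[gated[te], , drop = FALSE])
    acc <- mean(pred_te == y[te])
    per_class <- vapply(levels(y), function(cl) {
      sel <- y[te] == cl
      if (!any(sel)) NA_real_ else mean(pred_te[sel] == cl)
    }, numeric(1))
    un <- which(lab == "unassigned")
    full <- lab
    if (length(un)) {
      full[un] <- as.character(stats::predict(fit, tf[un, , drop = FALSE]))
    }
    cells$meta$lineage_full <- full
    list(cells = cells,
         report = list(split = split, accuracy = acc,
                       per_class_accuracy = per_class,
                       n_propagated = length(un),
                       n_train = length(tr), n_test = length(te)))
  })
}

#' Harmony-style batch integration on a principal-component embedding
#'
#' Simplified iterative correction: PCA of the scaled feature matrix, then
#' alternating (a) soft k-means in the corrected space with an
#' entropy-regularised diversity weight that up-weights clusters whose batch
#' composition diverges from the global one, and (b) per-cluster per-batch
#' linear centroid shifts. Stops when the correction norm drops below `tol`
#' or after `max_iter` rounds. With a single batch the embedding is returned
#' unchanged with a notice.
#'
#' @param x Feature matrix (cells x markers) or an existing embedding when
#'   `npc = 0`.
#' @param batch Batch id per row.
#' @param npc Number of principal components (0 = use `x` as-is).
#' @param n_clusters Soft clusters; default `min(20, floor(n/30))`.
#' @param theta Diversity-penalty strength.
#' @param sigma Soft-assignment bandwidth (in units of mean PC scale).
#' @param max_iter,tol Iteration controls.
#' @return List with `embedding` (corrected), `pca` (uncorrected), `R`
#'   (final soft assignments), `iterations`, `converged`.
#' @export
integrate_batches <- function(x, batch, npc = 10L, n_clusters = NULL,
                              theta = 2, sigma = 0.1, max_iter = 10L,
                              tol = 1e-4) {
  x <- as.matrix(x)
  batch <- as.factor(batch)
  if (nlevels(batch) < 2L) {
    message("single batch: identity correction applied")
    emb <- if (npc > 0L) prcomp_embed(x, npc) else x
    return(list(embedding = emb, pca = emb, R = NULL, iterations = 0L,
                converged = TRUE))
  }
  Z0 <- if (npc > 0L) prcomp_embed(x, npc) else x
  ## global per-batch centring removes any constant offset exactly; the
  ## iterative step then handles cluster-specific shifts
  Z <- Z0
  gm <- colMeans(Z)
  for (b in levels(batch)) {
    i <- batch == b
    Z[i, ] <- sweep(Z[i, , drop = FALSE], 2L, colMeans(Z[i, , drop = FALSE]) - gm)
  }
  n <- nrow(Z)
  if (is.null(n_clusters)) n_clusters <- max(2L, min(20L, floor(n / 30)))
  ## k-means++-free deterministic init: quantile-spread seeds on PC1 ordering
  ord <- order(Z[, 1])
  C <- Z[ord[round(seq(1, n, length.out = n_clusters))], , drop = FALSE]
  band <- sigma * mean(apply(Z, 2L, stats::sd))
  Pb <- prop.table(table(batch))
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    d2 <- outer(rowSums(Z^2), rowSums(C^2), "+") - 2 * tcrossprod(Z, C)
    d2[d2 < 0] <- 0
    logR <- -d2 / (2 * band^2)
    R0 <- exp(logR - apply(logR, 1L, max))
    R0 <- R0 / rowSums(R0)
    ## diversity weight: penalise clusters over-representing a batch
    O <- do.call(rbind, lapply(levels(batch), function(b) {
      colSums(R0[batch == b, , drop = FALSE])
    }))
    O <- sweep(O + 1e-8, 2L, colSums(O) + 1e-8, "/")  # batch share per cluster
    pen <- -theta * log(O / as.numeric(Pb))           # batches x clusters
    logR <- logR + pen[as.integer(batch), , drop = FALSE]
    R <- exp(logR - apply(logR, 1L, max))
    R <- R / rowSums(R)
    ## per-cluster per-batch linear shifts: cell i moves by
    ## sum_k R_ik * (mu_{k, batch(i)} - mu_k)
    correction <- matrix(0, n, ncol(Z))
    for (k in seq_len(n_clusters)) {
      w <- R[, k]
      if (sum(w) < 1e-6) next
      mu_all <- colSums(Z * w) / sum(w)
      for (b in levels(batch)) {
        i <- which(batch == b)
        wb <- w[i]
        if (sum(wb) < 1e-6) next
        mu_b <- colSums(Z[i, , drop = FALSE] * wb) / sum(wb)
        correction[i, ] <- correction[i, ] + outer(wb, mu_b - mu_all)
      }
    }
    Z_new <- Z - correction
    ## update centroids
    C <- t(R) %*% Z_new / pmax(colSums(R), 1e-12)
    delta <- sqrt(mean(correction^2))
    Z <- Z_new
    ## keep batch centroids pinned to the global mean: the iterative
    ## cluster-wise shifts must not reintroduce a global offset
    for (b in levels(batch)) {
      i <- batch == b
      Z[i, ] <- sweep(Z[i, , drop = FALSE], 2L,
                      colMeans(Z[i, , drop = FALSE]) - colMeans(Z))
    }
    if (delta < tol) { converged <- TRUE; break }
  }
  list(embedding = Z, pca = Z0, R = R, iterations = it,
       converged = converged)
}

prcomp_embed <- function(x, npc) {
  npc <- min(npc, ncol(x), nrow(x) - 1L)
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  p$x[, seq_len(npc), drop = FALSE]
}

#' Cluster batch-corrected B cells and name subsets by rules
#'
#' k-means clustering of the corrected embedding; each cluster is named by
#' the first rule matching its median marker profile (including the
#' intraepithelial-DN rule, E-cadherin-high, and DN2, CD11c-high CD21-low).
#' Unmatched clusters are labelled `"none"`. The first two embedding
#' dimensions serve as the 2-D visualisation coordinates (any embedding can
#' be substituted).
#'
#' @param embedding Corrected embedding (cells x dims).
#' @param markers Transformed marker matrix for profile medians.
#' @param rules A [subset_rules()]; default [default_b_subset_rules()]`("imc")`.
#' @param k Number of clusters.
#' @param thresholds Optional named thresholds; fitted from `markers` if
#'   `NULL`.
#' @param seed Integer seed.
#' @return List with `cluster`, `subset` (per cell), `cluster_subset`,
#'   `medians`, `viz` (2-D coordinates).
#' @export
cluster_and_classify_b_cells <- function(embedding, markers,
                                         rules = default_b_subset_rules("imc"),
                                         k = 12L, thresholds = NULL,
                                         seed = 1L) {
  embedding <- as.matrix(embedding)
  markers <- as.matrix(markers)
  stopifnot(nrow(embedding) == nrow(markers))
  if (k < length(rules)) {
    warning("k is below the number of rule subsets; subsets may merge",
            call. = FALSE)
  }
  cl <- with_stream(seed, "b_cluster", {
    if (k == 1L) rep(1L, nrow(embedding)) else
      stats::kmeans(embedding, centers = k, iter.max = 50L,
                    nstart = 5L)$cluster
  })
  need <- intersect(unique(unlist(lapply(rules, unlist))), colnames(markers))
  if (is.null(thresholds)) {
    thresholds <- marker_thresholds(markers, markers = need)
  }
  med <- do.call(rbind, lapply(seq_len(max(cl)), function(kk) {
    apply(markers[cl == kk, , drop = FALSE], 2L, stats::median)
  }))
  colnames(med) <- colnames(markers)
  cs <- classify_profiles(med, rules, thresholds)
  cs[cs == "unclassified"] <- "none"
  list(cluster = cl, subset = cs[cl], cluster_subset = cs, medians = med,
       viz = embedding[, seq_len(min(2L, ncol(embedding))), drop = FALSE])
}

#' Run the full imaging-mass-cytometry stage on a simulated cohort
#'
#' QC, spillover compensation, per-image gating, random-forest propagation,
#' B-cell batch integration across ROIs, and subset classification.
#'
#' @param cohort Output of [simulate_imc_cohort()].
#' @param S Spillover matrix (defaults to the cohort's configured matrix).
#' @param min_area_px,split,k,seed Stage parameters.
#' @return List with labelled `cells`, `qc_log`, `propagation` report, and
#'   B-cell `subsets`.
#' @export
run_imc_stage <- function(cohort, S, min_area_px = 11L, split = 0.7,
                          k = 12L, seed = 1L) {
  cells <- cohort$combined$cells
  qc <- qc_filter(cells, min_area_px = min_area_px)
  cells <- compensate_spillover(qc$cells, S)
  cells <- gate_cells(cells)
  prop <- propagate_labels(cells, split = split, seed = seed)
  cells <- prop$cells
  bsel <- which(cells$meta$lineage_full == "B")
  b_markers <- intersect(c("CD20", "CD27", "IgD", "CD21", "CD38", "CD10",
                           "CD45RB", "IgM", "CD138", "CD11c", "Ki67", "Ecad"),
                         cells$channels)
  tf <- intensity_layer(cells, "transformed")[bsel, b_markers, drop = FALSE]
  ib <- integrate_batches(tf, cells$meta$roi[bsel], npc = 8L)
  cls <- cluster_and_classify_b_cells(ib$embedding, tf, k = k, seed = seed)
  cells$meta$b_subset <- "none"
  cells$meta$b_subset[bsel] <- cls$subset
  list(cells = cells, qc_log = qc$log, propagation = prop$report,
       b_index = bsel, b_clusters = cls, integration = ib)
}
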
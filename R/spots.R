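#' Log-normalise spot counts, select variable genes, compute PCs
#'
#' Counts are log-normalised as `log1p(count / spot_total * scale)`; highly
#' variable genes are ranked by the variance of the log-normalised expression
#' standardised within 20 mean-expression bins; PCA is run on the scaled HVG
#' submatrix. Defaults follow the spatial-clustering convention of 2000 HVGs
#' and 15 principal components.
#'
#' @param counts Genes x spots integer matrix.
#' @param n_hvg Number of highly variable genes (capped at the gene count).
#' @param n_pcs Number of principal components.
#' @param scale_factor Library-size scale.
#' @return List with `norm` (genes x spots), `hvg`, `pcs` (spots x n_pcs),
#'   `sdev`, `kept_spots` (zero-total spots are dropped with a warning).
#' @export
preprocess_spots <- function(counts, n_hvg = 2000L, n_pcs = 15L,
                             scale_factor = 1e4) {
  counts <- as.matrix(counts)
  totals <- colSums(counts)
  keep <- totals > 0
  if (any(!keep)) {
    warning(sum(!keep), " spot(s) with zero total counts removed",
            call. = FALSE)
    counts <- counts[, keep, drop = FALSE]
    totals <- totals[keep]
  }
  if (ncol(counts) < n_pcs) stop("fewer spots than requested PCs",
                                 call. = FALSE)
  norm <- log1p(sweep(counts, 2L, totals, "/") * scale_factor)
  hvg <- select_hvg(norm, n_hvg)
  x <- t(norm[hvg, , drop = FALSE])
  mu <- colMeans(x)
  sd <- pmax(apply(x, 2L, stats::sd), 1e-8)
  xs <- sweep(sweep(x, 2L, mu, "-"), 2L, sd, "/")
  n_pcs <- min(n_pcs, ncol(xs), nrow(xs) - 1L)
  p <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  list(norm = norm, hvg = hvg,
       pcs = p$x[, seq_len(n_pcs), drop = FALSE],
       sdev = p$sdev, kept_spots = colnames(counts))
}

# Mean-binned standardised variance ranking (20 bins).
select_hvg <- function(norm, n_hvg, n_bins = 20L) {
  m <- rowMeans(norm)
  v <- apply(norm, 1L, stats::var)
  br <- unique(stats::quantile(m, probs = seq(0, 1, length.out = n_bins + 1L)))
  bin <- cut(m, breaks = br, include.lowest = TRUE)
  z <- v
  for (b in levels(bin)) {
    i <- which(bin == b)
    med <- stats::median(v[i])
    s <- stats::mad(v[i])
    z[i] <- if (s < 1e-12) (v[i] - med) else (v[i] - med) / s
  }
  z[v < 1e-12] <- -Inf                   # constant genes are never variable
  rownames(norm)[order(z, decreasing = TRUE)[seq_len(min(n_hvg,
                                                         nrow(norm)))]]
}

#' Build the spot neighbourhood graph of a lattice
#'
#' Hex lattices (Visium-like, odd rows offset by half a pitch) give interior
#' spots 6 neighbours; square lattices give 4. Edges are symmetric with no
#' self-loops.
#'
#' @param spots Data.frame with integer `row` and `col` array coordinates.
#' @param lattice `"hex"` or `"square"`.
#' @return Object of class `spot_graph`: sparse adjacency matrix `adj`,
#'   `degree`, `lattice`.
#' @export
build_spot_graph <- function(spots, lattice = c("hex", "square")) {
  lattice <- match.arg(lattice)
  key <- paste(spots$row, spots$col)
  if (anyDuplicated(key)) stop("duplicate array coordinates", call. = FALSE)
  idx <- stats::setNames(seq_along(key), key)
  n <- nrow(spots)
  nb_of <- function(r, c) {
    if (lattice == "square") {
      cbind(r + c(-1L, 1L, 0L, 0L), c + c(0L, 0L, -1L, 1L))
    } else {
      off <- if (r %% 2L == 1L) 1L else -1L
      cbind(c(r, r, r - 1L, r - 1L, r + 1L, r + 1L),
            c(c - 1L, c + 1L, c, c + off, c, c + off))
    }
  }
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n)) {
    nb <- nb_of(spots$row[i], spots$col[i])
    j <- idx[paste(nb[, 1], nb[, 2])]
    j <- j[!is.na(j)]
    from <- c(from, rep(i, length(j)))
    to <- c(to, j)
  }
  adj <- Matrix::sparseMatrix(i = from, j = to, x = 1, dims = c(n, n))
  adj <- ((adj + Matrix::t(adj)) > 0) * 1    # symmetrise, numeric 0/1
  structure(list(adj = adj, degree = Matrix::rowSums(adj),
                 lattice = lattice, n = n),
            class = "spot_graph")
}

#' @export
print.spot_graph <- function(x, ...) {
  cat("spot_graph (", x$lattice, "):", x$n, "spots,",
      sum(x$degree) / 2, "edges\n")
  invisible(x)
}

graph_coloring <- function(graph) {
  g <- igraph::graph_from_adjacency_matrix(graph$adj, mode = "undirected")
  as.integer(igraph::greedy_vertex_coloring(g))
}

#' Spatially regularised spot clustering (Potts prior, Gibbs sampling)
#'
#' Spots are modelled as a Gaussian mixture over their principal components
#' with a Potts Markov-random-field prior on the label field: the full
#' conditional for spot i is proportional to
#' `N(pc_i; mu_k, sigma^2 I) * exp(2 * gamma * n_ik / degree_i)` where `n_ik`
#' counts neighbours currently carrying label k (the doubled exponent is the
#' convention of the reference spatial-clustering model, counting each edge
#' from both ends). Labels are updated by
#' chromatic Gibbs sweeps (colour classes updated jointly), component means
#' and the shared spherical variance by moment steps each sweep, and the
#' final labelling is the per-spot marginal mode over post-burn-in samples.
#' With `gamma = 0` the sampler reduces to a plain Gaussian-mixture Gibbs
#' sampler.
#'
#' @param pcs Spots x dims matrix (e.g. from [preprocess_spots()]).
#' @param graph A [build_spot_graph()] result.
#' @param q Number of clusters (>= 1).
#' @param gamma Smoothing weight (>= 0); default 2.
#' @param covariance `"shared_full"` (pooled within-cluster covariance,
#'   default — principal components carry correlated technical structure
#'   such as library-size gradients that a spherical model misattributes to
#'   cluster signal) or `"spherical"`.
#' @param iterations,burn_in Chain length controls.
#' @param seed Integer seed.
#' @return Object of class `potts_fit`: `labels`, `trace` (profile data
#'   log-likelihood per sweep), `mu`, `sigma2`, `q`, `gamma`, label votes.
#' @export
potts_cluster <- function(pcs, graph, q, gamma = 2,
                          covariance = c("shared_full", "spherical"),
                          iterations = 1000L, burn_in = 200L, seed = 1L) {
  covariance <- match.arg(covariance)
  pcs <- as.matrix(pcs)
  n <- nrow(pcs)
  if (q < 1L) stop("q must be >= 1", call. = FALSE)
  if (q > n) stop("q exceeds the number of spots", call. = FALSE)
  if (gamma < 0) stop("gamma must be non-negative", call. = FALSE)
  stopifnot(inherits(graph, "spot_graph"), graph$n == n)
  if (q == 1L) {
    return(structure(list(labels = rep(1L, n), trace = numeric(0),
                          mu = matrix(colMeans(pcs), 1L), sigma2 = 0,
                          q = 1L, gamma = gamma, samples = NULL),
                     class = "potts_fit"))
  }
  colors <- graph_coloring(graph)
  A <- graph$adj
  deg <- pmax(graph$degree, 1)
  with_stream(seed, "potts", {
    z <- stats::kmeans(pcs, centers = q, iter.max = 30L, nstart = 3L)$cluster
    d <- ncol(pcs)
    counts_mat <- function(z) {
      Z <- Matrix::sparseMatrix(i = seq_len(n), j = z, x = 1,
                                dims = c(n, q))
      as.matrix(A %*% Z)
    }
    ## component means + shared covariance (pooled within-cluster); the
    ## whitening transform W maps residuals to unit spherical noise
    update_params <- function(z) {
      mu <- matrix(0, q, d)
      resid <- pcs
      for (k in seq_len(q)) {
        i <- which(z == k)
        if (length(i) == 0L) {
          far <- which.max(rowSums((pcs - mu[max(1L, k - 1L), ])^2))
          mu[k, ] <- pcs[far, ]
        } else {
          mu[k, ] <- colMeans(pcs[i, , drop = FALSE])
          resid[i, ] <- sweep(pcs[i, , drop = FALSE], 2L, mu[k, ])
        }
      }
      if (covariance == "spherical") {
        s2 <- max(sum(resid^2) / (n * d), 1e-8)
        Sigma <- diag(s2, d)
      } else {
        Sigma <- crossprod(resid) / n
        Sigma <- Sigma + diag(max(sum(diag(Sigma)) / d, 1e-8) * 1e-4, d)
      }
      L <- chol(Sigma)
      list(mu = mu, Sigma = Sigma, W = backsolve(L, diag(d)),
           logdet = 2 * sum(log(diag(L))))
    }
    par <- update_params(z)
    keep <- matrix(0L, n, q)               # post-burn-in label votes
    trace <- numeric(iterations)
    for (it in seq_len(iterations)) {
      yw <- pcs %*% par$W                   # whitened coordinates
      mw <- par$mu %*% par$W
      sq <- outer(rowSums(yw^2), rowSums(mw^2), "+") - 2 * tcrossprod(yw, mw)
      loglik <- -sq / 2
      for (cc in sort(unique(colors))) {
        i <- which(colors == cc)
        nc <- counts_mat(z)[i, , drop = FALSE]
        M <- loglik[i, , drop = FALSE] + 2 * gamma * nc / deg[i]
        g <- -log(-log(matrix(stats::runif(length(M)), nrow(M))))
        z[i] <- max.col(M + g)
      }
      par <- update_params(z)
      ## profile log-likelihood of the data at the current labelling
      rw <- (pcs - par$mu[z, , drop = FALSE]) %*% par$W
      trace[it] <- -sum(rw^2) / 2 -
        n / 2 * (d * log(2 * pi) + par$logdet)
      if (it > burn_in) keep[cbind(seq_len(n), z)] <-
        keep[cbind(seq_len(n), z)] + 1L
    }
    labels <- max.col(keep, ties.method = "first")
    structure(list(labels = labels, trace = trace, mu = par$mu,
                   sigma2 = par$Sigma, q = q, gamma = gamma,
                   votes = keep, iterations = iterations,
                   burn_in = burn_in, covariance = covariance),
              class = "potts_fit")
  })
}

#' @export
print.potts_fit <- function(x, ...) {
  cat("potts_fit: q =", x$q, ", gamma =", x$gamma, "\n")
  cat("  label counts:", paste(tabulate(x$labels, x$q), collapse = ", "),
      "\n")
  if (length(x$trace)) {
    cat(sprintf("  final pseudo-log-likelihood: %.1f\n",
                x$trace[length(x$trace)]))
  }
  invisible(x)
}

#' @export
plot.potts_fit <- function(x, ...) {
  if (!length(x$trace)) return(invisible(x))
  graphics::plot(x$trace, type = "l", xlab = "sweep",
                 ylab = "pseudo-log-likelihood", ...)
  graphics::abline(v = x$burn_in, lty = 2)
  invisible(x)
}

#' Tune the cluster count by short chains over a q range
#'
#' Runs a short Potts chain per candidate q and records the negative
#' pseudo-log-likelihood (mean of the final quarter of the trace). The
#' suggested q is the maximum-discrete-curvature (elbow) point of the curve;
#' the full curve is always returned for inspection, since the choice is
#' advisory (per-sample overrides such as q = 7 or q = 8 are respected
#' downstream).
#'
#' @param pcs,graph,gamma As in [potts_cluster()].
#' @param q_range Integer vector of at least 3 candidate q values.
#' @param iterations,burn_in Short-chain controls.
#' @param seed Integer seed.
#' @return Object of class `q_tuning`: `curve` (q, negative pseudo-log-
#'   likelihood, failed flag) and `suggested_q`.
#' @export
tune_q <- function(pcs, graph, q_range = 2:12, gamma = 2,
                   iterations = 80L, burn_in = 30L, seed = 1L) {
  q_range <- sort(unique(as.integer(q_range)))
  if (length(q_range) < 3L) stop("q_range needs at least 3 values",
                                 call. = FALSE)
  npll <- rep(NA_real_, length(q_range))
  failed <- rep(FALSE, length(q_range))
  for (j in seq_along(q_range)) {
    fit <- tryCatch(
      potts_cluster(pcs, graph, q = q_range[j], gamma = gamma,
                    iterations = iterations, burn_in = burn_in,
                    seed = stream_seed(seed, paste0("tune_q", q_range[j]))),
      error = function(e) NULL)
    if (is.null(fit) || !length(fit$trace)) { failed[j] <- TRUE; next }
    tail_part <- fit$trace[seq(ceiling(0.75 * iterations), iterations)]
    npll[j] <- -mean(tail_part)
  }
  curve <- data.frame(q = q_range, neg_pll = npll, failed = failed)
  ok <- which(!failed & is.finite(npll))
  suggested <- NA_integer_
  if (length(ok) >= 3L) {
    qs <- q_range[ok]; ys <- npll[ok]
    ## maximum-discrete-curvature elbow on the normalised curve; the elbow
    ## must stand out from the curvature jitter of a structureless curve
    ## (extra components absorb noise at a near-constant, jittery rate)
    yn <- (ys - min(ys)) / max(max(ys) - min(ys), 1e-12)
    curv <- rep(NA_real_, length(ok))
    for (m in 2:(length(ok) - 1L)) {
      curv[m] <- (yn[m - 1L] - yn[m]) - (yn[m] - yn[m + 1L])
    }
    cv <- curv[is.finite(curv)]
    noise <- stats::mad(cv, center = 0)
    if (length(cv) >= 4L && is.finite(noise) &&
        max(cv) < 2 * noise) {
      suggested <- qs[1L]                  # no credible elbow
    } else {
      suggested <- qs[which.max(curv)]
    }
  }
  structure(list(curve = curve, suggested_q = suggested, gamma = gamma),
            class = "q_tuning")
}

#' @export
print.q_tuning <- function(x, ...) {
  cat("q_tuning: suggested q =", x$suggested_q, "\n")
  print(x$curve, row.names = FALSE)
  invisible(x)
}

#' @export
plot.q_tuning <- function(x, ...) {
  ok <- !x$curve$failed
  graphics::plot(x$curve$q[ok], x$curve$neg_pll[ok], type = "b",
                 xlab = "q", ylab = "negative pseudo-log-likelihood", ...)
  if (!is.na(x$suggested_q)) graphics::abline(v = x$suggested_q, lty = 2)
  invisible(x)
}

#' Select the cluster best representing lymphoid tissue
#'
#' Scores each cluster by the mean log-normalised expression of B-lineage
#' markers and selects the maximum. If the runner-up is within `tol` of the
#' winner (relative to the score range) the tie is flagged and selection is
#' left to the caller.
#'
#' @param labels Cluster label per spot.
#' @param norm Genes x spots log-normalised matrix.
#' @param markers Marker genes (all must be present).
#' @param tol Relative score tolerance for calling a tie.
#' @return List with `selected` (NA on a tie), `scores`, `margin`, `tie`,
#'   `candidates`.
#' @export
select_lymphoid_cluster <- function(labels, norm,
                                    markers = c("MS4A1", "IGHD", "IGHM"),
                                    tol = 0.05) {
  miss <- setdiff(markers, rownames(norm))
  if (length(miss)) stop("marker(s) absent from matrix: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  sc <- vapply(sort(unique(labels)), function(k) {
    mean(norm[markers, labels == k, drop = FALSE])
  }, numeric(1))
  names(sc) <- sort(unique(labels))
  ord <- order(sc, decreasing = TRUE)
  rng <- max(diff(range(sc)), 1e-12)
  margin <- (sc[ord[1]] - sc[ord[2]]) / rng
  tie <- margin < tol
  list(selected = if (tie) NA else names(sc)[ord[1]],
       scores = sc, margin = margin, tie = tie,
       candidates = names(sc)[ord[seq_len(min(2L, length(sc)))]])
}

#' Sub-cluster merged lymphoid spots across samples
#'
#' Merges the lymphoid spots of two (or more) samples over their common
#' genes, runs PCA, applies the Harmony-style batch correction with sample as
#' batch, clusters the corrected reduction (k-means) and names the regional
#' subclusters by lineage marker scores (GC, SED/epithelium, T zone,
#' follicle, other). With a single sample, subclustering proceeds without
#' correction and a notice is emitted.
#'
#' @param norm_list Named list of genes x spots log-normalised matrices (one
#'   per sample), already restricted to lymphoid spots.
#' @param n_subclusters Number of regional subclusters (default 5).
#' @param npc PCs for the merged reduction.
#' @param seed Integer seed.
#' @return List with `labels` (per merged spot), `sample`, `names`
#'   (subcluster -> region name), `embedding`.
#' @export
subcluster_lymphoid <- function(norm_list, n_subclusters = 5L, npc = 10L,
                                seed = 1L) {
  stopifnot(is.list(norm_list), length(norm_list) >= 1L)
  genes <- Reduce(intersect, lapply(norm_list, rownames))
  merged <- do.call(cbind, lapply(norm_list, function(m)
    m[genes, , drop = FALSE]))
  sample_id <- rep(names(norm_list),
                   vapply(norm_list, ncol, integer(1)))
  hvg <- select_hvg(merged, 2000L)
  x <- t(merged[hvg, , drop = FALSE])
  x <- sweep(sweep(x, 2L, colMeans(x), "-"), 2L,
             pmax(apply(x, 2L, stats::sd), 1e-8), "/")
  if (length(norm_list) == 1L) {
    message("single sample: subclustering without batch correction")
    emb <- prcomp_embed(x, npc)
  } else {
    emb <- integrate_batches(x, sample_id, npc = npc)$embedding
  }
  cl <- with_stream(seed, "subcluster", {
    stats::kmeans(emb, centers = n_subclusters, iter.max = 50L,
                  nstart = 5L)$cluster
  })
  marker_sets <- list(
    GC = c("BCL6", "AICDA", "MKI67"),
    `SED/epithelium` = c("DNASE1L3", "CCL20", "ITGAX", "C1QB", "EPCAM",
                         "KRT8"),
    `T zone` = c("CD3D", "CD3E", "TRAC"),
    Follicle = c("IGHD", "TCL1A", "MS4A1"))
  marker_sets <- lapply(marker_sets, intersect, y = genes)
  marker_sets <- marker_sets[vapply(marker_sets, length, integer(1)) > 0]
  ## z-score marker-set means over subclusters, take the best-matching set
  set_means <- vapply(seq_len(n_subclusters), function(k) {
    vapply(marker_sets, function(g) {
      mean(merged[g, cl == k, drop = FALSE])
    }, numeric(1))
  }, numeric(length(marker_sets)))
  if (is.null(dim(set_means))) {
    set_means <- matrix(set_means, nrow = length(marker_sets))
  }
  zs <- t(scale(t(set_means)))
  names_out <- vapply(seq_len(n_subclusters), function(k) {
    rownames(zs)[which.max(zs[, k])]
  }, character(1))
  list(labels = cl, sample = sample_id,
       names = stats::setNames(names_out, seq_len(n_subclusters)),
       region = names_out[cl], embedding = emb)
}

#' Region differential expression with fold-change and fraction thresholds
#'
#' Marker detection between two spot classifications (e.g. SED vs Follicle):
#' genes must show at least `logfc_min` absolute log fold change (difference
#' of mean log-normalised expression) and detection in at least
#' `min_fraction` of the spots of one region to be tested; tested genes get a
#' Wilcoxon rank-sum p value and Bonferroni adjustment over the tested set.
#' Filtered genes are flagged, never dropped. Defaults are the 0.25
#' log-fold-change and 10 % minimum-expression thresholds.
#'
#' @param counts Genes x spots raw counts (for detection fractions).
#' @param norm Genes x spots log-normalised matrix (for logFC and tests).
#' @param region Character vector per spot; exactly two distinct values
#'   among the spots considered (others are ignored).
#' @param region_a,region_b The two classifications; logFC is a minus b.
#' @param logfc_min,min_fraction Filter thresholds.
#' @param min_spots Minimum spots per region.
#' @return Object of class `de_table` (a data.frame): gene, mean log
#'   expression per region, logFC, detection fractions, tested flag, p
#'   (Wilcoxon), p_adj (Bonferroni), sorted by adjusted p then |logFC|.
#' @export
region_de <- function(counts, norm, region, region_a = "SED",
                      region_b = "Follicle", logfc_min = 0.25,
                      min_fraction = 0.10, min_spots = 3L) {
  ia <- which(region == region_a)
  ib <- which(region == region_b)
  if (length(ia) < min_spots || length(ib) < min_spots) {
    stop("need at least ", min_spots, " spots in each region", call. = FALSE)
  }
  counts <- as.matrix(counts); norm <- as.matrix(norm)
  mean_a <- rowMeans(norm[, ia, drop = FALSE])
  mean_b <- rowMeans(norm[, ib, drop = FALSE])
  lfc <- mean_a - mean_b
  pct_a <- rowMeans(counts[, ia, drop = FALSE] > 0)
  pct_b <- rowMeans(counts[, ib, drop = FALSE] > 0)
  tested <- abs(lfc) >= logfc_min & pmax(pct_a, pct_b) >= min_fraction
  p <- rep(NA_real_, nrow(norm))
  for (g in which(tested)) {
    p[g] <- wilcoxon_rank_sum(norm[g, ia], norm[g, ib])$p_value
  }
  ## Bonferroni over ALL genes (the reference implementation's convention):
  ## the fold-change filter selects genes with extreme observed differences,
  ## so adjusting only over the tested set would lose family-wise control
  p_adj <- rep(NA_real_, nrow(norm))
  p_adj[tested] <- pmin(1, p[tested] * nrow(norm))
  out <- data.frame(gene = rownames(norm),
                    mean_a = mean_a, mean_b = mean_b, logFC = lfc,
                    pct_a = pct_a, pct_b = pct_b,
                    tested = tested, p = p, p_adj = p_adj,
                    stringsAsFactors = FALSE)
  names(out)[names(out) == "mean_a"] <- paste0("mean_", region_a)
  names(out)[names(out) == "mean_b"] <- paste0("mean_", region_b)
  names(out)[names(out) == "pct_a"] <- paste0("pct_", region_a)
  names(out)[names(out) == "pct_b"] <- paste0("pct_", region_b)
  ord <- order(!out$tested, out$p_adj, -abs(out$logFC))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  if (!any(tested)) {
    attr(out, "diagnostics") <- sprintf(
      "no genes passed |logFC| >= %.2f with detection >= %.0f%%",
      logfc_min, 100 * min_fraction)
  }
  class(out) <- c("de_table", "data.frame")
  out
}

#' Pairwise Spearman correlation matrix with Holm adjustment
#'
#' Spearman rho for every gene pair over the selected spots, with the Holm
#' step-down adjustment applied across the m(m-1)/2 unique pairs. Genes
#' missing from the matrix are reported, not fatal; constant genes are
#' flagged with undefined rows/columns.
#'
#' @param norm Genes x spots log-normalised matrix.
#' @param genes Genes to correlate (>= 2 present).
#' @return List with symmetric `rho` (unit diagonal), `p_raw`, `p_adj`
#'   matrices, `missing` genes, `degenerate` genes.
#' @export
gene_correlation_matrix <- function(norm, genes) {
  missing <- setdiff(genes, rownames(norm))
  genes <- intersect(genes, rownames(norm))
  if (length(genes) < 2L) stop("need at least 2 genes present", call. = FALSE)
  if (ncol(norm) < 3L) stop("need at least 3 spots", call. = FALSE)
  m <- length(genes)
  rho <- diag(m); p_raw <- matrix(NA_real_, m, m)
  dimnames(rho) <- dimnames(p_raw) <- list(genes, genes)
  diag(p_raw) <- 0
  degenerate <- character(0)
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      sc <- spearman_cor(norm[genes[i], ], norm[genes[j], ])
      if (isTRUE(sc$degenerate)) {
        degenerate <- union(degenerate, genes[c(i, j)])
      }
      rho[i, j] <- rho[j, i] <- sc$rho
      p_raw[i, j] <- p_raw[j, i] <- sc$p_value
    }
  }
  up <- upper.tri(p_raw)
  adj <- adjust_pvalues(p_raw[up], "holm")$adjusted
  p_adj <- matrix(NA_real_, m, m, dimnames = dimnames(p_raw))
  p_adj[up] <- adj
  p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
  diag(p_adj) <- 0
  list(rho = rho, p_raw = p_raw, p_adj = p_adj,
       missing = missing, degenerate = degenerate)
}

#' Adjusted Rand index between two labelings
#'
#' Permutation-invariant clustering agreement, delegated to
#' [mclust::adjustedRandIndex()].
#'
#' @param a,b Label vectors of equal length.
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  mclust::adjustedRandIndex(a, b)
}
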
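#' Equal-event subsampling across samples
#'
#' Each sample contributes exactly `n_per_sample` events drawn without
#' replacement (the suspension analysis default of 9214 events per sample).
#' If a sample is smaller than requested, the request is capped at the
#' smallest sample with a warning so contributions stay equal.
#'
#' @param events Event data.frame with a `sample_id` column.
#' @param n_per_sample Events to keep per sample.
#' @param seed Integer seed for reproducible selection.
#' @return Subsampled data.frame (row order: samples in order of first
#'   appearance).
#' @export
subsample_equal <- function(events, n_per_sample = 9214, seed = 1L) {
  if (nrow(events) == 0L) stop("no events supplied", call. = FALSE)
  sizes <- table(factor(events$sample_id, levels = unique(events$sample_id)))
  if (any(sizes == 0L)) stop("empty sample present", call. = FALSE)
  n <- n_per_sample
  if (n > min(sizes)) {
    n <- min(sizes)
    warning("n_per_sample capped at smallest sample size (", n, ")",
            call. = FALSE)
  }
  with_stream(seed, "subsample_equal", {
    keep <- unlist(lapply(names(sizes), function(s) {
      idx <- which(events$sample_id == s)
      sort(sample(idx, n))
    }), use.names = FALSE)
    events[keep, , drop = FALSE]
  })
}

#' Density-dependent downsampling of events
#'
#' The density-normalisation step of a SPADE-style analysis: local density is
#' the number of neighbours inside a fixed kernel radius (the median distance
#' to the `k_density`-th nearest neighbour, so the median density is about
#' `k_density`), and each point is retained with probability
#' `min(1, target_density / density)`. Dense regions are thinned toward a
#' uniform target and rare populations survive; the expected number of
#' retained events per unit volume is constant wherever the density exceeds
#' the target.
#'
#' @param x Numeric matrix of points (events x dimensions).
#' @param target_density Target density; default is the 3rd percentile of the
#'   estimated densities.
#' @param k_density Neighbour rank that calibrates the kernel radius.
#' @param seed Integer seed.
#' @param ref_size Optional size of a random reference sample against which
#'   neighbours are counted (a performance option for large event sets;
#'   `NULL` uses every point).
#' @return Integer vector of retained row indices.
#' @export
density_downsample <- function(x, target_density = NULL, k_density = 15L,
                               seed = 1L, ref_size = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n <= k_density) stop("need more than k_density points", call. = FALSE)
  ref <- if (!is.null(ref_size) && ref_size < n) {
    with_stream(seed, "density_ref", sample(n, ref_size))
  } else seq_len(n)
  ## kernel radius from a calibration subsample of the reference
  cal <- if (length(ref) > 500L) {
    ref[round(seq(1, length(ref), length.out = 500L))]
  } else ref
  L <- stats::median(knn_kth_dist(x, cal, ref, k_density))
  dens <- count_within(x, x[ref, , drop = FALSE], L)
  scale_up <- n / length(ref)
  dens <- dens * scale_up
  if (is.null(target_density)) {
    target_density <- stats::quantile(dens, 0.03, names = FALSE)
  }
  if (is.na(target_density) || target_density <= 0) {
    stop("target_density must be positive", call. = FALSE)
  }
  keep_prob <- pmin(1, target_density / pmax(dens, 1e-12))
  with_stream(seed, "density_downsample",
              which(stats::runif(n) < keep_prob))
}

# Distance from each row in `cal` (indices into x) to its k-th nearest
# neighbour among `ref` (indices into x).
knn_kth_dist <- function(x, cal, ref, k) {
  xr <- x[ref, , drop = FALSE]
  xc <- x[cal, , drop = FALSE]
  sqr <- rowSums(xr^2); sqc <- rowSums(xc^2)
  negD <- tcrossprod(xc, xr) * 2
  negD <- sweep(negD, 2L, sqr, "-")
  rows <- seq_len(nrow(xc))
  kth <- numeric(nrow(xc))
  ## the calibration points are members of the reference, so the closest
  ## match is the point itself; take the (k+1)-th smallest
  for (j in seq_len(k + 1L)) {
    jm <- max.col(negD, ties.method = "first")
    sel <- cbind(rows, jm)
    kth <- sqc - negD[sel]
    negD[sel] <- -Inf
  }
  sqrt(pmax(kth, 0))
}

# Number of reference points within radius L of each row of x (excluding
# exact self-matches).
count_within <- function(x, xr, L) {
  sqr <- rowSums(xr^2)
  n <- nrow(x)
  out <- integer(n)
  L2 <- L^2
  block <- max(256L, min(4096L, ceiling(4e7 / nrow(xr))))
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(n, start + block - 1L)
    d2 <- tcrossprod(x[idx, , drop = FALSE], xr) * -2
    d2 <- sweep(d2, 2L, sqr, "+") + rowSums(x[idx, , drop = FALSE]^2)
    out[idx] <- rowSums(d2 <= L2) - as.integer(rowSums(d2 <= 1e-16) > 0)
  }
  pmax(out, 1L)
}

#' Build a SPADE-style clustering tree
#'
#' Downsampled points are clustered into `k_nodes` nodes (k-means by default;
#' agglomerative optional), a minimum spanning tree is built over the node
#' centroids, and every event — including those removed by downsampling — is
#' assigned to its nearest node ("upsampling"). Node medians are recomputed
#' over all assigned events.
#'
#' @param events Event data.frame (carried through to per-node sample
#'   counts via `sample_id`).
#' @param markers Character vector of the columns used as coordinates.
#' @param k_nodes Number of tree nodes.
#' @param keep Optional integer index of downsampled rows (from
#'   [density_downsample()]); default uses all rows.
#' @param profile_markers Markers over which node medians are reported;
#'   defaults to `markers` but may include panel markers not used for the
#'   tree coordinates (e.g. CD11c for the DN2/3 bubble).
#' @param method `"kmeans"` or `"hclust"` for the node clustering.
#' @param seed Integer seed.
#' @return Object of class `spade_tree`: node table (median profiles, event
#'   counts per sample), MST `edges`, and per-event `assignment`.
#' @export
build_spade_tree <- function(events, markers, k_nodes = 100L, keep = NULL,
                             profile_markers = markers,
                             method = c("kmeans", "hclust"), seed = 1L) {
  method <- match.arg(method)
  if (k_nodes < 2L) stop("k_nodes must be at least 2", call. = FALSE)
  x <- as.matrix(events[, markers, drop = FALSE])
  if (is.null(keep)) keep <- seq_len(nrow(x))
  xd <- x[keep, , drop = FALSE]
  if (nrow(xd) < k_nodes) stop("fewer retained points than k_nodes",
                               call. = FALSE)
  centers <- with_stream(seed, "spade_cluster", {
    if (method == "kmeans") {
      stats::kmeans(xd, centers = k_nodes, iter.max = 50L,
                    nstart = 3L)$centers
    } else {
      hc <- stats::hclust(stats::dist(xd), method = "average")
      cl <- stats::cutree(hc, k = k_nodes)
      do.call(rbind, lapply(split(seq_len(nrow(xd)), cl), function(i) {
        colMeans(xd[i, , drop = FALSE])
      }))
    }
  })
  ## upsample: nearest (and second-nearest) node for every event
  nn <- nearest_row(x, centers, n_best = 2L)
  assignment <- nn[, 1L]
  ## medians over assigned events, reported over the full profile panel
  profile_markers <- unique(profile_markers)
  xp <- as.matrix(events[, profile_markers, drop = FALSE])
  med <- matrix(NA_real_, k_nodes, length(profile_markers),
                dimnames = list(NULL, profile_markers))
  for (k in seq_len(k_nodes)) {
    idx <- which(assignment == k)
    if (length(idx)) {
      med[k, ] <- apply(xp[idx, , drop = FALSE], 2L, stats::median)
    } else {
      med[k, ] <- NA_real_
      med[k, markers] <- centers[k, ]
    }
  }
  counts <- table(factor(assignment, levels = seq_len(k_nodes)),
                  events$sample_id)
  ## MST over node medians
  dm <- as.matrix(stats::dist(med))
  g <- igraph::graph_from_adjacency_matrix(dm, mode = "undirected",
                                           weighted = TRUE)
  mst <- igraph::mst(g)
  el <- igraph::as_edgelist(mst, names = FALSE)
  nodes <- data.frame(node = seq_len(k_nodes), n_events = as.integer(
    rowSums(counts)))
  structure(list(nodes = nodes, medians = med,
                 sample_counts = unclass(counts),
                 edges = data.frame(from = el[, 1], to = el[, 2]),
                 assignment = assignment, assignment2 = nn[, 2L],
                 markers = markers, sample_id = events$sample_id,
                 bubbles = NULL),
            class = "spade_tree")
}

#' @export
print.spade_tree <- function(x, ...) {
  cat("spade_tree:", nrow(x$nodes), "nodes,", nrow(x$edges), "MST edges,",
      length(x$assignment), "events\n")
  if (!is.null(x$bubbles)) {
    cat("  bubbles:", paste(names(table(x$bubbles)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.spade_tree <- function(x, ...) {
  g <- igraph::graph_from_data_frame(x$edges, directed = FALSE,
                                     vertices = x$nodes$node)
  sz <- 1 + 4 * sqrt(x$nodes$n_events / max(1, max(x$nodes$n_events)))
  igraph::plot.igraph(g, vertex.size = sz * 3, vertex.label = NA, ...)
  invisible(x)
}

# Index of the nearest row(s) of `centers` for every row of `x`.
nearest_row <- function(x, centers, n_best = 1L) {
  x <- as.matrix(x); centers <- as.matrix(centers)
  cs <- rowSums(centers^2)
  n <- nrow(x)
  out <- matrix(0L, n, n_best)
  block <- max(256L, min(4096L, ceiling(5e7 / nrow(centers))))
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(n, start + block - 1L)
    negd2 <- 2 * tcrossprod(x[idx, , drop = FALSE], centers)
    negd2 <- sweep(negd2, 2L, cs, "-")
    rows <- seq_along(idx)
    for (j in seq_len(n_best)) {
      jm <- max.col(negd2, ties.method = "first")
      out[idx, j] <- jm
      if (j < n_best) negd2[cbind(rows, jm)] <- -Inf
    }
  }
  if (n_best == 1L) drop(out) else out
}

# --- declarative subset rules ----------------------------------------------

#' Declarative marker-positivity rules for B-cell subsets
#'
#' A rule set is an ordered list of rules, each requiring some markers to be
#' above ("high") and others below ("low") their per-marker thresholds;
#' graded conditions (e.g. CD21-low, CD11c-high for DN2) are expressed the
#' same way. A profile is labelled by the first matching rule; no match gives
#' `"unclassified"` — the mandated fallback sink.
#'
#' @param rules Named list; each element a list with character vectors
#'   `high` and `low`.
#' @return Object of class `subset_rules`.
#' @export
subset_rules <- function(rules) {
  for (r in rules) {
    if (!all(names(r) %in% c("high", "low"))) {
      stop("each rule may only have 'high' and 'low' marker sets",
           call. = FALSE)
    }
  }
  sig <- vapply(rules, function(r) {
    paste(paste(sort(r$high), collapse = ","), "|",
          paste(sort(r$low), collapse = ","))
  }, character(1))
  if (anyDuplicated(sig)) stop("duplicate rules in rule set", call. = FALSE)
  structure(rules, class = "subset_rules")
}

#' Default B-cell subset rules
#'
#' Encodes the canonical subset phenotypes: transitional (CD10+CD24++CD38++),
#' GC (CD38++CD10++), PB/PC (CD38++CD138+), MZB (CD27+CD45RB+IgM+IgD+), MZP
#' (CD27-CD45RB+IgM+IgD+), memory (CD27+CD45RB+IgD-), naive (CD27-IgM+IgD+),
#' and the double-negative split where DN2/3 differ from DN1 by lower CD21
#' and high CD11c. The `"imc"` context adds the intraepithelial DN rule
#' (DN + E-cadherin-high) and names GC light/dark zones by Ki67.
#'
#' @param context `"suspension"` (Fig-style CyTOF panel) or `"imc"`.
#' @return A [subset_rules()] object (ordered; evaluated first-match).
#' @export
default_b_subset_rules <- function(context = c("suspension", "imc")) {
  context <- match.arg(context)
  if (context == "suspension") {
    subset_rules(list(
      PBPC = list(high = c("CD38", "CD138")),
      TS   = list(high = c("CD10", "CD24", "CD38"), low = "CD138"),
      GC   = list(high = c("CD38", "CD10"), low = "CD138"),
      DN23 = list(high = "CD11c", low = c("CD27", "IgD", "CD21")),
      DN1  = list(high = "CD21", low = c("CD27", "IgD", "CD11c")),
      MZB  = list(high = c("CD27", "CD45RB", "IgM", "IgD")),
      MZP  = list(high = c("CD45RB", "IgM", "IgD"), low = "CD27"),
      Mem  = list(high = c("CD27", "CD45RB"), low = "IgD"),
      Naive = list(high = c("IgM", "IgD"), low = c("CD27", "CD45RB"))))
  } else {
    subset_rules(list(
      `PB/PC` = list(high = c("CD38", "CD138")),
      `GC DZ` = list(high = c("CD38", "CD10", "Ki67")),
      `GC LZ` = list(high = c("CD38", "CD10"), low = "Ki67"),
      IEDN = list(high = "Ecad", low = c("CD27", "IgD")),
      DN2  = list(high = "CD11c", low = c("CD27", "IgD", "CD21")),
      DN1  = list(high = "CD21", low = c("CD27", "IgD", "CD11c", "Ecad")),
      MZB  = list(high = c("CD27", "CD45RB", "IgM", "IgD")),
      MZP  = list(high = c("CD45RB", "IgM", "IgD"), low = "CD27"),
      Mem  = list(high = c("CD27", "CD45RB"), low = "IgD"),
      Naive = list(high = c("IgM", "IgD"), low = c("CD27", "CD45RB"))))
  }
}

#' Per-marker positivity thresholds from two-component mixture fits
#'
#' For each marker, a two-component Gaussian mixture is fitted to the pooled
#' arcsinh-transformed intensities and the threshold is the midpoint of the
#' two component means. Degenerate (effectively unimodal) markers fall back
#' to a quantile rule with a warning.
#'
#' @param x Numeric matrix (events/cells x markers), transformed scale.
#' @param markers Columns to threshold (default: all).
#' @param fallback_quantile Quantile used when the mixture is degenerate.
#' @return Named numeric vector of thresholds.
#' @export
marker_thresholds <- function(x, markers = colnames(x),
                              fallback_quantile = 0.5) {
  x <- as.matrix(x)
  out <- stats::setNames(numeric(length(markers)), markers)
  for (m in markers) {
    out[m] <- mixture_threshold(x[, m], fallback_quantile)
  }
  out
}

mixture_threshold <- function(v, fallback_quantile = 0.5) {
  v <- v[is.finite(v)]
  if (stats::sd(v) < 1e-8) return(stats::quantile(v, fallback_quantile,
                                                  names = FALSE))
  sub <- if (length(v) > 5000L) v[seq(1L, length(v),
                                      length.out = 5000L)] else v
  fit <- em2_fit(sub)
  sep <- abs(diff(fit$mu)) / sqrt(mean(fit$sigma2))
  if (!is.finite(sep) || sep < 1) {
    warning("degenerate marker distribution; falling back to quantile rule",
            call. = FALSE)
    return(stats::quantile(v, fallback_quantile, names = FALSE))
  }
  mean(fit$mu)
}

# Two-component Gaussian mixture by EM (vectorised, quantile-initialised).
em2_fit <- function(v, max_iter = 50L, tol = 1e-6) {
  mu <- stats::quantile(v, c(0.1, 0.9), names = FALSE)
  if (diff(mu) < 1e-8) mu <- mu + c(-1e-3, 1e-3)
  s2 <- rep(stats::var(v) / 4 + 1e-8, 2L)
  w <- c(0.5, 0.5)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(v, mu[1], sqrt(s2[1]))
    d2 <- w[2] * stats::dnorm(v, mu[2], sqrt(s2[2]))
    tot <- d1 + d2 + 1e-300
    r <- d2 / tot
    w <- c(mean(1 - r), mean(r))
    if (any(w < 1e-4)) break
    mu <- c(sum((1 - r) * v) / sum(1 - r), sum(r * v) / sum(r))
    s2 <- c(sum((1 - r) * (v - mu[1])^2) / sum(1 - r),
            sum(r * (v - mu[2])^2) / sum(r))
    s2 <- pmax(s2, 1e-8)
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol * abs(ll_old + 1)) break
    ll_old <- ll
  }
  list(mu = sort(mu), sigma2 = s2[order(mu)], weight = w[order(mu)])
}

# Label a matrix of profiles (rows) by the first matching rule.
classify_profiles <- function(profiles, rules, thresholds) {
  stopifnot(inherits(rules, "subset_rules"))
  need <- unique(unlist(lapply(rules, unlist)))
  miss <- setdiff(need, colnames(profiles))
  if (length(miss)) stop("rule references marker(s) absent from panel: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  hi <- sweep(profiles, 2L, thresholds[colnames(profiles)], ">=")
  lab <- rep("unclassified", nrow(profiles))
  for (nm in names(rules)) {
    r <- rules[[nm]]
    ok <- rep(TRUE, nrow(profiles))
    for (m in r$high) ok <- ok & hi[, m]
    for (m in r$low) ok <- ok & !hi[, m]
    ok <- ok & lab == "unclassified"
    lab[ok] <- nm
  }
  lab
}

#' Label SPADE tree nodes with subset bubbles
#'
#' Automated stand-in for manual bubble drawing: each node is labelled by the
#' first rule matching its median marker profile against per-marker
#' thresholds (derived from pooled mixture fits when not supplied).
#'
#' @param tree A [build_spade_tree()] result.
#' @param rules A [subset_rules()] object.
#' @param thresholds Named threshold vector; `NULL` fits them from the node
#'   medians' parent events.
#' @param events Event table; used to fit thresholds when `thresholds` is
#'   `NULL`, and to refine bubble-boundary events (see below) when supplied.
#' @details Events whose nearest and second-nearest nodes carry different
#'   bubbles sit on a bubble boundary; when the event table is available,
#'   such events are assigned to whichever of the two nodes is nearer on the
#'   full profile panel (which includes key markers such as CD11c that are
#'   not part of the reduction panel), the same information an analyst uses
#'   when adjudicating nodes between bubbles.
#' @return The tree with `bubbles` (per node) and `event_bubbles` filled in.
#' @export
assign_bubbles <- function(tree, rules, thresholds = NULL, events = NULL) {
  stopifnot(inherits(tree, "spade_tree"))
  if (is.null(thresholds)) {
    if (is.null(events)) stop("supply thresholds or events", call. = FALSE)
    need <- intersect(unique(unlist(lapply(rules, unlist))),
                      colnames(tree$medians))
    thresholds <- marker_thresholds(as.matrix(events[, need, drop = FALSE]),
                                    markers = need)
  }
  tree$bubbles <- classify_profiles(tree$medians, rules, thresholds)
  assignment <- tree$assignment
  if (!is.null(events) && !is.null(tree$assignment2)) {
    b1 <- tree$bubbles[assignment]
    b2 <- tree$bubbles[tree$assignment2]
    amb <- which(b1 != b2)
    if (length(amb)) {
      xp <- as.matrix(events[amb, colnames(tree$medians), drop = FALSE])
      d1 <- rowSums((xp - tree$medians[assignment[amb], , drop = FALSE])^2)
      d2 <- rowSums((xp - tree$medians[tree$assignment2[amb], ,
                                       drop = FALSE])^2)
      flip <- d2 < d1
      assignment[amb[flip]] <- tree$assignment2[amb[flip]]
      ## keep per-node counts consistent with the refined assignment
      counts <- table(factor(assignment, levels = seq_len(nrow(tree$nodes))),
                      tree$sample_id)
      tree$sample_counts <- unclass(counts)
      tree$nodes$n_events <- as.integer(rowSums(counts))
      tree$assignment <- assignment
    }
  }
  tree$event_bubbles <- tree$bubbles[assignment]
  tree$thresholds <- thresholds
  tree
}

#' Per-sample subset proportions with paired tissue/blood tests
#'
#' Computes subset fractions per sample (summing to 1 over labelled subsets
#' plus unclassified) and, for each subset, a paired two-tailed t test of
#' GALT versus PBMC fractions across donors. Donors missing a compartment are
#' excluded with a warning.
#'
#' @param events Event table with `donor`, `compartment`, `sample_id`.
#' @param labels Character vector of subset labels, one per event.
#' @return Object of class `proportion_report`: `proportions` (long
#'   data.frame) and `tests` (per-subset paired t results).
#' @export
subset_proportion_report <- function(events, labels) {
  stopifnot(nrow(events) == length(labels))
  tab <- table(events$sample_id, labels)
  prop <- sweep(tab, 1L, rowSums(tab), "/")
  meta <- unique(events[, c("sample_id", "donor", "compartment")])
  meta <- meta[match(rownames(prop), meta$sample_id), ]
  have <- table(meta$donor, meta$compartment)
  complete <- rownames(have)[rowSums(have > 0) == 2L]
  if (length(complete) < nrow(have)) {
    warning("donor(s) missing a compartment excluded: ",
            paste(setdiff(rownames(have), complete), collapse = ", "),
            call. = FALSE)
  }
  long <- data.frame(
    sample_id = rep(rownames(prop), ncol(prop)),
    donor = rep(meta$donor, ncol(prop)),
    compartment = rep(meta$compartment, ncol(prop)),
    subset = rep(colnames(prop), each = nrow(prop)),
    fraction = as.vector(prop), stringsAsFactors = FALSE)
  tests <- list()
  for (s in colnames(prop)) {
    g <- p <- numeric(0)
    for (d in complete) {
      gi <- meta$sample_id[meta$donor == d & meta$compartment == "GALT"][1]
      pi <- meta$sample_id[meta$donor == d & meta$compartment == "PBMC"][1]
      g <- c(g, prop[gi, s]); p <- c(p, prop[pi, s])
    }
    if (length(g) >= 2L) tests[[s]] <- t_test2(g, p, paired = TRUE)
  }
  structure(list(proportions = long, tests = tests,
                 report = test_report(tests, adjust = NULL)),
            class = "proportion_report")
}

#' @export
print.proportion_report <- function(x, ...) {
  cat("proportion_report over",
      length(unique(x$proportions$sample_id)), "samples\n")
  print(x$report, digits = 4)
  invisible(x)
}

#' Run the full suspension-cytometry stage
#'
#' Equal-event subsampling, density-dependent downsampling, SPADE-style tree,
#' rule-based bubbles, and the paired GALT-versus-PBMC proportion report.
#'
#' @param pair Output of [simulate_suspension_pair()] or a compatible list
#'   with an `events` data.frame.
#' @param markers Markers used for tree building (default: the dimension-
#'   reduction panel).
#' @param n_per_sample,k_nodes,k_density Stage parameters.
#' @param density_ref_size Reference-sample size for the density estimate
#'   (see [density_downsample()]).
#' @param seed Integer seed.
#' @return List with `tree`, `report`, and the subsampled labelled `events`.
#' @export
run_cytof_stage <- function(pair,
                            markers = c("CD45RB", "IgD", "CD20", "IgA",
                                        "CD138", "CD21", "CD38", "CD10",
                                        "CD27", "CD24", "IgG", "IgM"),
                            n_per_sample = 9214, k_nodes = 100L,
                            k_density = 15L, density_ref_size = 2000L,
                            seed = 1L) {
  ev <- subsample_equal(pair$events, n_per_sample, seed = seed)
  x <- as.matrix(ev[, markers])
  keep <- density_downsample(x, k_density = k_density, seed = seed,
                             ref_size = density_ref_size)
  rules <- default_b_subset_rules("suspension")
  need <- intersect(unique(unlist(lapply(rules, unlist))), colnames(ev))
  tree <- build_spade_tree(ev, markers, k_nodes = k_nodes, keep = keep,
                           profile_markers = union(markers, need),
                           seed = seed)
  thr <- marker_thresholds(as.matrix(ev[, need, drop = FALSE]),
                           markers = need)
  tree <- assign_bubbles(tree, rules, thresholds = thr, events = ev)
  report <- subset_proportion_report(ev, tree$event_bubbles)
  list(tree = tree, report = report, events = ev)
}
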
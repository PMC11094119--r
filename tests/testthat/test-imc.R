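tiny_cells <- function(areas, dna = 50) {
  ch <- c("CD20", "CD3", "DNA1", "DNA2")
  n <- length(areas)
  raw <- matrix(dna, n, length(ch), dimnames = list(NULL, ch))
  meta <- data.frame(cell_id = paste0("c", seq_len(n)), roi = "R1",
                     x = seq_len(n), y = seq_len(n), area_px = areas)
  cell_table(meta, raw)
}

test_that("QC removes small and DNA-poor cells with a reasoned log", {
  cells <- tiny_cells(c(5, 11, 20))
  out <- qc_filter(cells, min_area_px = 11, dna_channels = NULL)
  expect_equal(nrow(out$cells$meta), 2)
  expect_equal(out$log$n_small, 1)

  ## identity when both rules are off
  out0 <- qc_filter(cells, min_area_px = 0, dna_channels = NULL)
  expect_equal(nrow(out0$cells$meta), 3)

  ## a large cell without DNA is removed for the DNA reason
  cells2 <- tiny_cells(c(50, 40, 45, 60, 30))
  cells2$layers$raw[1, c("DNA1", "DNA2")] <- 0
  out2 <- qc_filter(cells2, min_area_px = 11)
  expect_equal(out2$log$n_low_dna, 1)
  expect_false("c1" %in% out2$cells$meta$cell_id)

  cells3 <- tiny_cells(c(1, 2))
  expect_warning(qc_filter(cells3, min_area_px = 11, dna_channels = NULL),
                 "every cell")
})

test_that("spillover compensation inverts the forward model and never goes
           negative", {
  S <- matrix(c(1, 0, 0.1, 1), 2, 2)
  expect_equal(compensate_spillover(c(10, 1), S), c(10, 0))
  expect_equal(compensate_spillover(matrix(c(3, 7, 0.3, 0.7), 2), diag(2)),
               matrix(c(3, 7, 0.3, 0.7), 2))
  ## negative-going noise in a pure-spillover channel clamps at zero
  comp <- compensate_spillover(c(10, 0.5), S)   # true second channel ~ -0.5
  expect_gte(comp[2], 0)

  set.seed(12)
  k <- 6
  S6 <- diag(k); S6[cbind(1:(k - 1), 2:k)] <- runif(k - 1, 0, 0.1)
  X <- matrix(rexp(40 * k, 1 / 30), 40, k)
  expect_equal(compensate_spillover(apply_spillover(X, S6), S6), X,
               tolerance = 1e-8)

  bad <- matrix(1, 2, 2)
  expect_error(compensate_spillover(c(1, 2), bad), "ill-conditioned")
})

test_that("gating is mutually exclusive, order-independent and leaves
           double-positives unassigned", {
  ch <- c("CD20", "CD3", "CD11c", "CD11b", "CD68", "CD31", "Ecad")
  n <- 6
  raw <- matrix(1, n, length(ch), dimnames = list(NULL, ch))
  raw[1, "CD20"] <- 200                      # B
  raw[2, "CD3"] <- 200                       # T
  raw[3, c("CD20", "CD3")] <- 200            # B-T neighbour
  raw[4, "CD68"] <- 200                      # MacDC via OR semantics
  raw[5, c("CD20", "Ecad")] <- 200           # two gates -> unassigned
  ## row 6 stays background
  ## anchor rows so per-image mixture thresholds are well defined
  anchor <- matrix(1, 40, length(ch), dimnames = list(NULL, ch))
  anchor[1:10, ] <- 150
  raw <- rbind(raw, anchor)
  meta <- data.frame(cell_id = paste0("c", 1:nrow(raw)), roi = "R1",
                     x = 1, y = 1, area_px = 20)
  cells <- cell_table(meta, raw)
  out <- gate_cells(cells)
  lab <- out$meta$lineage[1:6]
  expect_equal(lab, c("B", "T", "unassigned", "MacDC", "unassigned",
                      "unassigned"))

  ## permuting the gate order changes nothing
  sch <- default_gating_scheme()
  out2 <- gate_cells(cells, scheme = structure(rev(sch),
                                               class = "gating_scheme"))
  expect_equal(out2$meta$lineage, out$meta$lineage)

  bad <- structure(list(X = list(any_of = "missing")),
                   class = "gating_scheme")
  expect_error(gate_cells(cells, bad), "missing")
})

test_that("label propagation reports held-out accuracy and never rewrites a
           gated label", {
  centres <- matrix(c(5, 0, 0, 0, 5, 0, 0, 0, 5), 3, 3, byrow = TRUE)
  colnames(centres) <- c("CD20", "CD3", "Ecad")
  blobs <- marker_blobs(150, centres, sd = 0.4, seed = 6)
  meta <- data.frame(cell_id = paste0("c", 1:450), roi = "R1", x = 1, y = 1,
                     area_px = 20)
  cells <- cell_table(meta, inv_arcsinh(blobs$x, 5))
  cells$layers$transformed <- blobs$x
  lineage <- c("B", "T", "Epithelial")[blobs$label]
  unlab <- seq(1, 450, by = 5)
  lineage[unlab] <- "unassigned"
  cells$meta$lineage <- lineage

  out <- propagate_labels(cells, split = 0.7, seed = 3)
  expect_gte(out$report$accuracy, 0.99)
  expect_equal(out$report$split, 0.7)
  expect_equal(out$report$n_propagated, length(unlab))
  gated <- lineage != "unassigned"
  expect_equal(out$cells$meta$lineage_full[gated], lineage[gated])
  ## recovered labels match the generating blobs
  expect_gte(mean(out$cells$meta$lineage_full[unlab] ==
                    c("B", "T", "Epithelial")[blobs$label[unlab]]), 0.95)
})

test_that("batch integration removes constant offsets, respects identical
           batches and keeps real structure apart", {
  set.seed(3)
  mu <- matrix(rnorm(18, sd = 4), 3, 6)
  grp <- sample(1:3, 600, TRUE)
  x <- matrix(rnorm(600 * 6), 600, 6) + mu[grp, ]
  b <- rep(c("a", "b"), 300)
  x[b == "b", ] <- x[b == "b", ] + 2
  ib <- integrate_batches(x, b, npc = 6)
  gap0 <- sqrt(sum((colMeans(ib$pca[b == "a", ]) -
                      colMeans(ib$pca[b == "b", ]))^2))
  gap1 <- sqrt(sum((colMeans(ib$embedding[b == "a", ]) -
                      colMeans(ib$embedding[b == "b", ]))^2))
  expect_lt(gap1, 0.1 * gap0)
  km <- stats::kmeans(ib$embedding, 3, nstart = 10)
  expect_gte(adjusted_rand_index(km$cluster, grp), 0.95)

  x2 <- matrix(rnorm(400 * 6), 400, 6)
  x2[201:400, ] <- x2[1:200, ]
  ib2 <- integrate_batches(x2, rep(c("a", "b"), each = 200), npc = 4)
  expect_lt(max(abs(ib2$embedding - ib2$pca)), 1e-6)

  expect_message(one <- integrate_batches(x2, rep("a", 400), npc = 4),
                 "single batch")
  expect_equal(dim(one$embedding), c(400L, 4L))
})

test_that("shared subsets mix while batch-exclusive subsets stay separate", {
  set.seed(5)
  mu <- matrix(rnorm(18, sd = 4), 3, 6)
  grp <- c(sample(1:3, 300, TRUE), sample(1:2, 300, TRUE))
  b <- rep(c("a", "b"), each = 300)
  x <- matrix(rnorm(600 * 6), 600, 6) + mu[grp, ]
  x[b == "b", ] <- x[b == "b", ] + 1
  ib <- integrate_batches(x, b, npc = 6)
  d <- as.matrix(stats::dist(ib$embedding))
  sil <- vapply(seq_len(600), function(i) {
    within <- mean(d[i, grp == grp[i]][-1])
    between <- min(tapply(d[i, ], grp, mean)[as.character(
      setdiff(unique(grp), grp[i]))])
    (between - within) / max(within, between)
  }, numeric(1))
  expect_gt(mean(sil), 0.4)
})

test_that("corrected B-cell clusters are named by their median phenotype", {
  rules <- default_b_subset_rules("imc")
  markers <- unique(unlist(lapply(rules, unlist)))
  thr <- stats::setNames(rep(1.5, length(markers)), markers)
  med <- matrix(0, 3, length(markers), dimnames = list(NULL, markers))
  med[1, "Ecad"] <- 3                       # CD27-/IgD- + E-cadherin high
  med[2, "CD11c"] <- 3                      # CD27-/IgD-/CD21lo/CD11c high
  lab <- domemap:::classify_profiles(med, rules, thr)
  expect_equal(lab[1], "IEDN")
  expect_equal(lab[2], "DN2")

  ## k = 1 collapses everything onto one label
  emb <- matrix(rnorm(60), 30, 2)
  mk <- matrix(0, 30, length(markers), dimnames = list(NULL, markers))
  mk[, "Ecad"] <- 3
  one <- cluster_and_classify_b_cells(emb, mk, rules, k = 1,
                                      thresholds = thr, seed = 1)
  expect_equal(length(unique(one$subset)), 1)
})
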
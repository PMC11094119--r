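test_that("preprocessing normalises, ranks variable genes and orders PCs", {
  set.seed(1)
  counts <- matrix(rpois(100 * 60, 5), 100, 60,
                   dimnames = list(paste0("g", 1:100), paste0("s", 1:60)))
  counts["g1", ] <- 7                       # constant gene
  counts[, 1] <- 0                          # empty spot
  expect_warning(pp <- preprocess_spots(counts, n_hvg = 50, n_pcs = 10),
                 "zero total")
  expect_equal(ncol(pp$norm), 59)
  expect_false("g1" %in% pp$hvg)
  expect_true(all(diff(pp$sdev) <= 1e-12))
  expect_equal(dim(pp$pcs), c(59L, 10L))
})

test_that("spot graphs realise lattice neighbourhoods symmetrically", {
  hexs <- expand.grid(col = 0:9, row = 0:9)
  g <- build_spot_graph(hexs, "hex")
  interior <- which(hexs$col %in% 3:6 & hexs$row %in% 3:6)
  expect_true(all(g$degree[interior] == 6))
  expect_true(Matrix::isSymmetric(g$adj))
  expect_true(all(Matrix::diag(g$adj) == 0))

  sq <- build_spot_graph(hexs, "square")
  corner <- which(hexs$col == 0 & hexs$row == 0)
  expect_equal(unname(sq$degree[corner]), 2)

  expect_error(build_spot_graph(rbind(hexs, hexs[1, ])), "duplicate")
})

test_that("the Potts sampler reduces to a non-spatial mixture at gamma 0 and
           smoothing never hurts neighbour agreement", {
  lb <- lattice_blobs(24, 24, bands = 3, sep = 5, d = 4, seed = 2)
  g <- build_spot_graph(lb$spots)
  f0 <- potts_cluster(lb$pcs, g, q = 3, gamma = 0, iterations = 150,
                      burn_in = 50, seed = 2)
  mc <- Mclust(lb$pcs, G = 3, modelNames = "EEE", verbose = FALSE)
  expect_gte(adjusted_rand_index(f0$labels, mc$classification), 0.95)

  lb2 <- lattice_blobs(20, 20, bands = 3, sep = 2, d = 4, seed = 3)
  g2 <- build_spot_graph(lb2$spots)
  agree <- vapply(c(0, 1, 2, 4), function(gam) {
    neighbour_agreement(potts_cluster(lb2$pcs, g2, q = 3, gamma = gam,
                                      iterations = 120, burn_in = 40,
                                      seed = 4)$labels, g2)
  }, numeric(1))
  expect_true(all(diff(agree) > -0.02))

  one <- potts_cluster(lb$pcs, g, q = 1)
  expect_true(all(one$labels == 1))
  expect_error(potts_cluster(lb$pcs, g, q = 10000), "exceeds")
  expect_error(potts_cluster(lb$pcs, g, q = 3, gamma = -1), "non-negative")
})

test_that("q tuning finds the programme count and declines to suggest
           structure in noise", {
  hits <- vapply(11:14, function(s) {
    pl <- simulate_program_lattice(seed = s)
    pp <- preprocess_spots(pl$counts, n_hvg = 2000, n_pcs = 15)
    g <- build_spot_graph(pl$spots)
    tune_q(pp$pcs, g, q_range = 2:12, iterations = 80, burn_in = 30,
           seed = s)$suggested_q
  }, integer(1))
  expect_gte(sum(hits == 7L), 3)

  noise <- vapply(2:5, function(s) {
    pl <- simulate_program_lattice(seed = s, n_programs = 1L, n_null = 100)
    pp <- preprocess_spots(pl$counts, n_hvg = 2000, n_pcs = 10)
    g <- build_spot_graph(pl$spots)
    tune_q(pp$pcs, g, q_range = 2:8, iterations = 50, burn_in = 20,
           seed = s)$suggested_q
  }, integer(1))
  expect_gte(sum(noise <= 2L), 3)

  expect_error(tune_q(matrix(rnorm(20), 10), NULL, q_range = c(2, 3)),
               "at least 3")
})

test_that("the lymphoid cluster is selected by marker score with explicit
           tie handling", {
  set.seed(6)
  norm <- matrix(rexp(5 * 90), 5, 90,
                 dimnames = list(c("MS4A1", "IGHD", "IGHM", "g4", "g5"),
                                 NULL))
  labels <- rep(1:3, each = 30)
  norm[1:3, labels == 2] <- norm[1:3, labels == 2] + 5
  sel <- select_lymphoid_cluster(labels, norm)
  expect_equal(sel$selected, "2")
  expect_false(sel$tie)

  flat <- matrix(1, 3, 60, dimnames = list(c("MS4A1", "IGHD", "IGHM"), NULL))
  tie <- select_lymphoid_cluster(rep(1:2, each = 30), flat)
  expect_true(tie$tie)
  expect_true(is.na(tie$selected))

  expect_error(select_lymphoid_cluster(labels, norm[4:5, , drop = FALSE]),
               "absent")
})

test_that("merged-sample subclustering aligns with tissue regions, not with
           the sample id", {
  cfg <- sim_config(seed = 22)
  sa <- simulate_spot_sample(cfg, "STA")
  sb <- simulate_spot_sample(cfg, "STB")
  ppa <- preprocess_spots(sa$counts)
  ppb <- preprocess_spots(sb$counts)
  la <- sa$ground_truth$zone %in% c("SED", "FAE", "mantle", "GC", "T_zone")
  lb <- sb$ground_truth$zone %in% c("SED", "FAE", "mantle", "GC", "T_zone")
  sc <- subcluster_lymphoid(list(STA = ppa$norm[, la], STB = ppb$norm[, lb]),
                            n_subclusters = 5, seed = 22)
  truez <- c(sa$ground_truth$zone[la], sb$ground_truth$zone[lb])
  truez[truez == "FAE"] <- "SED"
  expect_gte(adjusted_rand_index(sc$region, truez), 0.6)
  expect_lte(abs(adjusted_rand_index(sc$labels, sc$sample)), 0.1)
  expect_setequal(unique(sc$names[c("1", "2", "3", "4", "5")]) |> sort(),
                  sort(unique(sc$names)))

  expect_message(single <- subcluster_lymphoid(list(STA = ppa$norm[, la]),
                                               n_subclusters = 4, seed = 1),
                 "single sample")
  expect_equal(length(single$labels), sum(la))
})

test_that("region differential expression applies thresholds as flags and
           negates cleanly under region swap", {
  cfg <- sim_config(seed = 8)
  sa <- simulate_spot_sample(cfg, "STA")
  pp <- preprocess_spots(sa$counts)
  z <- sa$ground_truth$zone
  region <- ifelse(z %in% c("SED", "FAE"), "SED",
                   ifelse(z %in% c("mantle", "GC"), "Follicle", "none"))
  de <- region_de(sa$counts, pp$norm, region)
  expect_setequal(names(de)[1:2], c("gene", "mean_SED"))
  expect_true(all(!is.na(de$p[de$tested])))
  expect_true(all(is.na(de$p[!de$tested])))       # flagged, not dropped
  expect_equal(nrow(de), nrow(sa$counts))
  expect_true(all(de$p_adj >= de$p - 1e-15, na.rm = TRUE))

  de2 <- region_de(sa$counts, pp$norm, region, region_a = "Follicle",
                   region_b = "SED")
  m <- match(de$gene, de2$gene)
  expect_equal(de$logFC, -de2$logFC[m])
  expect_equal(de$p, de2$p[m])

  ## no genes passing the filters yields an empty tested set with a note
  tiny <- matrix(rpois(40 * 30, 5), 40, 30,
                 dimnames = list(paste0("g", 1:40), paste0("s", 1:30)))
  nn <- log1p(sweep(tiny, 2, colSums(tiny), "/") * 1e4)
  de0 <- region_de(tiny, nn, rep(c("SED", "Follicle"), 15), logfc_min = 5)
  expect_false(any(de0$tested))
  expect_match(attr(de0, "diagnostics"), "no genes")
})

test_that("gene correlation matrices are symmetric with Holm-adjusted pairs
           and tolerate missing or constant genes", {
  set.seed(4)
  norm <- matrix(rexp(4 * 80), 4, 80,
                 dimnames = list(c("a", "b", "c", "d"), NULL))
  norm["b", ] <- norm["a", ] + rnorm(80, sd = 0.1)
  cm <- gene_correlation_matrix(norm, c("a", "b", "c", "d", "ghost"))
  expect_equal(cm$missing, "ghost")
  expect_equal(diag(cm$rho), rep(1, 4), ignore_attr = TRUE)
  expect_equal(cm$rho, t(cm$rho))
  expect_equal(cm$p_adj, t(cm$p_adj))
  expect_true(all(cm$p_adj >= cm$p_raw - 1e-15, na.rm = TRUE))
  expect_gt(cm$rho["a", "b"], 0.9)

  ## two genes: a single pair, Holm == raw
  cm2 <- gene_correlation_matrix(norm, c("a", "c"))
  expect_equal(cm2$p_adj["a", "c"], cm2$p_raw["a", "c"])

  norm["d", ] <- 1
  cm3 <- gene_correlation_matrix(norm, c("a", "d"))
  expect_true("d" %in% cm3$degenerate)
})
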
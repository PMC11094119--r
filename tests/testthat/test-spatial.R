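test_that("nearest-epithelial distance matches hand geometry and the
           brute-force oracle exactly", {
  meta <- data.frame(roi = "R1", x = c(0, 3), y = c(0, 4),
                     lineage_full = c("Epithelial", "B"))
  expect_equal(nearest_epithelial_distance(meta), c(0, 5))

  set.seed(10)
  meta <- data.frame(roi = rep(c("R1", "R2"), each = 500),
                     x = runif(1000, 0, 600), y = runif(1000, 0, 600),
                     lineage_full = sample(c("Epithelial", "B", "T"), 1000,
                                           TRUE, prob = c(0.1, 0.5, 0.4)))
  d <- nearest_epithelial_distance(meta)
  for (r in c("R1", "R2")) {
    i <- which(meta$roi == r)
    epi <- i[meta$lineage_full[i] == "Epithelial"]
    full <- as.matrix(stats::dist(meta[, c("x", "y")]))[i, epi, drop = FALSE]
    oracle <- apply(full, 1L, min)
    oracle[meta$lineage_full[i] == "Epithelial"] <- 0
    expect_identical(unname(d[i]), unname(oracle))
  }

  ## adding an epithelial cell can only shrink distances
  meta2 <- rbind(meta, data.frame(roi = "R1", x = 300, y = 300,
                                  lineage_full = "Epithelial"))
  d2 <- nearest_epithelial_distance(meta2)[seq_len(nrow(meta))]
  expect_true(all(d2 <= d + 1e-12))

  noepi <- data.frame(roi = "R3", x = 1:3, y = 1:3, lineage_full = "B")
  expect_warning(dn <- nearest_epithelial_distance(noepi), "no epithelial")
  expect_true(all(is.nan(dn)))
})

test_that("positivity classification separates bimodal channels and
           respects conventions", {
  set.seed(2)
  truth <- rep(c(FALSE, TRUE), each = 600)
  v <- c(rnorm(600, 0.3, 0.4), rnorm(600, 3.3, 0.4))
  flag <- positivity_classify(v, method = "mixture")
  expect_lt(mean(flag != truth), 0.02)

  expect_true(all(!positivity_classify(rep(0, 50), method = "mixture")))
  expect_true(positivity_classify(2, method = "fixed", threshold = 2))
  expect_false(positivity_classify(1.99, method = "fixed", threshold = 2))
  expect_error(positivity_classify(1:3, method = "fixed"), "threshold")
})

test_that("expression contrasts honour the unit of analysis and flag
           degenerate groups", {
  ## balanced noiseless data: identical group means under both units
  vals <- rep(c(1, 3), times = 8)
  grp <- rep(c("a", "b"), times = 8)
  roi <- rep(c("R1", "R2"), each = 8)
  cr <- expression_contrast(vals, grp, roi, unit = "ROI")
  cc <- expression_contrast(vals, grp, roi, unit = "cell")
  expect_equal(c(cr$mean_a, cr$mean_b), c(cc$mean_a, cc$mean_b))

  ## identical groups are flagged degenerate with p = 1
  same <- expression_contrast(rep(2, 16), grp, roi, unit = "ROI")
  expect_true(same$test$degenerate)
  expect_equal(same$test$p_value, 1)

  expect_error(expression_contrast(vals, rep("a", 16), roi), "2 levels")

  ## an ROI missing one group is dropped with a warning
  vals2 <- c(vals, 5, 5)
  grp2 <- c(grp, "a", "a")
  roi2 <- c(roi, "R3", "R3")
  expect_warning(expression_contrast(vals2, grp2, roi2, unit = "ROI"), "R3")
})

test_that("simulated subepithelial myeloid biology reproduces the expected
           contrasts across ROIs", {
  cfg <- sim_config(seed = 6)
  coh <- simulate_imc_cohort(cfg, n_roi = 6)
  gt <- coh$combined$ground_truth
  meta <- coh$combined$cells$meta
  meta$lineage_full <- gt$lineage
  d <- nearest_epithelial_distance(meta)
  mac <- gt$lineage == "MacDC"

  level_mean <- function(ct, lev) {
    if (ct$levels[1] == lev) ct$mean_a else ct$mean_b
  }

  ## transcript-positive myeloid cells sit nearer the epithelium
  ct <- expression_contrast(d[mac],
                            ifelse(gt$dnase1l3_pos[mac], "pos", "neg"),
                            roi = meta$roi[mac])
  expect_lt(ct$test$p_value, 0.05)
  expect_lt(level_mean(ct, "pos"), level_mean(ct, "neg"))

  ## among transcript-positive cells, microbicide expression is higher in
  ## the dome
  tf <- arcsinh_transform(intensity_layer(coh$combined$cells), 5)
  sel <- mac & gt$dnase1l3_pos
  grp <- ifelse(gt$zone[sel] == "SED", "SED", "nonSED")
  for (chan in c("Lysozyme", "NOX2")) {
    ct2 <- expression_contrast(tf[sel, chan], grp, roi = meta$roi[sel])
    expect_lt(ct2$test$p_value, 0.05)
    expect_gt(level_mean(ct2, "SED"), level_mean(ct2, "nonSED"))
  }
})

test_that("object segmentation follows connectivity semantics and size
           filters", {
  m <- matrix(0, 6, 6)
  m[2:3, 2:3] <- 10
  m[4:5, 4:5] <- 10                         # touches the first at one corner
  seg8 <- segment_objects(m, connectivity = 8, threshold = 5,
                          min_diameter_px = 1)
  seg4 <- segment_objects(m, connectivity = 4, threshold = 5,
                          min_diameter_px = 1)
  expect_equal(nrow(seg8$objects), 1)
  expect_equal(nrow(seg4$objects), 2)

  two <- matrix(0, 10, 10)
  two[2:3, 2:3] <- 10; two[7:8, 7:8] <- 10
  expect_equal(nrow(segment_objects(two, threshold = 5,
                                    min_diameter_px = 1)$objects), 2)

  blank <- matrix(0, 8, 8)
  expect_equal(nrow(segment_objects(blank, threshold = 5)$objects), 0)

  ## objects under the minimum diameter are discarded
  small <- matrix(0, 10, 10); small[5, 5] <- 10; small[1:3, 1:3] <- 10
  seg <- segment_objects(small, threshold = 5, min_diameter_px = 3)
  expect_equal(nrow(seg$objects), 1)
  expect_equal(seg$objects$area, 9)
})

test_that("colocalization fractions count signal pixels inside the
           reference mask", {
  sig <- matrix(0, 10, 10); sig[2:3, 2:3] <- 10
  ref <- matrix(FALSE, 10, 10); ref[1:5, 1:5] <- TRUE
  expect_equal(coloc_fraction(sig, reference = ref, threshold = 5), 1)
  expect_equal(coloc_fraction(sig, reference = !ref, threshold = 5), 0)
  expect_warning(f <- coloc_fraction(matrix(0, 5, 5),
                                     reference = matrix(TRUE, 5, 5),
                                     threshold = 5), "undefined")
  expect_true(is.nan(f))
  expect_error(coloc_fraction(sig, reference = matrix(TRUE, 3, 3),
                              threshold = 5), "shape")

  ## generator round trip at a requested overlap
  cfg <- sim_config(seed = 19)
  r <- simulate_coloc_raster(cfg, overlap = 0.3)
  got <- coloc_fraction(r, "A", "B")
  expect_lt(abs(got - r$ground_truth$overlap), 0.02)
})
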
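test_that("suspension pairs are deterministic, calibrated and honour edge
           cases", {
  cfg <- sim_config(seed = 11)
  p1 <- simulate_suspension_pair(cfg, n_donors = 2, n_events = 400)
  p2 <- simulate_suspension_pair(cfg, n_donors = 2, n_events = 400)
  expect_identical(p1, p2)
  expect_equal(nrow(p1$events), 4 * 400)
  expect_equal(nrow(p1$ground_truth), nrow(p1$events))

  empty <- simulate_suspension_pair(cfg, n_donors = 0)
  expect_equal(nrow(empty$events), 0)

  ## binomial concentration of the configured DN2/3 fraction with donor
  ## noise off: SE = sqrt(p(1-p)/n) ~ 0.0015 at n = 50,000
  cfg0 <- sim_config(seed = 5, suspension = list(donor_sd = 0))
  big <- simulate_suspension_pair(cfg0, n_donors = 1, n_events = 50000)
  galt <- big$events$compartment == "GALT"
  frac <- mean(big$ground_truth$subset[galt] == "DN23")
  expect_lt(abs(frac - 0.12), 0.01)

  bad <- sim_config(seed = 1)
  bad$suspension$subsets$galt[1] <- bad$suspension$subsets$galt[1] + 0.5
  expect_error(sim_config(seed = 1,
                          suspension = list(subsets = bad$suspension$subsets)),
               "sum to 1")
})

test_that("spillover forward model multiplies through the matrix", {
  S <- matrix(c(1, 0, 0.1, 1), 2, 2)
  expect_equal(apply_spillover(c(10, 0), S), c(10, 1))
  expect_equal(apply_spillover(c(0, 0), S), c(0, 0))
  expect_equal(apply_spillover(diag(2) * 7, diag(2)), diag(2) * 7)
  expect_error(apply_spillover(c(1, 2, 3), S), "dimension")
  expect_error(apply_spillover(c(1, 2), matrix(c(2, 0, 0, 1), 2)),
               "diagonal")
})

test_that("simulated ROIs are deterministic with faithful geometry and
           intensity forward model", {
  cfg <- sim_config(seed = 21)
  r1 <- simulate_imc_roi(cfg, "ROIX")
  r2 <- simulate_imc_roi(cfg, "ROIX")
  expect_identical(r1$cells$layers$raw, r2$cells$layers$raw)

  gt <- r1$ground_truth
  expect_equal(nrow(gt), nrow(r1$cells$meta))
  expect_false(any(duplicated(gt$cell_id)))

  ## every centroid lies inside a named zone; FAE-typed cells in the FAE strip
  expect_true(all(gt$zone != "other"))
  epi <- gt$type == "Epithelial"
  expect_true(all(gt$zone[epi] == "FAE"))

  ## with identity spillover and no batch shift, observed raw intensities
  ## are exactly the inverse-arcsinh of the true transformed layer
  cfg0 <- sim_config(seed = 21,
                     imc = list(spillover = diag(length(imc_channels())),
                                batch_sd = 0))
  r0 <- simulate_imc_roi(cfg0, "ROI0")
  expect_equal(unname(r0$cells$layers$raw),
               unname(inv_arcsinh(r0$cells$layers$true, cfg0$cofactor)),
               tolerance = 1e-10)

  ## the configured subepithelial niche: DN2 cells sit closer to the
  ## epithelium than naive cells by construction
  meta <- r1$cells$meta
  meta$lineage_full <- gt$lineage
  d <- nearest_epithelial_distance(meta)
  expect_lt(median(d[gt$subset == "DN2"]), median(d[gt$subset == "Naive"]))
})

test_that("spot samples are deterministic with calibrated programmes", {
  cfg <- sim_config(seed = 31)
  s1 <- simulate_spot_sample(cfg, "STA")
  s2 <- simulate_spot_sample(cfg, "STA")
  expect_identical(s1$counts, s2$counts)
  expect_equal(nrow(s1$spots), cfg$spots$nrow * cfg$spots$ncol)
  expect_equal(nrow(s1$ground_truth), ncol(s1$counts))

  z <- s1$ground_truth$zone
  ## DNASE1L3 is configured at fold change 4 in the dome; the realised
  ## SED / follicle mean ratio concentrates around it
  ratio <- mean(s1$counts["DNASE1L3", z == "SED"]) /
    mean(s1$counts["DNASE1L3", z %in% c("mantle", "GC")])
  expect_gt(ratio, 3.2)
  expect_lt(ratio, 4.8)

  ## null genes carry no regional signal
  nulls <- grep("^NULL", rownames(s1$counts), value = TRUE)
  l2r <- vapply(nulls, function(g) {
    log2((mean(s1$counts[g, z %in% c("SED", "FAE")]) + 0.1) /
           (mean(s1$counts[g, z %in% c("mantle", "GC")]) + 0.1))
  }, numeric(1))
  expect_lt(stats::quantile(abs(l2r), 0.9, names = FALSE), 0.3)

  expect_error(
    simulate_spot_sample(
      sim_config(seed = 1, spots = list(programmes = list(SED = c(X = -1)))),
      "STA"),
    "positive")
})

test_that("colocalization rasters hit the requested overlap", {
  cfg <- sim_config(seed = 41)
  for (f in c(0, 0.3, 1)) {
    r <- simulate_coloc_raster(cfg, overlap = f)
    expect_lt(abs(r$ground_truth$overlap - f), 0.02)
  }
  r0 <- simulate_coloc_raster(cfg, overlap = 0)
  expect_equal(sum(r0$masks$A & r0$masks$B), 0)
  r1 <- simulate_coloc_raster(cfg, overlap = 1)
  expect_true(all(r1$masks$B[r1$masks$A]))
  expect_error(simulate_coloc_raster(cfg, overlap = 1.5), "\\[0, 1\\]")
  small <- sim_config(seed = 1, coloc = list(dim = c(40L, 40L)))
  expect_error(simulate_coloc_raster(small, 0.5), "too small")
})

test_that("programme lattices are balanced and deterministic", {
  p1 <- simulate_program_lattice(seed = 3)
  p2 <- simulate_program_lattice(seed = 3)
  expect_identical(p1$counts, p2$counts)
  expect_equal(length(unique(p1$zone)), 7)
  expect_true(max(table(p1$zone)) / min(table(p1$zone)) < 1.5)
})

test_that("RNG streams are independent across output objects", {
  cfg <- sim_config(seed = 77)
  a1 <- simulate_spot_sample(cfg, "STA")
  ## generating an unrelated object in between must not perturb the stream
  invisible(simulate_imc_roi(cfg, "ROI9"))
  a2 <- simulate_spot_sample(cfg, "STA")
  expect_identical(a1$counts, a2$counts)
})
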
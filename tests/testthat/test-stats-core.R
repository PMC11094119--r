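test_that("arcsinh transform matches closed forms and inverts exactly", {
  expect_equal(arcsinh_transform(0, 5), 0)
  expect_equal(arcsinh_transform(5, 5), log(1 + sqrt(2)))
  expect_equal(arcsinh_transform(100, 5), log(20 + sqrt(401)))
  x <- c(0, 0.01, 1, 7, 300, 1e5)
  expect_equal(inv_arcsinh(arcsinh_transform(x, 5), 5), x, tolerance = 1e-10)
  expect_true(all(diff(arcsinh_transform(x, 3)) > 0))
  expect_error(arcsinh_transform(1, 0), "cofactor")
  expect_error(arcsinh_transform(1, -2), "cofactor")
})

test_that("t test handles paired, unpaired and degenerate inputs", {
  a <- c(1.2, 3.4, 2.2, 5.0)
  same <- t_test2(a, a, paired = TRUE)
  expect_true(same$degenerate)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  ## differences 1,2,3: t = 2 / (1/sqrt(3)), df = 2
  r <- t_test2(c(1, 2, 3), c(0, 0, 0), paired = TRUE)
  expect_equal(r$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(r$df, 2)
  expect_equal(r$p_value, 2 * stats::pt(-2 * sqrt(3), df = 2),
               tolerance = 1e-10)
  expect_equal(round(r$p_value, 4), 0.0742)

  ## separation limit: p -> 0 as jitter shrinks
  p_eps <- vapply(c(0.1, 0.01), function(eps) {
    t_test2(c(0, 0, 0, 0) + c(-1, 1, -1, 1) * eps, c(1, 1, 1, 1) +
              c(1, -1, 1, -1) * eps)$p_value
  }, numeric(1))
  expect_true(all(diff(p_eps) < 0))
  expect_lt(p_eps[2], 1e-6)

  ## paired test equals the one-sample test of the differences
  set.seed(1)
  x <- rnorm(8); y <- rnorm(8)
  r1 <- t_test2(x, y, paired = TRUE)
  r2 <- t_test2(x - y, rep(0, 8), paired = TRUE)
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p_value, r2$p_value)

  ## agrees with the base oracle
  ht <- stats::t.test(x, y)
  r3 <- t_test2(x, y)
  expect_equal(r3$statistic, unname(ht$statistic))
  expect_equal(r3$p_value, ht$p.value)
})

test_that("Wilcoxon exact enumeration matches hand counts and the normal
           approximation tracks it", {
  ## all C(6,3) = 20 assignments; ranks 1:6 fully separated -> p = 2/20
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1)
  expect_true(r$exact)

  const <- wilcoxon_rank_sum(rep(2, 4), rep(2, 5))
  expect_equal(const$p_value, 1)
  expect_true(const$degenerate)

  ## enumeration vs normal approximation within 0.02 (continuous data;
  ## heavy ties coarsen the exact null beyond what any approximation with
  ## continuity correction can track at these sizes)
  set.seed(42)
  for (rep_i in 1:25) {
    na <- sample(5:8, 1); nb <- sample(5:8, 1)
    a <- rnorm(na); b <- rnorm(nb, 0.3)
    pe <- wilcoxon_rank_sum(a, b, exact_limit = 16)$p_value
    pn <- wilcoxon_rank_sum(a, b, exact_limit = 0)$p_value
    expect_lt(abs(pe - pn), 0.02)
  }
  ## under ties the exact path still matches the oracle built on midranks:
  ## enumeration over assignments of the observed midranks
  a <- c(1, 2, 2, 3); b <- c(2, 3, 3, 4)
  r <- rank(c(a, b))
  combos <- utils::combn(8, 4)
  sums <- colSums(matrix(r[combos], nrow = 4))
  w <- sum(r[1:4]); mu <- 4 * 9 / 2
  p_manual <- mean(abs(sums - mu) >= abs(w - mu) - 1e-9)
  expect_equal(wilcoxon_rank_sum(a, b)$p_value, p_manual)

  ## tie-free case agrees with the base oracle exactly
  set.seed(7)
  a <- rnorm(6); b <- rnorm(7)
  expect_equal(wilcoxon_rank_sum(a, b)$p_value,
               stats::wilcox.test(a, b, exact = TRUE)$p.value,
               tolerance = 1e-12)
  ## large-sample path agrees with the base continuity-corrected oracle
  a <- rnorm(30); b <- rnorm(25, 0.4)
  expect_equal(wilcoxon_rank_sum(a, b)$p_value,
               stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-9)
})

test_that("p-value adjustment follows Holm and Bonferroni and is
           permutation-equivariant", {
  expect_equal(adjust_pvalues(0.03, "holm")$adjusted, 0.03)
  expect_equal(adjust_pvalues(c(0.01, 0.04, 0.03), "holm")$adjusted,
               c(0.03, 0.06, 0.06))
  expect_equal(adjust_pvalues(c(0.2, 0.9), "bonferroni")$adjusted,
               c(0.4, 1.0))
  expect_error(adjust_pvalues(c(0.5, 1.2), "holm"), "\\[0, 1\\]")

  set.seed(3)
  p <- runif(12)
  perm <- sample(12)
  a1 <- adjust_pvalues(p, "holm")$adjusted
  a2 <- adjust_pvalues(p[perm], "holm")$adjusted
  expect_equal(a2, a1[perm])
  expect_true(all(a1 >= p))
  expect_true(all(a1 <= 1))
})

test_that("Spearman correlation matches rank formula, extremes and the
           exact permutation null", {
  expect_equal(spearman_cor(1:6, (1:6)^3)$rho, 1)
  expect_equal(spearman_cor(1:6, -(1:6)^3)$rho, -1)
  ## d^2 = (1-2)^2 + (2-1)^2 = 2 -> rho = 1 - 6*2/(3*8) = 0.5
  expect_equal(spearman_cor(c(1, 2, 3), c(2, 1, 3))$rho, 0.5)

  set.seed(9)
  x <- rnorm(20); y <- x + rnorm(20)
  expect_equal(spearman_cor(x, y)$rho,
               spearman_cor(rank(x), rank(y))$rho)

  ## exact permutation p matches the base oracle for small tie-free n
  x <- c(0.3, 1.8, -0.2, 0.9, 2.4)
  y <- c(1.1, 0.4, 0.2, 2.0, 1.7)
  expect_equal(spearman_cor(x, y)$p_value,
               stats::cor.test(x, y, method = "spearman",
                               exact = TRUE)$p.value,
               tolerance = 1e-12)

  const <- spearman_cor(rep(1, 5), rnorm(5))
  expect_true(const$degenerate)
  expect_true(is.na(const$rho))
})

test_that("test_report assembles tidy rows with adjusted p values", {
  r1 <- t_test2(c(1, 2, 3), c(0, 0, 0), paired = TRUE)
  r2 <- wilcoxon_rank_sum(1:4, 5:9)
  rep <- test_report(list(a = r1, b = r2), adjust = "holm")
  expect_equal(nrow(rep), 2)
  expect_true(all(rep$p_adj >= rep$p_raw))
  expect_equal(rep$group, c("a", "b"))
})
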
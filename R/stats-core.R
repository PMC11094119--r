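#' Arcsinh variance-stabilising transform
#'
#' Mass-cytometry intensities span several decades and are variance-stabilised
#' with `asinh(x / cofactor)` before any statistics are computed. The default
#' cofactor of 5 is the mass-cytometry convention.
#'
#' @param x Numeric vector, matrix or array of (typically non-negative)
#'   intensities.
#' @param cofactor Positive scaling divisor.
#' @return Transformed values with the same shape as `x`.
#' @seealso [inv_arcsinh()] for the exact inverse.
#' @export
#' @examples
#' arcsinh_transform(5, cofactor = 5)  # asinh(1) = log(1 + sqrt(2))
arcsinh_transform <- function(x, cofactor = 5) {
  if (!is.numeric(cofactor) || length(cofactor) != 1L || !is.finite(cofactor) ||
      cofactor <= 0) {
    stop("`cofactor` must be a single positive number", call. = FALSE)
  }
  asinh(x / cofactor)
}

#' Inverse of the arcsinh transform
#'
#' @inheritParams arcsinh_transform
#' @return `sinh(x) * cofactor`.
#' @export
inv_arcsinh <- function(x, cofactor = 5) {
  if (!is.numeric(cofactor) || length(cofactor) != 1L || !is.finite(cofactor) ||
      cofactor <= 0) {
    stop("`cofactor` must be a single positive number", call. = FALSE)
  }
  sinh(x) * cofactor
}

new_test_result <- function(statistic, p_value, df = NA_real_, n = integer(),
                            method = "", degenerate = FALSE, extra = list()) {
  structure(
    c(list(statistic = statistic, p_value = p_value, df = df, n = n,
           tails = "two", method = method, degenerate = degenerate), extra),
    class = "domemap_test")
}

#' @export
print.domemap_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  statistic = %.4g, df = %s, p = %.4g%s\n",
              x$statistic, format(x$df), x$p_value,
              if (isTRUE(x$degenerate)) "  [degenerate]" else ""))
  invisible(x)
}

#' Two-tailed t test with explicit degenerate handling
#'
#' A thin wrapper around [stats::t.test()] that returns a tidy result object
#' and flags zero-variance (degenerate) inputs instead of propagating
#' infinities. Group comparisons between paired tissue/blood samples and
#' between paired ROI summaries use `paired = TRUE`; the unpaired default is
#' the Welch unequal-variance convention (`pooled = TRUE` gives the classic
#' Student test).
#'
#' @param a,b Numeric vectors. Paired mode requires equal lengths >= 2.
#' @param paired Logical; compare paired differences.
#' @param pooled Logical; for unpaired tests, assume equal variances.
#' @return A `domemap_test` with `statistic`, `p_value`, `df`, `n`,
#'   `degenerate` and the group means.
#' @export
t_test2 <- function(a, b, paired = FALSE, pooled = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  keep <- if (paired) is.finite(a) & is.finite(b) else NULL
  if (paired) { a <- a[keep]; b <- b[keep] } else {
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
  }
  if (paired && length(a) != length(b)) {
    stop("paired t test requires equal-length vectors", call. = FALSE)
  }
  n <- if (paired) length(a) else c(length(a), length(b))
  if (any(n < 2L)) stop("each group needs at least 2 observations", call. = FALSE)
  method <- if (paired) "Paired two-tailed t test" else if (pooled)
    "Two-sample t test (pooled variance)" else "Welch two-sample t test"
  degenerate <- if (paired) stats::var(a - b) == 0 else
    (stats::var(a) == 0 && stats::var(b) == 0)
  if (degenerate) {
    same <- if (paired) all(a == b) else isTRUE(all.equal(mean(a), mean(b)))
    return(new_test_result(
      statistic = if (same) 0 else NA_real_,
      p_value = if (same) 1 else NA_real_,
      df = if (paired) n - 1 else sum(n) - 2,
      n = n, method = method, degenerate = TRUE,
      extra = list(mean_a = mean(a), mean_b = mean(b))))
  }
  ht <- stats::t.test(a, b, paired = paired, var.equal = pooled)
  new_test_result(statistic = unname(ht$statistic), p_value = ht$p.value,
                  df = unname(ht$parameter), n = n, method = method,
                  extra = list(mean_a = mean(a), mean_b = mean(b)))
}

# Sum of midranks of group a within the pooled sample.
rank_sum_stat <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)])
}

#' Wilcoxon rank-sum test with exact enumeration for small samples
#'
#' Rank-sum test with midrank tie handling. For a total sample size not above
#' `exact_limit` the two-sided p value is computed by exhaustive enumeration of
#' all group assignments (valid under ties); above it a normal approximation
#' with tie-corrected variance and continuity correction is used.
#'
#' @param a,b Non-empty numeric vectors.
#' @param exact_limit Total size at or below which enumeration is used.
#' @return A `domemap_test`; `statistic` is W (rank sum of `a` minus its
#'   minimum possible value, the Mann-Whitney U).
#' @export
wilcoxon_rank_sum <- function(a, b, exact_limit = 16) {
  a <- as.numeric(a); b <- as.numeric(b)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) stop("both groups must be non-empty", call. = FALSE)
  pooled <- c(a, b)
  if (stats::var(pooled) == 0) {
    return(new_test_result(statistic = na * nb / 2, p_value = 1,
                           n = c(na, nb), method = "Wilcoxon rank sum test",
                           degenerate = TRUE))
  }
  r <- rank(pooled)
  w <- sum(r[seq_len(na)])                     # rank sum of group a
  u <- w - na * (na + 1) / 2                   # Mann-Whitney U
  n <- na + nb
  if (n <= exact_limit) {
    ## enumerate all C(n, na) assignments of the observed midranks
    combos <- utils::combn(n, na)
    sums <- colSums(matrix(r[combos], nrow = na))
    ## two-sided: total probability of assignments at least as extreme,
    ## measured by distance of the rank sum from its mean
    mu <- na * (n + 1) / 2
    eps <- 1e-9
    p <- mean(abs(sums - mu) >= abs(w - mu) - eps)
  } else {
    mu <- na * nb / 2
    ties <- table(r)
    sigma2 <- (na * nb / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    cc <- sign(u - mu) * 0.5                   # continuity correction
    z <- (u - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  new_test_result(statistic = u, p_value = p, n = c(na, nb),
                  method = "Wilcoxon rank sum test",
                  extra = list(rank_sum = w,
                               exact = n <= exact_limit))
}

#' Multiple-testing adjustment (Holm or Bonferroni)
#'
#' @param raw Numeric vector of p values in `[0, 1]`.
#' @param method `"holm"` (step-down, family-wise) or `"bonferroni"`.
#' @return A list with `raw`, `adjusted` (same order as input) and `method`.
#' @export
adjust_pvalues <- function(raw, method = c("holm", "bonferroni")) {
  method <- match.arg(method)
  if (any(!is.na(raw) & (raw < 0 | raw > 1))) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  list(raw = raw, adjusted = stats::p.adjust(raw, method = method),
       method = method)
}

#' Spearman rank correlation with p value
#'
#' rho is the Pearson correlation of midranks. The p value uses the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` except for very
#' small samples (`n <= exact_limit`, no ties), where the exact permutation
#' null is enumerated.
#'
#' @param x,y Paired numeric vectors of length >= 3.
#' @param exact_limit Largest n for which the permutation null is enumerated.
#' @return List with `rho`, `p_value`, `n`, `degenerate`.
#' @export
spearman_cor <- function(x, y, exact_limit = 7) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n, degenerate = TRUE))
  }
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  if (n <= exact_limit && !ties) {
    perms <- permutations_of(n)
    rhos <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- min(1, 2 * stats::pt(-abs(tstat), df = n - 2))
  }
  list(rho = rho, p_value = p, n = n, degenerate = FALSE)
}

# All permutations of 1..n as a matrix with n! rows (n small).
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    for (i in seq_len(nrow(sub))) {
      rest <- seq_len(n)[-k]
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

#' Tidy data frame from one or more test results
#'
#' @param ... `domemap_test` objects (optionally named).
#' @param adjust Method passed to [adjust_pvalues()], or `NULL` to skip.
#' @return data.frame with group, statistic, df, p_raw, p_adj, method.
#' @export
test_report <- function(..., adjust = "holm") {
  tests <- list(...)
  if (length(tests) == 1L && is.list(tests[[1]]) &&
      !inherits(tests[[1]], "domemap_test")) {
    tests <- tests[[1]]
  }
  nm <- names(tests)
  if (is.null(nm)) nm <- paste0("test", seq_along(tests))
  out <- data.frame(
    group = nm,
    statistic = vapply(tests, function(t) t$statistic, numeric(1)),
    df = vapply(tests, function(t) as.numeric(t$df)[1], numeric(1)),
    p_raw = vapply(tests, function(t) t$p_value, numeric(1)),
    method = vapply(tests, function(t) t$method, character(1)),
    degenerate = vapply(tests, function(t) isTRUE(t$degenerate), logical(1)),
    stringsAsFactors = FALSE)
  out$p_adj <- if (is.null(adjust)) out$p_raw else
    adjust_pvalues(out$p_raw, adjust)$adjusted
  out
}
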
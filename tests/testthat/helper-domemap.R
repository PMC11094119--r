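# mclust serves as the independent non-spatial mixture oracle; attaching it
# works around its internal use of the search path.
suppressMessages(library(mclust))

# Gaussian blobs on a lattice: `bands` vertical zones with means separated by
# `sep` standard deviations in `d` dimensions.
lattice_blobs <- function(nrow = 40, ncol = 40, bands = 3, sep = 2, d = 5,
                          seed = 1) {
  spots <- expand.grid(col = seq_len(ncol) - 1L, row = seq_len(nrow) - 1L)
  zone <- 1L + pmin(bands - 1L, floor(spots$col / (ncol / bands)))
  mu <- matrix(0, bands, d)
  for (k in seq_len(bands)[-1]) mu[k, k - 1L] <- sep
  set.seed(seed)
  pcs <- mu[zone, , drop = FALSE] + matrix(stats::rnorm(nrow(spots) * d),
                                           nrow(spots), d)
  list(spots = spots, zone = zone, pcs = pcs)
}

# Well-separated marker-space blobs for tree/classifier tests.
marker_blobs <- function(n_per = 200, centres, sd = 0.3, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centres)), function(k) {
    matrix(stats::rnorm(n_per * ncol(centres), mean = rep(centres[k, ],
                                                          each = n_per),
                        sd = sd), n_per, ncol(centres))
  }))
  colnames(x) <- colnames(centres)
  list(x = x, label = rep(seq_len(nrow(centres)), each = n_per))
}

# Fraction of graph edges whose endpoints share a label.
neighbour_agreement <- function(labels, graph) {
  A <- graph$adj
  idx <- Matrix::which(A != 0, arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  mean(labels[idx[, 1]] == labels[idx[, 2]])
}
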
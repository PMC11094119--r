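#' Distance from every cell to its nearest epithelial cell
#'
#' Euclidean centroid-to-centroid distance, computed independently per ROI
#' (distances never cross ROI boundaries). Epithelial cells themselves get 0
#' by the target-cell convention unless `self_exclude = TRUE`, in which case
#' they get the distance to the nearest *other* epithelial cell. The blocked
#' computation is exact — identical to the brute-force minimum.
#'
#' @param meta Data.frame with `roi`, `x`, `y` and a label column.
#' @param label_col Column holding lineage labels.
#' @param epithelial_label Label identifying epithelial cells.
#' @param self_exclude See above.
#' @return Numeric vector of distances (micrometres); `NaN` with a warning
#'   for ROIs without epithelial cells.
#' @export
nearest_epithelial_distance <- function(meta, label_col = "lineage_full",
                                        epithelial_label = "Epithelial",
                                        self_exclude = FALSE) {
  out <- rep(NaN, nrow(meta))
  for (r in unique(meta$roi)) {
    i <- which(meta$roi == r)
    epi <- i[meta[[label_col]][i] == epithelial_label]
    if (length(epi) == 0L) {
      warning("ROI ", r, " has no epithelial cells; distances undefined",
              call. = FALSE)
      next
    }
    ## squared distances via explicit coordinate differences: exact, and
    ## bitwise-identical to the naive two-point formula
    d2 <- outer(meta$x[i], meta$x[epi], "-")^2 +
      outer(meta$y[i], meta$y[epi], "-")^2
    if (self_exclude) {
      is_epi <- match(epi, i)
      d2[cbind(is_epi, seq_along(epi))] <- Inf
    }
    dmin <- sqrt(apply(d2, 1L, min))
    if (!self_exclude) dmin[meta[[label_col]][i] == epithelial_label] <- 0
    out[i] <- dmin
  }
  out
}

#' Otsu threshold
#'
#' Maximises between-class variance over a histogram of the values; the
#' default raster threshold of the quantification steps.
#'
#' @param x Numeric values (vector or matrix).
#' @param n_breaks Histogram resolution.
#' @return Threshold value.
#' @export
otsu_threshold <- function(x, n_breaks = 256L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  if (length(unique(v)) < 2L) return(max(v))
  h <- graphics::hist(v, breaks = n_breaks, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w1 <- cumsum(p)
  mu1 <- cumsum(p * mids)
  mu_t <- mu1[length(mu1)]
  between <- (mu_t * w1 - mu1)^2 / (w1 * (1 - w1))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Classify cells as marker-positive
#'
#' Per-ROI threshold on transformed intensities by a two-component mixture
#' (default), Otsu, or a fixed value; positivity is `intensity >= threshold`.
#' A degenerate unimodal channel under the mixture method falls back to a
#' quantile rule with a warning.
#'
#' @param values Numeric vector of (transformed) intensities.
#' @param roi ROI id per value (one shared threshold if `NULL`).
#' @param method `"mixture"`, `"otsu"` or `"fixed"`.
#' @param threshold Required for `method = "fixed"`.
#' @return Logical vector of positivity flags.
#' @export
positivity_classify <- function(values, roi = NULL,
                                method = c("mixture", "otsu", "fixed"),
                                threshold = NULL) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(threshold)) stop("fixed method requires a threshold",
                                 call. = FALSE)
    return(values >= threshold)
  }
  if (is.null(roi)) roi <- rep("all", length(values))
  out <- logical(length(values))
  for (r in unique(roi)) {
    i <- roi == r
    if (stats::sd(values[i]) < 1e-12) next   # featureless channel: all negative
    thr <- if (method == "otsu") otsu_threshold(values[i]) else
      mixture_threshold(values[i])
    out[i] <- values[i] >= thr
  }
  out
}

#' Two-group expression/distance contrast
#'
#' Compares a per-cell quantity between two groups (e.g. DNASE1L3+ vs
#' DNASE1L3-, SED vs non-SED, GC vs non-GC). The default unit of analysis is
#' the ROI: per-ROI group means are computed and compared by a paired
#' two-tailed t test across ROIs (figure legends report n as ROIs);
#' `unit = "cell"` pools cells into a Welch two-sample test instead. ROIs
#' missing one group are dropped from the paired analysis with a warning.
#'
#' @param values Numeric vector (the quantity being contrasted).
#' @param group Two-level factor/character vector.
#' @param roi ROI id per value (required for `unit = "ROI"`).
#' @param unit `"ROI"` or `"cell"`.
#' @return Object of class `contrast_report`: group means, per-ROI summary
#'   table, the test, group sizes and the unit flag.
#' @export
expression_contrast <- function(values, group, roi = NULL,
                                unit = c("ROI", "cell")) {
  unit <- match.arg(unit)
  group <- as.character(group)
  lv <- sort(unique(group))
  if (length(lv) != 2L) stop("grouping variable must have exactly 2 levels",
                             call. = FALSE)
  if (unit == "ROI") {
    if (is.null(roi)) stop("unit = 'ROI' requires roi ids", call. = FALSE)
    tab <- stats::aggregate(values,
                            by = list(roi = roi, group = group), FUN = mean)
    wide <- stats::reshape(tab, idvar = "roi", timevar = "group",
                           direction = "wide")
    complete <- stats::complete.cases(wide)
    if (any(!complete)) {
      warning("ROI(s) missing one group dropped: ",
              paste(wide$roi[!complete], collapse = ", "), call. = FALSE)
      wide <- wide[complete, , drop = FALSE]
    }
    a <- wide[[paste0("x.", lv[1])]]
    b <- wide[[paste0("x.", lv[2])]]
    test <- t_test2(a, b, paired = TRUE)
    summary_tab <- wide
  } else {
    a <- values[group == lv[1]]
    b <- values[group == lv[2]]
    test <- t_test2(a, b, paired = FALSE)
    summary_tab <- data.frame(group = lv,
                              mean = c(mean(a), mean(b)),
                              n = c(length(a), length(b)))
  }
  structure(list(levels = lv,
                 mean_a = mean(values[group == lv[1]]),
                 mean_b = mean(values[group == lv[2]]),
                 n = c(sum(group == lv[1]), sum(group == lv[2])),
                 per_roi = summary_tab, test = test, unit = unit),
            class = "contrast_report")
}

#' @export
print.contrast_report <- function(x, ...) {
  cat(sprintf("contrast_report (%s-level): %s vs %s\n", x$unit,
              x$levels[1], x$levels[2]))
  cat(sprintf("  means: %.4g vs %.4g (n = %d, %d)\n",
              x$mean_a, x$mean_b, x$n[1], x$n[2]))
  print(x$test)
  invisible(x)
}

#' Segment supra-threshold objects in a raster channel
#'
#' Threshold (Otsu by default) then connected components at 4- or
#' 8-connectivity; objects below the minimum diameter are discarded. The
#' primary-object segmentation used for transcript-positive cell counting.
#'
#' @param raster Numeric matrix (one channel) or the list produced by
#'   [simulate_coloc_raster()] plus a `channel` name.
#' @param channel Channel name when `raster` is a multi-channel list.
#' @param min_diameter_px Minimum equivalent diameter in pixels.
#' @param connectivity 4 or 8.
#' @param threshold Fixed threshold; `NULL` uses Otsu.
#' @return List with `labels` (integer matrix, 0 = background) and `objects`
#'   (data.frame: object, centroid row/col, area).
#' @export
segment_objects <- function(raster, channel = NULL, min_diameter_px = 2,
                            connectivity = 8, threshold = NULL) {
  m <- raster_channel(raster, channel)
  if (length(m) == 0L) {
    return(list(labels = m, objects = data.frame(object = integer(),
                                                 row = numeric(),
                                                 col = numeric(),
                                                 area = integer())))
  }
  thr <- if (is.null(threshold)) otsu_threshold(m) else threshold
  mask <- m > thr
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) {
    return(list(labels = lab, objects = data.frame(object = integer(),
                                                   row = numeric(),
                                                   col = numeric(),
                                                   area = integer())))
  }
  objs <- do.call(rbind, lapply(seq_len(max(lab)), function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    data.frame(object = k, row = mean(idx[, 1]), col = mean(idx[, 2]),
               area = nrow(idx))
  }))
  min_area <- pi * (min_diameter_px / 2)^2
  keep <- objs$area >= min_area
  drop_ids <- objs$object[!keep]
  if (length(drop_ids)) lab[lab %in% drop_ids] <- 0L
  objs <- objs[keep, , drop = FALSE]
  if (nrow(objs)) {
    relab <- stats::setNames(seq_len(nrow(objs)), objs$object)
    lab[lab > 0L] <- relab[as.character(lab[lab > 0L])]
    objs$object <- seq_len(nrow(objs))
  }
  list(labels = lab, objects = objs)
}

raster_channel <- function(raster, channel) {
  if (is.matrix(raster)) return(raster)
  if (is.list(raster) && !is.null(raster$channels)) raster <- raster$channels
  if (is.null(channel) || is.null(raster[[channel]])) {
    stop("specify an existing channel of the raster", call. = FALSE)
  }
  raster[[channel]]
}

# Connected-component labelling of a logical mask (iterative flood fill).
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  if (!any(mask)) return(lab)
  offs <- if (connectivity == 4) {
    cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  } else {
    cbind(rep(c(-1L, 0L, 1L), 3L), rep(c(-1L, 0L, 1L), each = 3L))[-5L, ]
  }
  current <- 0L
  todo <- which(mask & lab == 0L)
  while (length(todo)) {
    current <- current + 1L
    stack <- todo[1L]
    lab[stack] <- current
    while (length(stack)) {
      px <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r0 <- ((px - 1L) %% h) + 1L
      c0 <- ((px - 1L) %/% h) + 1L
      nr <- r0 + offs[, 1]; nc <- c0 + offs[, 2]
      ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
      nidx <- (nc[ok] - 1L) * h + nr[ok]
      nidx <- nidx[mask[nidx] & lab[nidx] == 0L]
      lab[nidx] <- current
      stack <- c(stack, nidx)
    }
    todo <- which(mask & lab == 0L)
  }
  lab
}

#' Colocalization fraction of a signal channel within a reference mask
#'
#' The proportion of signal-positive pixels (threshold method as in
#' [segment_objects()]) that fall inside the reference mask, mirroring the
#' binarise-mask-divide quantification of transcript overlap.
#'
#' @param raster Matrix or multi-channel list.
#' @param signal_channel Channel name of the signal of interest.
#' @param reference Either a logical mask of the same shape or the name of a
#'   channel to be thresholded into one.
#' @param threshold Fixed signal threshold; `NULL` uses Otsu.
#' @return Fraction in `[0, 1]`, or `NaN` (with a warning) when no pixel is
#'   signal-positive.
#' @export
coloc_fraction <- function(raster, signal_channel = NULL, reference,
                           threshold = NULL) {
  sig <- raster_channel(raster, signal_channel)
  ref_mask <- if (is.logical(reference)) reference else {
    rm <- raster_channel(raster, reference)
    rm > otsu_threshold(rm)
  }
  if (!identical(dim(sig), dim(ref_mask))) {
    stop("reference mask shape differs from signal channel", call. = FALSE)
  }
  thr <- if (is.null(threshold)) otsu_threshold(sig) else threshold
  pos <- sig > thr
  if (!any(pos)) {
    warning("no signal-positive pixels; colocalization fraction undefined",
            call. = FALSE)
    return(NaN)
  }
  sum(pos & ref_mask) / sum(pos)
}
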
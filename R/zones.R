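#' Zone maps: named tissue-region polygons
#'
#' A zone map is a named list of simple polygons (n x 2 matrices of x/y
#' vertices, in micrometres, origin top-left with y increasing downward)
#' describing the microanatomy of a gut-associated lymphoid tissue (GALT)
#' follicle: lumen, follicle-associated epithelium (FAE), subepithelial dome
#' (SED), germinal centre (GC), mantle, T zone and lamina propria. Nested
#' polygons are resolved by the smallest-area-containing rule, so the GC disc
#' may sit inside the follicle disc.
#'
#' @param zones Named list of numeric matrices with two columns.
#' @return An object of class `zone_map`.
#' @export
zone_map <- function(zones) {
  if (is.null(names(zones)) || anyDuplicated(names(zones))) {
    stop("zones must be uniquely named", call. = FALSE)
  }
  zones <- lapply(zones, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2L || nrow(p) < 3L) {
      stop("each zone polygon needs >= 3 vertices in 2 columns", call. = FALSE)
    }
    storage.mode(p) <- "double"
    colnames(p) <- c("x", "y")
    p
  })
  areas <- vapply(zones, polygon_area, numeric(1))
  if (any(areas <= 0)) {
    stop("degenerate polygon for zone(s): ",
         paste(names(zones)[areas <= 0], collapse = ", "), call. = FALSE)
  }
  structure(list(zones = zones, areas = areas), class = "zone_map")
}

#' @export
print.zone_map <- function(x, ...) {
  cat("zone_map with", length(x$zones), "zones:\n")
  for (nm in names(x$zones)) {
    cat(sprintf("  %-16s %5d vertices, area %.0f um^2\n",
                nm, nrow(x$zones[[nm]]), x$areas[[nm]]))
  }
  invisible(x)
}

# Shoelace area (absolute).
polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  n <- nrow(p)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

disc_polygon <- function(cx, cy, r, n = 48L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

rect_polygon <- function(x0, y0, x1, y1) {
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

#' Default concentric GALT follicle geometry
#'
#' Lumen strip above a flat FAE strip; SED cap between the FAE and the
#' follicle; GC disc inside a mantle (follicle) disc; T zone beside the
#' follicle; lamina propria filling the remainder. The layout approximates a
#' well-orientated follicle section with both GC and FAE in view.
#'
#' @param width,height Extent of the region of interest in micrometres.
#' @return A [zone_map()].
#' @export
default_zone_map <- function(width = 600, height = 600) {
  w <- width; h <- height
  fae_top <- 0.07 * h; fae_bot <- 0.13 * h
  gc_c <- c(0.5 * w, 0.62 * h); gc_r <- 0.18 * min(w, h)
  fol_r <- 0.30 * min(w, h)
  sed <- cbind(
    x = c(0.18 * w, 0.82 * w, 0.74 * w, 0.26 * w),
    y = c(fae_bot, fae_bot, 0.36 * h, 0.36 * h))
  zone_map(list(
    lumen = rect_polygon(0, 0, w, fae_top),
    FAE = rect_polygon(0.15 * w, fae_top, 0.85 * w, fae_bot),
    SED = sed,
    mantle = disc_polygon(gc_c[1], gc_c[2], fol_r),
    GC = disc_polygon(gc_c[1], gc_c[2], gc_r),
    T_zone = disc_polygon(0.12 * w, 0.70 * h, 0.14 * min(w, h)),
    lamina_propria = rect_polygon(0, fae_top, w, h)))
}

# TRUE for points inside or on the boundary of polygon p.
points_in_polygon <- function(xy, p) {
  xy <- matrix(as.numeric(xy), ncol = 2L)
  inside <- mgcv::in.out(rbind(p, p[1L, , drop = FALSE]), xy)
  ## force boundary-inclusive containment: check points near an edge
  if (!all(inside)) {
    miss <- which(!inside)
    on_edge <- vapply(miss, function(i) point_on_boundary(xy[i, ], p),
                      logical(1))
    inside[miss[on_edge]] <- TRUE
  }
  inside
}

point_on_boundary <- function(pt, p, tol = 1e-9) {
  n <- nrow(p)
  for (i in seq_len(n)) {
    a <- p[i, ]; b <- p[if (i == n) 1L else i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) 0 else sum((pt - a) * ab) / len2
    t <- min(1, max(0, t))
    if (sum((pt - (a + t * ab))^2) <= tol^2) return(TRUE)
  }
  FALSE
}

#' Assign cells to zones by the smallest containing polygon
#'
#' Each centroid receives the name of the smallest-area polygon that contains
#' it (boundary-inclusive); centroids outside every polygon get `"other"`.
#'
#' @param cells Data frame with `x` and `y` columns (micrometres), or a
#'   two-column matrix.
#' @param zones A [zone_map()].
#' @return Character vector of zone labels, one per row of `cells`.
#' @export
zone_assign <- function(cells, zones) {
  stopifnot(inherits(zones, "zone_map"))
  xy <- if (is.matrix(cells)) cells else cbind(cells$x, cells$y)
  lab <- rep("other", nrow(xy))
  best <- rep(Inf, nrow(xy))
  for (nm in names(zones$zones)) {
    a <- zones$areas[[nm]]
    hit <- points_in_polygon(xy, zones$zones[[nm]]) & a < best
    lab[hit] <- nm
    best[hit] <- a
  }
  lab
}

# Uniform sample of n points inside `zone`, rejecting points that fall inside
# any strictly smaller polygon of the map (so "mantle" means the annulus).
sample_in_zone <- function(zones, zone, n) {
  p <- zones$zones[[zone]]
  if (is.null(p)) stop("unknown zone: ", zone, call. = FALSE)
  smaller <- names(zones$zones)[zones$areas < zones$areas[[zone]]]
  out <- matrix(0, 0, 2)
  bb <- c(range(p[, 1]), range(p[, 2]))
  guard <- 0L
  while (nrow(out) < n && guard < 1000L) {
    m <- max(64L, 4L * (n - nrow(out)))
    cand <- cbind(stats::runif(m, bb[1], bb[2]), stats::runif(m, bb[3], bb[4]))
    ok <- points_in_polygon(cand, p)
    for (s in smaller) {
      if (!any(ok)) break
      ok[ok] <- !points_in_polygon(cand[ok, , drop = FALSE], zones$zones[[s]])
    }
    out <- rbind(out, cand[ok, , drop = FALSE])
    guard <- guard + 1L
  }
  if (nrow(out) < n) {
    stop("could not place points in zone ", zone,
         " (is it fully covered by nested zones?)", call. = FALSE)
  }
  out[seq_len(n), , drop = FALSE]
}

#' Write a zone map as GeoJSON
#'
#' Coordinates are micrometres, origin top-left, y increasing downward.
#'
#' @param zones A [zone_map()].
#' @param path Output file.
#' @export
write_zone_map_geojson <- function(zones, path) {
  stopifnot(inherits(zones, "zone_map"))
  feats <- lapply(names(zones$zones), function(nm) {
    p <- zones$zones[[nm]]
    ring <- rbind(p, p[1L, , drop = FALSE])
    list(type = "Feature",
         properties = list(name = nm),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a zone map from GeoJSON
#'
#' @param path GeoJSON file written by [write_zone_map_geojson()] or any
#'   FeatureCollection of named Polygon features.
#' @return A [zone_map()].
#' @export
read_zone_map_geojson <- function(path) {
  g <- jsonlite::read_json(path)
  zones <- list()
  for (f in g$features) {
    ring <- f$geometry$coordinates[[1]]
    p <- do.call(rbind, lapply(ring, function(v) as.numeric(unlist(v))))
    zones[[f$properties$name]] <- p[-nrow(p), , drop = FALSE]
  }
  zone_map(zones)
}
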
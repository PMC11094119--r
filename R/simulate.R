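#' Simulation configuration for synthetic GALT data
#'
#' Bundles every parameter of the synthetic tissue generator: the follicle
#' zone geometry, cell-type compositions and marker models for the suspension
#' and imaging panels, the spillover matrix, per-ROI batch effects, zone gene
#' programmes with negative-binomial count noise for spot transcriptomes, and
#' the colocalization raster layout. The defaults encode the study conditions
#' the pipeline is validated against (e.g. a configured 2x enrichment of
#' DN2/3 B cells in GALT over blood, DNASE1L3 carrying the largest
#' subepithelial-dome fold change); every derived output is reproducible from
#' `seed` via independent, stably hashed RNG streams.
#'
#' @param seed Master integer seed.
#' @param cofactor Arcsinh cofactor shared by all cytometry channels.
#' @param suspension,imc,spots,coloc Named lists overriding individual
#'   defaults of the four generators (see Details in the methods vignette).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, cofactor = 5,
                       suspension = list(), imc = list(), spots = list(),
                       coloc = list()) {
  cfg <- list(
    seed = as.integer(seed),
    cofactor = cofactor,
    suspension = utils::modifyList(default_suspension_config(), suspension),
    imc = utils::modifyList(default_imc_config(), imc),
    spots = utils::modifyList(default_spots_config(), spots),
    coloc = utils::modifyList(default_coloc_config(), coloc))
  ps <- cfg$suspension$subsets
  for (col in c("galt", "pbmc")) {
    if (abs(sum(ps[[col]]) - 1) > 1e-6) {
      stop("suspension ", toupper(col), " proportions must sum to 1",
           call. = FALSE)
    }
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config (seed", x$seed, ")\n")
  cat("  suspension:", nrow(x$suspension$subsets), "B subsets,",
      x$suspension$n_events, "events/sample\n")
  cat("  imc:", x$imc$n_cells, "cells/ROI,",
      length(x$imc$channels), "channels\n")
  cat("  spots:", x$spots$nrow, "x", x$spots$ncol, "hex grid,",
      "dispersion", x$spots$dispersion, "\n")
  invisible(x)
}

# --- reproducible sub-streams ----------------------------------------------

#' Derive a reproducible sub-seed from a master seed and a stream name
#'
#' Stable string hash mapped below 2^31, so each output object has its own
#' RNG stream and adding an output never perturbs the others.
#'
#' @param seed Master integer seed.
#' @param name Stream label.
#' @return Integer sub-seed.
#' @export
stream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

with_stream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  suppressWarnings(set.seed(stream_seed(seed, name),
                            kind = "Mersenne-Twister",
                            normal.kind = "Inversion",
                            sample.kind = "Rejection"))
  force(expr)
}

# --- marker model -----------------------------------------------------------

# Two-component lognormal marker model on the raw scale; levels are
# expression codes: 0 negative, 1 positive, 2 high, -1 dim ("lo").
level_params <- function(separation = 1) {
  base <- c(`0` = 0.3, `-1` = 1.6, `1` = 3.2, `2` = 4.2)
  gap <- base - base[["0"]]
  meanlog <- base[["0"]] + gap * separation
  sdlog <- c(`0` = 0.60, `-1` = 0.50, `1` = 0.50, `2` = 0.45)
  list(meanlog = meanlog, sdlog = sdlog)
}

# Draw raw lognormal intensities for a vector of level codes (one per cell)
# for a single marker.
draw_marker_raw <- function(levels, separation = 1) {
  lp <- level_params(separation)
  key <- as.character(levels)
  stats::rlnorm(length(levels), lp$meanlog[key], lp$sdlog[key])
}

profile_matrix <- function(profiles, markers) {
  m <- matrix(0, length(profiles), length(markers),
              dimnames = list(names(profiles), markers))
  for (nm in names(profiles)) {
    for (mk in names(profiles[[nm]])) {
      if (!mk %in% markers) stop("profile marker not in panel: ", mk,
                                 call. = FALSE)
      m[nm, mk] <- profiles[[nm]][[mk]]
    }
  }
  m
}

# --- suspension defaults ----------------------------------------------------

suspension_markers <- function() {
  c("CD45RB", "IgD", "CD20", "IgA", "CD138", "CD21", "CD38", "CD10",
    "CD27", "CD24", "IgG", "IgM", "FcRL4", "CD40", "HLADR", "CD11c")
}

default_suspension_config <- function() {
  subsets <- data.frame(
    name = c("TS", "Naive", "MZP", "MZB", "Mem", "GC", "PBPC", "DN1", "DN23"),
    galt = c(0.02, 0.26, 0.06, 0.12, 0.14, 0.15, 0.08, 0.05, 0.12),
    pbmc = c(0.05, 0.50, 0.08, 0.10, 0.12, 0.01, 0.03, 0.05, 0.06),
    stringsAsFactors = FALSE)
  profiles <- list(
    TS    = list(CD20 = 1, CD10 = 1, CD24 = 2, CD38 = 2, IgM = 1, IgD = 1,
                 CD21 = -1, CD40 = 1, HLADR = 1),
    Naive = list(CD20 = 1, IgM = 1, IgD = 1, CD21 = 1, CD24 = 1, CD40 = 1,
                 HLADR = 1),
    MZP   = list(CD20 = 1, CD45RB = 1, IgM = 1, IgD = 1, CD21 = 1, CD40 = 1,
                 HLADR = 1),
    MZB   = list(CD20 = 1, CD27 = 1, CD45RB = 1, IgM = 1, IgD = 1, CD21 = 1,
                 FcRL4 = 1, CD40 = 1, HLADR = 1),
    Mem   = list(CD20 = 1, CD27 = 1, CD45RB = 1, IgG = 1, CD21 = 1, CD40 = 1,
                 HLADR = 1),
    GC    = list(CD20 = 1, CD38 = 2, CD10 = 2, CD21 = -1, CD40 = 1,
                 HLADR = 1),
    PBPC  = list(CD38 = 2, CD138 = 1, CD27 = 2, IgA = 1, CD20 = -1,
                 HLADR = 1),
    DN1   = list(CD20 = 1, IgG = 1, CD21 = 1, CD40 = 1, HLADR = 1),
    DN23  = list(CD20 = 1, IgG = 1, CD21 = -1, CD11c = 2, FcRL4 = 1,
                 CD40 = -1, HLADR = -1))
  list(subsets = subsets, profiles = profiles,
       markers = suspension_markers(),
       n_events = 12000L, donor_sd = 0.10, separation = 1)
}

# --- IMC defaults -----------------------------------------------------------

imc_channels <- function() {
  c("CD20", "CD3", "CD11b", "CD11c", "CD68", "CD31", "Ecad",
    "CD27", "IgD", "CD21", "CD38", "CD10", "CD45RB", "IgM", "CD138", "Ki67",
    "DNASE1L3", "Lysozyme", "NOX2", "DNA1", "DNA2")
}

#' Default spillover matrix with nearest-channel leakage
#'
#' Identity plus a small symmetric leakage between adjacent channels of the
#' panel, standing in for the isotope-impurity crosstalk of a real
#' acquisition. The true matrix is always an input to the pipeline.
#'
#' @param channels Character vector of channel names.
#' @param leak Off-diagonal leakage fraction between adjacent channels.
#' @return A channels x channels matrix with unit diagonal.
#' @export
default_spillover <- function(channels = imc_channels(), leak = 0.04) {
  k <- length(channels)
  S <- diag(k)
  for (i in seq_len(k - 1L)) {
    S[i, i + 1L] <- leak
    S[i + 1L, i] <- leak / 2
  }
  dimnames(S) <- list(channels, channels)
  S
}

default_imc_config <- function() {
  # fractions are normalised at generation time
  types <- list(
    list(name = "Epithelial", lineage = "Epithelial", subset = "none",
         frac = 0.07, zones = c(FAE = 1)),
    list(name = "B_Naive", lineage = "B", subset = "Naive", frac = 0.17,
         zones = c(mantle = 1)),
    list(name = "B_MZP", lineage = "B", subset = "MZP", frac = 0.04,
         zones = c(mantle = 1)),
    list(name = "B_MZB", lineage = "B", subset = "MZB", frac = 0.06,
         zones = c(mantle = 1)),
    list(name = "B_Mem", lineage = "B", subset = "Mem", frac = 0.06,
         zones = c(mantle = 0.8, lamina_propria = 0.2)),
    list(name = "B_GC_LZ", lineage = "B", subset = "GC LZ", frac = 0.07,
         zones = c(GC = 1)),
    list(name = "B_GC_DZ", lineage = "B", subset = "GC DZ", frac = 0.07,
         zones = c(GC = 1)),
    list(name = "B_PBPC", lineage = "B", subset = "PB/PC", frac = 0.03,
         zones = c(SED = 0.5, lamina_propria = 0.5)),
    list(name = "B_DN1", lineage = "B", subset = "DN1", frac = 0.02,
         zones = c(mantle = 0.7, SED = 0.3)),
    list(name = "B_DN2", lineage = "B", subset = "DN2", frac = 0.04,
         zones = c(FAE = 0.6, SED = 0.4), band_below_fae = 15),
    list(name = "B_IEDN", lineage = "B", subset = "IEDN", frac = 0.008,
         zones = c(FAE = 1), epithelial_exclusion = 9),
    list(name = "T", lineage = "T", subset = "none", frac = 0.17,
         zones = c(T_zone = 0.55, GC = 0.10, mantle = 0.15,
                   lamina_propria = 0.20)),
    list(name = "MacDC", lineage = "MacDC", subset = "none", frac = 0.09,
         zones = c(SED = 0.45, lamina_propria = 0.30, GC = 0.15,
                   T_zone = 0.10)),
    list(name = "Endothelial", lineage = "Endothelial", subset = "none",
         frac = 0.05, zones = c(lamina_propria = 1)),
    list(name = "BT", lineage = "BT", subset = "none", frac = 0.02,
         zones = c(T_zone = 0.5, mantle = 0.5)))
  profiles <- list(
    Epithelial = list(Ecad = 2),
    B_Naive = list(CD20 = 1, IgM = 1, IgD = 1, CD21 = 1),
    B_MZP = list(CD20 = 1, CD45RB = 1, IgM = 1, IgD = 1, CD21 = 1),
    B_MZB = list(CD20 = 1, CD27 = 1, CD45RB = 1, IgM = 1, IgD = 1, CD21 = 1),
    B_Mem = list(CD20 = 1, CD27 = 1, CD45RB = 1, CD21 = 1),
    B_GC_LZ = list(CD20 = 1, CD38 = 2, CD10 = 2, CD21 = -1),
    B_GC_DZ = list(CD20 = 1, CD38 = 2, CD10 = 2, CD21 = -1, Ki67 = 2),
    B_PBPC = list(CD38 = 2, CD138 = 1, CD27 = 2, CD20 = -1),
    B_DN1 = list(CD20 = 1, CD21 = 1),
    B_DN2 = list(CD20 = 1, CD21 = -1, CD11c = 2),
    B_IEDN = list(CD20 = 1, CD21 = -1, Ecad = 2),
    T = list(CD3 = 2),
    MacDC = list(CD11c = 1, CD11b = 1, CD68 = 1),
    Endothelial = list(CD31 = 2),
    BT = list(CD20 = 1, CD3 = 1))
  list(n_cells = 2500L, width = 600, height = 600,
       zones = NULL,               # default_zone_map(width, height) if NULL
       types = types, profiles = profiles, channels = imc_channels(),
       separation = 1,
       spillover = default_spillover(),
       batch_sd = 0.15,            # per-ROI per-channel shift, asinh scale
       debris_frac = 0.02,         # low-DNA fragments for QC
       area_meanlog = log(30), area_sdlog = 0.6,
       dnase1l3_pos = c(SED = 0.8, other = 0.15),
       microbicide_pos = c(SED = 0.8, other = 0.35))
}

# --- spot defaults ----------------------------------------------------------

default_spots_config <- function() {
  programmes <- list(
    SED = c(DNASE1L3 = 4, C1QB = 3, C1QA = 3, C3 = 2.5, C1R = 2.5,
            C1S = 2, CCL20 = 2, ITGAX = 2.5),
    ## FAE spots capture underlying dome tissue at spot resolution, so the
    ## SED programme bleeds into them at ~0.7 of its strength
    FAE = c(EPCAM = 5, KRT8 = 4, OLFM4 = 3, CCL20 = 4, CCL23 = 3,
            DNASE1L3 = 2.8, C1QB = 2.2, C1QA = 2.2, C3 = 1.9, C1R = 1.9,
            C1S = 1.6, ITGAX = 1.9),
    mantle = c(MS4A1 = 3, IGHD = 2.5, IGHM = 2.5, TCL1A = 2, CD79A = 2,
               CD19 = 2),
    GC = c(BCL6 = 3, AICDA = 4, MKI67 = 3, MS4A1 = 2.5, CD79A = 2),
    T_zone = c(CD3D = 4, CD3E = 3.5, TRAC = 3, IL7R = 2.5, CCL19 = 3,
               CCL21 = 3, DNASE1L3 = 1.5, C1QB = 1.5, C1QA = 1.5,
               C3 = 1.3, C1R = 1.3),
    lamina_propria = c(PIGR = 3, CEACAM5 = 2.5, FABP1 = 2.5, MUC2 = 2),
    lumen = c(MUC2 = 4, TFF3 = 3, FCGBP = 3, SPINK4 = 2.5))
  list(nrow = 30L, ncol = 30L, pitch = 100, lattice = "hex",
       programmes = programmes,
       n_programme_filler = 6L,    # extra synthetic marker genes per zone
       filler_fc = 3,
       n_null_genes = 600L,
       programme_base = 8,
       activity_sdlog = 0.9,       # shared per-spot programme activity
       activity_bg_sdlog = 0.7,    # background abundance variation
       sed_gradient_tau = 250,     # um; dome-programme decay into follicle
       base_meanlog = 1.0, base_sdlog = 0.8,
       libsize_sdlog = 0.3, lumen_lib_factor = 0.5,
       dispersion = 0.2,
       batch_sdlog = 0.15)         # gene-wise factor applied to sample STB
}

default_coloc_config <- function() {
  list(dim = c(160L, 160L), n_blobs = 60L, blob_radius = 3L,
       reference_radius = 45, background_mean = 2, background_sd = 0.5,
       blob_intensity = 25)
}

# --- spillover forward model ------------------------------------------------

#' Mix true channel intensities through a spillover matrix
#'
#' Forward model of channel crosstalk: each source channel i leaks fraction
#' `S[i, j]` of its signal into channel j, so observed = true %*% S.
#'
#' @param x Numeric vector (one cell) or matrix (cells x channels) of true
#'   intensities on the raw scale.
#' @param S Square spillover matrix, unit diagonal, non-negative entries.
#' @return Observed intensities, same shape as `x`.
#' @seealso [compensate_spillover()] for the inverse problem.
#' @export
apply_spillover <- function(x, S) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S)) stop("spillover matrix must be square", call. = FALSE)
  if (any(S < 0)) stop("spillover entries must be non-negative", call. = FALSE)
  if (any(abs(diag(S) - 1) > 1e-8)) {
    stop("spillover diagonal must be 1", call. = FALSE)
  }
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(xm) != nrow(S)) stop("dimension mismatch between x and S",
                                call. = FALSE)
  out <- xm %*% S
  if (vec) drop(out) else out
}

# --- suspension generator ---------------------------------------------------

#' Simulate paired GALT/PBMC B-cell suspension samples
#'
#' For each donor, two event tables (tissue and blood) are generated whose
#' subset composition is drawn around the configured compartment means with
#' donor-level log-normal noise, and whose marker intensities follow the
#' two-component lognormal marker model (arcsinh-transformed in the output).
#' GALT defaults have elevated DN2/3, GC and PB/PC fractions.
#'
#' @param config A [sim_config()].
#' @param n_donors Number of donors (each contributes a GALT and a PBMC
#'   sample). Zero yields an empty table.
#' @param n_events Events per sample; defaults to the configured value.
#' @return List with `events` (data.frame: sample_id, donor, compartment,
#'   one arcsinh-transformed column per marker) and `ground_truth`
#'   (data.frame: event row, true subset).
#' @export
simulate_suspension_pair <- function(config, n_donors = 5L,
                                     n_events = NULL) {
  stopifnot(inherits(config, "sim_config"))
  sc <- config$suspension
  if (is.null(n_events)) n_events <- sc$n_events
  markers <- sc$markers
  prof <- profile_matrix(sc$profiles, markers)
  subsets <- sc$subsets
  empty <- function() {
    ev <- cbind(data.frame(sample_id = character(), donor = character(),
                           compartment = character()),
                stats::setNames(as.data.frame(matrix(numeric(), 0,
                                                     length(markers))),
                                markers))
    list(events = ev,
         ground_truth = data.frame(event = integer(), subset = character()))
  }
  if (n_donors == 0L || n_events == 0L) return(empty())
  with_stream(config$seed, "suspension", {
    rows <- list(); truth <- list()
    for (d in seq_len(n_donors)) {
      for (comp in c("GALT", "PBMC")) {
        p <- subsets[[tolower(comp)]]
        p <- p * exp(stats::rnorm(length(p), 0, sc$donor_sd))
        p <- p / sum(p)
        counts <- drop(stats::rmultinom(1L, n_events, p))
        lev <- prof[rep(subsets$name, counts), , drop = FALSE]
        raw <- matrix(0, nrow(lev), length(markers),
                      dimnames = list(NULL, markers))
        for (j in seq_along(markers)) {
          raw[, j] <- draw_marker_raw(lev[, j], sc$separation)
        }
        X <- arcsinh_transform(raw, config$cofactor)
        sid <- paste0("D", d, "_", comp)
        rows[[sid]] <- cbind(
          data.frame(sample_id = sid, donor = paste0("D", d),
                     compartment = comp, stringsAsFactors = FALSE),
          as.data.frame(X))
        truth[[sid]] <- rep(subsets$name, counts)
      }
    }
    events <- do.call(rbind, rows)
    rownames(events) <- NULL
    list(events = events,
         ground_truth = data.frame(event = seq_len(nrow(events)),
                                   subset = unlist(truth, use.names = FALSE),
                                   stringsAsFactors = FALSE))
  })
}

# --- segmented-image container ----------------------------------------------

#' Construct a segmented single-cell table with intensity layers
#'
#' @param meta Data frame of per-cell metadata (cell_id, roi, x, y, area_px,
#'   label columns as they accrue).
#' @param raw Cells x channels matrix of observed raw mean intensities.
#' @param layers Optional named list of further matrices (e.g. compensated,
#'   transformed) with the same shape as `raw`.
#' @return Object of class `cell_table`.
#' @export
cell_table <- function(meta, raw, layers = list()) {
  raw <- as.matrix(raw)
  stopifnot(nrow(meta) == nrow(raw), !is.null(colnames(raw)))
  structure(list(meta = meta, layers = c(list(raw = raw), layers),
                 channels = colnames(raw)),
            class = "cell_table")
}

#' @export
print.cell_table <- function(x, ...) {
  cat("cell_table:", nrow(x$meta), "cells,", length(x$channels),
      "channels, layers:", paste(names(x$layers), collapse = ", "), "\n")
  rois <- unique(x$meta$roi)
  cat("  ROIs:", paste(utils::head(rois, 8L), collapse = ", "),
      if (length(rois) > 8L) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.cell_table <- function(x) c(nrow(x$meta), length(x$channels))

#' Extract an intensity layer from a cell table
#'
#' @param cells A [cell_table()].
#' @param layer Layer name (`"raw"`, `"compensated"`, `"transformed"`, ...).
#' @return Cells x channels numeric matrix.
#' @export
intensity_layer <- function(cells, layer = "raw") {
  stopifnot(inherits(cells, "cell_table"))
  out <- cells$layers[[layer]]
  if (is.null(out)) stop("no layer '", layer, "' in cell_table", call. = FALSE)
  out
}

# --- IMC ROI generator ------------------------------------------------------

#' Simulate one segmented imaging-mass-cytometry ROI
#'
#' Cells are placed by a zone-weighted point process over the follicle
#' geometry (DN2 concentrated in the FAE and the subepithelial band, IEDN
#' inside the FAE, naive/MZ subsets in the mantle, GC subsets in the GC so the
#' observed distance-to-epithelium ordering holds by construction). True
#' arcsinh-scale intensities follow the marker model; observed raw intensities
#' are the inverse transform of (true + per-ROI batch shift) mixed through the
#' spillover matrix. Cell areas are lognormal with a configurable fraction
#' below the 11-pixel QC limit, and a small debris fraction carries low DNA.
#'
#' @param config A [sim_config()].
#' @param roi_id Label for the ROI; also keys its RNG stream and batch shift.
#' @return List with `cells` (a [cell_table()] with `raw` and `true`
#'   layers), `zones` (the [zone_map()]), and `ground_truth` (data.frame:
#'   cell_id, type, lineage, subset, zone, dnase1l3_pos).
#' @export
simulate_imc_roi <- function(config, roi_id = "ROI1") {
  stopifnot(inherits(config, "sim_config"))
  ic <- config$imc
  zones <- if (is.null(ic$zones)) default_zone_map(ic$width, ic$height) else
    ic$zones
  channels <- ic$channels
  prof <- profile_matrix(ic$profiles, channels)
  fracs <- vapply(ic$types, function(t) t$frac, numeric(1))
  fracs <- fracs / sum(fracs)
  counts <- round(fracs * ic$n_cells)
  with_stream(config$seed, paste0("imc_", roi_id), {
    pos <- list(); type_of <- list()
    pocket_xy <- matrix(0, 0, 2); pocket_r <- numeric()
    ## intraepithelial B cells claim pockets first; the epithelium is then
    ## placed around them (they locally displace epithelial cells); all other
    ## types follow.
    prio <- vapply(ic$types, function(t) {
      if (!is.null(t$epithelial_exclusion)) 1 else
        if (t$name == "Epithelial") 2 else 3
    }, numeric(1))
    for (k in order(prio)) {
      tp <- ic$types[[k]]
      n <- counts[k]
      if (n == 0L) {
        if (!is.null(ic$types[[k]]$must_place) && tp$frac > 0) {
          stop("empty zone requested for type with nonzero count: ", tp$name,
               call. = FALSE)
        }
        next
      }
      zw <- tp$zones
      bad <- setdiff(names(zw), names(zones$zones))
      if (length(bad)) stop("type ", tp$name, " requests unknown zone(s): ",
                            paste(bad, collapse = ", "), call. = FALSE)
      nz <- drop(stats::rmultinom(1L, n, zw))
      xy <- matrix(0, 0, 2)
      for (zi in seq_along(zw)) {
        if (nz[zi] == 0L) next
        zname <- names(zw)[zi]
        if (!is.null(tp$band_below_fae) && zname == "SED") {
          ## tight subepithelial band under the FAE
          fae <- zones$zones[["FAE"]]
          y0 <- max(fae[, 2])
          cand <- sample_in_zone(zones, "SED", nz[zi] * 10L)
          cand <- cand[cand[, 2] <= y0 + tp$band_below_fae, , drop = FALSE]
          guard <- 0L
          while (nrow(cand) < nz[zi] && guard < 50L) {
            extra <- sample_in_zone(zones, "SED", nz[zi] * 10L)
            cand <- rbind(cand,
                          extra[extra[, 2] <= y0 + tp$band_below_fae, ,
                                drop = FALSE])
            guard <- guard + 1L
          }
          xy <- rbind(xy, cand[seq_len(nz[zi]), , drop = FALSE])
        } else if (tp$name == "Epithelial" && nrow(pocket_xy) > 0L) {
          ## avoid the pockets claimed by intraepithelial cells
          need <- nz[zi]; got <- matrix(0, 0, 2)
          guard <- 0L
          while (nrow(got) < need && guard < 200L) {
            cand <- sample_in_zone(zones, zname, need * 3L)
            d2 <- vapply(seq_len(nrow(cand)), function(i) {
              min((pocket_xy[, 1] - cand[i, 1])^2 +
                    (pocket_xy[, 2] - cand[i, 2])^2 - pocket_r^2)
            }, numeric(1))
            got <- rbind(got, cand[d2 >= 0, , drop = FALSE])
            guard <- guard + 1L
          }
          if (nrow(got) < need) stop("epithelium does not fit around ",
                                     "intraepithelial pockets", call. = FALSE)
          xy <- rbind(xy, got[seq_len(need), , drop = FALSE])
        } else {
          xy <- rbind(xy, sample_in_zone(zones, zname, nz[zi]))
        }
      }
      if (!is.null(tp$epithelial_exclusion)) {
        pocket_xy <- rbind(pocket_xy, xy)
        pocket_r <- c(pocket_r, rep(tp$epithelial_exclusion, nrow(xy)))
      }
      pos[[tp$name]] <- xy
      type_of[[tp$name]] <- rep(tp$name, n)
    }
    type <- unlist(type_of, use.names = FALSE)
    xy <- do.call(rbind, pos)
    n_total <- length(type)
    cell_id <- paste0(roi_id, "_c", seq_len(n_total))
    zone <- zone_assign(xy, zones)

    ## true transformed intensities
    lev <- prof[type, , drop = FALSE]
    ## context-dependent DNASE1L3 / microbicide positivity for myeloid cells
    dnase_pos <- rep(FALSE, n_total)
    mac <- type == "MacDC"
    if (any(mac)) {
      p <- ifelse(zone[mac] == "SED", ic$dnase1l3_pos[["SED"]],
                  ic$dnase1l3_pos[["other"]])
      dnase_pos[mac] <- stats::runif(sum(mac)) < p
      lev[mac, "DNASE1L3"] <- ifelse(dnase_pos[mac], 2, 0)
      pm <- ifelse(zone[mac] == "SED", ic$microbicide_pos[["SED"]],
                   ic$microbicide_pos[["other"]])
      lyso <- dnase_pos[mac] & (stats::runif(sum(mac)) < pm)
      nox <- dnase_pos[mac] & (stats::runif(sum(mac)) < pm)
      lev[mac, "Lysozyme"] <- ifelse(lyso, 2, 0)
      lev[mac, "NOX2"] <- ifelse(nox, 1, 0)
    }
    ## DNA channels positive for intact cells
    lev[, "DNA1"] <- 2; lev[, "DNA2"] <- 2
    debris <- stats::runif(n_total) < ic$debris_frac
    lev[debris, "DNA1"] <- 0; lev[debris, "DNA2"] <- 0

    raw_true <- matrix(0, n_total, length(channels),
                       dimnames = list(NULL, channels))
    for (j in seq_along(channels)) {
      raw_true[, j] <- draw_marker_raw(lev[, j], ic$separation)
    }
    true_tf <- arcsinh_transform(raw_true, config$cofactor)
    shift <- if (ic$batch_sd > 0) {
      with_stream(config$seed, paste0("batch_", roi_id),
                  stats::rnorm(length(channels), 0, ic$batch_sd))
    } else rep(0, length(channels))
    shifted <- sweep(true_tf, 2L, shift, "+")
    observed <- apply_spillover(inv_arcsinh(shifted, config$cofactor),
                                ic$spillover)
    dimnames(observed) <- list(NULL, channels)
    area <- pmax(1, round(stats::rlnorm(n_total, ic$area_meanlog,
                                        ic$area_sdlog)))
    meta <- data.frame(cell_id = cell_id, roi = roi_id,
                       x = xy[, 1], y = xy[, 2], area_px = area,
                       stringsAsFactors = FALSE)
    gt <- data.frame(cell_id = cell_id, type = type,
                     lineage = vapply(ic$types, function(t) t$lineage,
                                      character(1))[
                       match(type, vapply(ic$types, function(t) t$name,
                                          character(1)))],
                     subset = vapply(ic$types, function(t) t$subset,
                                     character(1))[
                       match(type, vapply(ic$types, function(t) t$name,
                                          character(1)))],
                     zone = zone, dnase1l3_pos = dnase_pos,
                     debris = debris, stringsAsFactors = FALSE)
    list(cells = cell_table(meta, observed, layers = list(true = true_tf)),
         zones = zones, ground_truth = gt, batch_shift = shift)
  })
}

#' Simulate a cohort of IMC ROIs
#'
#' @param config A [sim_config()].
#' @param n_roi Number of ROIs; each gets its own RNG stream and batch shift.
#' @return List of [simulate_imc_roi()] results, plus a `combined`
#'   convenience element binding all cells and ground truth.
#' @export
simulate_imc_cohort <- function(config, n_roi = 4L) {
  rois <- lapply(seq_len(n_roi), function(i) {
    simulate_imc_roi(config, roi_id = sprintf("ROI%02d", i))
  })
  names(rois) <- vapply(rois, function(r) r$cells$meta$roi[1], character(1))
  meta <- do.call(rbind, lapply(rois, function(r) r$cells$meta))
  raw <- do.call(rbind, lapply(rois, function(r) intensity_layer(r$cells)))
  true <- do.call(rbind, lapply(rois, function(r)
    intensity_layer(r$cells, "true")))
  rownames(meta) <- NULL
  gt <- do.call(rbind, lapply(rois, function(r) r$ground_truth))
  rownames(gt) <- NULL
  list(rois = rois,
       combined = list(cells = cell_table(meta, raw,
                                          layers = list(true = true)),
                       ground_truth = gt,
                       zones = rois[[1]]$zones))
}

# --- spot generator ---------------------------------------------------------

hex_coordinates <- function(nrow, ncol, pitch) {
  g <- expand.grid(col = seq_len(ncol) - 1L, row = seq_len(nrow) - 1L)
  x <- g$col * pitch + (g$row %% 2L) * pitch / 2
  y <- g$row * pitch * sqrt(3) / 2
  data.frame(row = g$row, col = g$col, x = x, y = y)
}

# Deterministic per-gene baselines shared by all samples of one config.
spot_gene_table <- function(config) {
  pc <- config$spots
  prog_genes <- unique(unlist(lapply(pc$programmes, names)))
  filler <- unlist(lapply(names(pc$programmes), function(z) {
    paste0("PRG.", z, ".", seq_len(pc$n_programme_filler))
  }))
  nulls <- sprintf("NULL%03d", seq_len(pc$n_null_genes))
  genes <- c(prog_genes, filler, nulls)
  fc <- matrix(1, length(genes), length(pc$programmes),
               dimnames = list(genes, names(pc$programmes)))
  for (z in names(pc$programmes)) {
    fc[names(pc$programmes[[z]]), z] <- pc$programmes[[z]]
    fc[paste0("PRG.", z, ".", seq_len(pc$n_programme_filler)), z] <-
      pc$filler_fc
  }
  base <- with_stream(config$seed, "spot_genes",
                      stats::rlnorm(length(genes), pc$base_meanlog,
                                    pc$base_sdlog))
  ## programme genes carry a fixed moderate baseline so differential-
  ## expression strength is ordered by the configured fold changes (the
  ## tissue fact the programmes encode: DNASE1L3, at the largest SED fold
  ## change, is the top subepithelial-dome marker); null genes keep random
  ## baselines
  base[seq_len(length(prog_genes) + length(filler))] <- pc$programme_base
  list(genes = genes, base = stats::setNames(base, genes), fc = fc)
}

#' Simulate a Visium-like spot sample over the follicle geometry
#'
#' Spots sit on a hex (or square) lattice; each spot's zone comes from the
#' scaled follicle geometry, its expected expression from per-zone gene
#' programmes over a shared baseline, and its counts from a negative binomial
#' with spot-specific library size. Sample `"STB"` additionally carries a
#' gene-wise lognormal batch factor so two-sample integration can be tested.
#'
#' @param config A [sim_config()].
#' @param sample_id `"STA"`, `"STB"`, or any label (labels other than
#'   `"STA"` get their own batch factor).
#' @return List with `counts` (genes x spots integer matrix), `spots`
#'   (data.frame: spot_id, row, col, x, y, sample), `genes` (data.frame with
#'   per-zone fold changes), and `ground_truth` (true zone per spot).
#' @export
simulate_spot_sample <- function(config, sample_id = "STA") {
  stopifnot(inherits(config, "sim_config"))
  pc <- config$spots
  if (any(unlist(lapply(pc$programmes, unname)) <= 0)) {
    stop("programme fold changes must be positive", call. = FALSE)
  }
  coords <- if (pc$lattice == "hex") {
    hex_coordinates(pc$nrow, pc$ncol, pc$pitch)
  } else {
    g <- expand.grid(col = seq_len(pc$ncol) - 1L, row = seq_len(pc$nrow) - 1L)
    data.frame(row = g$row, col = g$col, x = g$col * pc$pitch,
               y = g$row * pc$pitch)
  }
  zones <- default_zone_map(max(coords$x) + pc$pitch,
                            max(coords$y) + pc$pitch)
  zone <- zone_assign(as.matrix(coords[, c("x", "y")]), zones)
  ## spots outside every named zone behave like lamina propria background
  zone_eff <- ifelse(zone == "other", "lamina_propria", zone)
  gt <- spot_gene_table(config)
  batch <- if (sample_id == "STA") rep(1, length(gt$genes)) else {
    with_stream(config$seed, paste0("spot_batch_", sample_id),
                stats::rlnorm(length(gt$genes), 0, pc$batch_sdlog))
  }
  with_stream(config$seed, paste0("spots_", sample_id), {
    n_spot <- nrow(coords)
    lib <- stats::rlnorm(n_spot, 0, pc$libsize_sdlog)
    lib[zone_eff == "lumen"] <- lib[zone_eff == "lumen"] * pc$lumen_lib_factor
    zi <- match(zone_eff, colnames(gt$fc))
    if (anyNA(zi)) stop("zone(s) without a gene programme: ",
                        paste(unique(zone_eff[is.na(zi)]), collapse = ", "),
                        call. = FALSE)
    fcmat <- gt$fc[, zi, drop = FALSE]
    ## the dome programme decays smoothly into the follicle below (complement
    ## and DNASE1L3 are also seen at the follicle periphery), giving the
    ## co-programmed genes a graded shared spatial profile
    if (pc$sed_gradient_tau > 0) {
      sed_genes <- gt$genes[gt$fc[, "SED"] > 1]
      fae_bot <- max(zones$zones[["FAE"]][, 2])
      grad <- exp(-pmax(0, coords$y - fae_bot) / pc$sed_gradient_tau)
      fc_sed <- gt$fc[sed_genes, "SED"]
      fcmat[sed_genes, ] <- pmax(fcmat[sed_genes, , drop = FALSE],
                                 1 + outer(fc_sed - 1, grad))
    }
    mu <- (gt$base * batch) * fcmat
    ## the dome programme is carried by a mobile dendritic-cell population
    ## whose per-spot abundance fluctuates strongly; all its genes share one
    ## mean-one lognormal abundance factor (stronger inside the dome,
    ## milder in the background), so the co-expressed DNASE1L3/complement
    ## set co-fluctuates beyond the zone pattern. Structural zone programmes
    ## (B-follicle, GC, T zone, epithelium) are stable.
    if (pc$activity_sdlog > 0) {
      gs <- which(gt$fc[, "SED"] > 1)
      if (length(gs)) {
        sdv <- ifelse(zone_eff %in% c("SED", "FAE"), pc$activity_sdlog,
                      pc$activity_bg_sdlog)
        act <- stats::rlnorm(n_spot, -sdv^2 / 2, sdv)
        mu[gs, ] <- sweep(mu[gs, , drop = FALSE], 2L, act, "*")
      }
    }
    mu <- sweep(mu, 2L, lib, "*")
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / pc$dispersion),
                     length(gt$genes), n_spot,
                     dimnames = list(gt$genes,
                                     paste0(sample_id, "_s",
                                            seq_len(n_spot))))
    spots <- data.frame(spot_id = colnames(counts), coords,
                        sample = sample_id, stringsAsFactors = FALSE)
    list(counts = counts, spots = spots,
         genes = data.frame(gene = gt$genes, base_mean = gt$base,
                            gt$fc, check.names = FALSE),
         ground_truth = data.frame(spot_id = spots$spot_id, zone = zone_eff,
                                   stringsAsFactors = FALSE),
         zones = zones)
  })
}

#' Simulate a lattice of spots with a fixed number of expression programmes
#'
#' A calibration generator for cluster-number recovery: the lattice is split
#' into `n_programs` contiguous column bands of near-equal size, each with
#' its own set of marker genes at a common fold change over a negative-
#' binomial baseline. Unlike the tissue generator, programmes are balanced in
#' prominence, which is the regime in which an elbow criterion can identify
#' the programme count.
#'
#' @param seed Integer seed.
#' @param n_programs Number of spatial programmes.
#' @param nrow,ncol Lattice dimensions (hex).
#' @param genes_per_program Marker genes per programme.
#' @param n_null Additional programme-free genes.
#' @param fc Marker fold change.
#' @param base_meanlog,base_sdlog Baseline lognormal parameters.
#' @param dispersion NB overdispersion.
#' @param libsize_sdlog Spot library-size lognormal sd.
#' @return List with `counts`, `spots` (row/col/x/y), `zone` (true
#'   programme per spot).
#' @export
simulate_program_lattice <- function(seed = 1L, n_programs = 7L,
                                     nrow = 24L, ncol = 24L,
                                     genes_per_program = 8L, n_null = 60L,
                                     fc = 4, base_meanlog = 0.7,
                                     base_sdlog = 0.6, dispersion = 0.2,
                                     libsize_sdlog = 0.3) {
  coords <- hex_coordinates(nrow, ncol, 100)
  zone <- 1L + pmin(n_programs - 1L,
                    floor(coords$col / (ncol / n_programs)))
  n_genes <- n_programs * genes_per_program + n_null
  gene <- c(paste0("PRG", rep(seq_len(n_programs),
                              each = genes_per_program), ".",
                   rep(seq_len(genes_per_program), n_programs)),
            sprintf("NULL%03d", seq_len(n_null)))
  prog_of_gene <- c(rep(seq_len(n_programs), each = genes_per_program),
                    rep(0L, n_null))
  with_stream(seed, "program_lattice", {
    base <- stats::rlnorm(n_genes, base_meanlog, base_sdlog)
    lib <- stats::rlnorm(nrow(coords), 0, libsize_sdlog)
    fcm <- 1 + (fc - 1) * outer(prog_of_gene, zone, "==")
    mu <- sweep(base * fcm, 2L, lib, "*")
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / dispersion),
                     n_genes, nrow(coords),
                     dimnames = list(gene, paste0("s", seq_len(nrow(coords)))))
    list(counts = counts,
         spots = data.frame(spot_id = colnames(counts), coords),
         zone = zone)
  })
}

# --- colocalization raster generator ---------------------------------------

#' Simulate a two-channel raster with a known overlap fraction
#'
#' Channel B is a large reference disc; channel A consists of small signal
#' blobs, a requested fraction of which fall entirely inside the reference
#' mask and the rest entirely outside (blob centres are placed with a
#' minimum-separation rule so same-side blobs do not merge). The ground-truth
#' overlap fraction is measured by pixel counting on the generated masks.
#'
#' @param config A [sim_config()].
#' @param overlap Requested fraction of channel-A signal pixels inside the
#'   channel-B mask, in `[0, 1]`.
#' @return List with `channels` (named list of intensity matrices `A`, `B`),
#'   `masks` (the true binary masks) and `ground_truth` (realised fraction).
#' @export
simulate_coloc_raster <- function(config, overlap = 0.3) {
  stopifnot(inherits(config, "sim_config"))
  if (overlap < 0 || overlap > 1) stop("overlap must be in [0, 1]",
                                       call. = FALSE)
  cc <- config$coloc
  h <- cc$dim[1]; w <- cc$dim[2]
  r <- cc$blob_radius
  ctr <- c(h / 2, w / 2)
  R <- cc$reference_radius
  if (R + 4 * r >= min(h, w) / 2) stop("raster too small for requested blobs",
                                       call. = FALSE)
  with_stream(config$seed, sprintf("coloc_%.4f", overlap), {
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    d2ctr <- (rows - ctr[1])^2 + (cols - ctr[2])^2
    mask_b <- d2ctr <= R^2
    n_in <- round(overlap * cc$n_blobs)
    n_out <- cc$n_blobs - n_in
    place <- function(n, inside) {
      centres <- matrix(0, 0, 2)
      guard <- 0L
      while (nrow(centres) < n && guard < 5000L) {
        cand <- c(stats::runif(1, r + 2, h - r - 1),
                  stats::runif(1, r + 2, w - r - 1))
        d <- sqrt(sum((cand - ctr)^2))
        ok <- if (inside) d <= R - r - 1 else d >= R + r + 2
        if (ok && nrow(centres) > 0L) {
          ok <- min(colSums((t(centres) - cand)^2)) > (2 * r + 1)^2
        }
        if (ok) centres <- rbind(centres, cand)
        guard <- guard + 1L
      }
      if (nrow(centres) < n) stop("raster too small to place requested blobs",
                                  call. = FALSE)
      centres
    }
    centres <- rbind(if (n_in > 0L) place(n_in, TRUE),
                     if (n_out > 0L) place(n_out, FALSE))
    mask_a <- matrix(FALSE, h, w)
    if (cc$n_blobs > 0L && !is.null(centres)) {
      for (i in seq_len(nrow(centres))) {
        mask_a <- mask_a |
          ((rows - centres[i, 1])^2 + (cols - centres[i, 2])^2 <= r^2)
      }
    }
    A <- matrix(stats::rnorm(h * w, cc$background_mean, cc$background_sd),
                h, w)
    B <- matrix(stats::rnorm(h * w, cc$background_mean, cc$background_sd),
                h, w)
    A[mask_a] <- A[mask_a] + cc$blob_intensity
    B[mask_b] <- B[mask_b] + cc$blob_intensity
    frac <- if (sum(mask_a) == 0L) NaN else sum(mask_a & mask_b) / sum(mask_a)
    list(channels = list(A = A, B = B),
         masks = list(A = mask_a, B = mask_b),
         ground_truth = list(overlap = frac, requested = overlap))
  })
}
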
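#' Side of the regular hexagon with the same area as a circle
#'
#' The microcircuit cross-section is a regular hexagon chosen to have the
#' same area as the circle obtained from the dendritic-density analysis,
#' which facilitates gap-free tiling of multiple microcircuits.
#'
#' @param radius circle radius in micrometers (must be positive).
#' @return hexagon side length in micrometers, satisfying
#'   \eqn{(3\sqrt{3}/2) s^2 = \pi r^2}.
#' @examples
#' equal_area_hexagon_side(294) # ~323 um
#' @export
equal_area_hexagon_side <- function(radius) {
  if (!is.numeric(radius) || any(radius <= 0))
    stop("radius must be positive")
  sqrt(2 * pi / (3 * sqrt(3))) * radius
}

#' Area of a regular hexagon
#' @param side side length.
#' @return area in squared units of `side`.
#' @export
hexagon_area <- function(side) 3 * sqrt(3) / 2 * side^2

#' Build the hexagonal-prism microcircuit geometry
#'
#' The prism spans the ventral posterolateral nucleus (VPL, bottom slab)
#' and the reticular nucleus (Rt, top slab). The vertical axis is y, with
#' the origin at the center of the bottom face; all lengths are in
#' micrometers.
#'
#' @param hex_side hexagon side (um); default 323 (the printed value for a
#'   294-um equal-area circle).
#' @param vpl_height,rt_height slab heights (um); defaults 550 and 250.
#' @return an object of class `microcircuit_geometry` with volumes (mm^3)
#'   and slab boundaries.
#' @examples
#' g <- build_geometry()
#' g$volume_mm3 # ~0.22
#' @export
build_geometry <- function(hex_side = 323, vpl_height = 550, rt_height = 250) {
  if (hex_side <= 0 || vpl_height < 0 || rt_height < 0 ||
      vpl_height + rt_height <= 0)
    stop("lengths must be positive")
  area <- hexagon_area(hex_side)
  height <- vpl_height + rt_height
  g <- list(
    hex_side = hex_side,
    vpl_height = vpl_height,
    rt_height = rt_height,
    height = height,
    area_um2 = area,
    volume_mm3 = area * height * 1e-9,
    vpl_volume_mm3 = area * vpl_height * 1e-9,
    rt_volume_mm3 = area * rt_height * 1e-9
  )
  class(g) <- "microcircuit_geometry"
  g
}

#' @export
print.microcircuit_geometry <- function(x, ...) {
  cat(sprintf(
    "Hexagonal-prism microcircuit: side %.1f um, heights VPL %.0f / Rt %.0f um\n",
    x$hex_side, x$vpl_height, x$rt_height))
  cat(sprintf("  volume %.3f mm^3 (VPL %.3f, Rt %.3f)\n",
              x$volume_mm3, x$vpl_volume_mm3, x$rt_volume_mm3))
  invisible(x)
}

#' Classify points into microcircuit regions
#'
#' @param geom geometry from [build_geometry()].
#' @param x,y,z coordinates (um; y vertical).
#' @return character vector: "VPL", "Rt" or "outside".
#' @export
point_region <- function(geom, x, y, z) {
  inside <- cpp_in_hexagon(x, z, geom$hex_side)
  out <- rep("outside", length(x))
  out[inside & y >= 0 & y < geom$vpl_height] <- "VPL"
  out[inside & y >= geom$vpl_height & y <= geom$height] <- "Rt"
  out
}

#' Default cell-density specification
#'
#' Densities and identity fractions measured by cell counting:
#' 68,750 cells/mm^3 in Rt (all inhibitory reticular cells) and
#' 57,467 cells/mm^3 in VPL with 0.5% local interneurons. Electrical-type
#' fractions: Rt_RC 57% cAD_ltb / 43% cNAD_ltb, VPL_TC 64% / 36%, VPL_IN
#' all bAC.
#'
#' @param density_scale global multiplier applied to all densities (1 =
#'   full scale; desk-scale experiments use 0.1).
#' @return a list with per-region densities (cells/mm^3), identity
#'   fractions, and the jitter fraction (0.05).
#' @export
density_spec <- function(density_scale = 1) {
  list(
    density = c(Rt = 68750, VPL = 57467) * density_scale,
    density_scale = density_scale,
    inhibitory_fraction = c(Rt = 1.0, VPL = 0.005),
    etype_fractions = list(
      Rt_RC = c(cAD_ltb = 0.57, cNAD_ltb = 0.43),
      VPL_TC = c(cAD_ltb = 0.64, cNAD_ltb = 0.36),
      VPL_IN = c(bAC = 1.0)
    ),
    jitter_fraction = 0.05
  )
}

# min distance for Poisson-disc sampling from density (cells/um^3):
# (k / d)^(1/3) with k = 0.5
.poisson_min_distance <- function(density_mm3, k = 0.5) {
  (k / (density_mm3 * 1e-9))^(1 / 3)
}

#' Place somata by Poisson-disc sampling
#'
#' Populates each region slab with soma positions such that no two somata
#' are closer than the region's minimum distance, derived from the target
#' density d (cells/um^3) as (0.5 / d)^(1/3). Per instance, densities are
#' jittered uniformly in +/- `jitter_fraction` (independently per region).
#'
#' @param geom geometry from [build_geometry()].
#' @param spec density specification from [density_spec()].
#' @param jitter apply the density jitter? (default TRUE).
#' @param seed integer seed.
#' @return data.frame with columns id, x, y, z, region.
#' @export
place_somata <- function(geom, spec = density_spec(), jitter = TRUE,
                         seed = 1) {
  set.seed(seed)
  slabs <- list(VPL = c(0, geom$vpl_height),
                Rt = c(geom$vpl_height, geom$height))
  out <- list()
  for (region in names(slabs)) {
    d0 <- spec$density[[region]]
    if (is.null(d0) || d0 <= 0) next
    jf <- if (jitter) stats::runif(1, -spec$jitter_fraction,
                                   spec$jitter_fraction) else 0
    d <- d0 * (1 + jf)
    vol_mm3 <- geom$area_um2 * diff(slabs[[region]]) * 1e-9
    n_target <- round(d * vol_mm3)
    if (n_target == 0) next
    # min distance from the unjittered, unscaled-per-instance density
    mind <- .poisson_min_distance(d)
    pts <- cpp_poisson_disc_hex(geom$hex_side, slabs[[region]][1],
                                slabs[[region]][2], n_target, mind,
                                200L, sample.int(.Machine$integer.max, 1))
    if (nrow(pts) < n_target)
      warning(sprintf(
        "region %s: placed %d of %d requested somata before exhausting retries",
        region, nrow(pts), n_target))
    out[[region]] <- data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                                region = region)
  }
  nodes <- do.call(rbind, out)
  rownames(nodes) <- NULL
  nodes <- cbind(id = seq_len(nrow(nodes)), nodes)
  nodes
}

#' Assign m-types, e-types and rotations to placed somata
#'
#' Rt somata are all reticular cells (Rt_RC); VPL somata are local
#' interneurons (VPL_IN) with the configured inhibitory fraction (0.5%)
#' and thalamocortical relay cells (VPL_TC) otherwise. E-types are sampled
#' from the per-m-type fractions and each cell receives a uniform random
#' rotation about the vertical (y) axis.
#'
#' @param nodes placement table from [place_somata()].
#' @param spec density specification.
#' @param seed integer seed.
#' @return `nodes` with added columns mtype, etype, rotation.
#' @export
assign_identities <- function(nodes, spec = density_spec(), seed = 1) {
  set.seed(seed + 1e6)
  for (fr in spec$etype_fractions)
    if (abs(sum(fr) - 1) > 1e-8)
      stop("e-type fractions must sum to 1")
  n <- nrow(nodes)
  mtype <- character(n)
  mtype[nodes$region == "Rt"] <- "Rt_RC"
  vpl <- which(nodes$region == "VPL")
  is_in <- stats::runif(length(vpl)) < spec$inhibitory_fraction[["VPL"]]
  mtype[vpl] <- ifelse(is_in, "VPL_IN", "VPL_TC")
  etype <- character(n)
  for (mt in unique(mtype)) {
    idx <- which(mtype == mt)
    fr <- spec$etype_fractions[[mt]]
    etype[idx] <- sample(names(fr), length(idx), replace = TRUE, prob = fr)
  }
  nodes$mtype <- mtype
  nodes$etype <- etype
  nodes$rotation <- stats::runif(n, 0, 2 * pi)
  nodes
}

#' Assign morphologies to placed cells
#'
#' Each cell is assigned a morphology from the per-m-type pool whose
#' annotated vertical spans, translated to the soma position, fall inside
#' the required slab. Scoring is binary: a morphology is feasible (score
#' 1) if the annotation constraints hold, infeasible otherwise (score 0);
#' among feasible morphologies one is chosen uniformly at random.
#'
#' Constraints: the Rt-collateral span of a VPL_TC axon must lie in the Rt
#' slab; the dense-axon span of an Rt_RC must lie in the VPL slab; a
#' VPL_IN morphology must be contained in the VPL; an Rt_RC morphology may
#' not exceed the top circuit boundary by more than `rt_top_tolerance`.
#'
#' @param nodes identity table from [assign_identities()].
#' @param pool named list of morphology pools, one list of
#'   [morphology][generate_morphology] objects per m-type.
#' @param geom geometry.
#' @param rt_top_tolerance tolerance (um) for Rt morphologies exceeding
#'   the top boundary; default 30.
#' @param seed integer seed.
#' @return `nodes` with added column morphology (index into the m-type
#'   pool; NA and a warning for cells with no feasible morphology).
#' @export
place_morphology <- function(nodes, pool, geom, rt_top_tolerance = 30,
                             seed = 1) {
  set.seed(seed + 2e6)
  nodes$morphology <- NA_integer_
  dropped <- 0L
  spans <- lapply(pool, function(ms) lapply(ms, morphology_spans))
  for (i in seq_len(nrow(nodes))) {
    mt <- nodes$mtype[i]
    cand <- spans[[mt]]
    if (is.null(cand)) next
    y0 <- nodes$y[i]
    feas <- vapply(cand, function(sp) {
      .placement_feasible(sp, mt, y0, geom, rt_top_tolerance)
    }, logical(1))
    if (!any(feas)) {
      dropped <- dropped + 1L
      next
    }
    feas_idx <- which(feas)
    nodes$morphology[i] <- feas_idx[sample.int(length(feas_idx), 1)]
  }
  if (dropped > 0)
    warning(sprintf("%d cells had no feasible morphology and were flagged (morphology = NA)",
                    dropped))
  nodes
}

# vertical placement feasibility for one morphology at soma height y0
.placement_feasible <- function(sp, mtype, y0, geom, tol) {
  if (mtype == "VPL_TC") {
    if (is.null(sp$rt_collaterals)) return(FALSE)
    lo <- y0 + sp$rt_collaterals[1]
    hi <- y0 + sp$rt_collaterals[2]
    lo >= geom$vpl_height && hi <= geom$height
  } else if (mtype == "Rt_RC") {
    if (is.null(sp$dense_axon_arbor)) return(FALSE)
    lo <- y0 + sp$dense_axon_arbor[1]
    hi <- y0 + sp$dense_axon_arbor[2]
    top <- y0 + sp$full[2]
    lo >= 0 && hi <= geom$vpl_height && top <= geom$height + tol
  } else { # VPL_IN: entire morphology inside the VPL
    lo <- y0 + sp$full[1]
    hi <- y0 + sp$full[2]
    lo >= 0 && hi <= geom$vpl_height
  }
}
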
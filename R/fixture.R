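#' Build a complete miniature circuit end to end
#'
#' Runs the full pipeline at a reduced density scale: geometry,
#' Poisson-disc soma placement, identity assignment, synthetic
#' morphology pools (with placement rules), apposition detection,
#' pathway filtering, bouton-density pruning, gap-junction prediction,
#' afferent synapse construction and network assembly. The result is an
#' executable network plus all intermediate tables, used by integration
#' tests and the desk-scale experiments.
#'
#' Volumetric afferent bouton densities are configuration placeholders
#' (the source values are figure data): the CT default reproduces the
#' order of the printed full-scale CT synapse count, while the ML
#' default is set higher than the printed lemniscal count so that relay
#' cells receive enough driver input for sustained asynchronous firing
#' at desk scale; both scale with `density_scale` so per-cell afferent
#' input is density-invariant.
#'
#' @param density_scale fraction of the measured cell densities
#'   (default 0.1, the desk-scale operating point).
#' @param seed integer seed controlling every stage.
#' @param pool_size morphologies per m-type pool.
#' @param gj_retention fraction of dendrodendritic appositions kept as
#'   gap junctions (used when `gj_divergence_target` is NULL).
#' @param gj_divergence_target mean number of gap-junction-coupled
#'   partners per Rt cell that the retention is tuned to (default 11,
#'   the midpoint of the experimentally reported 2-20 range); set NULL
#'   to use the fixed retention.
#' @param with_afferents build ML/CT afferents?
#' @param g_compensation compensate synaptic conductances by
#'   1/density_scale?
#' @param geom circuit geometry.
#' @return list with nodes, pools, synapses, gap junctions, afferents,
#'   axon lengths, and the assembled `network`.
#' @export
make_fixture_circuit <- function(density_scale = 0.1, seed = 1,
                                 pool_size = 8, gj_retention = 0.3,
                                 gj_divergence_target = 11,
                                 with_afferents = TRUE,
                                 g_compensation = TRUE,
                                 geom = build_geometry()) {
  spec <- density_spec(density_scale)
  nodes <- place_somata(geom, spec, seed = seed)
  nodes <- assign_identities(nodes, spec, seed = seed)
  pools <- list(
    Rt_RC = morphology_pool("Rt_RC", pool_size, geom, seed = seed + 11),
    VPL_TC = morphology_pool("VPL_TC", pool_size, geom, seed = seed + 22),
    VPL_IN = morphology_pool("VPL_IN", pool_size, geom, seed = seed + 33))
  nodes <- place_morphology(nodes, pools, geom, seed = seed)
  nodes <- nodes[!is.na(nodes$morphology), ]

  circ <- circuit_segments(nodes, pools)
  apps <- filter_touches(detect_touches(circ, kind = "chemical"))
  syn <- prune_to_constraints(apps, circ$axon_length, seed = seed)
  dendro <- detect_touches(circ, kind = "dendrodendritic")
  gj <- predict_gap_junctions(dendro, retention = gj_retention,
                              seed = seed,
                              divergence_target = gj_divergence_target)

  afferents <- list()
  if (with_afferents) {
    afferents$ML <- build_afferent_synapses(
      circ, nodes, geom, "ML",
      volumetric_density = 4e-4 * density_scale,
      n_fibers = max(10, round(2601 * density_scale)), seed = seed + 44)
    afferents$CT <- build_afferent_synapses(
      circ, nodes, geom, "CT",
      volumetric_density = 1.88e-4 * density_scale,
      n_fibers = max(10, round(75325 * density_scale)), seed = seed + 55)
  }

  net <- build_network(nodes, syn, gj, afferents,
                       density_scale = density_scale,
                       g_compensation = g_compensation, seed = seed)
  list(nodes = nodes, pools = pools, segments = circ, appositions = apps,
       synapses = syn, dendro_appositions = dendro, gap_junctions = gj,
       afferents = afferents, network = net, geom = geom,
       density_scale = density_scale, seed = seed,
       manifest = run_manifest(seed, list(density_scale = density_scale,
                                          pool_size = pool_size)))
}
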
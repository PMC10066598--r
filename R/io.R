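#' Read a morphology from an SWC file
#'
#' Standard 7-column SWC (id, type, x, y, z, radius, parent). An optional
#' sidecar annotation table `<path>.annotations.tsv` (columns
#' annotation, node_id) is loaded when present.
#'
#' @param path SWC file path.
#' @param mtype optional m-type label.
#' @return a `morphology`.
#' @export
read_swc <- function(path, mtype = NA_character_) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) stop("no data lines in ", path)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(fields) != 7)
  if (length(bad))
    stop(sprintf("malformed SWC line %d in %s", which(keep)[bad[1]], path))
  m <- matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE)
  if (anyNA(m))
    stop("non-numeric field in ", path)
  nodes <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                      x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
                      parent = as.integer(m[, 7]))
  miss <- nodes$parent != -1 & !(nodes$parent %in% nodes$id)
  if (any(miss))
    stop(sprintf("malformed parent id at SWC line %d in %s",
                 which(keep)[which(miss)[1]], path))
  ann <- list()
  apath <- paste0(path, ".annotations.tsv")
  if (file.exists(apath)) {
    at <- utils::read.delim(apath, stringsAsFactors = FALSE)
    ann <- split(at$node_id, at$annotation)
  }
  out <- new_morphology(nodes, ann, mtype)
  validate_morphology(out)
  out
}

#' Write a morphology to an SWC file (with annotation sidecar)
#' @param m morphology.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_swc <- function(m, path) {
  n <- m$nodes
  con <- file(path, "w")
  writeLines("# SWC export (id type x y z radius parent)", con)
  writeLines(sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                     n$id, n$type, n$x, n$y, n$z, n$radius, n$parent), con)
  close(con)
  if (length(m$annotations)) {
    at <- do.call(rbind, lapply(names(m$annotations), function(a)
      data.frame(annotation = a, node_id = m$annotations[[a]])))
    utils::write.table(at, paste0(path, ".annotations.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Write circuit node and edge tables
#'
#' SONATA-convention plain-text tables: `<dir>/nodes.csv` with columns
#' id, x, y, z, rotation_angle_yaxis, mtype, etype, morphology, region;
#' `<dir>/edges.csv` with source/target ids, synapse location and
#' pathway metadata; `<dir>/gap_junctions.csv` when present.
#'
#' @param nodes cell table.
#' @param edges synapse table (may be NULL).
#' @param path output directory (created if needed).
#' @param gj gap-junction table (may be NULL).
#' @return `path` invisibly.
#' @export
write_circuit <- function(nodes, edges = NULL, path, gj = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  nd <- nodes
  names(nd)[names(nd) == "rotation"] <- "rotation_angle_yaxis"
  utils::write.csv(nd, file.path(path, "nodes.csv"), row.names = FALSE)
  if (!is.null(edges))
    utils::write.csv(edges, file.path(path, "edges.csv"), row.names = FALSE)
  if (!is.null(gj))
    utils::write.csv(gj, file.path(path, "gap_junctions.csv"),
                     row.names = FALSE)
  invisible(path)
}

#' Read circuit tables written by [write_circuit()]
#' @param path circuit directory.
#' @return list(nodes, edges, gj); edge/gj NULL when absent.
#' @export
read_circuit <- function(path) {
  nodes <- utils::read.csv(file.path(path, "nodes.csv"),
                           stringsAsFactors = FALSE)
  names(nodes)[names(nodes) == "rotation_angle_yaxis"] <- "rotation"
  edges <- NULL
  ef <- file.path(path, "edges.csv")
  if (file.exists(ef)) {
    edges <- utils::read.csv(ef, stringsAsFactors = FALSE)
    dangling <- !(edges$pre %in% c(nodes$id, -seq_len(1e6))) &
      edges$pre > 0 | !(edges$post %in% nodes$id)
    if (any(!(edges$post %in% nodes$id)) ||
        any(edges$pre > 0 & !(edges$pre %in% nodes$id)))
      stop("dangling edge reference in ", ef)
  }
  gj <- NULL
  gf <- file.path(path, "gap_junctions.csv")
  if (file.exists(gf)) gj <- utils::read.csv(gf, stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges, gj = gj)
}

#' Run manifest
#'
#' Records seeds, package version and stage parameters so a run can be
#' reproduced bit-identically.
#' @param seed master seed.
#' @param stages named list of per-stage parameter lists.
#' @return a `run_manifest`.
#' @export
run_manifest <- function(seed, stages = list()) {
  structure(list(
    package = "thalamosim",
    version = as.character(utils::packageVersion("thalamosim")),
    seed = seed, stages = stages,
    timestamp = format(Sys.time(), tz = "UTC")),
    class = "run_manifest")
}
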
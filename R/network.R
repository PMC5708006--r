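# Road-network travel times and Patient Access Areas (PAAs). Mesh centroids
# and hospital locations are snapped to their nearest network node; shortest
# travel times come from Dijkstra on the edge minutes; a PAA is the
# threshold-bounded access set read off the travel-time matrix in both
# directions (hospitals reachable from a mesh, meshes served by a hospital).

#' Construct a road network
#'
#' @param nodes `data.frame` with columns `node_id`, `x`, `y` (meters,
#'   planar projected CRS).
#' @param edges `data.frame` with columns `node_a`, `node_b`, `minutes`
#'   (undirected edges, positive finite travel minutes). The graph may be
#'   disconnected; disconnection is meaningful (inaccessible meshes).
#' @return an object of class `paam_network`.
#' @export
road_network <- function(nodes, edges) {
  need_n <- c("node_id", "x", "y")
  need_e <- c("node_a", "node_b", "minutes")
  if (length(setdiff(need_n, names(nodes))))
    stop("nodes need columns node_id, x, y", call. = FALSE)
  if (length(setdiff(need_e, names(edges))))
    stop("edges need columns node_a, node_b, minutes", call. = FALSE)
  nodes$node_id <- as.character(nodes$node_id)
  edges$node_a <- as.character(edges$node_a)
  edges$node_b <- as.character(edges$node_b)
  if (anyDuplicated(nodes$node_id)) stop("duplicate node ids", call. = FALSE)
  if (any(!is.finite(nodes$x)) || any(!is.finite(nodes$y)))
    stop("node coordinates must be finite", call. = FALSE)
  if (nrow(edges) > 0 &&
      (anyNA(edges$minutes) || any(!is.finite(edges$minutes)) ||
       any(edges$minutes <= 0)))
    stop("edge minutes must be positive and finite", call. = FALSE)
  unknown <- setdiff(c(edges$node_a, edges$node_b), nodes$node_id)
  if (length(unknown))
    stop("edges reference unknown nodes: ",
         paste(head(unknown, 3), collapse = ", "), call. = FALSE)
  structure(list(nodes = nodes[, need_n], edges = edges[, need_e]),
            class = "paam_network")
}

#' @export
print.paam_network <- function(x, ...) {
  cat(sprintf("Road network: %d nodes, %d undirected edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    d = data.frame(from = network$edges$node_a, to = network$edges$node_b,
                   weight = network$edges$minutes),
    directed = FALSE,
    vertices = data.frame(name = network$nodes$node_id)
  )
}

#' Shortest travel time between network nodes
#'
#' Minimum total minutes over all paths; `Inf` when no path exists.
#'
#' @param network a `paam_network`.
#' @param from,to node id vectors.
#' @return matrix of minutes (`length(from)` x `length(to)`); a single
#'   number when both are scalars.
#' @export
shortest_travel_time <- function(network, from, to) {
  stopifnot(inherits(network, "paam_network"))
  unknown <- setdiff(c(from, to), network$nodes$node_id)
  if (length(unknown))
    stop("unknown node id: ", paste(unknown, collapse = ", "), call. = FALSE)
  g <- as_igraph(network)
  d <- igraph::distances(g, v = unique(from), to = unique(to),
                         mode = "all", algorithm = "dijkstra")
  out <- d[match(from, unique(from)), match(to, unique(to)), drop = FALSE]
  dimnames(out) <- list(from, to)
  if (length(from) == 1 && length(to) == 1) out[1, 1] else out
}

# nearest network node for each point; ties broken by lowest node id
snap_to_nodes <- function(network, x, y) {
  ord <- order(network$nodes$node_id)
  nx <- network$nodes$x[ord]
  ny <- network$nodes$y[ord]
  ids <- network$nodes$node_id[ord]
  vapply(seq_along(x), function(i) {
    d2 <- (nx - x[i])^2 + (ny - y[i])^2
    ids[which.min(d2)]  # which.min takes the first (lowest id) on ties
  }, character(1))
}

#' Build the mesh-by-hospital travel-time matrix
#'
#' In `network` mode every mesh centroid and hospital location snaps to its
#' nearest network node (Euclidean, ties to the lowest node id) and the
#' entry is the shortest network time between the snapped nodes. In `direct`
#' mode the network is bypassed and the entry is the straight-line distance
#' divided by `speed_kmh`.
#'
#' @param meshes a mesh table.
#' @param hospitals a hospital table.
#' @param network a `paam_network` (required in network mode).
#' @param mode `"network"` or `"direct"`.
#' @param speed_kmh travel speed for direct mode.
#' @return numeric matrix of minutes, mesh ids x hospital ids, `Inf` where
#'   unreachable.
#' @export
build_travel_matrix <- function(meshes, hospitals, network = NULL,
                                mode = c("network", "direct"),
                                speed_kmh = 40) {
  mode <- match.arg(mode)
  if (nrow(meshes) == 0 || nrow(hospitals) == 0)
    stop("meshes and hospitals must be non-empty", call. = FALSE)
  if (mode == "direct") {
    m <- outer(seq_len(nrow(meshes)), seq_len(nrow(hospitals)),
               function(i, j) {
                 sqrt((meshes$x[i] - hospitals$x[j])^2 +
                        (meshes$y[i] - hospitals$y[j])^2) / 1000 /
                   speed_kmh * 60
               })
  } else {
    if (is.null(network) || nrow(network$nodes) == 0)
      stop("network mode requires a non-empty road network", call. = FALSE)
    mesh_nodes <- snap_to_nodes(network, meshes$x, meshes$y)
    hosp_nodes <- snap_to_nodes(network, hospitals$x, hospitals$y)
    g <- as_igraph(network)
    um <- unique(mesh_nodes)
    uh <- unique(hosp_nodes)
    d <- igraph::distances(g, v = um, to = uh, mode = "all",
                           algorithm = "dijkstra")
    m <- d[match(mesh_nodes, um), match(hosp_nodes, uh), drop = FALSE]
  }
  dimnames(m) <- list(meshes$mesh_id, hospitals$hospital_id)
  m
}

#' Derive Patient Access Areas from a travel-time matrix
#'
#' A hospital belongs to a mesh's PAA exactly when its travel time is within
#' the threshold (inclusive); dually, the mesh belongs to that hospital's
#' PAA. Both directions are returned and satisfy the duality by
#' construction.
#'
#' @param matrix mesh-by-hospital matrix of minutes from
#'   [build_travel_matrix()].
#' @param threshold_minutes positive travel-time threshold (default 60, the
#'   one-hour-by-car criterion).
#' @return an object of class `paam_paa` with named lists `by_mesh`
#'   (hospital ids reachable from each mesh) and `by_hospital` (mesh ids
#'   each hospital can serve).
#' @export
compute_paa <- function(matrix, threshold_minutes = 60) {
  if (!is.numeric(threshold_minutes) || length(threshold_minutes) != 1 ||
      is.na(threshold_minutes) || threshold_minutes <= 0)
    stop("threshold_minutes must be positive", call. = FALSE)
  within <- matrix <= threshold_minutes
  by_mesh <- lapply(seq_len(nrow(matrix)),
                    function(i) colnames(matrix)[within[i, ]])
  names(by_mesh) <- rownames(matrix)
  by_hospital <- lapply(seq_len(ncol(matrix)),
                        function(j) rownames(matrix)[within[, j]])
  names(by_hospital) <- colnames(matrix)
  structure(list(by_mesh = by_mesh, by_hospital = by_hospital,
                 threshold_minutes = threshold_minutes),
            class = "paam_paa")
}

#' @export
print.paam_paa <- function(x, ...) {
  sizes <- lengths(x$by_mesh)
  cat(sprintf(
    "Patient Access Areas (threshold %g min): %d meshes, %d hospitals\n",
    x$threshold_minutes, length(x$by_mesh), length(x$by_hospital)))
  cat(sprintf("  hospitals reachable per mesh: min %d, median %g, max %d\n",
              min(sizes), stats::median(sizes), max(sizes)))
  if (any(sizes == 0))
    cat(sprintf("  %d meshes have no reachable hospital\n", sum(sizes == 0)))
  invisible(x)
}
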
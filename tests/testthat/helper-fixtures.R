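# Shared fixtures and independent oracles, all built in code.

# Rate tables with scalar rates (recycled over sex x band); survival 1,
# migration 0, fertility 0 gives the pure-aging identity.
simple_rates <- function(survival = 1, migration = 0, fertility = 0,
                         inpatient = 0, sex_ratio = 1) {
  rate_tables(
    fertility = rep(fertility, 7),
    sex_ratio_at_birth = sex_ratio,
    survival = survival,
    net_migration = migration,
    inpatient_rate = inpatient
  )
}

# A population with the same count in every sex x band cell.
uniform_population <- function(count) population(count)

# Random connected-ish graph on n nodes (edge probability p).
random_graph <- function(n, p = 0.35) {
  ids <- sprintf("v%02d", seq_len(n))
  nodes <- data.frame(node_id = ids, x = runif(n, 0, 1000),
                      y = runif(n, 0, 1000), stringsAsFactors = FALSE)
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p
  edges <- data.frame(node_a = ids[pairs[keep, 1]],
                      node_b = ids[pairs[keep, 2]],
                      minutes = round(runif(sum(keep), 1, 60), 1),
                      stringsAsFactors = FALSE)
  road_network(nodes, edges)
}

# Exhaustive shortest-path oracle: enumerate every simple path from `from`
# by depth-first search (no pruning) and record the minimum total minutes
# reaching each node. Independent of the package's Dijkstra route.
brute_shortest_from <- function(network, from) {
  ids <- network$nodes$node_id
  n <- length(ids)
  adj <- vector("list", n)
  ia <- match(network$edges$node_a, ids)
  ib <- match(network$edges$node_b, ids)
  for (k in seq_along(ia)) {
    adj[[ia[k]]] <- rbind(adj[[ia[k]]], c(ib[k], network$edges$minutes[k]))
    adj[[ib[k]]] <- rbind(adj[[ib[k]]], c(ia[k], network$edges$minutes[k]))
  }
  best <- rep(Inf, n)
  start <- match(from, ids)
  best[start] <- 0
  visited <- rep(FALSE, n)
  visit <- function(node, time) {
    visited[node] <<- TRUE
    nbrs <- adj[[node]]
    if (!is.null(nbrs)) {
      for (k in seq_len(nrow(nbrs))) {
        nb <- nbrs[k, 1]
        if (visited[nb]) next
        nt <- time + nbrs[k, 2]
        if (nt < best[nb]) best[nb] <<- nt
        visit(nb, nt)
      }
    }
    visited[node] <<- FALSE
  }
  visit(start, 0)
  setNames(best, ids)
}

# Maximum-bipartite-flow oracle for the minimum possible over-demand:
# source -> meshes (capacity = patients), mesh -> hospital if reachable,
# hospital -> sink (capacity = available beds).
flow_min_overdemand <- function(patients, paa, capacities) {
  meshes <- names(patients)
  hosps <- names(capacities)
  e_from <- c(rep("s", length(meshes)))
  e_to <- meshes
  e_cap <- as.numeric(patients)
  for (m in meshes) {
    for (h in intersect(paa$by_mesh[[m]], hosps)) {
      e_from <- c(e_from, m)
      e_to <- c(e_to, h)
      e_cap <- c(e_cap, sum(patients))
    }
  }
  e_from <- c(e_from, hosps)
  e_to <- c(e_to, rep("t", length(hosps)))
  e_cap <- c(e_cap, as.numeric(capacities))
  g <- igraph::graph_from_data_frame(
    data.frame(from = e_from, to = e_to), directed = TRUE,
    vertices = data.frame(name = c("s", "t", meshes, hosps)))
  fl <- igraph::max_flow(g, "s", "t", capacity = e_cap)
  sum(patients) - fl$value
}

# A tiny one-mesh / n-hospital world for allocation unit tests.
toy_world <- function(minutes, beds, in_region = TRUE) {
  meshes <- mesh_table("m1", 0, 0)
  hospitals <- hospital_table(sprintf("h%d", seq_along(beds)),
                              x = seq_along(beds) * 1000, y = 0,
                              total_beds = beds, in_region = in_region)
  tm <- matrix(minutes, nrow = 1,
               dimnames = list("m1", hospitals$hospital_id))
  list(meshes = meshes, hospitals = hospitals, tm = tm,
       paa = compute_paa(tm, max(minutes[is.finite(minutes)], 1) + 1))
}

# Small random synthetic region spec for property sweeps.
random_small_spec <- function(seed) {
  set.seed(seed)
  region_spec(
    nx = sample(2:4, 1), ny = sample(2:4, 1),
    total_population = sample(500:3000, 1),
    n_hospitals = sample(1:3, 1),
    hospital_placement = sample(c("population_weighted", "uniform"), 1),
    edge_removal_fraction = sample(c(0, 0.3), 1),
    seed = seed
  )
}
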
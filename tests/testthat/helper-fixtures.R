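# Shared desk-scale fixtures, built once per test run.

fix_mesh2 <- make_icosphere(2)   # 162 vertices
fix_mesh3 <- make_icosphere(3)   # 642 vertices

# two 5-cliques joined by one weak edge; planted 2-community structure
two_clique_graph <- function(weak = 0.1) {
  pairs <- expand.grid(i = 1:5, j = 1:5)
  pairs <- pairs[pairs$i < pairs$j, ]
  structure(
    list(n_nodes = 10L,
         edges = data.frame(i = c(pairs$i, pairs$i + 5L, 5L),
                            j = c(pairs$j, pairs$j + 5L, 6L),
                            w = c(rep(1, 20), weak)),
         density = NA),
    class = "fc_graph")
}

# ring of 4 triangles with weak inter-triangle links
triangle_ring_graph <- function(weak = 0.05) {
  tri <- do.call(rbind, lapply(0:3, function(k)
    data.frame(i = 3 * k + c(1, 1, 2), j = 3 * k + c(2, 3, 3), w = 1)))
  link <- data.frame(i = c(3, 6, 9, 12), j = c(4, 7, 10, 1), w = weak)
  structure(list(n_nodes = 12L, edges = rbind(tri, link), density = NA),
            class = "fc_graph")
}

# exhaustive minimum-codelength partition by enumerating restricted growth
# strings (independent oracle for the greedy optimizer)
exhaustive_best_partition <- function(graph) {
  n <- graph$n_nodes
  best <- Inf
  best_m <- NULL
  rec <- function(m, pos, k) {
    if (pos > n) {
      L <- map_equation_codelength(graph, m)
      if (L < best) {
        best <<- L
        best_m <<- m
      }
      return(invisible())
    }
    for (v in seq_len(k + 1)) {
      m[pos] <- v
      rec(m, pos + 1L, max(k, v))
    }
  }
  rec(integer(n), 1L, 0L)
  list(codelength = best, membership = best_m)
}

# connected components of a vertex subset on a mesh (BFS oracle,
# independent of grow_patches)
n_components <- function(vertices, adj) {
  vs <- sort(vertices)
  seen <- logical(length(adj))
  comp <- 0L
  for (v in vs) {
    if (seen[v]) next
    comp <- comp + 1L
    queue <- v
    seen[v] <- TRUE
    while (length(queue) > 0) {
      u <- queue[1]
      queue <- queue[-1]
      nb <- intersect(adj[[u]], vs)
      nb <- nb[!seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  comp
}

# small preconfigured experiment for pipeline-level tests
tiny_splithalf_config <- function(...) {
  splithalf_config(n_subjects = 6L, subdivisions = 2L, n_networks = 6L,
                   n_parcels = 20L, n_frames = 300L, n_subcortical = 60L,
                   n_rotations = 100L, min_retained = 120L, seed = 7L, ...)
}

ks_distance_uniform <- function(p) {
  grid <- seq(0, 1, 0.01)
  max(abs(vapply(grid, function(q) mean(p <= q) - q, numeric(1))))
}
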
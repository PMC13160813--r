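#' Two-level map-equation codelength of a partition
#'
#' Pure-R evaluation of the map equation for a hard partition of a weighted
#' undirected graph, with edge-weight-proportional flow (no teleportation):
#' node visit rates are strengths normalized by total strength, module exit
#' rates are boundary-crossing weight over total strength.
#'
#' @param graph An `fc_graph` from [threshold_at_density()] (or a list with
#'   `n_nodes` and an `edges` data.frame `i`, `j`, `w`).
#' @param membership Integer module label per node.
#' @return Codelength in bits per step.
#' @export
map_equation_codelength <- function(graph, membership) {
  n <- graph$n_nodes
  stopifnot(length(membership) == n)
  e <- graph$edges
  strength <- numeric(n)
  add <- rowsum(c(e$w, e$w), c(e$i, e$j))
  strength[as.integer(rownames(add))] <- add[, 1]
  total <- sum(strength)
  if (total <= 0) stop("graph has no edges")
  p <- strength / total
  cross <- membership[e$i] != membership[e$j]
  q <- numeric(max(membership))
  if (any(cross)) {
    cw <- rowsum(c(e$w[cross], e$w[cross]),
                 c(membership[e$i[cross]], membership[e$j[cross]]))
    q[as.integer(rownames(cw))] <- cw[, 1] / total
  }
  mod_p <- numeric(max(membership))
  mp <- rowsum(p, membership)
  mod_p[as.integer(rownames(mp))] <- mp[, 1]
  sum(plogp(sum(q))) - 2 * sum(plogp(q)) +
    sum(plogp(q + mod_p)) - sum(plogp(p))
}

#' Map-equation community detection
#'
#' Seeded greedy minimization of the two-level map equation: random-order
#' node-to-module moves, repeated with module aggregation until no move
#' lowers the codelength; the best of `n_restarts` randomized restarts is
#' returned. This is the standard two-level Infomap scheme for undirected
#' weighted graphs.
#'
#' @param graph An `fc_graph` from [threshold_at_density()].
#' @param seed Integer seed (controls node visit orders).
#' @param n_restarts Number of randomized restarts.
#' @param record_trace Record the codelength after every accepted greedy
#'   move of the winning restart (for diagnostics).
#' @return A `community_solution`: list with `membership` (integer labels
#'   contiguous from 1), `codelength`, `n_communities`, `density`, and
#'   optionally `trace`.
#' @export
infomap_partition <- function(graph, seed = 1L, n_restarts = 10L,
                              record_trace = FALSE) {
  stopifnot(inherits(graph, "fc_graph") || is.list(graph))
  if (nrow(graph$edges) == 0) stop("empty graph")
  best <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      res <- .infomap_greedy(graph$n_nodes, graph$edges$i, graph$edges$j,
                             graph$edges$w, record_trace)
      if (is.null(best) || res$codelength < best$codelength) best <- res
    }
  })
  structure(
    list(membership = best$membership,
         codelength = best$codelength,
         n_communities = best$n_communities,
         density = graph$density,
         trace = best$trace),
    class = "community_solution"
  )
}

#' @export
print.community_solution <- function(x, ...) {
  cat("community_solution: ", x$n_communities, " communities, codelength ",
      round(x$codelength, 4), " bits", sep = "")
  if (!is.null(x$density)) cat(" (density ", x$density, ")", sep = "")
  cat("\n")
  invisible(x)
}
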
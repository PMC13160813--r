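# Canonical network name pool, in the order used for K <= 12 templates.
canonical_network_names <- function() {
  c("DMN", "VIS", "FPN", "DAN", "SAL", "AMN",
    "SMH", "SMF", "AUD", "LANG", "CGP", "RST")
}

# Synchronized breadth-first patch growth: patches take turns claiming the
# next unlabeled neighbor of their frontier, which guarantees contiguity and
# roughly balanced sizes on a connected mesh.
grow_patches <- function(adj, seed_vertices) {
  n <- length(adj)
  k <- length(seed_vertices)
  lab <- integer(n)
  lab[seed_vertices] <- seq_len(k)
  frontier <- lapply(seed_vertices, function(v) v)
  repeat {
    grew <- FALSE
    for (p in seq_len(k)) {
      while (length(frontier[[p]]) > 0L) {
        v <- frontier[[p]][1L]
        nb <- adj[[v]]
        nb <- nb[lab[nb] == 0L]
        if (length(nb) > 0L) {
          u <- nb[1L]
          lab[u] <- p
          frontier[[p]] <- c(frontier[[p]], u)
          grew <- TRUE
          break
        }
        frontier[[p]] <- frontier[[p]][-1L]
      }
    }
    if (!grew) break
  }
  lab
}

#' Plant a contiguous network template on a mesh
#'
#' Grows `K` spatially contiguous network patches by synchronized
#' breadth-first accretion from randomly chosen seed vertices until every
#' vertex is labeled. Deterministic given `seed`.
#'
#' @param mesh A `surface_mesh`.
#' @param K Number of networks (2 <= K <= n_vertices).
#' @param seed Integer seed controlling seed-vertex choice.
#' @param names Optional character vector of K network names; defaults to a
#'   pool of canonical resting-state network abbreviations, extended with
#'   `NETxx` when K exceeds the pool.
#' @return A `network_template`: list with `labels` (character vector over
#'   vertices), `names` (ordered network names), `K`.
#' @export
make_template <- function(mesh, K, seed = 1L, names = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (K < 2 || K > mesh$n_vertices)
    stop("K must satisfy 2 <= K <= n_vertices")
  if (is.null(names)) {
    pool <- canonical_network_names()
    names <- if (K <= length(pool)) pool[seq_len(K)] else
      c(pool, sprintf("NET%02d", seq_len(K - length(pool)) + length(pool)))
  }
  stopifnot(length(names) == K, !anyDuplicated(names))
  adj <- mesh_adjacency(mesh)
  seeds <- withr::with_seed(seed, sample.int(mesh$n_vertices, K))
  lab_int <- grow_patches(adj, seeds)
  structure(
    list(labels = names[lab_int], names = names, K = as.integer(K)),
    class = "network_template"
  )
}

#' @export
print.network_template <- function(x, ...) {
  cat("network_template: K =", x$K, "networks over", length(x$labels),
      "vertices\n")
  print(table(x$labels))
  invisible(x)
}

#' Grow a contiguous parcellation on a mesh
#'
#' Same synchronized breadth-first growth as [make_template()], but producing
#' anonymous parcels used as graph nodes for parcel-level connectivity.
#'
#' @param mesh A `surface_mesh`.
#' @param n_parcels Number of parcels.
#' @param seed Integer seed.
#' @return A `parcellation`: list with `assignment` (integer vector over
#'   vertices, ids contiguous from 1) and `parcel_names`.
#' @export
make_parcellation <- function(mesh, n_parcels, seed = 1L) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (n_parcels < 1 || n_parcels > mesh$n_vertices)
    stop("n_parcels must satisfy 1 <= n_parcels <= n_vertices")
  adj <- mesh_adjacency(mesh)
  seeds <- withr::with_seed(seed, sample.int(mesh$n_vertices, n_parcels))
  assignment <- grow_patches(adj, seeds)
  structure(
    list(assignment = assignment,
         parcel_names = sprintf("P%03d", seq_len(n_parcels))),
    class = "parcellation"
  )
}

# per-label vertex index sets, dropping the unassigned sentinel
label_sets <- function(labels) {
  s <- split(seq_along(labels), labels)
  s[setdiff(names(s), UNASSIGNED)]
}
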
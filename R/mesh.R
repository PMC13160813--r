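#' Build a unit icosphere surface mesh
#'
#' Starts from a regular icosahedron and applies `subdivisions` rounds of
#' 4-way triangle subdivision, projecting every vertex back onto the unit
#' sphere. The result is the geometric substrate for planted network
#' templates, parcellations, and spherical spin rotations.
#'
#' @param subdivisions Number of subdivision rounds (>= 0). The mesh has
#'   `10 * 4^subdivisions + 2` vertices and `20 * 4^subdivisions` faces.
#' @return A `surface_mesh`: list with `vertices` (n x 3 matrix of unit
#'   vectors), `faces` (m x 3 integer matrix, 1-based), `n_vertices`.
#' @examples
#' mesh <- make_icosphere(1)
#' mesh$n_vertices # 42
#' @export
make_icosphere <- function(subdivisions = 3) {
  if (length(subdivisions) != 1L || is.na(subdivisions) || subdivisions < 0)
    stop("`subdivisions` must be a single nonnegative integer")
  subdivisions <- as.integer(subdivisions)

  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  f <- 1L + rbind(
    c(0, 11, 5), c(0, 5, 1), c(0, 1, 7), c(0, 7, 10), c(0, 10, 11),
    c(1, 5, 9), c(5, 11, 4), c(11, 10, 2), c(10, 7, 6), c(7, 1, 8),
    c(3, 9, 4), c(3, 4, 2), c(3, 2, 6), c(3, 6, 8), c(3, 8, 9),
    c(4, 9, 5), c(2, 4, 11), c(6, 2, 10), c(8, 6, 7), c(9, 8, 1)
  )
  storage.mode(f) <- "integer"

  normalize <- function(m) m / sqrt(rowSums(m^2))
  v <- normalize(v)

  for (s in seq_len(subdivisions)) {
    n <- nrow(v)
    midpoint_id <- new.env(hash = TRUE, parent = emptyenv())
    new_v <- list()
    n_new <- 0L
    get_mid <- function(a, b) {
      key <- paste0(min(a, b), "_", max(a, b))
      id <- midpoint_id[[key]]
      if (!is.null(id)) return(id)
      n_new <<- n_new + 1L
      new_v[[n_new]] <<- (v[a, ] + v[b, ]) / 2
      id <- n + n_new
      midpoint_id[[key]] <- id
      id
    }
    new_f <- matrix(0L, nrow(f) * 4L, 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      ab <- get_mid(a, b); bc <- get_mid(b, c_); ca <- get_mid(c_, a)
      new_f[(i - 1L) * 4L + 1L, ] <- c(a, ab, ca)
      new_f[(i - 1L) * 4L + 2L, ] <- c(b, bc, ab)
      new_f[(i - 1L) * 4L + 3L, ] <- c(c_, ca, bc)
      new_f[(i - 1L) * 4L + 4L, ] <- c(ab, bc, ca)
    }
    v <- normalize(rbind(v, do.call(rbind, new_v)))
    f <- new_f
  }

  structure(
    list(vertices = v, faces = f, n_vertices = nrow(v)),
    class = "surface_mesh"
  )
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh:", x$n_vertices, "vertices,", nrow(x$faces), "faces\n")
  invisible(x)
}

#' Vertex adjacency list of a surface mesh
#'
#' @param mesh A `surface_mesh`.
#' @return List of length `n_vertices`; element i is the sorted integer
#'   vector of vertices sharing an edge with vertex i.
#' @export
mesh_adjacency <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  adj <- split(e[, 2], e[, 1])
  out <- vector("list", mesh$n_vertices)
  for (i in seq_along(adj)) {
    out[[as.integer(names(adj)[i])]] <- sort(unique(adj[[i]]))
  }
  out
}
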
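#' Default edge-density grid
#'
#' Densities spanning 0.1% to 5% of the positive node pairs.
#'
#' @return Numeric vector of strictly increasing densities.
#' @export
default_density_grid <- function() {
  c(0.001, 0.002, 0.005, 0.01, 0.02, 0.03, 0.04, 0.05)
}

#' Threshold a correlation matrix at an edge density
#'
#' Among the E strictly-upper-triangle node pairs with positive weight,
#' retains the `ceiling(d * E)` largest-weight edges with weights preserved.
#' Negative correlations are excluded before thresholding (density is
#' defined over positive pairs). Ties at the cut are broken
#' deterministically: weight descending, then node pair (i, j)
#' lexicographically ascending, which makes edge sets nested across
#' densities.
#'
#' @param fc An `fc_matrix` (or symmetric matrix).
#' @param d Edge density in (0, 1].
#' @return An `fc_graph`: list with `n_nodes`, `edges` (data.frame `i`,
#'   `j`, `w`; 1-based, i < j), `density`.
#' @export
threshold_at_density <- function(fc, d) {
  stopifnot(d > 0, d <= 1)
  m <- unclass(fc)
  n <- nrow(m)
  ut <- which(upper.tri(m), arr.ind = TRUE)
  w <- m[ut]
  pos <- w > 0
  ut <- ut[pos, , drop = FALSE]
  w <- w[pos]
  e_total <- length(w)
  n_keep <- ceiling(d * e_total)
  if (e_total == 0 || n_keep < 1)
    stop("density yields zero edges")
  ord <- order(-w, ut[, 1], ut[, 2])
  keep <- ord[seq_len(n_keep)]
  structure(
    list(n_nodes = n,
         edges = data.frame(i = ut[keep, 1], j = ut[keep, 2], w = w[keep]),
         density = d),
    class = "fc_graph"
  )
}

#' @export
print.fc_graph <- function(x, ...) {
  cat("fc_graph: ", x$n_nodes, " nodes, ", nrow(x$edges),
      " edges (density ", x$density, ")\n", sep = "")
  invisible(x)
}
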
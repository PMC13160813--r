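#' Construct a functional connectivity matrix object
#'
#' @param values Symmetric node x node Pearson correlation matrix.
#' @param node_ids Ordered node identity vector.
#' @param level One of "vertex", "voxel", "parcel".
#' @return An `fc_matrix` (a matrix with identity metadata).
#' @export
fc_matrix <- function(values, node_ids = NULL, level = "vertex") {
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values))
  if (is.null(node_ids)) node_ids <- seq_len(nrow(values)) - 1L
  stopifnot(length(node_ids) == nrow(values))
  if (max(abs(values - t(values))) > 1e-12)
    stop("fc_matrix values must be symmetric")
  values <- (values + t(values)) / 2
  diag(values) <- 1
  structure(values, node_ids = node_ids,
            level = match.arg(level, c("vertex", "voxel", "parcel")),
            class = c("fc_matrix", "matrix", "array"))
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat("fc_matrix (", attr(x, "level"), " level): ",
      nrow(x), " x ", ncol(x), " nodes\n", sep = "")
  invisible(x)
}

#' Subject-level Pearson correlation matrix
#'
#' Pairwise Pearson correlations of node time series over retained frames
#' only.
#'
#' @param timeseries Node x frame matrix.
#' @param retain Logical retain vector; defaults to all frames. At least 3
#'   retained frames are required.
#' @param level Node level tag for the result.
#' @return An `fc_matrix`.
#' @export
subject_fc <- function(timeseries, retain = NULL, level = "vertex") {
  if (is.null(retain)) retain <- rep(TRUE, ncol(timeseries))
  if (sum(retain) < 3) stop("need at least 3 retained frames")
  r <- stats::cor(t(timeseries[, retain, drop = FALSE]))
  fc_matrix(r, node_ids = rownames(timeseries), level = level)
}

#' Group-average correlation matrix
#'
#' Element-wise arithmetic mean of per-subject correlation matrices (raw r
#' by default; `fisher_z = TRUE` averages Fisher z-transforms and
#' back-transforms).
#'
#' @param matrices List of `fc_matrix` objects with identical node ids.
#' @param fisher_z Average in Fisher-z space.
#' @return An `fc_matrix`.
#' @export
group_average_fc <- function(matrices, fisher_z = FALSE) {
  stopifnot(length(matrices) >= 1)
  ids <- attr(matrices[[1]], "node_ids")
  for (m in matrices)
    if (!identical(attr(m, "node_ids"), ids))
      stop("node ids must agree across subjects")
  acc <- matrix(0, nrow(matrices[[1]]), ncol(matrices[[1]]))
  for (m in matrices) {
    v <- unclass(m)
    if (fisher_z) {
      v <- atanh(pmin(pmax(v, -1 + 1e-15), 1 - 1e-15))
      diag(v) <- 0
    }
    acc <- acc + v
  }
  acc <- acc / length(matrices)
  if (fisher_z) {
    acc <- tanh(acc)
  }
  diag(acc) <- 1
  fc_matrix(acc, node_ids = ids, level = attr(matrices[[1]], "level"))
}

#' Parcel-level correlation matrix
#'
#' Averages member-vertex time series into one series per parcel
#' (unweighted mean), then computes Pearson correlations over retained
#' frames.
#'
#' @param timeseries Vertex x frame matrix.
#' @param parcellation A [make_parcellation()] result (or integer
#'   assignment vector).
#' @param retain Logical retain vector; defaults to all frames.
#' @return A parcel-level `fc_matrix` with parcel names as node ids.
#' @export
parcel_fc <- function(timeseries, parcellation, retain = NULL) {
  if (inherits(parcellation, "parcellation")) {
    assignment <- parcellation$assignment
    pnames <- parcellation$parcel_names
  } else {
    assignment <- as.integer(parcellation)
    pnames <- sprintf("P%03d", seq_len(max(assignment)))
  }
  stopifnot(length(assignment) == nrow(timeseries))
  pm <- parcel_mean_series(timeseries, assignment)
  rownames(pm) <- pnames
  subject_fc(pm, retain, level = "parcel")
}

# parcel x frame matrix of unweighted member-vertex means
parcel_mean_series <- function(timeseries, assignment) {
  sums <- rowsum(timeseries, assignment)
  counts <- as.vector(table(assignment)[rownames(sums)])
  sums / counts
}

#' Similarity of two connectivity matrices
#'
#' Pearson correlation over the strictly-upper-triangle entries of two
#' matrices defined on the same nodes.
#'
#' @param a,b `fc_matrix` objects (or plain symmetric matrices) with equal
#'   dimension and node ids.
#' @return Pearson r.
#' @export
fc_similarity <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  ia <- attr(a, "node_ids"); ib <- attr(b, "node_ids")
  if (!is.null(ia) && !is.null(ib) && !identical(ia, ib))
    stop("node ids must agree")
  stats::cor(upper_tri_values(unclass(a)), upper_tri_values(unclass(b)))
}
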
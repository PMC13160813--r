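#' Mean time series per cortical network
#'
#' Unweighted mean over member vertices for each named (non-unassigned)
#' network.
#'
#' @param timeseries Vertex x frame matrix.
#' @param labels Character label map over vertices.
#' @return Network x frame matrix with network names as row names.
#' @export
network_mean_series <- function(timeseries, labels) {
  stopifnot(nrow(timeseries) == length(labels))
  sets <- label_sets(labels)
  if (length(sets) == 0) stop("no assigned vertices")
  out <- t(vapply(sets, function(idx)
    colMeans(timeseries[idx, , drop = FALSE]), numeric(ncol(timeseries))))
  rownames(out) <- names(sets)
  out
}

# voxel x network Pearson correlation matrix over retained frames
voxel_network_correlation <- function(voxel_series, network_series,
                                      retain = NULL) {
  if (is.null(retain)) retain <- rep(TRUE, ncol(voxel_series))
  stopifnot(ncol(voxel_series) == ncol(network_series))
  stats::cor(t(voxel_series[, retain, drop = FALSE]),
             t(network_series[, retain, drop = FALSE]))
}

#' Winner-take-all network assignment of subcortical voxels
#'
#' Each voxel is assigned to the cortical network whose mean time series it
#' correlates with most strongly over retained frames. Exact ties are broken
#' by network-name order (row order of `network_series`) with a warning.
#'
#' @param voxel_series Voxel x frame matrix.
#' @param network_series Network x frame matrix from
#'   [network_mean_series()].
#' @param retain Logical retain vector; defaults to all frames.
#' @return Character label map over voxels.
#' @export
wta_assign <- function(voxel_series, network_series, retain = NULL) {
  r <- voxel_network_correlation(voxel_series, network_series, retain)
  if (anyNA(r)) {
    bad <- which(rowSums(is.na(r)) == ncol(r))
    if (length(bad) > 0)
      stop("all correlations undefined for voxel(s) ",
           paste(head(bad, 5), collapse = ", "),
           " (constant series over retained frames)")
  }
  wta_from_correlations(r)
}

# argmax per row with documented first-name tie-break
wta_from_correlations <- function(r) {
  win <- max.col(r, ties.method = "first")
  rowmax <- r[cbind(seq_len(nrow(r)), win)]
  n_tied <- rowSums(r == rowmax)
  if (any(n_tied > 1, na.rm = TRUE))
    warning(sum(n_tied > 1, na.rm = TRUE),
            " voxel(s) had tied correlations; assigned to the first ",
            "network in name order")
  colnames(r)[win]
}

#' Group-level winner-take-all assignment
#'
#' Averages each subject's voxel-to-network correlation matrix across the
#' cohort, then assigns each voxel to the argmax network of the averaged
#' correlations.
#'
#' @param subjects List of per-subject lists with elements
#'   `voxel_series` (voxel x frame), `timeseries` (vertex x frame,
#'   denoised), and `retain` (logical analysis mask).
#' @param cortical_labels Character label map over vertices (e.g. the
#'   consensus map) defining the cortical networks.
#' @return Character label map over voxels, with the averaged voxel x
#'   network correlation matrix as attribute `correlations`.
#' @export
group_wta <- function(subjects, cortical_labels) {
  stopifnot(length(subjects) >= 1)
  acc <- NULL
  for (s in subjects) {
    nets <- network_mean_series(s$timeseries, cortical_labels)
    r <- voxel_network_correlation(s$voxel_series, nets, s$retain)
    acc <- if (is.null(acc)) r else acc + r
  }
  acc <- acc / length(subjects)
  out <- wta_from_correlations(acc)
  attr(out, "correlations") <- acc
  out
}
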
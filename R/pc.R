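#' Participation coefficient of each node
#'
#' PC_i = 1 - sum_s (k_is / k_i)^2, where k_i is node i's total retained
#' edge weight and k_is its weight to network s. Connections are the
#' off-diagonal entries of the connectivity matrix with negative
#' correlations set to zero (`binarize = TRUE` instead thresholds positive
#' weights to 1). Edges to unassigned nodes are excluded, unassigned nodes
#' get NA, and a node with no retained weight gets NA.
#'
#' @param fc An `fc_matrix` (or symmetric matrix) over parcels.
#' @param labels Character network label per node.
#' @param binarize Use binary positive edges instead of weights.
#' @return Named numeric vector of PC values in \[0, 1) with NA for
#'   unassigned or isolated nodes.
#' @export
participation_coefficient <- function(fc, labels, binarize = FALSE) {
  w <- unclass(as.matrix(fc))
  stopifnot(nrow(w) == length(labels))
  diag(w) <- 0
  w[w < 0] <- 0
  if (binarize) w <- (w > 0) * 1
  assigned <- labels != UNASSIGNED & !is.na(labels)
  pc <- rep(NA_real_, length(labels))
  if (!any(assigned)) return(pc)
  wa <- w[assigned, assigned, drop = FALSE]
  la <- labels[assigned]
  k <- rowSums(wa)
  # k_is: node x network weight totals
  kis <- t(rowsum(t(wa), la))
  valid <- k > 0
  pc_a <- rep(NA_real_, sum(assigned))
  pc_a[valid] <- 1 - rowSums((kis[valid, , drop = FALSE] / k[valid])^2)
  pc[assigned] <- pc_a
  names(pc) <- rownames(w)
  pc
}

#' Mean participation coefficient per network
#'
#' Unweighted mean of member-node PC values; missing values excluded.
#'
#' @param pc Numeric PC vector from [participation_coefficient()].
#' @param labels Character network label per node.
#' @return Named numeric vector of per-network means.
#' @export
network_mean_pc <- function(pc, labels) {
  stopifnot(length(pc) == length(labels))
  keep <- labels != UNASSIGNED & !is.na(labels)
  tapply(pc[keep], labels[keep], mean, na.rm = TRUE)
}

#' Per-node participation-coefficient difference
#'
#' Element-wise `pc_a - pc_b` over shared nodes (group A minus group B).
#'
#' @param pc_a,pc_b Numeric PC vectors of equal length (same parcels).
#' @return Numeric difference vector.
#' @export
delta_pc <- function(pc_a, pc_b) {
  stopifnot(length(pc_a) == length(pc_b))
  pc_a - pc_b
}
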
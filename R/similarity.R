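#' Normalized mutual information of two label maps
#'
#' Mutual information of the joint label distribution, normalized by the
#' arithmetic mean of the two marginal entropies (2I / (Ha + Hb);
#' `normalization` selects the max- or min-entropy variants instead). Nodes
#' unassigned in either map are excluded pairwise. If either remaining
#' marginal has zero entropy (a single-label map), NMI is 0 by convention.
#'
#' @param a,b Character label maps over the same node set.
#' @param normalization One of "mean", "max", "min".
#' @return NMI in \[0, 1\].
#' @export
nmi <- function(a, b, normalization = c("mean", "max", "min")) {
  normalization <- match.arg(normalization)
  stopifnot(length(a) == length(b))
  keep <- a != UNASSIGNED & b != UNASSIGNED & !is.na(a) & !is.na(b)
  if (!any(keep))
    stop("no nodes assigned in both maps")
  ct <- table(a[keep], b[keep])
  p <- ct / sum(ct)
  px <- rowSums(p)
  py <- colSums(p)
  ha <- -sum(plogp(px))
  hb <- -sum(plogp(py))
  pp <- as.vector(p)
  pe <- as.vector(outer(px, py))
  pos <- pp > 0
  mi <- sum(pp[pos] * log2(pp[pos] / pe[pos]))
  denom <- switch(normalization,
                  mean = (ha + hb) / 2,
                  max = max(ha, hb),
                  min = min(ha, hb))
  if (denom == 0) return(0)
  min(1, max(0, mi / denom))
}

#' Dice coefficient of two node sets
#'
#' @param a,b Vectors of node identifiers (binary maps as index sets).
#' @return 2|A intersect B| / (|A| + |B|); 1 for identical sets, 0 for
#'   disjoint sets.
#' @export
dice <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) + length(b) == 0) stop("Dice undefined for two empty sets")
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Per-network Dice coefficients of two label maps
#'
#' @param a,b Character label maps over the same node set.
#' @param networks Network names to test; defaults to names present in
#'   either map.
#' @return Named numeric vector of Dice coefficients (NA where a network is
#'   empty in both maps).
#' @export
dice_by_network <- function(a, b, networks = NULL) {
  stopifnot(length(a) == length(b))
  if (is.null(networks))
    networks <- setdiff(sort(unique(c(a, b))), UNASSIGNED)
  vapply(networks, function(nm) {
    sa <- which(a == nm); sb <- which(b == nm)
    if (length(sa) + length(sb) == 0) return(NA_real_)
    dice(sa, sb)
  }, numeric(1))
}

#' Sample uniformly random 3-D rotations
#'
#' Uniform (Haar) rotations via normalized Gaussian quaternions;
#' deterministic given `seed`.
#'
#' @param n_rot Number of rotations.
#' @param seed Integer seed.
#' @return A `spin_rotation_set`: 3 x 3 x n_rot array of orthogonal
#'   matrices with determinant +1.
#' @export
spin_rotations <- function(n_rot, seed = 1L) {
  q <- withr::with_seed(seed, matrix(rnorm(4 * n_rot), n_rot, 4))
  q <- q / sqrt(rowSums(q^2))
  out <- array(0, c(3, 3, n_rot))
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  out[1, 1, ] <- 1 - 2 * (y^2 + z^2)
  out[1, 2, ] <- 2 * (x * y - z * w)
  out[1, 3, ] <- 2 * (x * z + y * w)
  out[2, 1, ] <- 2 * (x * y + z * w)
  out[2, 2, ] <- 1 - 2 * (x^2 + z^2)
  out[2, 3, ] <- 2 * (y * z - x * w)
  out[3, 1, ] <- 2 * (x * z - y * w)
  out[3, 2, ] <- 2 * (y * z + x * w)
  out[3, 3, ] <- 1 - 2 * (x^2 + y^2)
  structure(out, seed = seed, class = "spin_rotation_set")
}

#' Rotate a label map on the sphere
#'
#' Applies a rotation to the mesh's vertex coordinates and gives each vertex
#' the label of the nearest original vertex to its rotated position
#' (nearest neighbor by maximal dot product on the unit sphere). Unassigned
#' labels rotate like any other label.
#'
#' @param labels Character label map over mesh vertices.
#' @param mesh A `surface_mesh`.
#' @param rotation 3 x 3 rotation matrix.
#' @return Rotated character label map.
#' @export
rotate_labelmap <- function(labels, mesh, rotation) {
  stopifnot(length(labels) == mesh$n_vertices,
            all(dim(rotation) == c(3, 3)))
  rotated <- mesh$vertices %*% t(rotation)
  nn <- max.col(rotated %*% t(mesh$vertices), ties.method = "first")
  labels[nn]
}

# permutation/rotation test result container
similarity_result <- function(observed, null_sample, convention) {
  n_perm <- length(null_sample)
  k <- sum(null_sample >= observed)
  p <- switch(convention,
              addone = (k + 1) / (n_perm + 1),
              proportion = k / n_perm)
  structure(
    list(observed = observed, null_sample = null_sample, p_value = p,
         n_perm = n_perm, convention = convention),
    class = "similarity_result"
  )
}

#' @export
print.similarity_result <- function(x, ...) {
  cat("similarity_result: observed = ", signif(x$observed, 4),
      ", p = ", signif(x$p_value, 4), " (", x$n_perm, " permutations, ",
      x$convention, " convention)\n", sep = "")
  invisible(x)
}

#' Spin permutation test for a map-pair statistic
#'
#' Builds a spatial null by rotating map `a` on the sphere `n_rot` times
#' (nearest-vertex remapping) and recomputing `stat(rotated_a, b)` per
#' rotation; only `a` is rotated. The p-value counts null values greater
#' than or equal to the observed statistic; the default add-one convention
#' reports (k + 1) / (n_rot + 1), the "proportion" convention the raw
#' fraction k / n_rot.
#'
#' @param stat Function of two label maps returning a scalar (e.g. [nmi()],
#'   or a Dice wrapper).
#' @param a,b Character label maps over mesh vertices.
#' @param mesh A `surface_mesh`.
#' @param n_rot Number of rotations.
#' @param seed Integer seed.
#' @param convention "addone" or "proportion".
#' @return A `similarity_result`.
#' @export
spin_pvalue <- function(stat, a, b, mesh, n_rot = 1000L, seed = 1L,
                        convention = c("addone", "proportion")) {
  convention <- match.arg(convention)
  observed <- stat(a, b)
  rots <- spin_rotations(n_rot, seed)
  null_sample <- vapply(seq_len(n_rot), function(i)
    stat(rotate_labelmap(a, mesh, rots[, , i]), b), numeric(1))
  similarity_result(observed, null_sample, convention)
}

#' Mantel test between two connectivity matrices
#'
#' Observed statistic: Spearman (`method = "rank"`) or Pearson
#' (`method = "linear"`) correlation over strictly-upper-triangle entries.
#' Null: node labels of `a` are randomly permuted jointly over rows and
#' columns before recomputing the statistic.
#'
#' @param a,b `fc_matrix` objects (or symmetric matrices) on the same
#'   nodes.
#' @param method "rank" (Spearman) or "linear" (Pearson).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param convention "addone" or "proportion".
#' @return A `similarity_result`.
#' @export
mantel <- function(a, b, method = c("rank", "linear"), n_perm = 999L,
                   seed = 1L, convention = c("addone", "proportion")) {
  method <- match.arg(method)
  convention <- match.arg(convention)
  stopifnot(nrow(a) == nrow(b))
  a <- unclass(a); b <- unclass(b)
  cm <- if (method == "rank") "spearman" else "pearson"
  vb <- upper_tri_values(b)
  observed <- stats::cor(upper_tri_values(a), vb, method = cm)
  n <- nrow(a)
  null_sample <- withr::with_seed(seed, vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n)
    stats::cor(upper_tri_values(a[idx, idx]), vb, method = cm)
  }, numeric(1)))
  similarity_result(observed, null_sample, convention)
}
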
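#' Orient SCP feature vectors onto one half-plane
#'
#' For each single-component point k, the real 2-vector
#' `(reference_row[k], test_row[k])` is normalized to unit l2-norm and its
#' sign is flipped when its larger-magnitude entry is negative, mapping
#' antipodal directions to a common representative. Zero-norm vectors are
#' skipped.
#'
#' @param rows numeric 2 x K mixture (row 1 = reference, row 2 = test).
#' @param scps an `scp_set` from [select_scps()].
#' @return J x 2 matrix of unit vectors (J <= number of SCP indices).
#' @export
orient_scp_vectors <- function(rows, scps) {
  stopifnot(inherits(scps, "scp_set"))
  v <- t(rows[, scps$indices, drop = FALSE])
  nrm <- sqrt(rowSums(v^2))
  keep <- nrm > 0
  v <- v[keep, , drop = FALSE] / nrm[keep]
  dominant <- ifelse(abs(v[, 1L]) >= abs(v[, 2L]), v[, 1L], v[, 2L])
  flip <- dominant < 0
  v[flip, ] <- -v[flip, , drop = FALSE]
  v
}

cosine_distance_matrix <- function(v) {
  sim <- tcrossprod(v)           # rows already unit-norm
  d <- 1 - sim
  d[d < 0] <- 0
  as.dist(d)
}

#' Mixing angle of a non-negative unit 2-vector
#'
#' Angle in degrees from the reference-sample axis (first coordinate):
#' `atan2(test_coord, reference_coord)`.
#'
#' @param column numeric length-2 vector with non-negative entries.
#' @return Angle in degrees, in [0, 90].
#' @export
mixing_angle <- function(column) {
  if (any(column < 0))
    stop("mixing_angle: entries must be non-negative")
  atan2(column[2L], column[1L]) * 180 / pi
}

#' Estimate the mixing matrix by clustering SCP directions
#'
#' Agglomerative clustering with complete linkage under cosine distance
#' groups the oriented SCP unit vectors into exactly M clusters. Each cluster
#' centroid (arithmetic mean of its members, clipped to the non-negative
#' quadrant and renormalized to unit l2-norm) is a column of the estimated
#' 2 x M mixing matrix; column angles are measured from the reference axis.
#' Hierarchical clustering is the default because it is deterministic:
#' identical SCP inputs always yield the identical mixing matrix. k-means is
#' available for comparison only.
#'
#' When the SCP vectors span fewer than M distinct directions some centroids
#' coincide; this is tolerated (the extremal angles that drive component
#' selection are unaffected), but if all vectors lie on a single direction
#' the decomposition is meaningless and an "insufficient angular diversity"
#' error is raised.
#'
#' When more than `max_points` vectors are supplied, a deterministic
#' subsample evenly spaced in angle rank is clustered instead; on clean data
#' the centroids are unchanged because cluster members are nearly collinear.
#'
#' @param vectors J x 2 matrix of oriented unit vectors
#'   (see [orient_scp_vectors()]).
#' @param M number of components/clusters (grid \{2..5\}).
#' @param method `"hclust"` (default) or `"kmeans"`.
#' @param max_points cap on the number of vectors clustered (default 500).
#' @return An object of class `mixing_estimate`: list with `A` (2 x M,
#'   non-negative unit-norm columns), `angles` (degrees, per column) and
#'   `n_scps_used`.
#' @export
cluster_mixing <- function(vectors, M, method = c("hclust", "kmeans"),
                           max_points = 500L) {
  method <- match.arg(method)
  vectors <- as.matrix(vectors)
  j <- nrow(vectors)
  if (j < M)
    stop("too few SCPs for ", M, " components (J = ", j, ")")
  if (j > max_points) {
    ang <- atan2(vectors[, 2L], vectors[, 1L])
    ord <- order(ang, seq_len(j))
    pick <- ord[unique(round(seq(1L, j, length.out = max_points)))]
    vectors <- vectors[sort(pick), , drop = FALSE]
    j <- nrow(vectors)
  }
  cl <- if (method == "hclust") {
    cutree(hclust(cosine_distance_matrix(vectors), method = "complete"), k = M)
  } else {
    kmeans(vectors, centers = M, nstart = 10L)$cluster
  }
  A <- matrix(0, 2L, M)
  for (m in seq_len(M)) {
    centroid <- colMeans(vectors[cl == m, , drop = FALSE])
    centroid[centroid < 0] <- 0
    nrm <- sqrt(sum(centroid^2))
    if (nrm == 0)
      stop("insufficient angular diversity: degenerate centroid for cluster ", m)
    A[, m] <- centroid / nrm
  }
  gram <- crossprod(A)
  off <- gram[upper.tri(gram)]
  if (all(1 - off < 1e-12))
    stop("insufficient angular diversity: SCP vectors span a single direction")
  angles <- apply(A, 2L, mixing_angle)
  structure(list(A = A, angles = angles, n_scps_used = j),
            class = "mixing_estimate")
}

#' @export
print.mixing_estimate <- function(x, ...) {
  cat("Mixing estimate (2 x ", ncol(x$A), "), from ", x$n_scps_used,
      " single-component points\n", sep = "")
  cat("  angles (deg):", paste(sprintf("%.2f", x$angles), collapse = ", "), "\n")
  invisible(x)
}
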
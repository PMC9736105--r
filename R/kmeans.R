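# Squared Euclidean distances between rows of X (N x d) and centroids
# (k x d): N x k matrix.
sq_dist_to_centroids <- function(X, centers) {
  xn <- rowSums(X^2)
  cn <- rowSums(centers^2)
  d2 <- outer(xn, cn, `+`) - 2 * X %*% t(centers)
  d2[d2 < 0] <- 0
  d2
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  first <- sample.int(n, 1L)
  centers[1L, ] <- X[first, ]
  d2 <- sq_dist_to_centroids(X, centers[1L, , drop = FALSE])[, 1L]
  for (j in seq_len(k - 1L) + 1L) {
    if (sum(d2) <= 0) {
      pick <- sample.int(n, 1L)
    } else {
      pick <- sample.int(n, 1L, prob = d2)
    }
    centers[j, ] <- X[pick, ]
    d2 <- pmin(d2, sq_dist_to_centroids(X, centers[j, , drop = FALSE])[, 1L])
  }
  centers
}

lloyd_once <- function(X, k, max_iter, tol) {
  n <- nrow(X)
  centers <- kmeanspp_init(X, k)
  labels <- integer(n)
  obj_trace <- numeric(0)
  repairs <- 0L
  prev_obj <- Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- sq_dist_to_centroids(X, centers)
    labels <- max.col(-d2, ties.method = "first")
    # repair empty clusters: move the farthest point of the largest cluster
    repeat {
      sizes <- tabulate(labels, nbins = k)
      empty <- which(sizes == 0L)
      if (length(empty) == 0L) break
      big <- which.max(sizes)
      members <- which(labels == big)
      far <- members[which.max(d2[cbind(members, labels[members])])]
      labels[far] <- empty[1L]
      centers[empty[1L], ] <- X[far, ]
      d2[, empty[1L]] <- sq_dist_to_centroids(X, centers[empty[1L], , drop = FALSE])[, 1L]
      repairs <- repairs + 1L
    }
    obj <- mean(d2[cbind(seq_len(n), labels)])
    obj_trace <- c(obj_trace, obj)
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(X[labels == j, , drop = FALSE])
    }
    if (iter >= max_iter) break
    if (is.finite(prev_obj) &&
        (prev_obj - obj) <= tol * max(prev_obj, .Machine$double.eps)) break
    prev_obj <- obj
  }
  # final assignment against the converged centroids
  d2 <- sq_dist_to_centroids(X, centers)
  labels <- max.col(-d2, ties.method = "first")
  obj <- mean(d2[cbind(seq_len(n), labels)])
  list(labels = labels, centers = centers, objective = obj,
       n_iterations = iter, repairs = repairs,
       objective_trace = c(obj_trace, obj))
}

#' K-Means clustering of image features
#'
#' Lloyd's algorithm with k-means++ seeding, restarts, and empty-cluster
#' repair (the largest cluster's farthest point is moved to the empty
#' centroid; repairs are counted). The objective is the mean squared Euclidean
#' distance of each row to its assigned centroid; within one run it is
#' non-increasing across Lloyd iterations, and the best of `n_restarts` runs
#' is returned. Deterministic for a fixed `rng_seed`.
#'
#' @param features `N x d` finite numeric matrix, `N >= k`.
#' @param k number of clusters (>= 2); fruit maturity grading uses 3.
#' @param max_iter Lloyd iteration cap per restart.
#' @param tol relative objective-change convergence threshold.
#' @param n_restarts independent k-means++ restarts.
#' @param rng_seed integer seed.
#' @return object of class `rc_clustering`: `assignments` (1..k),
#'   `centroids` (`d x k`, one column per cluster), `objective`,
#'   `n_iterations`, `empty_cluster_repairs`, `objective_trace`, `sizes`.
#' @export
kmeans_fit <- function(features, k = 3, max_iter = 100, tol = 1e-4,
                       n_restarts = 5, rng_seed = NULL) {
  X <- as.matrix(features)
  if (any(!is.finite(X))) stop_input("features must be finite")
  n <- nrow(X)
  k <- as.integer(k)
  if (k < 2) stop_input("k must be at least 2")
  if (n < k) stop_input("need at least k rows")
  best <- NULL
  with_rng_seed(rng_seed, {
    for (r in seq_len(max(1L, as.integer(n_restarts)))) {
      run <- lloyd_once(X, k, max_iter, tol)
      if (is.null(best) || run$objective < best$objective) best <- run
    }
  })
  structure(list(assignments = best$labels,
                 centroids = t(best$centers),
                 objective = best$objective,
                 n_iterations = best$n_iterations,
                 empty_cluster_repairs = best$repairs,
                 objective_trace = best$objective_trace,
                 sizes = tabulate(best$labels, nbins = k),
                 k = k),
            class = "rc_clustering")
}

#' @export
print.rc_clustering <- function(x, ...) {
  cat(sprintf("<rc_clustering k=%d n=%d objective=%.6g iterations=%d repairs=%d>\n",
              x$k, length(x$assignments), x$objective, x$n_iterations,
              x$empty_cluster_repairs))
  cat("sizes:", paste(x$sizes, collapse = " "), "\n")
  invisible(x)
}

#' Assign points to the nearest centroids
#'
#' Each row is mapped to the centroid minimizing squared Euclidean distance
#' (the one-hot inner minimization of the clustering objective); ties break to
#' the lowest centroid index.
#'
#' @param features `N x d` matrix.
#' @param centroids `d x k` matrix (one column per centroid), e.g.
#'   `rc_clustering$centroids`.
#' @return integer labels in 1..k.
#' @export
assign_to_centroids <- function(features, centroids) {
  X <- as.matrix(features)
  C <- as.matrix(centroids)
  if (ncol(X) != nrow(C)) {
    stop_input(sprintf("feature dimension %d does not match centroid dimension %d",
                       ncol(X), nrow(C)))
  }
  d2 <- sq_dist_to_centroids(X, t(C))
  max.col(-d2, ties.method = "first")
}

#' Normalized mutual information between two labelings
#'
#' Permutation-invariant agreement between two partitions of the same items:
#' mutual information normalized by `sqrt(H(a) * H(b))`, in `[0, 1]`. When
#' either partition has a single class (zero entropy), the value is 1 if the
#' two partitions are identical as partitions and 0 otherwise.
#'
#' @param labels_a,labels_b equal-length label vectors (any type coercible to
#'   factor).
#' @return NMI in `[0, 1]`.
#' @export
clustering_agreement <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop_input("labelings differ in length")
  if (length(labels_a) == 0L) stop_input("empty labelings")
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  pij <- tab / n
  pi <- rowSums(pij); pj <- colSums(pij)
  ha <- -sum(ifelse(pi > 0, pi * log(pi), 0))
  hb <- -sum(ifelse(pj > 0, pj * log(pj), 0))
  if (ha == 0 || hb == 0) {
    same <- all(apply(tab > 0, 1L, sum) == 1L) && all(apply(tab > 0, 2L, sum) == 1L)
    return(if (same) 1 else 0)
  }
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / (pi[row(pij)[nz]] * pj[col(pij)[nz]])))
  max(0, min(1, mi / sqrt(ha * hb)))
}
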
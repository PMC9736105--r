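#' Fit a PCA feature-selection model
#'
#' Principal component analysis of the feature matrix, used to reduce the
#' backbone features to the `d` dimensions that are clustered. Components are
#' ordered by decreasing explained variance; the sign of each component is
#' fixed so that its largest-magnitude loading is positive, making the fit
#' deterministic.
#'
#' @param features `N x D` numeric matrix (`N >= 2`).
#' @param n_components number of retained components `d`; default
#'   `min(256, N - 1, D)`.
#' @param whiten if `TRUE`, projected coordinates are scaled to unit variance
#'   per component.
#' @return object of class `rc_reduction`: `rotation` (`D x d` orthonormal),
#'   `center`, `sdev`, `explained_variance_ratio`, `whiten`, `n_components`.
#' @export
fit_reduction <- function(features, n_components = NULL, whiten = FALSE) {
  features <- as.matrix(features)
  n <- nrow(features); d_in <- ncol(features)
  if (n < 2) stop_input("PCA needs at least two rows")
  n_components <- as.integer(n_components %||% min(256L, n - 1L, d_in))
  if (n_components < 1 || n_components > min(n - 1L, d_in)) {
    stop_input(sprintf("n_components must be in [1, %d]", min(n - 1L, d_in)))
  }
  pc <- prcomp(features, center = TRUE, scale. = FALSE, rank. = n_components)
  rot <- pc$rotation
  # sign convention: largest-|loading| positive
  flips <- vapply(seq_len(ncol(rot)), function(j) {
    v <- rot[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  rot <- sweep(rot, 2L, flips, `*`)
  total_var <- sum(apply(features, 2L, var))
  sdev <- pc$sdev[seq_len(n_components)]
  structure(list(rotation = rot, center = pc$center, sdev = sdev,
                 explained_variance_ratio = sdev^2 / total_var,
                 whiten = isTRUE(whiten), n_components = n_components),
            class = "rc_reduction")
}

#' Project features through a fitted PCA model
#'
#' @param model an [fit_reduction()] object.
#' @param features `N x D` matrix with `D` matching the fit.
#' @return `N x d` matrix of projected (optionally whitened) coordinates.
#' @export
apply_reduction <- function(model, features) {
  stopifnot(inherits(model, "rc_reduction"))
  features <- as.matrix(features)
  if (ncol(features) != length(model$center)) {
    stop_input(sprintf("feature dimension %d does not match the fitted model (%d)",
                       ncol(features), length(model$center)))
  }
  scores <- sweep(features, 2L, model$center) %*% model$rotation
  if (model$whiten) {
    sdev <- ifelse(model$sdev > 0, model$sdev, 1)
    scores <- sweep(scores, 2L, sdev, `/`)
  }
  rownames(scores) <- rownames(features)
  scores
}

#' L2-normalize feature rows
#'
#' Scales every row to unit Euclidean norm, so that no single image's feature
#' magnitude dominates the clustering geometry. Zero rows are left at zero and
#' counted in a warning.
#'
#' @param features numeric matrix.
#' @return matrix of the same shape; non-zero rows have norm 1.
#' @export
l2_normalize <- function(features) {
  features <- as.matrix(features)
  norms <- sqrt(rowSums(features^2))
  zero <- norms == 0
  if (any(zero)) {
    warning(sprintf("%d zero row(s) left unnormalized", sum(zero)))
    norms[zero] <- 1
  }
  features / norms
}
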
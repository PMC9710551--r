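# Dimensionality reduction fitted strictly on training rows.

#' Fit a principal component analysis model
#'
#' Centred (optionally standardised) linear projection; components are
#' ordered by decreasing explained variance and the effective dimension is
#' `min(n_components, rank)`.
#'
#' @param X numeric matrix (n x d), n >= 2.
#' @param n_components requested output dimension.
#' @param standardize divide each feature by its training standard
#'   deviation before the rotation (constant features are left unscaled).
#' @return object of class `savanno_pca`: `center`, `scale`, `rotation`
#'   (d x k), `sdev`, `explained_variance_ratio`, `k`.
#' @export
fit_pca <- function(X, n_components, standardize = TRUE) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) sv_stop("savanno_config", "PCA needs at least two rows")
  if (!is_count(n_components)) {
    sv_stop("savanno_config", "n_components must be a positive integer")
  }
  center <- colMeans(X)
  scl <- rep(1, ncol(X))
  if (standardize) {
    s <- apply(X, 2L, stats::sd)
    scl <- ifelse(is.finite(s) & s > 1e-12, s, 1)
  }
  Xs <- sweep(sweep(X, 2L, center, "-"), 2L, scl, "/")
  sv <- svd(Xs, nu = 0)
  tol <- max(dim(Xs)) * max(sv$d) * .Machine$double.eps
  rank <- sum(sv$d > tol)
  k <- min(as.integer(n_components), rank, ncol(X))
  sdev <- sv$d / sqrt(max(1, nrow(X) - 1L))
  evr <- sdev^2 / sum(sdev^2)
  structure(list(center = center, scale = scl,
                 rotation = sv$v[, seq_len(k), drop = FALSE],
                 sdev = sdev[seq_len(k)],
                 explained_variance_ratio = evr[seq_len(k)],
                 k = k, standardize = standardize),
            class = "savanno_pca")
}

#' Project rows with a fitted PCA model
#'
#' @param model a `savanno_pca`.
#' @param X numeric matrix with the training feature dimension.
#' @return n x k matrix of projected coordinates.
#' @export
apply_pca <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$center)) {
    sv_stop("savanno_schema", "PCA dimension mismatch: model %d, input %d",
            length(model$center), ncol(X))
  }
  Xs <- sweep(sweep(X, 2L, model$center, "-"), 2L, model$scale, "/")
  Xs %*% model$rotation
}
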
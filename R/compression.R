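# PCA compression of the normalized training features.
#
# The covariance of the normalized feature vectors is eigendecomposed and the
# top-d eigenvectors form the projection. The projection itself is applied
# uncentered by default (X = P' Fbar, following the printed transform);
# nearest-neighbour distances are translation-invariant, so centering the
# projection does not change any classification decision. A `center` flag
# enables the centered convention.

#' Fit a PCA model to normalized training features
#'
#' Unbiased covariance (divisor `N - 1`) about the sample mean, symmetric
#' eigendecomposition, top-`d` eigenvectors by descending eigenvalue. Each
#' eigenvector's sign is fixed so its largest-magnitude entry is positive;
#' eigenvalue ties keep the decomposition order.
#'
#' @param Fnorm `n_features x N` matrix of normalized feature columns
#'   (`N >= 2`).
#' @param d Retained dimension, `1 <= d <= n_features`.
#' @param center Logical; if `TRUE`, [project()] subtracts the training mean
#'   before projecting.
#' @return A `pca_model` with `mean`, `eigvecs` (`n_features x d`), `eigvals`
#'   (length `d`, descending), `eigvals_all` and `d`.
#' @export
fit_pca <- function(Fnorm, d, center = FALSE) {
  stopifnot(is.matrix(Fnorm))
  if (!all(is.finite(Fnorm))) stop("non-finite feature matrix", call. = FALSE)
  n_feat <- nrow(Fnorm); n <- ncol(Fnorm)
  if (n < 2L) stop("need at least 2 training vectors", call. = FALSE)
  if (!(d >= 1L && d <= n_feat))
    stop("`d` must be between 1 and the number of features", call. = FALSE)
  m <- rowMeans(Fnorm)
  Xc <- Fnorm - m
  Cov <- tcrossprod(Xc) / (n - 1)
  e <- eigen(Cov, symmetric = TRUE)
  V <- e$vectors
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  structure(list(mean = m, eigvecs = V[, seq_len(d), drop = FALSE],
                 eigvals = e$values[seq_len(d)], eigvals_all = e$values,
                 d = as.integer(d), center = isTRUE(center)),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d -> %d dims; leading eigenvalues: %s\n",
              length(x$mean), x$d,
              paste(signif(x$eigvals, 4), collapse = ", ")))
  invisible(x)
}

#' Project feature vectors into the retained PCA subspace
#'
#' `x = P' f` (uncentered by default; `P' (f - m)` when the model was fitted
#' with `center = TRUE`).
#'
#' @param model A `pca_model`.
#' @param fv Feature vector of length `n_features`, or a matrix with one
#'   vector per column.
#' @return Length-`d` vector, or `d x n` matrix for matrix input.
#' @export
project <- function(model, fv) {
  stopifnot(inherits(model, "pca_model"))
  vec_in <- !is.matrix(fv)
  x <- if (vec_in) matrix(fv, ncol = 1L) else fv
  if (nrow(x) != length(model$mean))
    stop("feature dimension does not match the PCA model", call. = FALSE)
  if (model$center) x <- x - model$mean
  out <- crossprod(model$eigvecs, x)
  if (vec_in) drop(out) else out
}

#' Attach a fitted PCA model and compressed features to a training database
#'
#' @param db A `training_db`.
#' @param d Retained dimension.
#' @param center Passed to [fit_pca()].
#' @return The database with `pca` and compressed training matrix `X`
#'   (`d x N_tr`) filled in.
#' @export
compress_db <- function(db, d, center = FALSE) {
  stopifnot(inherits(db, "training_db"))
  db$pca <- fit_pca(db$Fnorm, d, center = center)
  db$X <- project(db$pca, db$Fnorm)
  db
}
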
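# Nearest-neighbour classification in the compressed feature space and
# accuracy/confusion evaluation.

#' Nearest-neighbour classification of compressed test features
#'
#' In `per_class` mode `x_test` holds one compressed test vector per class
#' (the vector computed against that class's basis bank); the candidate
#' distance for class `p` is the minimum Euclidean distance between the
#' class-`p` test vector and the class-`p` training vectors, and the
#' predicted class minimizes over `p`. In `single_bank` mode `x_test` is one
#' vector and the label of the globally nearest training vector is returned.
#' Ties break to the lowest class index, then the lowest training-vector
#' index.
#'
#' @param x_test `d x P` matrix (per_class; column `p` is the class-`p` test
#'   vector) or length-`d` vector (single_bank).
#' @param db A compressed `training_db` (see [compress_db()]).
#' @param mode `"per_class"` or `"single_bank"`.
#' @return Predicted integer class label.
#' @export
nn_classify <- function(x_test, db, mode = c("per_class", "single_bank")) {
  stopifnot(inherits(db, "training_db"))
  if (is.null(db$X) || ncol(db$X) == 0L)
    stop("database has no compressed training vectors; run compress_db()",
         call. = FALSE)
  mode <- match.arg(mode)
  if (mode == "per_class") {
    if (!is.matrix(x_test)) x_test <- matrix(x_test, ncol = 1L)
    if (ncol(x_test) != length(db$classes))
      stop("per_class mode needs one test vector per class", call. = FALSE)
    if (nrow(x_test) != nrow(db$X))
      stop("test vector dimension does not match the database", call. = FALSE)
    cand <- vapply(seq_along(db$classes), function(j) {
      cols <- db$X[, db$labels == db$classes[j], drop = FALSE]
      min(colSums((cols - x_test[, j])^2))
    }, numeric(1))
    db$classes[which.min(cand)]  # which.min takes the first (lowest class)
  } else {
    x_test <- as.numeric(x_test)
    if (length(x_test) != nrow(db$X))
      stop("test vector dimension does not match the database", call. = FALSE)
    d2 <- colSums((db$X - x_test)^2)
    min(db$labels[d2 == min(d2)])
  }
}

#' Classify a raw radar test segment end to end
#'
#' Computes the per-class (or per-instance) test features, normalizes with the
#' training extrema, projects with the database's PCA model and applies the
#' nearest-neighbour rule.
#'
#' @param signal A `radar_signal` of one window length.
#' @param db A compressed `training_db`.
#' @param mode `"per_instance"` (default; the feature is recomputed against
#'   each training window's own bank and compared to that window's stored
#'   vector) or `"per_class"` (fast single-bank approximation).
#' @return Predicted integer class label.
#' @export
classify_signal <- function(signal, db,
                            mode = c("per_instance", "per_class")) {
  mode <- match.arg(mode)
  classify_from_features(test_feature(signal, db, mode), db, mode)
}

#' Classify precomputed test features
#'
#' Separating feature extraction ([test_feature()]) from the decision lets
#' the same features be reused across PCA dimensions (features do not depend
#' on `d`).
#'
#' @param tf Output of [test_feature()] in the matching mode.
#' @param db A compressed `training_db`.
#' @param mode `"per_instance"` or `"per_class"`.
#' @return Predicted integer class label.
#' @export
classify_from_features <- function(tf, db,
                                   mode = c("per_instance", "per_class")) {
  mode <- match.arg(mode)
  if (is.null(db$pca))
    stop("database has no PCA model; run compress_db()", call. = FALSE)
  if (mode == "per_class") {
    nn_classify(project(db$pca, tf), db, "per_class")
  } else {
    cand <- vapply(seq_along(db$classes), function(j) {
      key <- as.character(db$classes[j])
      Z <- project(db$pca, tf[[key]])
      if (!is.matrix(Z)) Z <- matrix(Z, ncol = 1L)
      cols <- db$X[, db$labels == db$classes[j], drop = FALSE]
      # each instance feature is paired with its own stored training vector
      min(colSums((Z - cols)^2))
    }, numeric(1))
    db$classes[which.min(cand)]
  }
}

#' Evaluate predictions against ground truth
#'
#' @param predictions,truths Equal-length integer label vectors with labels in
#'   `1..n_classes`.
#' @param n_classes Number of classes (default: largest label seen).
#' @return An `eval_result`: overall accuracy `Pc`, counts `Ncc`/`Ns`,
#'   `P x P` confusion matrix (rows = truth, columns = prediction) and
#'   per-class accuracy.
#' @export
evaluate <- function(predictions, truths, n_classes = NULL) {
  stopifnot(length(predictions) == length(truths), length(truths) >= 1L)
  n_classes <- n_classes %||% max(c(predictions, truths))
  if (any(predictions < 1L | predictions > n_classes) ||
      any(truths < 1L | truths > n_classes))
    stop("labels must lie in 1..n_classes", call. = FALSE)
  lv <- seq_len(n_classes)
  confusion <- table(factor(truths, levels = lv),
                     factor(predictions, levels = lv))
  confusion <- matrix(confusion, n_classes, n_classes,
                      dimnames = list(truth = lv, predicted = lv))
  ncc <- sum(diag(confusion))
  ns <- length(truths)
  row_n <- rowSums(confusion)
  structure(list(Pc = ncc / ns, Ncc = ncc, Ns = ns, confusion = confusion,
                 per_class_Pc = ifelse(row_n > 0, diag(confusion) / row_n,
                                       NA_real_)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> Pc = %.4f (%d/%d)\n", x$Pc, x$Ncc, x$Ns))
  print(x$confusion)
  invisible(x)
}
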
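# Classification: GFK-kernel SVM (domain-adapted arm), plain linear SVM
# (baseline arm) and the evaluation conventions (per-task F1 with the
# undefined "-" policy, macro F1, accuracy, confusion matrix).

as_domain <- function(x) {
  if (inherits(x, "domain_dataset")) x else domain_dataset(as.matrix(x))
}

ensure_standardized <- function(domain) {
  if (domain$standardized) domain else standardize(domain)
}

#' Fit a geodesic-flow-kernel SVM for unsupervised domain adaptation
#'
#' The full adaptation pipeline: both domains are standardized with their own
#' statistics, the subspace dimension is chosen by the subspace disagreement
#' measure (unless `d` is given), PCA subspaces and their principal-angle
#' decomposition yield the closed-form geodesic kernel G, and a C-SVM is
#' trained on the precomputed source kernel `XS G XS'` (one-vs-one
#' multi-class).  Target labels are never used.
#'
#' @param source labelled [domain_dataset] (>= 2 classes).
#' @param target unlabelled [domain_dataset] (labels, if present, are
#'   ignored by the fit).
#' @param C SVM cost parameter (default 1).
#' @param d subspace dimension; default `NULL` selects it via
#'   [select_dimension].
#' @return An object of class `gfk_svm` with `predict`, `print` and
#'   `summary` methods.
#' @seealso [fit_predict_da], [fit_predict_baseline]
#' @export
gfk_svm <- function(source, target, C = 1, d = NULL) {
  source <- ensure_standardized(as_domain(source))
  target <- ensure_standardized(as_domain(target))
  if (is.null(source$labels)) stop("source must be labelled", call. = FALSE)
  if (length(unique(source$labels)) < 2L) {
    stop("source labels must cover at least two classes", call. = FALSE)
  }
  if (ncol(source$X) != ncol(target$X)) {
    stop("feature dimension mismatch", call. = FALSE)
  }
  stopifnot(is.numeric(C), C > 0)
  sdm <- NULL
  if (is.null(d)) {
    sdm <- select_dimension(source$X, target$X)
    d <- sdm$d_star
  }
  PS <- pca_basis(source$X, d)
  PT <- pca_basis(target$X, d)
  dec <- principal_angles(PS, PT)
  gk <- geodesic_kernel(dec, PS)
  # G is PSD, so training a linear SVM on the explicit feature map
  # Z = X Q sqrt(lambda) (G = Q diag(lambda) Q') is exactly the SVM with
  # precomputed kernel x' G y, and much cheaper than kernelized training.
  eg <- eigen(gk$G, symmetric = TRUE)
  keep <- eg$values > 1e-10
  fmap <- eg$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(eg$values[keep]), sum(keep))
  y <- factor(source$labels)
  model <- e1071::svm(source$X %*% fmap, y, kernel = "linear", cost = C,
                      scale = FALSE)
  structure(list(svm = model, kernel = gk, fmap = fmap, sdm = sdm,
                 d = as.integer(d), source = source, target = target, C = C,
                 levels = levels(y)),
            class = "gfk_svm")
}

#' Predict task labels from a fitted GFK SVM
#'
#' @param object a fitted [gfk_svm].
#' @param newdata optional [domain_dataset] or feature matrix on the original
#'   (unstandardized) feature scale of the target domain; defaults to the
#'   target domain the model was fitted with.
#' @param ... unused.
#' @return A character vector of predicted task labels.
#' @export
predict.gfk_svm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    Xt <- object$target$X
  } else if (inherits(newdata, "domain_dataset")) {
    Xt <- ensure_standardized(newdata)$X
  } else {
    Xt <- sweep(sweep(as.matrix(newdata), 2, object$target$center, `-`),
                2, object$target$scale, `/`)
  }
  as.character(predict(object$svm, Xt %*% object$fmap))
}

#' @export
print.gfk_svm <- function(x, ...) {
  cat(sprintf(paste0("<gfk_svm> %d source windows (%d classes) -> %d target",
                     " windows\n  subspace d = %d, C = %g\n"),
              nrow(x$source$X), length(x$levels), nrow(x$target$X), x$d, x$C))
  invisible(x)
}

#' @export
summary.gfk_svm <- function(object, ...) {
  theta <- object$kernel$decomposition$theta
  cat("Geodesic flow kernel SVM\n")
  cat(sprintf("  source: %d windows, %d classes (%s)\n",
              nrow(object$source$X), length(object$levels),
              paste(object$levels, collapse = ", ")))
  cat(sprintf("  target: %d windows (unlabelled)\n", nrow(object$target$X)))
  cat(sprintf("  subspace dimension d = %d%s\n", object$d,
              if (!is.null(object$sdm)) " (SDM-selected)" else " (fixed)"))
  cat(sprintf("  principal angles: min %.3f, max %.3f rad\n",
              min(theta), max(theta)))
  invisible(object)
}

#' Domain-adapted and baseline label prediction
#'
#' `fit_predict_da()` runs the full GFK pipeline and predicts target labels;
#' `fit_predict_baseline()` trains a linear-kernel C-SVM on the standardized
#' source features with no adaptation and predicts the standardized target
#' features.  Both are deterministic given their inputs.
#'
#' @param source labelled [domain_dataset].
#' @param target unlabelled [domain_dataset].
#' @param svm_C SVM cost parameter.
#' @param d optional fixed subspace dimension (DA arm only).
#' @return Character vector of predicted target labels.
#' @rdname fit_predict
#' @export
fit_predict_da <- function(source, target, svm_C = 1, d = NULL) {
  predict(gfk_svm(source, target, C = svm_C, d = d))
}

#' @rdname fit_predict
#' @export
fit_predict_baseline <- function(source, target, svm_C = 1) {
  source <- ensure_standardized(as_domain(source))
  target <- ensure_standardized(as_domain(target))
  if (is.null(source$labels)) stop("source must be labelled", call. = FALSE)
  if (length(unique(source$labels)) < 2L) {
    stop("source labels must cover at least two classes", call. = FALSE)
  }
  stopifnot(is.numeric(svm_C), svm_C > 0)
  y <- factor(source$labels)
  model <- e1071::svm(source$X, y, kernel = "linear", cost = svm_C,
                      scale = FALSE)
  as.character(predict(model, target$X))
}

#' Evaluate predictions with the per-task F1 conventions
#'
#' Per-task F1 is `2PR/(P + R)`; when a task's precision or recall
#' denominator is zero (the task was never predicted, or never occurs in the
#' truth) its F1 is undefined and reported as `NA` (the tables' "-"
#' convention).  The overall (macro) F1 is the unweighted mean of per-task
#' F1 and is undefined if any per-task F1 is.  Accuracy is the exact-match
#' fraction and is always defined.
#'
#' @param y_true,y_pred equal-length label vectors drawn from
#'   `task_vocabulary`.
#' @param task_vocabulary the task labels evaluated (default: tasks present
#'   in `y_true`).
#' @param rod_bar optional mean ROD to attach to the report.
#' @return An object of class `evaluation_report` with fields `per_task_f1`,
#'   `overall_f1`, `accuracy`, `confusion`, `n`, `rod_bar`.
#' @export
evaluate <- function(y_true, y_pred, task_vocabulary = NULL, rod_bar = NA_real_) {
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` must have equal length", call. = FALSE)
  }
  if (is.null(task_vocabulary)) task_vocabulary <- sort(unique(as.character(y_true)))
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (!all(c(y_true, y_pred) %in% task_vocabulary)) {
    stop("labels outside the task vocabulary", call. = FALSE)
  }
  tt <- factor(y_true, levels = task_vocabulary)
  pp <- factor(y_pred, levels = task_vocabulary)
  conf <- table(truth = tt, predicted = pp)
  tp <- diag(conf)
  n_true <- rowSums(conf)
  n_pred <- colSums(conf)
  f1 <- rep(NA_real_, length(task_vocabulary))
  names(f1) <- task_vocabulary
  ok <- n_true > 0 & n_pred > 0
  prec <- tp[ok] / n_pred[ok]
  rec <- tp[ok] / n_true[ok]
  pr <- prec + rec
  f1[ok] <- ifelse(pr > 0, 2 * prec * rec / pr, 0)
  structure(list(per_task_f1 = f1,
                 overall_f1 = if (anyNA(f1)) NA_real_ else mean(f1),
                 accuracy = mean(y_true == y_pred),
                 confusion = conf,
                 n = length(y_true),
                 rod_bar = rod_bar),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, digits = 3, ...) {
  f1 <- ifelse(is.na(x$per_task_f1), "-",
               formatC(x$per_task_f1, digits = digits, format = "f"))
  cat("<evaluation_report>\n")
  cat("  per-task F1: ",
      paste(sprintf("%s=%s", names(x$per_task_f1), f1), collapse = " "), "\n")
  cat(sprintf("  overall F1: %s   accuracy: %.3f   n = %d\n",
              if (is.na(x$overall_f1)) "-" else
                formatC(x$overall_f1, digits = digits, format = "f"),
              x$accuracy, x$n))
  if (!is.na(x$rod_bar)) cat(sprintf("  mean ROD: %.4f\n", x$rod_bar))
  invisible(x)
}
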
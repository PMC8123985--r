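#' Tune an RBF-SVM by dyadic grid search with stratified cross-validation
#'
#' Searches `C` and `gamma` over the dyadic grid `2^-10 .. 2^10` (integer
#' exponents, 21 x 21 combinations), scoring each pair by pooled k-fold
#' stratified cross-validation overall accuracy of the one-vs-one RBF-SVM.
#' Ties are broken toward the smallest `gamma` (smoothest kernel), then
#' the largest `C`: with a soft margin that is too loose, leave-one-out
#' folds — whose training halves are one sample short of class balance —
#' degenerate into majority voting even when balanced CV folds score
#' perfectly, so among equally scoring cells the hard-margin end is the
#' one whose jackknife behaviour matches its CV estimate.
#'
#' @param X Numeric feature matrix (samples x features).
#' @param y Class labels, at least 2 classes.
#' @param seed Seed for the fold assignment.
#' @param exponents Integer exponents of the dyadic grid (default -10:10).
#' @param folds Cross-validation folds (default 10); reduced with a
#'   warning, never below 2, when the smallest class has fewer members.
#' @param standardize Scale features by training-fold standard deviations
#'   inside each fold (centering cancels in the RBF kernel).
#' @return An `svm_params` object: list with `C`, `gamma`, `cv_accuracy`,
#'   `folds`, `seed`.
#' @export
svm_grid_search <- function(X, y, seed = 1L, exponents = -10:10,
                            folds = 10L, standardize = TRUE) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  if (nrow(X) < 20L) stop("grid search needs at least 20 samples")
  yi <- as.integer(factor(as.character(y)))
  if (max(yi) < 2L) stop("degenerate problem: all labels identical")
  cls_min <- min(tabulate(yi))
  if (cls_min < folds) {
    folds <- max(2L, cls_min)
    warning("smallest class has ", cls_min,
            " members; reducing CV folds to ", folds)
  }
  fold <- integer(length(yi))
  local_seed(seed, {
    for (k in seq_len(max(yi))) {
      members <- sample(which(yi == k))
      fold[members] <- rep_len(seq_len(folds), length(members))
    }
  })
  grid <- 2^exponents
  acc <- cv_grid_cpp(X, yi, fold, grid, grid, standardize)
  # ties -> smallest gamma (col), then largest C (row)
  best <- which(acc == max(acc), arr.ind = TRUE)
  best <- best[order(best[, 2L], -best[, 1L]), , drop = FALSE][1L, ]
  structure(list(C = grid[best[[1L]]], gamma = grid[best[[2L]]],
                 cv_accuracy = max(acc), folds = folds,
                 seed = as.integer(seed)),
            class = "svm_params")
}

#' @export
print.svm_params <- function(x, ...) {
  cat(sprintf("svm_params: C = 2^%g, gamma = 2^%g (CV accuracy %.4f, %d folds)\n",
              log2(x$C), log2(x$gamma), x$cv_accuracy, x$folds))
  invisible(x)
}

#' Jackknife (leave-one-out) evaluation of the one-vs-one RBF-SVM
#'
#' Fits `n` models, each predicting its single held-out sample; the report
#' is assembled from the `n` predictions.  Standardization statistics are
#' refit on the `n - 1` training samples of every fold.  A singleton class
#' is predicted by a model trained without it (it can never be recovered);
#' such classes are flagged in the report.
#'
#' @param X Numeric feature matrix.
#' @param y Class labels (`n >= 4`, at least 2 classes).
#' @param params An `svm_params` (or list with `C` and `gamma`); ignored
#'   when `nested = TRUE`.
#' @param standardize As in [svm_grid_search()].
#' @param nested Re-run the full grid search on the `n - 1` training
#'   samples of every fold (leak-free but roughly `n` times slower).
#' @param seed Fold-assignment seed for the nested grid searches.
#' @return An `eval_report`, see [metrics_from_confusion()]; also carries
#'   `predictions` and `params`.
#' @export
jackknife_evaluate <- function(X, y, params, standardize = TRUE,
                               nested = FALSE, seed = 1L) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), nrow(X) >= 4L)
  yf <- factor(as.character(y))
  if (nlevels(yf) < 2L) stop("need at least 2 classes")
  if (isTRUE(nested)) {
    pred_i <- vapply(seq_len(nrow(X)), function(i) {
      p <- svm_grid_search(X[-i, , drop = FALSE], yf[-i], seed = seed,
                           standardize = standardize)
      s <- if (standardize) {
        sdv <- apply(X[-i, , drop = FALSE], 2L, stats::sd)
        ifelse(sdv < 1e-12, 1, sdv)
      } else rep(1, ncol(X))
      A <- sweep(X, 2L, s, "/")
      D <- as.matrix(stats::dist(A))^2
      K <- exp(-p$gamma * D)
      ovo_predict_cpp(K[-i, -i, drop = FALSE], as.integer(yf)[-i],
                      K[i, -i, drop = FALSE], nlevels(yf), p$C)
    }, integer(1))
    params <- list(C = NA_real_, gamma = NA_real_)
  } else {
    pred_i <- jackknife_cpp(X, as.integer(yf), params$C, params$gamma,
                            standardize)
  }
  pred <- levels(yf)[pred_i]
  conf <- confusion_matrix(as.character(y), pred, levels(yf))
  rep <- metrics_from_confusion(conf)
  rep$predictions <- pred
  rep$params <- list(C = params$C, gamma = params$gamma)
  rep$singleton_classes <- levels(yf)[tabulate(yf) == 1L]
  rep
}

#' Per-class metrics and accuracies from a confusion matrix
#'
#' One-vs-rest decomposition per class: `Sens = TP/(TP+FN)`,
#' `Spec = TN/(FP+TN)`, `F1 = 2TP/(2TP+FN+FP)`, per-class accuracy
#' `TP_i/|C_i|`, overall accuracy `sum(TP_i)/sum(|C_i|)`.  Ratios with a
#' zero denominator are reported as 0 and flagged.
#'
#' @param confusion Square non-negative count matrix, rows = true class.
#' @return An `eval_report`: list with `confusion`, `per_class`
#'   (data.frame: class, n, accuracy, sens, spec, f1, zero_division),
#'   `overall_accuracy`.
#' @export
metrics_from_confusion <- function(confusion) {
  conf <- as.matrix(confusion)
  stopifnot(nrow(conf) == ncol(conf), all(conf >= 0))
  classes <- rownames(conf) %||% paste0("class", seq_len(nrow(conf)))
  n <- sum(conf)
  tp <- diag(conf)
  fn <- rowSums(conf) - tp
  fp <- colSums(conf) - tp
  tn <- n - tp - fn - fp
  safe <- function(num, den) ifelse(den > 0, num / den, 0)
  per_class <- data.frame(
    class = classes,
    n = rowSums(conf),
    accuracy = safe(tp, rowSums(conf)),
    sens = safe(tp, tp + fn),
    spec = safe(tn, fp + tn),
    f1 = safe(2 * tp, 2 * tp + fn + fp),
    zero_division = (rowSums(conf) == 0) | (fp + tn == 0),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(confusion = conf, per_class = per_class,
                 overall_accuracy = if (n > 0) sum(tp) / n else 0),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report: overall accuracy",
      sprintf("%.4f", x$overall_accuracy), "\n")
  df <- x$per_class
  df[c("accuracy", "sens", "spec", "f1")] <-
    lapply(df[c("accuracy", "sens", "spec", "f1")],
           function(v) sprintf("%.2f%%", 100 * v))
  print(df[c("class", "n", "accuracy", "sens", "spec", "f1")],
        row.names = FALSE)
  if (length(x$singleton_classes %||% character(0)) > 0L) {
    cat("singleton classes (unlearnable in jackknife):",
        paste(x$singleton_classes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize / restore an evaluation report as JSON
#'
#' Round-trips exactly: `read_eval_report(write_eval_report(r, p))` equals
#' `r` up to numeric representation in JSON.
#'
#' @param report An `eval_report`.
#' @param path Output path.
#' @return `write_eval_report`: the path, invisibly.
#' @export
write_eval_report <- function(report, path) {
  obj <- list(confusion = unclass(as.matrix(report$confusion)),
              classes = rownames(report$confusion),
              per_class = report$per_class,
              overall_accuracy = report$overall_accuracy,
              predictions = report$predictions,
              params = report$params,
              singleton_classes = report$singleton_classes)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_eval_report
#' @export
read_eval_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  conf <- as.matrix(obj$confusion)
  dimnames(conf) <- list(obj$classes, obj$classes)
  structure(list(confusion = conf,
                 per_class = as.data.frame(obj$per_class),
                 overall_accuracy = obj$overall_accuracy,
                 predictions = obj$predictions,
                 params = obj$params,
                 singleton_classes = obj$singleton_classes),
            class = "eval_report")
}
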
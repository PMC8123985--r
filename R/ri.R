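#' Relative-importance scores from a random forest of entropy trees
#'
#' The `d` candidate features are shuffled once and partitioned into `s`
#' contiguous subsets of near-equal size `m = ceiling(d/s)`.  For each
#' subset, `t` times: half of the samples are drawn (without replacement)
#' as a training half, a tree is grown on the subset's features, and the
#' tree's weighted classification rate `w` (macro-averaged recall) is
#' measured on the held-out half.  A feature's relative importance is
#'
#' `RI(g) = sum over trees tau of w_tau * sum over tau's nodes splitting
#' on g of IG(node) * n(node) / n(root)`.
#'
#' Features never used in any split have RI = 0.  All stochastic steps
#' draw from a single seeded generator, so results are reproducible.
#'
#' @param X Numeric matrix (samples x features, named columns).
#' @param y Class labels, length `nrow(X)`.
#' @param s Number of feature subsets; default `ceiling(d / 30)` (about
#'   30 features per subset).
#' @param t Trees per subset (default 50).
#' @param seed Integer seed.
#' @param min_samples_split,max_depth Tree growth controls, see
#'   [build_tree()].
#' @param max_retries Resampling attempts when a class is absent from a
#'   test half.
#' @param keep_trees Keep the fitted trees (with their `w` and feature
#'   subsets) in the result, for auditing/oracles.  Off by default.
#' @return An `ri_result`: list with `ri` (named numeric, original column
#'   order), `s`, `t`, `m`, `seed`, and optionally `trees`.
#' @export
ri_scores <- function(X, y, s = NULL, t = 50L, seed = 1L,
                      min_samples_split = 2L, max_depth = Inf,
                      max_retries = 100L, keep_trees = FALSE) {
  stopifnot(is.matrix(X), nrow(X) == length(y), nrow(X) >= 4L)
  d <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(d))
  s <- as.integer(s %||% ceiling(d / 30))
  if (!(d >= s && s >= 1L)) stop("need d >= s >= 1 (d = ", d, ", s = ", s, ")")
  if (t < 1L) stop("t must be >= 1")
  n <- nrow(X)
  classes <- sort(unique(as.character(y)))
  y <- as.character(y)
  ri <- stats::setNames(numeric(d), colnames(X))
  trees <- if (keep_trees) vector("list", s * t) else NULL
  m <- as.integer(ceiling(d / s))

  local_seed(seed, {
    perm <- sample.int(d)
    subsets <- split(colnames(X)[perm],
                     rep(seq_len(s), each = m, length.out = d))
    k <- 0L
    for (sub in subsets) {
      for (rep in seq_len(t)) {
        tr <- NULL
        for (try in seq_len(max_retries)) {
          cand <- sample.int(n, n %/% 2L)
          if (all(classes %in% y[-cand])) { tr <- cand; break }
        }
        if (is.null(tr)) {
          stop("could not draw a test half containing every class after ",
               max_retries, " attempts")
        }
        fit <- build_tree(X[tr, sub, drop = FALSE], y[tr],
                          min_samples_split = min_samples_split,
                          max_depth = max_depth, classes = classes)
        pred <- predict(fit, X[-tr, sub, drop = FALSE])
        w <- weighted_rate(confusion_matrix(y[-tr], pred, classes))
        n_root <- fit$root$n_samples
        walk_tree(fit$root, function(node) {
          ri[node$feature] <<- ri[node$feature] +
            w * node$info_gain * node$n_samples / n_root
        })
        k <- k + 1L
        if (keep_trees) {
          trees[[k]] <- list(tree = fit, w = w, features = sub)
        }
      }
    }
  })
  structure(list(ri = ri, s = s, t = as.integer(t), m = m,
                 seed = as.integer(seed), trees = trees),
            class = "ri_result")
}

#' @export
print.ri_result <- function(x, ...) {
  cat("ri_result:", length(x$ri), "features,", x$s, "subsets x", x$t,
      "trees (m =", x$m, ", seed =", x$seed, ")\n")
  top <- sort(x$ri, decreasing = TRUE)[seq_len(min(5L, length(x$ri)))]
  cat("top features:\n")
  print(round(top, 4))
  invisible(x)
}

#' Rank features by RI and pick the best nested subset size
#'
#' Features are ranked by RI descending (ties broken stably by feature
#' name); for each candidate size `q` in `size_grid` the evaluation
#' function is applied to the top-`q` features, and the chosen subset is
#' the smallest `q` attaining the maximum score.
#'
#' @param X,y As in [ri_scores()].
#' @param ri An `ri_result` (or a named numeric vector of RI scores).
#' @param size_grid Integer vector of candidate sizes, each `<= ncol(X)`.
#' @param eval_fn `function(X_subset, y) -> scalar score`.  The default
#'   tunes an RBF-SVM by grid search on the subset and returns jackknife
#'   overall accuracy (see [make_jackknife_eval()]).
#' @param verbose Print per-size scores as they are computed.
#' @return List with `ranked` (all features, best first), `scores` (named
#'   by size), `chosen_size`, `chosen` (the selected feature names).
#' @export
select_feature_subset <- function(X, y, ri, size_grid,
                                  eval_fn = make_jackknife_eval(),
                                  verbose = FALSE) {
  ri_vec <- if (inherits(ri, "ri_result")) ri$ri else ri
  stopifnot(!is.null(colnames(X)), all(colnames(X) %in% names(ri_vec)))
  if (length(size_grid) == 0L) stop("size_grid must be non-empty")
  size_grid <- sort(unique(as.integer(size_grid)))
  if (any(size_grid < 1L) || any(size_grid > ncol(X))) {
    stop("size_grid values must be in [1, ncol(X)]")
  }
  ri_vec <- ri_vec[colnames(X)]
  ranked <- names(ri_vec)[order(-ri_vec, names(ri_vec))]
  scores <- stats::setNames(numeric(length(size_grid)), size_grid)
  for (i in seq_along(size_grid)) {
    q <- size_grid[i]
    scores[i] <- eval_fn(X[, ranked[seq_len(q)], drop = FALSE], y)
    if (verbose) message("  size ", q, ": score ", round(scores[i], 4))
  }
  chosen_size <- size_grid[which.max(scores)]  # first max -> smallest size
  list(ranked = ranked, scores = scores, chosen_size = chosen_size,
       chosen = ranked[seq_len(chosen_size)])
}

#' Default subset evaluator: jackknife overall accuracy of an RBF-SVM
#'
#' Returns a closure suitable for [select_feature_subset()]'s `eval_fn`.
#' With `params = NULL` the SVM is re-tuned by grid search on every
#' subset (slow); passing fixed `svm_params` reuses one tuning.
#'
#' @param params `svm_params` from [svm_grid_search()], or `NULL` to
#'   re-tune by grid search on every subset (the default: gamma's useful
#'   scale depends on the subset dimension).
#' @param seed Seed used for grid-search fold assignment when re-tuning.
#' @param standardize Standardize features inside each fold.
#' @param nested Tune inside every jackknife fold, see
#'   [jackknife_evaluate()].
#' @return `function(X, y) -> overall jackknife accuracy`.
#' @export
make_jackknife_eval <- function(params = NULL, seed = 1L, standardize = TRUE,
                                nested = FALSE) {
  force(params); force(seed); force(standardize); force(nested)
  function(X, y) {
    p <- params %||% svm_grid_search(X, y, seed = seed,
                                     standardize = standardize)
    rep <- jackknife_evaluate(X, y, p, standardize = standardize,
                              nested = nested, seed = seed)
    rep$overall_accuracy
  }
}

#' Write RI scores as a two-column TSV, descending
#'
#' @param ri An `ri_result` or named numeric vector.
#' @param path Output path.
#' @export
write_ri_tsv <- function(ri, path) {
  v <- if (inherits(ri, "ri_result")) ri$ri else ri
  o <- order(-v, names(v))
  writeLines(c("feature\tRI",
               paste0(names(v)[o], "\t", format(v[o], digits = 17,
                                                scientific = FALSE,
                                                trim = TRUE))),
             path)
  invisible(path)
}
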
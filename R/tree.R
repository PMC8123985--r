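#' Shannon entropy of a label vector, in bits
#'
#' `0 * log2(0)` is taken as 0.
#'
#' @param labels Non-empty vector of class labels.
#' @return Scalar in `[0, log2(n_classes)]`.
#' @export
entropy <- function(labels) {
  if (length(labels) == 0L) stop("entropy of an empty label set is undefined")
  p <- tabulate(as.integer(factor(labels)))
  p <- p / sum(p)
  -sum(ifelse(p > 0, p * log2(p), 0))
}

#' Information gain of a binary partition
#'
#' `IG = H(parent) - (|L|/|S|) H(L) - (|R|/|S|) H(R)`; the two children
#' must partition the parent as a multiset.
#'
#' @param parent,left,right Label vectors.
#' @return Scalar in `[0, entropy(parent)]`.
#' @export
info_gain <- function(parent, left, right) {
  if (!identical(sort(as.character(parent)),
                 sort(as.character(c(left, right))))) {
    stop("left and right do not partition the parent label multiset")
  }
  n <- length(parent)
  entropy(parent) -
    length(left) / n * entropy(left) -
    length(right) / n * entropy(right)
}

# Best axis-aligned split of (X, yi) by information gain.
# yi: integer labels 1..c.  Candidate thresholds are midpoints between
# consecutive distinct sorted values.  Ties: lower feature name, then
# smaller threshold.  Returns NULL if no split has positive gain.
# The exhaustive search runs in C++ (best_split_cpp).
best_split <- function(X, yi, nclass) {
  sp <- best_split_cpp(X, yi, nclass, order(colnames(X)))
  if (sp$fidx < 0L) return(NULL)
  list(feature = colnames(X)[sp$fidx], fidx = sp$fidx,
       threshold = sp$threshold, info_gain = sp$info_gain)
}

#' Grow an entropy/information-gain decision tree
#'
#' Binary axis-aligned threshold tree: at each node the (feature,
#' threshold) pair with maximal information gain is chosen (ties broken by
#' lower feature name, then smaller threshold; thresholds are midpoints
#' between consecutive distinct values).  Growth stops at purity, at fewer
#' than `min_samples_split` samples, at `max_depth`, or when no split has
#' positive gain.  Each internal node records its information gain and
#' sample count for relative-importance bookkeeping.
#'
#' @param X Numeric matrix (rows samples, named columns features).
#' @param y Class labels (factor or character), length `nrow(X)`.
#' @param min_samples_split Minimum samples to attempt a split (default 2).
#' @param max_depth Maximum depth (default `Inf`; root is depth 0).
#' @param classes Optional fixed class level set (for empty-class safety).
#' @return A `decision_tree` object: nested list of nodes.  Internal nodes
#'   carry `feature`, `threshold`, `info_gain`, `n_samples`, `left`,
#'   `right`; leaves carry `class` (majority, ties to first level) and
#'   `n_samples`.
#' @export
build_tree <- function(X, y, min_samples_split = 2L, max_depth = Inf,
                       classes = NULL) {
  stopifnot(is.matrix(X), nrow(X) == length(y), nrow(X) >= 1L)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  classes <- classes %||% sort(unique(as.character(y)))
  yi <- as.integer(factor(as.character(y), levels = classes))
  nclass <- length(classes)

  grow <- function(idx, depth) {
    yy <- yi[idx]
    counts <- tabulate(yy, nclass)
    maj <- classes[which.max(counts)]
    if (length(idx) < min_samples_split || depth >= max_depth ||
        max(counts) == length(idx)) {
      return(list(leaf = TRUE, class = maj, n_samples = length(idx)))
    }
    sp <- best_split(X[idx, , drop = FALSE], yy, nclass)
    if (is.null(sp)) {
      return(list(leaf = TRUE, class = maj, n_samples = length(idx)))
    }
    go_left <- X[idx, sp$fidx] <= sp$threshold
    list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
         info_gain = sp$info_gain, n_samples = length(idx),
         left = grow(idx[go_left], depth + 1L),
         right = grow(idx[!go_left], depth + 1L))
  }
  structure(list(root = grow(seq_len(nrow(X)), 0L), classes = classes),
            class = "decision_tree")
}

#' Predict classes with a fitted decision tree
#'
#' @param object A `decision_tree` from [build_tree()].
#' @param newdata Numeric matrix with (at least) the columns the tree
#'   splits on, by name.
#' @param ... Unused.
#' @return Character vector of predicted classes.
#' @export
predict.decision_tree <- function(object, newdata, ...) {
  one <- function(node, x) {
    while (!node$leaf) {
      node <- if (x[[node$feature]] <= node$threshold) node$left else node$right
    }
    node$class
  }
  vapply(seq_len(nrow(newdata)), function(i) one(object$root, newdata[i, ]), "")
}

# Walk a tree and apply f(node) to every internal node.
walk_tree <- function(node, f) {
  if (isTRUE(node$leaf)) return(invisible(NULL))
  f(node)
  walk_tree(node$left, f)
  walk_tree(node$right, f)
  invisible(NULL)
}

#' Weighted classification rate (macro-averaged recall)
#'
#' `w = (1/c) * sum_i n_ii / sum_j n_ij` over a c x c confusion matrix
#' with rows = true classes.
#'
#' @param confusion Square non-negative count matrix, rows = true class.
#' @return Scalar in `[0, 1]`.
#' @export
weighted_rate <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion))
  rs <- rowSums(confusion)
  if (any(rs == 0)) {
    stop("every true class needs at least one test sample (empty row ",
         which(rs == 0)[1L], ")")
  }
  mean(diag(confusion) / rs)
}

# Confusion matrix (plain integer matrix) of true vs predicted over a
# fixed class set; rows = true class.
confusion_matrix <- function(truth, pred, classes) {
  tab <- table(factor(truth, levels = classes),
               factor(pred, levels = classes))
  matrix(as.integer(tab), nrow = length(classes),
         dimnames = list(classes, classes))
}
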
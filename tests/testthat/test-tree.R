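test_that("entropy matches closed forms", {
  expect_equal(entropy(c("a", "a", "b", "b")), 1)
  expect_equal(entropy(rep("a", 4)), 0)
  expect_equal(entropy(c("a", "b", "c", "d")), 2)
  expect_error(entropy(character(0)), "empty")
})

test_that("info_gain matches closed forms and validates the partition", {
  p <- c("a", "a", "b", "b")
  expect_equal(info_gain(p, c("a", "a"), c("b", "b")), 1)
  expect_equal(info_gain(p, c("a", "b"), c("a", "b")), 0)
  p2 <- c("a", "a", "a", "b")
  ig <- info_gain(p2, c("a", "a"), c("a", "b"))
  expect_equal(ig, -0.75 * log2(0.75) - 0.25 * log2(0.25) - 0.5,
               tolerance = 1e-12)
  expect_equal(round(ig, 4), 0.3113)
  expect_error(info_gain(p, c("a", "a"), c("b", "a")), "partition")
})

test_that("build_tree splits by maximum IG and is deterministic", {
  X <- matrix(c(0, 0, 1, 1), ncol = 1, dimnames = list(NULL, "x"))
  y <- c("a", "a", "b", "b")
  tr <- build_tree(X, y)
  expect_false(tr$root$leaf)
  expect_equal(tr$root$threshold, 0.5)
  expect_equal(tr$root$info_gain, 1)
  expect_identical(predict(tr, X), y)

  pure <- build_tree(X, rep("a", 4))
  expect_true(pure$root$leaf)
  expect_identical(pure$root$class, "a")

  # constant features -> single majority leaf
  Xc <- matrix(1, 4, 2, dimnames = list(NULL, c("u", "v")))
  cl <- build_tree(Xc, c("a", "a", "a", "b"))
  expect_true(cl$root$leaf)
  expect_identical(cl$root$class, "a")

  withr::with_seed(5L, {
    Xr <- matrix(rnorm(80), 20, 4, dimnames = list(NULL, paste0("f", 1:4)))
    yr <- sample(c("a", "b"), 20, TRUE)
  })
  expect_identical(build_tree(Xr, yr), build_tree(Xr, yr))
})

test_that("tree node bookkeeping: child sample counts sum to parent", {
  withr::with_seed(8L, {
    X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
    y <- sample(c("a", "b", "c"), 50, TRUE)
  })
  tr <- build_tree(X, y)
  check <- function(node) {
    if (node$leaf) return(invisible(NULL))
    expect_gte(node$info_gain, 0)
    expect_identical(node$left$n_samples + node$right$n_samples,
                     node$n_samples)
    check(node$left); check(node$right)
  }
  check(tr$root)
})

test_that("weighted_rate is macro recall", {
  expect_equal(weighted_rate(matrix(c(3, 0, 1, 4), 2)), 0.875)
  expect_equal(weighted_rate(diag(c(5, 2, 7))), 1)
  expect_equal(weighted_rate(matrix(c(0, 3, 2, 0), 2)), 0)
  expect_error(weighted_rate(matrix(c(0, 1, 0, 1), 2)), "empty row")
})

test_that("ri_scores finds a planted feature, zeroes constants, reproduces", {
  hits <- 0L
  for (seed in 1:20) {
    pm <- planted_matrix(100L, 10L, 1L, 2.5, 2L, seed = seed)
    ri <- ri_scores(pm$X, pm$y, s = 2L, t = 20L, seed = seed)
    if (names(which.max(ri$ri)) == pm$informative) hits <- hits + 1L
  }
  expect_gte(hits, 18L)

  pm <- planted_matrix(60L, 8L, 2L, 2, 4L, seed = 2L)
  pm$X[, 5L] <- 1  # constant feature can never split
  ri <- ri_scores(pm$X, pm$y, t = 10L, seed = 3L)
  expect_identical(ri$ri[[colnames(pm$X)[5L]]], 0)

  r1 <- ri_scores(pm$X, pm$y, t = 5L, seed = 11L, keep_trees = TRUE)
  r2 <- ri_scores(pm$X, pm$y, t = 5L, seed = 11L, keep_trees = TRUE)
  expect_identical(r1, r2)
})

test_that("RI equals the tree-walking oracle exactly", {
  pm <- planted_matrix(80L, 12L, 3L, 1.5, 4L, seed = 6L)
  ri <- ri_scores(pm$X, pm$y, s = 2L, t = 5L, seed = 6L, keep_trees = TRUE)
  expect_length(ri$trees, 10L)
  expect_equal(ri$ri, oracle_ri_from_trees(ri, colnames(pm$X)),
               tolerance = 1e-15)
})

test_that("select_feature_subset ranks, sweeps, and breaks ties small", {
  pm <- planted_matrix(40L, 6L, 2L, 3, 2L, seed = 9L)
  ri <- ri_scores(pm$X, pm$y, t = 10L, seed = 9L)

  sel <- select_feature_subset(pm$X, pm$y, ri, size_grid = 3L,
                               eval_fn = function(X, y) 0.5)
  expect_identical(sel$chosen,
                   names(sort(ri$ri, decreasing = TRUE))[1:3])

  # equal scores at every size -> smallest size wins
  sel2 <- select_feature_subset(pm$X, pm$y, ri, size_grid = c(2L, 4L, 6L),
                                eval_fn = function(X, y) 1)
  expect_identical(sel2$chosen_size, 2L)

  # a tie in RI is broken stably by feature name
  ri0 <- stats::setNames(rep(0, 6L), colnames(pm$X))
  sel3 <- select_feature_subset(pm$X, pm$y, ri0, size_grid = 6L,
                                eval_fn = function(X, y) 1)
  expect_identical(sel3$ranked, sort(colnames(pm$X)))

  expect_error(select_feature_subset(pm$X, pm$y, ri, integer(0),
                                     eval_fn = function(X, y) 1),
               "non-empty")
})
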
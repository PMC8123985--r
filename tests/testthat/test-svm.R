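# The SMO solver is certified against the KKT optimality conditions of the
# SVM dual rather than against a reference library (none is available):
# for an optimal solution, alpha = 0 implies y f(x) >= 1, alpha = C implies
# y f(x) <= 1, and free alphas imply y f(x) = 1, all within the solver
# tolerance; additionally sum(alpha * y) = 0.
test_that("SMO solutions satisfy the KKT conditions on random problems", {
  withr::with_seed(31L, {
    for (rep in 1:10) {
      n <- 40L
      X <- matrix(rnorm(n * 3), n, 3)
      y <- c(rep(1, n / 2), rep(-1, n / 2))
      X[y > 0, 1] <- X[y > 0, 1] + runif(1, 0, 3)   # varying separability
      gamma <- runif(1, 0.05, 1)
      C <- 2^sample(-4:6, 1)
      K <- exp(-gamma * as.matrix(dist(X))^2)
      fit <- strucclass:::smo_fit_cpp(K, y, C)
      expect_lt(abs(sum(fit$alpha * y)), 1e-9)
      expect_true(all(fit$alpha >= -1e-12 & fit$alpha <= C + 1e-12))
      f <- as.vector(K %*% (fit$alpha * y)) + fit$b
      tol <- 2e-3
      at0 <- fit$alpha < 1e-10
      atC <- fit$alpha > C - 1e-10
      free <- !at0 & !atC
      expect_true(all(y[at0] * f[at0] >= 1 - tol))
      expect_true(all(y[atC] * f[atC] <= 1 + tol))
      expect_true(all(abs(y[free] * f[free] - 1) <= tol))
    }
  })
})

test_that("grid search nails separable blobs and rejects degenerate input", {
  pm <- planted_matrix(60L, 4L, 3L, 3, 2L, seed = 4L)
  p <- svm_grid_search(pm$X, pm$y, seed = 1L)
  expect_s3_class(p, "svm_params")
  expect_equal(p$cv_accuracy, 1)
  expect_true(p$C %in% 2^(-10:10) && p$gamma %in% 2^(-10:10))

  expect_error(svm_grid_search(pm$X, rep("a", 60L), seed = 1L), "degenerate")
  expect_error(svm_grid_search(pm$X[1:10, ], pm$y[1:10], seed = 1L),
               "at least 20")

  p2 <- svm_grid_search(pm$X, pm$y, seed = 1L)
  expect_identical(p, p2)

  # a class smaller than the fold count reduces folds with a warning
  y3 <- pm$y
  y3[which(pm$y == "c2")[1:3]] <- "c3"
  expect_warning(p3 <- svm_grid_search(pm$X, y3, seed = 1L), "folds")
  expect_gte(p3$folds, 2L)
})

test_that("jackknife evaluation: separable, bookkeeping, and twins", {
  pm <- planted_matrix(80L, 6L, 4L, 3, 4L, seed = 12L)
  p <- svm_grid_search(pm$X, pm$y, seed = 2L)
  rep1 <- jackknife_evaluate(pm$X, pm$y, p)
  expect_gte(rep1$overall_accuracy, 0.95)
  expect_equal(sum(rep1$confusion), 80)

  # n = 4, one per class: must not crash, confusion sums to 4,
  # singleton classes flagged
  X4 <- matrix(rnorm(16), 4, 4)
  y4 <- paste0("c", 1:4)
  rep4 <- jackknife_evaluate(X4, y4, list(C = 1, gamma = 0.1))
  expect_equal(sum(rep4$confusion), 4)
  expect_setequal(rep4$singleton_classes, y4)

  # duplicated separable data: every fold contains the held-out twin
  pm2 <- planted_matrix(30L, 4L, 2L, 3, 2L, seed = 13L)
  Xd <- rbind(pm2$X, pm2$X); yd <- c(pm2$y, pm2$y)
  pd <- svm_grid_search(Xd, yd, seed = 3L)
  expect_equal(jackknife_evaluate(Xd, yd, pd)$overall_accuracy, 1)
})

test_that("metrics_from_confusion implements the one-vs-rest formulas", {
  conf <- matrix(c(9, 1, 1, 9), 2, byrow = TRUE,
                 dimnames = list(c("a", "b"), c("a", "b")))
  m <- metrics_from_confusion(conf)
  expect_equal(m$per_class$sens[1], 0.9)
  expect_equal(m$per_class$spec[1], 0.9)
  expect_equal(m$per_class$f1[1], 0.9)
  expect_equal(m$overall_accuracy, 0.9)

  perfect <- metrics_from_confusion(diag(c(4, 4, 4, 4)))
  expect_true(all(perfect$per_class[c("sens", "spec", "f1")] == 1))
  expect_equal(perfect$overall_accuracy, 1)
})

test_that("metric identities hold on random confusion matrices", {
  withr::with_seed(77L, {
    for (i in 1:100) {
      conf <- matrix(rpois(16, 5), 4, 4,
                     dimnames = list(paste0("c", 1:4), paste0("c", 1:4)))
      if (any(rowSums(conf) == 0)) next
      m <- metrics_from_confusion(conf)
      # overall accuracy = trace / n = weighted mean of per-class accuracy
      expect_equal(m$overall_accuracy, sum(diag(conf)) / sum(conf))
      expect_equal(m$overall_accuracy,
                   sum(m$per_class$accuracy * m$per_class$n) /
                     sum(m$per_class$n))
      # one-vs-rest decomposition identities
      tp <- diag(conf)
      expect_equal(sum(tp), sum(conf) * m$overall_accuracy)
      expect_equal(sum(m$per_class$n), sum(conf))
    }
  })
})

test_that("evaluation reports round-trip through JSON", {
  pm <- planted_matrix(24L, 3L, 2L, 3, 4L, seed = 21L)
  rep1 <- jackknife_evaluate(pm$X, pm$y, list(C = 4, gamma = 0.25))
  f <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep1, f)
  back <- read_eval_report(f)
  expect_equal(back$confusion, rep1$confusion)
  expect_equal(back$overall_accuracy, rep1$overall_accuracy)
  expect_identical(back$predictions, rep1$predictions)
  expect_equal(as.data.frame(back$per_class), rep1$per_class)
})
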
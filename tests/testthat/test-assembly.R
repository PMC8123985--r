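test_that("feature matrix dimension contracts and family tags", {
  ds <- simulate_protein_dataset(2L, c(50L, 70L), seed = 1L)
  fm_psf <- build_feature_matrix(ds, families = "PSF")
  expect_equal(ncol(fm_psf$X), 420L)
  expect_true(all(fm_psf$family == "PSF"))

  fm <- build_feature_matrix(ds)
  expect_equal(ncol(fm$X), 886L)
  expect_equal(unname(table(fm$family)[c("PSF", "PPF", "RCF", "PSSF")]),
               c(420L, 420L, 24L, 22L), ignore_attr = TRUE)
  expect_false(anyDuplicated(colnames(fm$X)) > 0)
  expect_true(all(is.finite(fm$X)))
  expect_identical(rownames(fm$X), ds$id)

  fm11 <- build_feature_matrix(ds, ss_preset = "eleven")
  expect_equal(ncol(fm11$X), 420L + 420L + 24L + 11L)
})

test_that("per-row conservation of the content blocks", {
  ds <- simulate_protein_dataset(3L, c(40L, 80L), seed = 2L)
  fm <- build_feature_matrix(ds)
  scf1 <- fm$X[, grepl("^scf1_", colnames(fm$X)), drop = FALSE]
  rscf1 <- fm$X[, grepl("^r_scf1_", colnames(fm$X)), drop = FALSE]
  cont <- fm$X[, grepl("^ss_content_", colnames(fm$X)), drop = FALSE]
  expect_equal(unname(rowSums(scf1)), rep(1, nrow(fm$X)), tolerance = 1e-12)
  expect_equal(unname(rowSums(rscf1)), rep(1, nrow(fm$X)), tolerance = 1e-12)
  expect_equal(unname(rowSums(cont)), rep(1, nrow(fm$X)), tolerance = 1e-12)
})

test_that("PSSF without secondary structure fails naming the ids", {
  ds <- simulate_protein_dataset(1L, c(40L, 50L), seed = 3L)
  ds$ss_seq[2L] <- NA_character_
  expect_error(build_feature_matrix(ds), ds$id[2L])
  expect_silent(fm <- build_feature_matrix(ds, families = c("PSF", "RCF")))
  expect_equal(ncol(fm$X), 444L)
})

test_that("feature CSV is byte-deterministic and round-trips", {
  ds <- simulate_protein_dataset(2L, c(40L, 60L), seed = 4L)
  fm <- build_feature_matrix(ds)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(fm, f1)
  write_feature_csv(build_feature_matrix(ds), f2)
  expect_identical(readLines(f1), readLines(f2))

  back <- read_feature_csv(f1)
  expect_identical(back$ids, fm$ids)
  expect_identical(back$family, fm$family)
  expect_equal(back$X, fm$X, tolerance = 1e-15)
})
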
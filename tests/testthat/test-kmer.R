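test_that("kword_positions counts overlapping words with 1-based starts", {
  expect_identical(kword_positions("AAC", 1L), list(A = 1:2, C = 3L))
  expect_identical(kword_positions("AAC", 2L), list(AA = 1L, AC = 2L))
  expect_identical(kword_positions("A", 1L), list(A = 1L))
  expect_error(kword_positions("A", 2L), "exceeds")
})

test_that("scf_vector matches hand counts and conserves mass", {
  idx <- kmer_index(c("A", "C"), 1L)
  v <- scf_vector("AAC", 1L, idx)
  expect_equal(unname(v), c(2 / 3, 1 / 3))
  expect_identical(names(v), c("scf1_A", "scf1_C"))

  idx2 <- kmer_index(c("A", "C"), 2L)
  v2 <- scf_vector("AAC", 2L, idx2)
  expect_equal(unname(v2), c(1 / 2, 1 / 2, 0, 0))

  expect_equal(unname(scf_vector("AAAA", 1L, idx))[1L], 1)
})

test_that("interval_pmf and semi_moments match hand arithmetic", {
  p <- interval_pmf(c(1L, 2L, 4L, 5L))
  expect_identical(p$support, c(1L, 2L))
  expect_equal(p$probs, c(2 / 3, 1 / 3))
  expect_equal(unname(semi_moments(p)), c(4 / 3, 2 / 9))

  expect_length(interval_pmf(3L)$support, 0L)
  expect_equal(unname(semi_moments(interval_pmf(3L))), c(0, 0))

  p2 <- interval_pmf(c(1L, 3L, 5L))
  expect_identical(p2$support, 2L)
  expect_equal(p2$probs, 1)
  expect_equal(unname(semi_moments(p2)), c(2, 0))

  p3 <- structure(list(support = c(1L, 3L), probs = c(0.5, 0.5)),
                  class = "interval_pmf")
  expect_equal(unname(semi_moments(p3)), c(2, 1))

  expect_error(interval_pmf(c(2L, 1L)), "increasing")
})

test_that("spf_vector applies the degenerate conventions", {
  idx <- kmer_index(c("A", "B"), 1L)
  v <- spf_vector("AABAA", 1L, idx)
  expect_equal(v[["spf1_A"]], 6)     # (4/3) / (2/9)
  expect_equal(v[["spf1_B"]], 0)     # single occurrence
  expect_equal(spf_vector("ABABA", 1L, idx)[["spf1_A"]], 0)  # zero variance
})

test_that("scf/spf agree with the brute-force oracle on random sequences", {
  idx1 <- kmer_index(AA_ALPHABET20, 1L)
  idx2 <- kmer_index(AA_ALPHABET20, 2L)
  withr::with_seed(42L, {
    for (i in seq_len(100L)) {
      s <- random_aa_seq(sample(20:200, 1L))
      for (k in 1:2) {
        idx <- if (k == 1L) idx1 else idx2
        expect_equal(unname(scf_vector(s, k, idx)),
                     unname(oracle_scf(s, k, idx$words)), tolerance = 1e-12)
        expect_equal(unname(spf_vector(s, k, idx)),
                     unname(oracle_spf(s, k, idx$words)), tolerance = 1e-12)
        expect_equal(sum(scf_vector(s, k, idx)), 1, tolerance = 1e-12)
      }
    }
  })
})

test_that("permutation keeps content but generally moves position features", {
  withr::with_seed(9L, {
    s <- random_aa_seq(120L)
    sp <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
    idx <- kmer_index(AA_ALPHABET20, 1L)
    expect_equal(scf_vector(sp, 1L, idx), scf_vector(s, 1L, idx))
    expect_false(isTRUE(all.equal(spf_vector(sp, 1L, idx),
                                  spf_vector(s, 1L, idx))))
  })
})
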
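test_that("ss_content, cmv, segment_stats, nalt match hand computations", {
  expect_equal(ss_content("HHHCE"), c(H = 0.6, E = 0.2, C = 0.2))
  expect_equal(ss_content("CCCC"), c(H = 0, E = 0, C = 1))
  expect_equal(unname(ss_content("HECHEC")), rep(1 / 3, 3))
  expect_error(ss_content(""), "empty")

  expect_equal(cmv("HHHCE", "H", 1L), 1.5)        # (1+2+3)/4
  expect_equal(cmv("HHHCE", "H", 2L), 7 / 6)      # (1+4+9)/(4*3)
  expect_equal(cmv("CCC", "H", 1L), 0)
  expect_error(cmv("HH", "H", 2L), "too short")

  expect_equal(segment_stats("HHCHHHEC", "H"),
               c(max_seg = 3, nmax_seg = 0.375, avg_seg = 2.5,
                 navg_seg = 0.3125))
  expect_equal(segment_stats("HHHH", "H"),
               c(max_seg = 4, nmax_seg = 1, avg_seg = 4, navg_seg = 1))
  expect_equal(unname(segment_stats("CECE", "H")), rep(0, 4))

  expect_equal(nalt("HHEECHH"), 2 / 7)
  expect_equal(nalt("HHHH"), 0)
  expect_equal(nalt("HECHE"), 3 / 5)
})

test_that("ss_feature_vector dimension contracts hold", {
  v <- ss_feature_vector("HHHCE")
  expect_length(v, 22L)
  expect_equal(v[["ss_content_H"]], 0.6)
  expect_equal(v[["ss_cmv1_H"]], 1.5)
  expect_length(ss_feature_vector("HHHCE", "eleven"), 11L)
  expect_false("ss_content_C" %in% names(ss_feature_vector("HHHCE", "eleven")))
})

test_that("descriptors match the explicit-scan oracle on random strings", {
  withr::with_seed(17L, {
    for (i in seq_len(100L)) {
      ss <- random_ss_seq(sample(10:150, 1L))
      o <- oracle_ss(ss)
      cont <- ss_content(ss)
      expect_equal(sum(cont), 1, tolerance = 1e-12)
      for (e in c("H", "E", "C")) {
        expect_equal(cont[[e]], o[[paste0("content_", e)]], tolerance = 1e-12)
        expect_equal(cmv(ss, e, 1L), o[[paste0("cmv1_", e)]],
                     tolerance = 1e-12)
        expect_equal(cmv(ss, e, 2L), o[[paste0("cmv2_", e)]],
                     tolerance = 1e-12)
        st <- segment_stats(ss, e)
        expect_equal(st[["max_seg"]], o[[paste0("maxseg_", e)]])
        expect_equal(st[["avg_seg"]], o[[paste0("avgseg_", e)]],
                     tolerance = 1e-12)
        expect_equal(st[["navg_seg"]], o[[paste0("navgseg_", e)]],
                     tolerance = 1e-12)
      }
      expect_equal(nalt(ss), o$nalt, tolerance = 1e-12)
    }
  })
})

test_that("run bookkeeping: runs x mean length reconstruct N; reversal", {
  withr::with_seed(23L, {
    for (i in 1:25) {
      ss <- random_ss_seq(sample(10:80, 1L))
      n <- nchar(ss)
      total <- 0
      for (e in c("H", "E", "C")) {
        seg <- ss_segments(ss, e)
        if (nrow(seg) > 0L) total <- total + nrow(seg) * mean(seg$length)
      }
      expect_equal(total, n, tolerance = 1e-9)
      rev_ss <- paste(rev(strsplit(ss, "")[[1]]), collapse = "")
      expect_equal(ss_content(rev_ss), ss_content(ss))
      expect_equal(nalt(rev_ss), nalt(ss))
      for (e in c("H", "E", "C")) {
        expect_equal(segment_stats(rev_ss, e), segment_stats(ss, e))
      }
    }
  })
})
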
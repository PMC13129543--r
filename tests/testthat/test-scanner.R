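# Scanner: window arithmetic, shuffle contracts, z-score formula and
# degenerate policy, determinism, and planted-signal sanity.

test_that("sliding windows follow the count law and refuse short input", {
  p <- scan_params(window_length = 120, step = 1)
  w <- sliding_windows(120, p)
  expect_equal(nrow(w), 1L)
  expect_equal(c(w$start, w$end), c(1L, 120L))
  w <- sliding_windows(125, p)
  expect_equal(nrow(w), 6L)
  expect_equal(w$start, 1:6)
  expect_equal(w$end, 120:125)
  expect_error(sliding_windows(119, p), "shorter than the window")
  # general count law
  for (len in c(130, 200, 301)) {
    for (st in c(1, 7, 30)) {
      p2 <- scan_params(window_length = 120, step = st)
      expect_equal(nrow(sliding_windows(len, p2)),
                   (len - 120) %/% st + 1)
    }
  }
})

test_that("mononucleotide shuffle preserves composition and is seeded", {
  expect_equal(mononucleotide_shuffle("A"), "A")
  set.seed(9)
  for (r in 1:20) {
    s <- random_sequence(sample(5:80, 1))
    sh <- mononucleotide_shuffle(s)
    expect_equal(sort(strsplit(sh, "")[[1]]), sort(strsplit(s, "")[[1]]))
  }
  a <- with_local_seed(4, mononucleotide_shuffle("ACGUACGUACGU"))
  b <- with_local_seed(4, mononucleotide_shuffle("ACGUACGUACGU"))
  expect_identical(a, b)
})

test_that("dinucleotide shuffle preserves the dinucleotide count map", {
  expect_equal(dinucleotide_shuffle("AU"), "AU")
  set.seed(21)
  for (r in 1:60) {
    s <- random_sequence(sample(4:120, 1))
    sh <- dinucleotide_shuffle(s)
    expect_equal(oracle_dinuc_counts(sh), oracle_dinuc_counts(s))
    expect_equal(substr(sh, 1, 1), substr(s, 1, 1))
    expect_equal(substr(sh, nchar(s), nchar(s)),
                 substr(s, nchar(s), nchar(s)))
  }
  # endpoint preservation of the Eulerian construction
  sh <- with_local_seed(2, dinucleotide_shuffle("GCGCGC"))
  expect_equal(substr(sh, 1, 1), "G")
  expect_equal(substr(sh, 6, 6), "C")
})

test_that("window z-score follows the formula with population sd", {
  # native -26 against null mean -20, sd 2
  expect_equal(window_zscore(-26, c(-18, -22)), -3)
  expect_equal(window_zscore(-20, c(-18, -22)), 0)
  expect_warning(z <- window_zscore(-5, c(-3, -3, -3)), "degenerate")
  expect_equal(z, 0)
  expect_error(window_zscore(-5, numeric(0)), "at least two")
  expect_error(window_zscore(-5, -3), "at least two")
  # location-scale invariance under a common shift
  set.seed(1)
  x <- rnorm(20, -20, 3)
  expect_equal(window_zscore(-24, x), window_zscore(-24 + 5, x + 5))
})

test_that("scan records are reproducible and internally consistent", {
  p <- scan_params(window_length = 30, step = 7, n_shuffles = 12, seed = 8)
  s <- random_sequence(72, seed = 31)
  engine <- default_engine()
  sc <- scan_transcript(s, p, engine)
  expect_equal(nrow(sc), (72 - 30) %/% 7 + 1)
  expect_true(all(sc$end - sc$start + 1 == 30))
  expect_true(all(is.finite(sc$zscore)))

  # identical inputs give a byte-identical scan table
  sc2 <- scan_transcript(s, p, engine)
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_scan_tsv(sc, f1)
  write_scan_tsv(sc2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(as.data.frame(read_scan_tsv(f1))$zscore,
               round(sc$zscore, 6), tolerance = 1e-9)

  # each record recomputes from the engine and the same shuffle stream
  k <- 3L
  sub <- substr(s, sc$start[k], sc$end[k])
  expect_equal(engine$fold(sub)$energy, sc$native_mfe[k])
  shuf <- with_local_seed(derive_window_seed(p$seed, sc$start[k]), {
    vapply(seq_len(p$n_shuffles),
           function(i) engine$fold(mononucleotide_shuffle(sub))$energy,
           numeric(1))
  })
  expect_equal(mean(shuf), sc$shuffle_mean[k])
  expect_equal(window_zscore(sc$native_mfe[k], shuf), sc$zscore[k])

  expect_error(scan_transcript(random_sequence(20, seed = 1), p), "below")
})

test_that("a planted stable hairpin drags the minimum window z-score", {
  p <- scan_params(window_length = 60, step = 10, n_shuffles = 15,
                   seed = 2)
  hits <- 0L
  for (seed in 1:5) {
    bg <- random_sequence(240, seed = seed)
    planted <- plant_hairpin(bg, 100, stem_length = 18, loop_length = 5,
                             gc_fraction = 0.9, seed = seed + 100)
    sc <- scan_transcript(planted, p)
    k <- which.min(sc$zscore)
    span <- c(100, 100 + 2 * 18 + 5 - 1)
    if (sc$start[k] <= span[2] && span[1] <= sc$end[k]) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})
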
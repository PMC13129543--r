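# Consensus building: evidence accumulation arithmetic, mutual-best
# selection with the ambiguity rule, crossing resolution against the
# exhaustive subset oracle, threshold nesting, and coverage profiles.

test_that("pair evidence accumulates Zsum and counts per pair", {
  sc <- fake_scan(1L, -3, "((...))")
  ev <- accumulate_pair_evidence(sc, 7L)
  expect_equal(ev$i, c(1L, 2L))
  expect_equal(ev$j, c(7L, 6L))
  expect_equal(ev$zsum, c(-3, -3))
  expect_equal(ev$count, c(1L, 1L))

  # same pair seen in two windows at z -3 and -1
  sc <- fake_scan(c(1L, 2L), c(-3, -1), c("(...)..", ".(...)."),
                  window_length = 7L)
  sc$structure <- c("(...)..", "(...)..")
  ev <- accumulate_pair_evidence(sc[1, ], 8L)
  expect_equal(ev$zsum, -3)
  sc2 <- fake_scan(c(1L, 1L), c(-3, -1), c("(...)", "(...)"),
                   window_length = 5L)
  ev <- accumulate_pair_evidence(sc2, 5L)
  expect_equal(ev$zsum, -4)
  expect_equal(ev$count, 2L)
  expect_equal(ev$znorm, -2)

  # all-dot windows contribute nothing
  ev <- accumulate_pair_evidence(fake_scan(1L, -2, "......."), 7L)
  expect_equal(nrow(ev), 0L)

  # window-local pairs are shifted by the window offset
  sc3 <- fake_scan(5L, -2, "(...)")
  ev <- accumulate_pair_evidence(sc3, 12L)
  expect_equal(c(ev$i, ev$j), c(5L, 9L))
})

test_that("a single full-length window reproduces its own structure", {
  db <- "((..((...))..)).."
  sc <- fake_scan(1L, -2.5, db)
  ev <- accumulate_pair_evidence(sc, nchar(db))
  cons <- select_consensus(ev, nchar(db))
  expect_equal(consensus_to_dotbracket(cons), db)
  expect_true(all(cons$pairs$znorm == -2.5))
})

test_that("equal-minimal Znorm competitors leave the nucleotide unpaired", {
  # nucleotide 1 pairs with 10 and 12 at the same znorm in different windows
  ev <- data.frame(i = c(1L, 1L), j = c(10L, 12L), zsum = c(-2, -2),
                   count = c(1L, 1L), znorm = c(-2, -2))
  attr(ev, "length") <- 12L
  class(ev) <- c("pair_evidence", "data.frame")
  cons <- select_consensus(ev, 12L)
  expect_equal(nrow(cons$pairs), 0L)

  # a strictly better partner wins
  ev$znorm <- c(-3, -2)
  ev$zsum <- c(-3, -2)
  cons <- select_consensus(ev, 12L)
  expect_equal(cons$pairs$j, 10L)
})

test_that("crossing conflicts resolve like the exhaustive subset oracle", {
  set.seed(14)
  for (r in 1:30) {
    # two disjoint crossing conflicts plus nested and isolated pairs
    z <- -round(runif(7, 0.5, 4) + seq(0, 0.06, by = 0.01), 3)
    ev <- data.frame(
      i = c(1L, 5L, 21L, 25L, 41L, 42L, 60L),
      j = c(10L, 15L, 30L, 35L, 50L, 49L, 70L),
      zsum = z, count = rep(1L, 7), znorm = z)
    attr(ev, "length") <- 70L
    class(ev) <- c("pair_evidence", "data.frame")
    got <- select_consensus(ev, 70L)$pairs
    want <- oracle_consensus_pairs(ev)
    expect_equal(got[, c("i", "j")], want[, c("i", "j")],
                 ignore_attr = TRUE)
    # exactly one survivor per crossing conflict
    expect_equal(nrow(got), 5L)
  }
})

test_that("consensus output is non-crossing with unique positions", {
  set.seed(3)
  for (r in 1:10) {
    s <- random_sequence(80)
    p <- scan_params(window_length = 40, step = 8, n_shuffles = 6,
                     seed = r)
    sc <- suppressWarnings(scan_transcript(s, p))
    cons <- select_consensus(accumulate_pair_evidence(sc, 80), 80)
    prs <- as.matrix(cons$pairs[, c("i", "j")])
    expect_true(pairs_noncrossing(prs))
    expect_false(anyDuplicated(c(prs)) > 0)
    # dot-bracket conversion must therefore be balanced
    expect_silent(pair_table(consensus_to_dotbracket(cons)))
  }
})

test_that("threshold filtering keeps exactly znorm <= tau and nests", {
  ev <- data.frame(i = c(1L, 3L, 20L), j = c(10L, 8L, 30L),
                   zsum = c(-2.5, -1.2, -0.4), count = rep(1L, 3),
                   znorm = c(-2.5, -1.2, -0.4))
  attr(ev, "length") <- 30L
  class(ev) <- c("pair_evidence", "data.frame")
  cons <- select_consensus(ev, 30L)
  t1 <- apply_threshold(cons, -1)
  t2 <- apply_threshold(cons, -2)
  expect_equal(sort(t1$pairs$znorm), c(-2.5, -1.2))
  expect_equal(t2$pairs$znorm, -2.5)
  expect_true(all(paste(t2$pairs$i, t2$pairs$j) %in%
                    paste(t1$pairs$i, t1$pairs$j)))
  expect_true(all(paste(t1$pairs$i, t1$pairs$j) %in%
                    paste(cons$pairs$i, cons$pairs$j)))
  expect_equal(nrow(apply_threshold(
    select_consensus(ev[0, ], 30L), -1)$pairs), 0L)
})

test_that("per-nucleotide profiles average covering windows", {
  sc <- fake_scan(c(1L, 2L), c(-1, -3), c("....", "...."),
                  window_length = 4L)
  prof <- per_nucleotide_profiles(sc, 6L)
  expect_equal(nrow(prof), 6L)
  expect_equal(prof$mean_zscore[1], -1)   # only window 1 covers position 1
  expect_equal(prof$mean_zscore[3], -2)   # both windows cover position 3
  expect_equal(prof$coverage, c(1L, 2L, 2L, 2L, 1L, 0L))
  expect_true(is.na(prof$mean_zscore[6]))
})

test_that("step-1 coverage is flat inside and ramps at the ends", {
  s <- random_sequence(50, seed = 2)
  p <- scan_params(window_length = 20, step = 1, n_shuffles = 4, seed = 1)
  sc <- suppressWarnings(scan_transcript(s, p))
  prof <- per_nucleotide_profiles(sc, 50L)
  interior <- prof$coverage[20:31]
  expect_true(all(interior == 20L))
  expect_equal(prof$coverage[1:5], 1:5)
  expect_equal(prof$coverage[50:46], 1:5)
})
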
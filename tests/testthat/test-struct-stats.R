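# Structural census: element decomposition against the independent
# reference parser, hairpin classification and distances, tallies, GC
# summaries, and position frequency matrices.

test_that("canonical decompositions match hand enumeration", {
  cat1 <- parse_elements("(((...)))")
  df1 <- as.data.frame(cat1)
  expect_equal(sum(df1$kind == "stem"), 1L)
  expect_equal(df1$stem_bp[df1$kind == "stem"], 3L)
  expect_equal(sum(df1$kind == "hairpin_loop"), 1L)
  expect_equal(df1$loop_len[df1$kind == "hairpin_loop"], 3L)

  cat2 <- parse_elements("((.((...))))")
  df2 <- as.data.frame(cat2)
  expect_equal(sum(df2$kind == "stem"), 2L)
  expect_equal(sum(df2$kind == "bulge"), 1L)
  expect_equal(df2$side5[df2$kind == "bulge"] +
                 df2$side3[df2$kind == "bulge"], 1L)
  expect_equal(sum(df2$kind == "hairpin_loop"), 1L)

  cat3 <- parse_elements("((..((...))..((...))..))")
  df3 <- as.data.frame(cat3)
  expect_equal(sum(df3$kind == "multibranch_loop"), 1L)
  mbl <- cat3$elements[[which(vapply(cat3$elements, `[[`, character(1),
                                     "kind") == "multibranch_loop")]]
  expect_equal(nrow(mbl$enclosed_pairs), 2L)  # two branches
  basal <- cat3$stems[[1]]
  expect_equal(nrow(basal), 2L)               # 2-bp basal stem

  # two top-level hairpins: exterior loop, never a multibranch loop
  df4 <- as.data.frame(parse_elements("(((...)))..(((...)))"))
  expect_equal(sum(df4$kind == "multibranch_loop"), 0L)
  expect_equal(sum(df4$kind == "hairpin_loop"), 2L)
  expect_equal(sum(df4$kind == "exterior_loop"), 1L)

  expect_error(parse_elements("((..)"), "unbalanced")
})

test_that("decomposition agrees with the reference parser on a corpus", {
  corp <- random_structure_corpus(200, seed = 91)
  for (k in seq_len(nrow(corp))) {
    db <- corp$structure[k]
    cat_ <- parse_elements(db)
    ref <- ref_parse_elements(db)
    expect_identical(catalog_fingerprint(cat_),
                     element_fingerprint(ref$stems, ref$loops))
    # conservation: every position in exactly one element
    pos <- unlist(lapply(cat_$elements, `[[`, "positions"))
    paired <- unlist(lapply(cat_$stems, as.vector))
    loops_only <- pos[!pos %in% paired]
    expect_equal(sort(c(unique(paired), loops_only)), seq_len(nchar(db)))
    expect_equal(length(paired), 2L * nrow(db_pairs(db)))
    # round trip
    expect_equal(rebuild_structure(cat_), db)
  }
})

test_that("bulge, SIL and AIL are disjoint and exhaustive", {
  cases <- list(
    list(db = "((.((...))))", kind = "bulge"),
    list(db = "((.((...)).))", kind = "symmetric_internal_loop"),
    list(db = "((.((...))..))", kind = "asymmetric_internal_loop"))
  for (cs in cases) {
    df <- as.data.frame(parse_elements(cs$db))
    il <- df[df$kind %in% c("bulge", "symmetric_internal_loop",
                            "asymmetric_internal_loop"), ]
    expect_equal(nrow(il), 1L)
    expect_equal(il$kind, cs$kind)
  }
})

test_that("hairpin classification separates fully paired systems", {
  rec <- classify_hairpins(parse_elements("((((....))))"), "GGGGAAAACCCC")
  expect_true(rec$fully_paired)
  expect_equal(rec$stem_length, 4L)
  expect_equal(rec$apical_loop_length, 4L)
  expect_equal(rec$apical_loop_sequence, "AAAA")
  expect_null(nearest_feature_distance(rec[1, ]))

  rec <- classify_hairpins(parse_elements("(((.(((....))))))"),
                           "GGGAGGGAAAACCCCCC")
  expect_false(rec$fully_paired)
  expect_equal(rec$stem_length, 6L)
  nf <- nearest_feature_distance(rec[1, ])
  expect_equal(nf$kind, "bulge")
  # 2 stacked pairs strictly between the closing pair and the bulge
  expect_equal(nf$distance, 2L)

  # two substructures: the nearer one is reported
  db <- "(((.((.((....)))))))"
  sq <- strrep("A", nchar(db))
  rec <- classify_hairpins(parse_elements(db), sq)
  subs <- rec$substructures[[1]]
  expect_equal(nrow(subs), 2L)
  nf <- nearest_feature_distance(rec[1, ])
  expect_equal(nf$distance, min(subs$distance))
})

test_that("gc fraction of stems counts both strands", {
  st <- stem_table(parse_elements("(((...)))"), "GCGAAACGC")
  expect_equal(st$length_bp, 3L)
  expect_equal(st$gc_fraction, 1.0)
  st <- stem_table(parse_elements("(((...)))"), "AUAAAAUAU")
  expect_equal(st$gc_fraction, 0.0)
  st <- stem_table(parse_elements("((((...))))"), "GCAUAAAAUGC")
  expect_equal(st$gc_fraction, 0.5)
  tab <- stem_gc_by_length(data.frame(length_bp = c(3L, 3L, 5L),
                                      gc_fraction = c(1, 0, 0.4)))
  expect_equal(tab$count, c(2L, 1L))
  expect_equal(tab$mean_gc, c(0.5, 0.4))
})

test_that("region tallies match hand counts and ignore record order", {
  el <- data.frame(
    motif_id = c(1, 1, 2, 3, 3, 4, 5, 6, 6, 7),
    region = c(rep("intron", 6), rep("exon", 4)),
    kind = c("stem", "hairpin_loop", "stem", "stem", "bulge", "stem",
             "stem", "stem", "hairpin_loop", "multibranch_loop"))
  kinds <- c("stem", "hairpin_loop", "bulge", "symmetric_internal_loop",
             "asymmetric_internal_loop", "multibranch_loop",
             "exterior_loop")
  tab <- suppressMessages(tally_by_region(el, unit = "element"))
  intron <- tab[tab$region == "intron", ]
  expect_equal(intron$n, 6L)
  expect_equal(intron$stem, 100 * 4 / 6)
  expect_equal(intron$bulge, 100 * 1 / 6)
  expect_equal(sum(intron[, kinds]), 100, tolerance = 1e-9)
  tab_m <- suppressMessages(tally_by_region(el, unit = "motif"))
  expect_equal(tab_m$n[tab_m$region == "intron"], 4L) # motifs 1-4
  expect_equal(tab_m$stem[tab_m$region == "intron"], 100)
  # permutation invariance
  perm <- el[sample(nrow(el)), ]
  expect_equal(suppressMessages(tally_by_region(perm, unit = "element")),
               tab)
})

test_that("position frequency matrices count columns and score IC", {
  pfm <- position_frequency_matrix(rep("GAAA", 10))
  expect_true(all(rowSums(pfm$counts) == 10L))
  expect_equal(pfm$information_content, rep(2, 4))
  pfm <- position_frequency_matrix(c("ACGU", "CGUA", "GUAC", "UACG"))
  expect_equal(pfm$information_content, rep(0, 4))
  expect_error(position_frequency_matrix(c("ACG", "ACGU")), "same length")
  p <- withr::local_tempfile()
  write_pfm(pfm, p)
  expect_equal(length(readLines(p)), 5L)
})
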
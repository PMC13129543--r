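# Motif dictionary: bond-order extraction, flanks, structured errors,
# refolded metrics, coordinate mapping, and region assignment.

test_that("submotifs are the maximal depth-positive intervals", {
  mo <- extract_submotifs("((..)).", "GGAACCA")
  expect_equal(nrow(mo), 1L)
  expect_equal(c(mo$start, mo$end), c(1L, 6L))
  expect_equal(mo$structure, "((..))")

  mo <- extract_submotifs("((..))..((...))", "GGAACCAAGGGAACC")
  expect_equal(nrow(mo), 2L)
  expect_equal(mo$start, c(1L, 9L))
  expect_equal(mo$end, c(6L, 15L))
  expect_equal(mo$sequence, c("GGAACC", "GGGAACC"))

  expect_equal(nrow(extract_submotifs("......", "AAAAAA")), 0L)
})

test_that("flanks are appended and clipped at the sequence ends", {
  mo <- extract_submotifs("((..)).", "GGAACCA", flank = 2)
  expect_equal(c(mo$start, mo$end), c(1L, 7L)) # left clip at 1
  expect_equal(c(mo$core_start, mo$core_end), c(1L, 6L))
  expect_equal(mo$structure, "((..)).")
  expect_equal(mo$flank, 2L)
})

test_that("unbalanced structures raise structured errors, never repairs", {
  expect_error(extract_submotifs("((..", "GGAA"), "unmatched '\\(")
  expect_error(extract_submotifs("((..", "GGAA"), "position 1")
  expect_error(extract_submotifs("..))", "AACC"), "position 3")
})

test_that("motif metrics come from refolding and are position invariant", {
  model <- default_energy_model()
  engine <- default_engine(model)
  db <- "..((((....))))...((((....))))"
  sq <- "AAGGGCAAAAGCCCAAAGGGCAAAAGCCC"
  mo <- annotate_motif_metrics(extract_submotifs(db, sq), engine)
  expect_equal(nrow(mo), 2L)
  # identical motifs at different coordinates get identical metrics
  expect_equal(mo$mfe[1], mo$mfe[2])
  expect_equal(mo$ed[1], mo$ed[2])
  # metrics match the enumeration oracle for a short motif
  enum <- enumerate_all_structures(mo$sequence[1], model)
  expect_equal(mo$mfe[1], min(enum$energy[is.finite(enum$energy)]))
  expect_equal(mo$ed[1],
               oracle_ensemble_diversity(mo$sequence[1], model),
               tolerance = 1e-9)
})

test_that("transcript-genome mapping is strand aware and invertible", {
  gene_p <- region_annotation("t", "chr1", 1000L, 1999L, "+",
                              data.frame(kind = "exon", start = 1000L,
                                         end = 1999L))
  gene_m <- region_annotation("t", "chr1", 1000L, 1999L, "-",
                              data.frame(kind = "exon", start = 1000L,
                                         end = 1999L))
  expect_equal(map_transcript_to_genome(1L, gene_p), 1000L)
  expect_equal(map_transcript_to_genome(1L, gene_m), 1999L)
  expect_error(map_transcript_to_genome(1001L, gene_p), "outside")
  set.seed(6)
  pos <- sample(1:1000, 100)
  for (g in list(gene_p, gene_m)) {
    expect_equal(map_genome_to_transcript(
      map_transcript_to_genome(pos, g), g), pos)
    gpos <- sample(1000:1999, 100)
    expect_equal(map_transcript_to_genome(
      map_genome_to_transcript(gpos, g), g), gpos)
  }
})

test_that("region assignment honours UTR precedence and multi_region", {
  # gene 1-300 (+): exon 1-100 (5'UTR 1-40), intron 101-200, exon 201-300
  # (3'UTR 261-300)
  gene <- region_annotation(
    "t", "chr1", 1L, 300L, "+",
    data.frame(kind = c("exon", "exon", "five_utr", "three_utr"),
               start = c(1L, 201L, 1L, 261L),
               end = c(100L, 300L, 40L, 300L)))
  expect_equal(assign_region(120, 180, gene), "intron")
  expect_equal(assign_region(10, 30, gene), "five_utr")  # inside an exon too
  expect_equal(assign_region(50, 90, gene), "exon")
  expect_equal(assign_region(270, 290, gene), "three_utr")
  expect_equal(assign_region(90, 130, gene), "multi_region")
  expect_equal(assign_region(30, 60, gene), "multi_region")
  expect_error(assign_region(200, 400, gene), "outside")
  # labels are exhaustive and mutually exclusive across a tiling of motifs
  labs <- vapply(seq(1, 291, by = 10),
                 function(s) assign_region(s, s + 9, gene), character(1))
  expect_true(all(labs %in% c("five_utr", "exon", "intron", "three_utr",
                              "multi_region")))
})

test_that("motif region assignment uses core spans on a toy gene", {
  tg <- toy_gene_model(seed = 12, n_exons = 2, strand = "+")
  len <- nchar(tg$sequence)
  intr <- intron_intervals(tg$gene)
  # build a consensus-like structure with one hairpin inside the intron
  t_start <- map_genome_to_transcript(intr$start[1], tg$gene) + 5L
  db <- paste0(strrep(".", t_start - 1L), "(((((....)))))",
               strrep(".", len - t_start - 13L))
  mo <- assign_motif_regions(extract_submotifs(db, tg$sequence,
                                               transcript_id = tg$transcript_id),
                             tg$gene)
  expect_equal(mo$region, "intron")
})
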
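# Format IO: FASTA, GFF3 region extraction, WIG anchoring, arc colors,
# CT/DBN round trips, and the single coordinate-convention converter.

test_that("FASTA round trip preserves ids and normalizes sequences", {
  path <- withr::local_tempfile(fileext = ".fasta")
  seqs <- c(tx1 = random_sequence(150, seed = 1),
            tx2 = random_sequence(75, seed = 2))
  write_fasta(seqs, path)
  back <- read_fasta(path)
  expect_identical(back, seqs)

  # lowercase and T are normalized to uppercase U
  writeLines(c(">lower", "acgtacgt"), path)
  expect_equal(unname(read_fasta(path)), "ACGUACGU")

  writeLines(c(">a", "ACGU", ">a", "ACGU"), path)
  expect_error(read_fasta(path), "duplicate")
  writeLines(c(">empty", "", ">ok", "ACGU"), path)
  expect_error(read_fasta(path), "empty")
})

test_that("GFF3 region extraction is strand aware", {
  tg <- toy_gene_model(seed = 3, n_exons = 2, strand = "+")
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(tg$gff, path)
  gene <- read_gff_regions(path, tg$transcript_id)
  expect_equal(gene$gene_start, tg$gene$gene_start)
  expect_equal(gene$strand, "+")
  intr <- intron_intervals(gene)
  expect_equal(nrow(intr), 1L)
  ex <- gene$intervals[gene$intervals$kind == "exon", ]
  expect_equal(intr$start, ex$end[1] + 1L)
  expect_equal(intr$end, ex$start[2] - 1L)
  expect_error(read_gff_regions(path, "MISSING.1"), "not found")

  # minus strand: the 5'UTR is the highest-coordinate UTR block
  tgm <- toy_gene_model(seed = 5, n_exons = 3, strand = "-")
  writeLines(tgm$gff, path)
  gm <- read_gff_regions(path, tgm$transcript_id)
  u5 <- gm$intervals[gm$intervals$kind == "five_utr", ]
  u3 <- gm$intervals[gm$intervals$kind == "three_utr", ]
  expect_gt(u5$start, u3$end)

  # single exon means no introns
  single <- region_annotation("s", "chr1", 1L, 500L, "+",
                              data.frame(kind = "exon", start = 1L,
                                         end = 500L))
  expect_equal(nrow(intron_intervals(single)), 0L)

  # overlapping exons are refused
  expect_error(region_annotation(
    "bad", "chr1", 1L, 500L, "+",
    data.frame(kind = c("exon", "exon"), start = c(1L, 90L),
               end = c(100L, 200L))), "overlapping")
})

test_that("WIG tracks are correctly anchored on both strands", {
  vals <- seq(-3, 3, length.out = 200)
  gene_p <- region_annotation("t", "chr2", 1000L, 1199L, "+",
                              data.frame(kind = "exon", start = 1000L,
                                         end = 1199L))
  path <- withr::local_tempfile(fileext = ".wig")
  write_wig(vals, gene_p, path)
  back <- read_wig(path)
  expect_equal(back$start, 1000L)
  expect_equal(back$values, vals, tolerance = 1e-6)

  # minus strand: transcript 5' end sits at the high coordinate, so the
  # ascending-genomic file holds the values reversed
  gene_m <- region_annotation("t", "chr2", 1000L, 1199L, "-",
                              data.frame(kind = "exon", start = 1000L,
                                         end = 1199L))
  write_wig(vals, gene_m, path)
  back <- read_wig(path)
  expect_equal(back$start, 1000L)
  expect_equal(back$values, rev(vals), tolerance = 1e-6)

  # cross-check with an independent WIG reader
  gr <- rtracklayer::import(path, format = "wig")
  expect_equal(GenomicRanges::start(gr)[1], 1000L)
  expect_equal(S4Vectors::mcols(gr)$score, rev(vals), tolerance = 1e-6)

  expect_error(write_wig(vals[-1], gene_p, path), "does not match")
})

test_that("arc colors partition znorm <= 0 with the documented edges", {
  expect_equal(arc_color(c(-2.5, -2.0, -1.99, -1.0, -0.99, -0.5)),
               c("blue", "blue", "green", "green", "yellow", "yellow"))
  expect_true(is.na(arc_color(0.5)))
  expect_equal(arc_color(0), "yellow")

  cons <- structure(list(length = 40L,
                         pairs = data.frame(i = c(5L, 10L, 15L, 20L),
                                            j = c(35L, 30L, 25L, 24L),
                                            znorm = c(-2.5, -1.5, -0.5, 0.7),
                                            zsum = c(-5, -3, -1, 0.7),
                                            count = rep(1L, 4)),
                         threshold = NA_real_),
                    class = "consensus_structure")
  gene <- region_annotation("t", "chr3", 101L, 140L, "+",
                            data.frame(kind = "exon", start = 101L,
                                       end = 140L))
  path <- withr::local_tempfile(fileext = ".bed")
  write_arc_track(cons, gene, path)
  lines <- readLines(path)[-1]
  expect_equal(length(lines), 3L) # positive znorm excluded
  fields <- strsplit(lines, "\t")
  # 1-based inclusive -> 0-based half-open through the one converter
  expect_equal(as.integer(fields[[1]][2]), 101L + 5L - 1L - 1L)
  expect_equal(as.integer(fields[[1]][3]), 101L + 35L - 1L)
  expect_equal(vapply(fields, `[`, character(1), 9L),
               unname(c("0,0,255", "0,160,0", "230,200,0")))
})

test_that("CT files round trip and reject non-reciprocal pairing", {
  path <- withr::local_tempfile(fileext = ".ct")
  write_ct("GAAAC", "(...)", path, energy = -1.5, id = "toy")
  back <- read_ct(path)
  expect_equal(back$sequence, "GAAAC")
  expect_equal(back$structure, "(...)")
  expect_equal(back$energy, -1.5)
  rows <- strsplit(readLines(path)[-1], "\t")
  expect_equal(as.integer(vapply(rows, `[`, character(1), 5L)),
               c(5L, 0L, 0L, 0L, 1L))

  set.seed(8)
  corp <- random_structure_corpus(30, seed = 44)
  for (k in seq_len(nrow(corp))) {
    write_ct(corp$sequence[k], corp$structure[k], path)
    back <- read_ct(path)
    expect_equal(back$sequence, corp$sequence[k])
    expect_equal(back$structure, corp$structure[k])
  }

  # corrupt the partner column: i -> j but j -> k
  lines <- readLines(write_ct("GAAAC", "(...)", path))
  lines[6] <- sub("\t1\t", "\t2\t", lines[6])
  writeLines(lines, path)
  expect_error(read_ct(path), "reciprocate")
})

test_that("DBN files round trip", {
  path <- withr::local_tempfile(fileext = ".dbn")
  write_dbn("GGGAAACCC", "(((...)))", path, id = "hp")
  back <- read_dbn(path)
  expect_equal(back$id, "hp")
  expect_equal(back$sequence, "GGGAAACCC")
  expect_equal(back$structure, "(((...)))")
  expect_error(write_dbn("GG", "(((", path), "lengths differ")
})

test_that("interval conversion between 1-based and BED is an inverse pair", {
  set.seed(10)
  s <- sample(1:10000, 200, TRUE)
  e <- s + sample(0:500, 200, TRUE)
  bed <- interval_to_bed(s, e)
  expect_equal(bed$end - bed$start, e - s + 1L) # half-open width
  back <- interval_from_bed(bed$start, bed$end)
  expect_equal(back$start, s)
  expect_equal(back$end, e)
})
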
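# Synthetic inputs: composition-controlled random sequences, planted
# stable hairpins, random structure corpora from a stochastic grammar, and
# toy pre-mRNA gene models. Everything is reproducible from a seed and
# generated in code, so no module needs external data to be tested.

#' Random nucleotide sequence with controlled composition
#'
#' i.i.d. draws from the given base frequencies.
#'
#' @param length Sequence length.
#' @param composition Named numeric vector of frequencies for A, C, G, U;
#'   normalized to sum to 1. Negative entries are refused.
#' @param seed Optional seed; when given, the caller's RNG state is left
#'   untouched.
#' @return A nucleotide string.
#' @export
random_sequence <- function(length,
                            composition = c(A = 0.25, C = 0.25,
                                            G = 0.25, U = 0.25),
                            seed = NULL) {
  if (any(composition < 0) || sum(composition) <= 0) {
    stop("composition frequencies must be non-negative with positive sum",
         call. = FALSE)
  }
  comp <- composition[RNA_BASES]
  comp[is.na(comp)] <- 0
  comp <- comp / sum(comp)
  draw <- function() paste(sample(RNA_BASES, length, replace = TRUE,
                                  prob = comp), collapse = "")
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}

#' Plant a perfect hairpin into a background sequence
#'
#' Overwrites the span starting at `position` with a perfect inverted
#' repeat (stem of `stem_length` base pairs, `gc_fraction` of them G-C,
#' the rest A-U) around a random loop of `loop_length` nucleotides. The
#' background outside the span is unchanged. Planted spans are recorded in
#' the `planted` attribute and overlapping plants are refused.
#'
#' @param background Background sequence string.
#' @param position 1-based start of the planted span.
#' @param stem_length Stem length in base pairs.
#' @param loop_length Loop length in nucleotides (>= 3).
#' @param gc_fraction Fraction of stem pairs that are G-C (rounded to a
#'   whole number of pairs).
#' @param seed Optional seed for the arm composition and loop.
#' @return The modified sequence with attribute `planted`, a data.frame of
#'   `start`, `end` spans.
#' @export
plant_hairpin <- function(background, position, stem_length, loop_length,
                          gc_fraction, seed = NULL) {
  n <- nchar(background)
  span_len <- 2L * stem_length + loop_length
  start <- as.integer(position)
  end <- start + span_len - 1L
  if (start < 1L || end > n) {
    stop(sprintf("planted span %d-%d does not fit in the background (%d nt)",
                 start, end, n), call. = FALSE)
  }
  if (loop_length < 3L) stop("loop_length must be >= 3", call. = FALSE)
  prev <- attr(background, "planted") %||%
    data.frame(start = integer(0), end = integer(0))
  if (any(prev$start <= end & start <= prev$end)) {
    stop("planted span overlaps a previously planted hairpin",
         call. = FALSE)
  }
  build <- function() {
    n_gc <- round(gc_fraction * stem_length)
    is_gc <- sample(rep(c(TRUE, FALSE), c(n_gc, stem_length - n_gc)))
    left <- ifelse(is_gc,
                   sample(c("G", "C"), stem_length, replace = TRUE),
                   sample(c("A", "U"), stem_length, replace = TRUE))
    comp <- c(G = "C", C = "G", A = "U", U = "A")
    right <- rev(comp[left])
    loop <- sample(RNA_BASES, loop_length, replace = TRUE)
    paste(c(left, loop, right), collapse = "")
  }
  insert <- if (is.null(seed)) build() else with_local_seed(seed, build())
  out <- paste0(substr(background, 1, start - 1L), insert,
                substr(background, end + 1L, n))
  attr(out, "planted") <- rbind(prev, data.frame(start = start, end = end))
  out
}

#' Random structure corpus from a stochastic grammar
#'
#' Generates (sequence, dot-bracket) pairs by a recursive grammar over
#' helices and loops: a helix of geometric length is emitted, then with the
#' given probabilities the enclosed region continues as a hairpin loop, a
#' bulge, an internal loop, or a multibranch loop with 2-3 branches. Every
#' emitted structure is balanced, respects the minimum hairpin loop of 3,
#' and is pseudoknot free by construction; paired positions receive random
#' complementary bases (10% GU), unpaired positions random bases.
#'
#' @param n Number of structures.
#' @param min_len,max_len Approximate target length range (actual lengths
#'   vary with the grammar).
#' @param seed Seed for the whole corpus.
#' @param p_continue Probability a closed region holds a substructure
#'   rather than terminating in a hairpin loop.
#' @param p_mbl Probability that a continuing region is a multibranch loop
#'   (otherwise a bulge or internal loop, chosen evenly).
#' @return A data.frame with columns `sequence`, `structure`.
#' @export
random_structure_corpus <- function(n, min_len = 30L, max_len = 80L,
                                    seed = 1L, p_continue = 0.6,
                                    p_mbl = 0.25) {
  stopifnot(n >= 1L)
  gen_struct <- function(budget) {
    helix <- 2L + stats::rgeom(1, 0.45)
    budget <- budget - 2L * helix
    if (budget < 5L || runif(1) > p_continue) {
      loop <- sample(3:7, 1)
      return(paste0(strrep("(", helix), strrep(".", loop),
                    strrep(")", helix)))
    }
    if (runif(1) < p_mbl) {
      k <- sample(2:3, 1)
      parts <- vapply(seq_len(k), function(i) {
        gen_struct(max(10L, budget %/% (k + 1L)))
      }, character(1))
      gaps <- vapply(seq_len(k + 1L), function(i) {
        strrep(".", sample(0:3, 1))
      }, character(1))
      inner <- paste0(gaps[1],
                      paste0(parts, gaps[-1], collapse = ""))
      return(paste0(strrep("(", helix), inner, strrep(")", helix)))
    }
    s5 <- sample(0:4, 1)
    s3 <- if (s5 == 0L) sample(1:4, 1) else sample(0:4, 1)
    inner <- gen_struct(budget - s5 - s3)
    paste0(strrep("(", helix), strrep(".", s5), inner, strrep(".", s3),
           strrep(")", helix))
  }
  seq_for <- function(db) {
    pt <- pair_table(db)
    chars <- character(length(pt))
    pair_pool <- rbind(c("G", "C"), c("C", "G"), c("A", "U"), c("U", "A"),
                       c("G", "U"), c("U", "G"))
    for (k in seq_along(pt)) {
      if (pt[k] > k) {
        row <- sample.int(6L, 1L, prob = c(.3, .3, .15, .15, .05, .05))
        chars[k] <- pair_pool[row, 1]
        chars[pt[k]] <- pair_pool[row, 2]
      } else if (pt[k] == 0L) {
        chars[k] <- sample(RNA_BASES, 1)
      }
    }
    paste(chars, collapse = "")
  }
  with_local_seed(seed, {
    out <- vector("list", n)
    for (k in seq_len(n)) {
      target <- sample(min_len:max_len, 1)
      ext5 <- strrep(".", sample(0:4, 1))
      ext3 <- strrep(".", sample(0:4, 1))
      db <- paste0(ext5, gen_struct(target), ext3)
      out[[k]] <- data.frame(sequence = seq_for(db), structure = db,
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

#' Generate a toy pre-mRNA gene model
#'
#' A 2-4-exon gene with a 5'UTR in the first transcribed exon and a 3'UTR
#' in the last, on either strand, plus the matching transcript sequence
#' and GFF3 text. The GFF3 uses `gene` / `transcript` / `exon` /
#' `five_prime_UTR` / `three_prime_UTR` features with `ID`/`Parent`
#' attributes and parses with [read_gff_regions()].
#'
#' @param seed Seed controlling layout and sequence.
#' @param n_exons Number of exons (2-4; default drawn at random).
#' @param strand `"+"` or `"-"` (default drawn at random).
#' @param exon_len,intron_len Ranges (2-vectors) for exon and intron
#'   lengths in nucleotides.
#' @param chromosome Chromosome name for the GFF3.
#' @param gene_start Genomic start of the gene.
#' @return A list with `sequence` (transcript 5' to 3'), `gff` (character
#'   vector of GFF3 lines), `gene` (the `region_annotation`) and
#'   `transcript_id`.
#' @export
toy_gene_model <- function(seed = 1L, n_exons = NULL, strand = NULL,
                           exon_len = c(80L, 160L),
                           intron_len = c(60L, 140L),
                           chromosome = "chrS", gene_start = 1000L) {
  with_local_seed(seed, {
    if (is.null(n_exons)) n_exons <- sample(2:4, 1)
    if (is.null(strand)) strand <- sample(c("+", "-"), 1)
    stopifnot(n_exons >= 2L, n_exons <= 4L)
    ex_l <- sample(exon_len[1]:exon_len[2], n_exons, replace = TRUE)
    in_l <- sample(intron_len[1]:intron_len[2], n_exons - 1L,
                   replace = TRUE)
    # genomic exon layout
    starts <- integer(n_exons)
    cur <- gene_start
    for (k in seq_len(n_exons)) {
      starts[k] <- cur
      cur <- cur + ex_l[k]
      if (k < n_exons) cur <- cur + in_l[k]
    }
    ends <- starts + ex_l - 1L
    gene_end <- ends[n_exons]
    # transcribed first/last exon depends on strand
    first_ex <- if (strand == "+") 1L else n_exons
    last_ex <- if (strand == "+") n_exons else 1L
    utr5_len <- sample(20L:min(50L, ex_l[first_ex] - 10L), 1)
    utr3_len <- sample(20L:min(50L, ex_l[last_ex] - 10L), 1)
    if (strand == "+") {
      utr5 <- c(starts[first_ex], starts[first_ex] + utr5_len - 1L)
      utr3 <- c(ends[last_ex] - utr3_len + 1L, ends[last_ex])
    } else {
      utr5 <- c(ends[first_ex] - utr5_len + 1L, ends[first_ex])
      utr3 <- c(starts[last_ex], starts[last_ex] + utr3_len - 1L)
    }
    iv <- rbind(
      data.frame(kind = "exon", start = starts, end = ends),
      data.frame(kind = "five_utr", start = utr5[1], end = utr5[2]),
      data.frame(kind = "three_utr", start = utr3[1], end = utr3[2]))
    transcript_id <- sprintf("TOY%04d.1", seed %% 10000L)
    gene_id <- sub("\\.1$", "", transcript_id)
    gene <- region_annotation(transcript_id, chromosome, gene_start,
                              gene_end, strand, iv)
    sequence <- random_sequence(gene_end - gene_start + 1L)

    gff_kind <- c(exon = "exon", five_utr = "five_prime_UTR",
                  three_utr = "three_prime_UTR")
    feat <- function(type, s, e, attrs) {
      paste(chromosome, "thermoscan", type, s, e, ".", strand, ".", attrs,
            sep = "\t")
    }
    gff <- c("##gff-version 3",
             feat("gene", gene_start, gene_end,
                  sprintf("ID=%s", gene_id)),
             feat("transcript", gene_start, gene_end,
                  sprintf("ID=%s;Parent=%s", transcript_id, gene_id)),
             vapply(seq_len(nrow(iv)), function(r) {
               feat(gff_kind[[iv$kind[r]]], iv$start[r], iv$end[r],
                    sprintf("ID=%s.%s%d;Parent=%s", transcript_id,
                            iv$kind[r], r, transcript_id))
             }, character(1)))
    list(sequence = sequence, gff = gff, gene = gene,
         transcript_id = transcript_id)
  })
}
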
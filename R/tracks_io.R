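# Readers and writers for the formats the pipeline touches. Internal
# coordinates are 1-based inclusive everywhere; the only conversion to
# 0-based half-open happens in the BED emitters, through one function
# pair, so boundary semantics are property-testable by round trip.

#' Convert between 1-based inclusive and 0-based half-open intervals
#'
#' @param start,end 1-based inclusive coordinates.
#' @return `interval_to_bed`: list with 0-based half-open `start`, `end`.
#' @export
interval_to_bed <- function(start, end) {
  list(start = start - 1L, end = end)
}

#' @rdname interval_to_bed
#' @param bed_start,bed_end 0-based half-open coordinates.
#' @return `interval_from_bed`: list with 1-based inclusive `start`, `end`.
#' @export
interval_from_bed <- function(bed_start, bed_end) {
  list(start = bed_start + 1L, end = bed_end)
}

# ---------------------------------------------------------------------------
# FASTA

#' Read a FASTA file of transcript sequences
#'
#' Parsing is delegated to Biostrings; sequences are normalized to the
#' uppercase RNA alphabet (`T` becomes `U`). Duplicate identifiers and
#' zero-length records are refused by name.
#'
#' @param path FASTA file (multi-record allowed).
#' @return Named character vector, ids to sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  seqs <- as.character(set)
  empty <- nchar(seqs) == 0L
  if (any(empty)) {
    stop("FASTA record with no sequence: ", ids[empty][1], call. = FALSE)
  }
  out <- vapply(seqs, normalize_sequence, character(1), USE.NAMES = FALSE)
  names(out) <- ids
  out
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector (ids to sequences).
#' @param path Output path.
#' @param width Line-wrapping width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Gene models

#' Construct a transcript region annotation
#'
#' Intron/exon/UTR layout of one unspliced transcript on a contiguous
#' genomic span. Intervals are genomic, 1-based inclusive; introns are not
#' stored but derived as the gaps between consecutive exons
#' ([intron_intervals()]). Invariants enforced: intervals inside the gene
#' span, exons sorted and non-overlapping, every UTR contained in an exon.
#'
#' @param transcript_id Identifier.
#' @param chromosome Chromosome name.
#' @param gene_start,gene_end Genomic span (1-based inclusive).
#' @param strand `"+"` or `"-"`.
#' @param intervals data.frame with columns `kind` (`exon`, `five_utr`,
#'   `three_utr`), `start`, `end` in genomic coordinates.
#' @return An object of class `region_annotation`.
#' @export
region_annotation <- function(transcript_id, chromosome, gene_start,
                              gene_end, strand, intervals) {
  stopifnot(strand %in% c("+", "-"), gene_start <= gene_end)
  iv <- intervals[order(intervals$start), , drop = FALSE]
  rownames(iv) <- NULL
  if (any(iv$start > iv$end) || any(iv$start < gene_start) ||
      any(iv$end > gene_end)) {
    stop("annotation interval outside the gene span", call. = FALSE)
  }
  ex <- iv[iv$kind == "exon", , drop = FALSE]
  if (nrow(ex) > 1L && any(ex$start[-1] <= ex$end[-nrow(ex)])) {
    stop("overlapping exons in annotation for ", transcript_id,
         call. = FALSE)
  }
  for (r in which(iv$kind %in% c("five_utr", "three_utr"))) {
    inside <- any(ex$start <= iv$start[r] & iv$end[r] <= ex$end)
    if (!inside) {
      stop(sprintf("%s interval %d-%d not contained in an exon",
                   iv$kind[r], iv$start[r], iv$end[r]), call. = FALSE)
    }
  }
  structure(list(transcript_id = transcript_id, chromosome = chromosome,
                 gene_start = as.integer(gene_start),
                 gene_end = as.integer(gene_end), strand = strand,
                 intervals = iv),
            class = "region_annotation")
}

#' Intron intervals of a region annotation
#'
#' Maximal gaps between consecutive exons, genomic 1-based inclusive.
#'
#' @param gene A `region_annotation`.
#' @return data.frame with columns `start`, `end` (0 rows for single-exon
#'   genes).
#' @export
intron_intervals <- function(gene) {
  ex <- gene$intervals[gene$intervals$kind == "exon", , drop = FALSE]
  if (nrow(ex) < 2L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  data.frame(start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1] - 1L)
}

#' Read the region annotation of one transcript from a GFF3 file
#'
#' GFF3 parsing is delegated to rtracklayer. Exon and UTR features whose
#' `Parent` is the requested transcript are collected; the transcript
#' feature itself provides the genomic span and strand. GFF3 coordinates
#' are 1-based inclusive and are kept as such.
#'
#' @param path GFF3 file.
#' @param transcript_id Transcript identifier (matched against feature
#'   `ID`/`Parent` attributes).
#' @return A `region_annotation`.
#' @export
read_gff_regions <- function(path, transcript_id) {
  gr <- rtracklayer::import(path, format = "gff3")
  ids <- as.character(S4Vectors::mcols(gr)$ID)
  parents <- S4Vectors::mcols(gr)$Parent
  parent1 <- vapply(seq_along(gr), function(k) {
    p <- parents[[k]]
    if (length(p)) as.character(p[1]) else NA_character_
  }, character(1))
  tx <- which(!is.na(ids) & ids == transcript_id)
  if (!length(tx)) {
    stop("transcript not found in GFF3: ", transcript_id, call. = FALSE)
  }
  tx <- tx[1]
  kids <- which(!is.na(parent1) & parent1 == transcript_id)
  type <- as.character(S4Vectors::mcols(gr)$type)
  kind_map <- c(exon = "exon", five_prime_UTR = "five_utr",
                three_prime_UTR = "three_utr")
  sel <- kids[type[kids] %in% names(kind_map)]
  iv <- data.frame(kind = unname(kind_map[type[sel]]),
                   start = GenomicRanges::start(gr)[sel],
                   end = GenomicRanges::end(gr)[sel])
  region_annotation(
    transcript_id = transcript_id,
    chromosome = as.character(GenomicRanges::seqnames(gr))[tx],
    gene_start = GenomicRanges::start(gr)[tx],
    gene_end = GenomicRanges::end(gr)[tx],
    strand = as.character(GenomicRanges::strand(gr))[tx],
    intervals = iv)
}

# ---------------------------------------------------------------------------
# WIG

#' Write a per-nucleotide profile as a fixedStep WIG track
#'
#' The track is anchored at the genomic coordinate of transcript position 1
#' (strand-adjusted): on the minus strand the transcript 5' end is the
#' highest genomic coordinate, so values are emitted in reverse so that
#' the file ascends from `gene_start` as fixedStep requires. Positions with
#' no covering window are written as 0.
#'
#' @param values Numeric vector in transcript 5' to 3' order, one value per
#'   nucleotide.
#' @param gene A `region_annotation` whose span length equals
#'   `length(values)`.
#' @param path Output path.
#' @param name Track name written in the `track` line.
#' @return `path`, invisibly.
#' @export
write_wig <- function(values, gene, path, name = "thermoscan") {
  len <- gene$gene_end - gene$gene_start + 1L
  if (length(values) != len) {
    stop(sprintf("profile length %d does not match gene span %d",
                 length(values), len), call. = FALSE)
  }
  vals <- if (gene$strand == "-") rev(values) else values
  vals[is.na(vals)] <- 0
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(sprintf("track type=wiggle_0 name=\"%s\"", name),
               sprintf("fixedStep chrom=%s start=%d step=1",
                       gene$chromosome, gene$gene_start),
               fmt_num(vals)), con)
  invisible(path)
}

#' Read a fixedStep WIG track written by [write_wig()]
#'
#' @param path WIG file.
#' @return A list with `chromosome`, `start`, `step` and `values` (in
#'   genomic, ascending order).
#' @export
read_wig <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^track", lines)]
  hdr <- lines[1]
  m <- regmatches(hdr, regexec(
    "^fixedStep chrom=(\\S+) start=(\\d+) step=(\\d+)$", hdr))[[1]]
  if (length(m) != 4) stop("not a fixedStep WIG header: ", hdr,
                           call. = FALSE)
  list(chromosome = m[2], start = as.integer(m[3]), step = as.integer(m[4]),
       values = as.numeric(lines[-1]))
}

# ---------------------------------------------------------------------------
# Arc tracks

#' Arc color class of a Znorm value
#'
#' The z-score color convention: blue for znorm <= -2, green for
#' (-2, -1], yellow for (-1, 0]; pairs with positive znorm carry no color
#' class (`NA`) and are excluded from arc tracks by default. The boundary
#' values -2 and -1 fall in the stronger class so the three classes
#' partition znorm <= 0 totally.
#'
#' @param znorm Numeric vector.
#' @return Character vector: `"blue"`, `"green"`, `"yellow"` or `NA`.
#' @export
arc_color <- function(znorm) {
  ifelse(znorm <= -2, "blue",
         ifelse(znorm <= -1, "green",
                ifelse(znorm <= 0, "yellow", NA_character_)))
}

ARC_RGB <- c(blue = "0,0,255", green = "0,160,0", yellow = "230,200,0")

#' Write a consensus structure as a genomic arc track
#'
#' A BED9-derived dialect, one line per retained pair: `chrom`, 0-based
#' start of the left endpoint, end of the right endpoint, a
#' `znorm=<value>` name, score 0, strand, thickStart/thickEnd repeating
#' the interval, and an `itemRgb` encoding the color class. Pairs with
#' znorm > 0 are omitted unless `include_positive` is set (then colored
#' grey for debugging).
#'
#' @param consensus A `consensus_structure` in transcript coordinates.
#' @param gene A `region_annotation` used to map to genomic coordinates.
#' @param path Output path.
#' @param include_positive Keep pairs with znorm > 0 (default FALSE).
#' @return `path`, invisibly.
#' @export
write_arc_track <- function(consensus, gene, path,
                            include_positive = FALSE) {
  p <- consensus$pairs
  gi <- map_transcript_to_genome(p$i, gene)
  gj <- map_transcript_to_genome(p$j, gene)
  left <- pmin(gi, gj)
  right <- pmax(gi, gj)
  col <- arc_color(p$znorm)
  keep <- !is.na(col) | include_positive
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(sprintf("track name=\"%s arcs\" itemRgb=\"On\"",
                     gene$transcript_id), con)
  if (any(keep)) {
    bed <- interval_to_bed(left[keep], right[keep])
    rgb <- ifelse(is.na(col[keep]), "128,128,128", ARC_RGB[col[keep]])
    writeLines(paste(gene$chromosome, bed$start, bed$end,
                     paste0("znorm=", fmt_num(p$znorm[keep], 3L)), 0L,
                     gene$strand, bed$start, bed$end, rgb,
                     sep = "\t"), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# CT and DBN structure formats

#' Write a structure as a connectivity table (CT)
#'
#' Standard 6-column CT: index, base, previous index, next index, pairing
#' partner (0 if unpaired), and the index again. The header line carries
#' the sequence length, energy and identifier.
#'
#' @param sequence Nucleotide string.
#' @param structure Balanced dot-bracket of the same length.
#' @param path Output path.
#' @param energy Energy written in the header (kcal/mol).
#' @param id Identifier written in the header.
#' @return `path`, invisibly.
#' @export
write_ct <- function(sequence, structure, path, energy = 0,
                     id = "structure") {
  seqn <- normalize_sequence(sequence)
  pt <- pair_table(structure)
  n <- length(pt)
  if (nchar(seqn) != n) stop("sequence and structure lengths differ",
                             call. = FALSE)
  chars <- strsplit(seqn, "", fixed = TRUE)[[1]]
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(sprintf("%d\tENERGY = %s\t%s", n, fmt_num(energy, 2L), id), con)
  idx <- seq_len(n)
  writeLines(paste(idx, chars, idx - 1L, ifelse(idx == n, 0L, idx + 1L),
                   pt, idx, sep = "\t"), con)
  invisible(path)
}

#' Read a connectivity table (CT)
#'
#' Validates reciprocity of the pairing column: a row claiming partner `j`
#' whose row `j` does not point back is refused.
#'
#' @param path CT file.
#' @return A list with `id`, `energy`, `sequence`, `structure`.
#' @export
read_ct <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], "\t")[[1]]
  n <- as.integer(hdr[1])
  energy <- as.numeric(sub(".*ENERGY = ", "", hdr[2]))
  id <- if (length(hdr) >= 3) hdr[3] else "structure"
  body <- strsplit(lines[1 + seq_len(n)], "\t")
  base <- vapply(body, `[`, character(1), 2L)
  partner <- as.integer(vapply(body, `[`, character(1), 5L))
  for (i in seq_len(n)) {
    j <- partner[i]
    if (j > 0L && (j > n || partner[j] != i)) {
      stop(sprintf("malformed CT: row %d pairs with %d but row %d does not reciprocate",
                   i, j, j), call. = FALSE)
    }
  }
  chars <- rep(".", n)
  chars[partner > seq_len(n)] <- "("
  chars[partner > 0L & partner < seq_len(n)] <- ")"
  list(id = id, energy = energy, sequence = paste(base, collapse = ""),
       structure = paste(chars, collapse = ""))
}

#' Write / read dot-bracket (DBN) files
#'
#' Three lines per record: `>id`, sequence, structure.
#'
#' @param sequence Nucleotide string.
#' @param structure Dot-bracket of the same length.
#' @param path File path.
#' @param id Record identifier.
#' @return `path` invisibly (writer); a list with `id`, `sequence`,
#'   `structure` (reader).
#' @export
write_dbn <- function(sequence, structure, path, id = "structure") {
  if (nchar(sequence) != nchar(structure)) {
    stop("sequence and structure lengths differ", call. = FALSE)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(paste0(">", id), normalize_sequence(sequence), structure),
             con)
  invisible(path)
}

#' @rdname write_dbn
#' @export
read_dbn <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || !startsWith(lines[1], ">")) {
    stop("not a DBN file: ", path, call. = FALSE)
  }
  list(id = sub("^>", "", lines[1]), sequence = lines[2],
       structure = lines[3])
}
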
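# Sub-motif dictionary: split a consensus dot-bracket into discrete
# base-paired motifs with a bond-order counter, refold each motif for its
# metrics, and assign it to a transcript region from a gene model.

MOTIF_REGIONS <- c("five_utr", "exon", "intron", "three_utr", "multi_region")

#' Extract discrete base-paired sub-motifs from a dot-bracket
#'
#' Walks the structure with a bond-order counter (+1 per `(`, -1 per `)`).
#' Each maximal interval over which the counter is positive — from the
#' opening parenthesis that lifts it above zero to the closing parenthesis
#' that returns it to zero — is one motif. An optional flank of unpaired
#' context is appended on both sides, clipped at the transcript ends.
#' Unbalanced structures raise a structured error naming the first
#' offending position; they are never silently repaired.
#'
#' @param structure Dot-bracket string (balanced).
#' @param sequence Nucleotide string of the same length.
#' @param flank Flanking context in nucleotides (default 0). Flanks are
#'   annotation context only: the balance guarantee applies to the core
#'   span, not the flanks.
#' @param transcript_id Identifier copied into the output.
#' @return A data.frame of class `motif_table` with columns
#'   `transcript_id`, `start`, `end` (flank-inclusive span),
#'   `core_start`, `core_end` (the depth-positive interval), `sequence`,
#'   `structure`, `flank`; motifs ordered 5' to 3'.
#' @export
extract_submotifs <- function(structure, sequence, flank = 0L,
                              transcript_id = "transcript") {
  n <- nchar(structure)
  if (nchar(sequence) != n) {
    stop("sequence and structure lengths differ", call. = FALSE)
  }
  pair_table(structure) # validates balance; errors name the position
  chars <- strsplit(structure, "", fixed = TRUE)[[1]]
  opens <- integer(0); closes <- integer(0)
  d <- 0L
  cur_open <- NA_integer_
  for (k in seq_len(n)) {
    if (chars[k] == "(") {
      if (d == 0L) cur_open <- k
      d <- d + 1L
    } else if (chars[k] == ")") {
      d <- d - 1L
      if (d == 0L) {
        opens <- c(opens, cur_open)
        closes <- c(closes, k)
      }
    }
  }
  flank <- as.integer(flank)
  if (flank < 0L) stop("flank must be >= 0", call. = FALSE)
  if (!length(opens)) {
    out <- data.frame(transcript_id = character(0), start = integer(0),
                      end = integer(0), core_start = integer(0),
                      core_end = integer(0), sequence = character(0),
                      structure = character(0), flank = integer(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("motif_table", "data.frame")
    return(out)
  }
  start <- pmax(1L, opens - flank)
  end <- pmin(n, closes + flank)
  out <- data.frame(transcript_id = rep(transcript_id, length(opens)),
                    start = start, end = end,
                    core_start = opens, core_end = closes,
                    sequence = substring(sequence, start, end),
                    structure = substring(structure, start, end),
                    flank = rep(flank, length(opens)),
                    stringsAsFactors = FALSE)
  class(out) <- c("motif_table", "data.frame")
  out
}

#' Attach refolded metrics to motifs
#'
#' Each motif's subsequence (flanks included) is refolded with the engine:
#' `mfe` is the engine's minimum free energy and `ed` the ensemble
#' diversity of the motif in isolation. Metrics are therefore position
#' independent: identical motif sequences get identical metrics.
#'
#' @param motifs A `motif_table` from [extract_submotifs()].
#' @param engine A `fold_engine`.
#' @return The input table with `mfe` and `ed` columns added.
#' @export
annotate_motif_metrics <- function(motifs, engine = default_engine()) {
  mfe <- numeric(nrow(motifs))
  ed <- numeric(nrow(motifs))
  for (k in seq_len(nrow(motifs))) {
    res <- tryCatch({
      f <- engine$fold(motifs$sequence[k])
      e <- ensemble_diversity(engine$pair_probs(motifs$sequence[k]))
      list(mfe = f$energy, ed = e)
    }, error = function(e) {
      stop(sprintf("engine failure on motif %s:%d-%d: %s",
                   motifs$transcript_id[k], motifs$start[k], motifs$end[k],
                   conditionMessage(e)), call. = FALSE)
    })
    mfe[k] <- res$mfe
    ed[k] <- res$ed
  }
  motifs$mfe <- mfe
  motifs$ed <- ed
  motifs
}

#' Map transcript positions to genomic coordinates
#'
#' For an unspliced (pre-mRNA) transcript occupying a contiguous genomic
#' span: plus strand maps position `p` to `gene_start + p - 1`; minus
#' strand to `gene_end - p + 1`.
#'
#' @param position 1-based transcript coordinate(s).
#' @param gene A `region_annotation` (see [region_annotation()]).
#' @return Genomic coordinate(s), same length as `position`.
#' @export
map_transcript_to_genome <- function(position, gene) {
  len <- gene$gene_end - gene$gene_start + 1L
  if (any(position < 1L | position > len)) {
    stop(sprintf("transcript position outside [1, %d]", len), call. = FALSE)
  }
  if (gene$strand == "+") gene$gene_start + position - 1L
  else gene$gene_end - position + 1L
}

#' Map genomic positions to transcript coordinates
#'
#' Exact inverse of [map_transcript_to_genome()].
#'
#' @param gpos Genomic coordinate(s) within the gene span.
#' @param gene A `region_annotation`.
#' @return 1-based transcript coordinate(s).
#' @export
map_genome_to_transcript <- function(gpos, gene) {
  if (any(gpos < gene$gene_start | gpos > gene$gene_end)) {
    stop("genomic position outside the gene span", call. = FALSE)
  }
  if (gene$strand == "+") gpos - gene$gene_start + 1L
  else gene$gene_end - gpos + 1L
}

# per-position transcript-coordinate region labels for a gene model;
# precedence: UTRs over exon; anything not exonic is intron
transcript_region_labels <- function(gene) {
  len <- gene$gene_end - gene$gene_start + 1L
  lab <- rep("intron", len)
  iv <- gene$intervals
  paint <- function(kind_sel, value) {
    sel <- iv$kind == kind_sel
    for (r in which(sel)) {
      tpos <- map_genome_to_transcript(c(iv$start[r], iv$end[r]), gene)
      lab[min(tpos):max(tpos)] <<- value
    }
  }
  paint("exon", "exon")
  paint("five_utr", "five_utr")
  paint("three_utr", "three_utr")
  lab
}

#' Assign a motif span to a transcript region
#'
#' The label is the unique region (5'UTR, exon, intron, 3'UTR) containing
#' the whole core span; spans touching more than one region are labelled
#' `multi_region` rather than forced into a single category. UTR labels
#' take precedence over exon (UTR intervals lie within exons in GFF3);
#' `exon` therefore means coding/non-UTR exonic sequence.
#'
#' @param start,end 1-based transcript coordinates of the motif core.
#' @param gene A `region_annotation`.
#' @return One of `"five_utr"`, `"exon"`, `"intron"`, `"three_utr"`,
#'   `"multi_region"`.
#' @export
assign_region <- function(start, end, gene) {
  len <- gene$gene_end - gene$gene_start + 1L
  if (start < 1L || end > len || start > end) {
    stop(sprintf("motif span %d-%d outside the annotated transcript [1, %d]",
                 start, end, len), call. = FALSE)
  }
  lab <- unique(transcript_region_labels(gene)[start:end])
  if (length(lab) == 1L) lab else "multi_region"
}

#' Assign regions to every motif in a table
#'
#' @param motifs A `motif_table`.
#' @param gene A `region_annotation`.
#' @return The table with a `region` column (core spans are used, so flank
#'   context never changes the assignment).
#' @export
assign_motif_regions <- function(motifs, gene) {
  motifs$region <- vapply(seq_len(nrow(motifs)), function(k) {
    assign_region(motifs$core_start[k], motifs$core_end[k], gene)
  }, character(1))
  motifs
}

#' Write a motif dictionary as TSV
#'
#' Columns: `transcript_id`, `start`, `end`, `region`, `sequence`,
#' `structure`, `mfe`, `ed`. Missing optional columns (region or metrics)
#' are written as `NA`.
#'
#' @param motifs A `motif_table`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_motif_tsv <- function(motifs, path) {
  df <- data.frame(
    transcript_id = motifs$transcript_id,
    start = motifs$start, end = motifs$end,
    region = if ("region" %in% names(motifs)) motifs$region else NA,
    sequence = motifs$sequence, structure = motifs$structure,
    mfe = if ("mfe" %in% names(motifs)) fmt_num(motifs$mfe) else NA,
    ed = if ("ed" %in% names(motifs)) fmt_num(motifs$ed) else NA,
    stringsAsFactors = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = "\t"), con)
  if (nrow(df)) writeLines(do.call(paste, c(unname(as.list(df)), sep = "\t")),
                           con)
  invisible(path)
}
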
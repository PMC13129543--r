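# End-to-end driver: filter transcripts, scan, build consensus at the
# configured thresholds, extract and annotate the motif dictionary, and
# write the per-transcript output bundle plus a run manifest.

#' Pipeline configuration
#'
#' @param scan A `scan_params` object (window length, step, shuffles, seed).
#' @param thresholds Znorm cutoffs for the filtered outputs; strictly
#'   negative (default `c(-1, -2)`).
#' @param flank Flanking context for motif extraction (nucleotides).
#' @param out_dir Output directory (created if missing).
#' @param znorm_mode Partner-ranking denominator, see [select_consensus()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(scan = scan_params(), thresholds = c(-1, -2),
                            flank = 0L, out_dir = tempfile("thermoscan_"),
                            znorm_mode = "pair") {
  if (any(thresholds >= 0)) {
    stop("thresholds must be strictly negative", call. = FALSE)
  }
  structure(list(scan = scan, thresholds = sort(thresholds,
                                                decreasing = TRUE),
                 flank = as.integer(flank), out_dir = out_dir,
                 znorm_mode = znorm_mode),
            class = "pipeline_config")
}

#' Filter transcripts on the pipeline length bounds
#'
#' Accepts transcripts with lengths in the inclusive range
#' [120, 200000]; shorter or longer ones are rejected with a reason.
#'
#' @param sequences Named character vector of sequences.
#' @return A list with `accepted` (named character vector) and `rejected`
#'   (data.frame `id`, `length`, `reason`).
#' @export
filter_transcripts <- function(sequences) {
  len <- nchar(sequences)
  reason <- ifelse(len < MIN_TRANSCRIPT_LEN, "too short",
                   ifelse(len > MAX_TRANSCRIPT_LEN, "too long", NA))
  rejected <- data.frame(id = names(sequences)[!is.na(reason)],
                         length = len[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  rownames(rejected) <- NULL
  list(accepted = sequences[is.na(reason)], rejected = rejected)
}

bundle_paths <- function(out_dir, id, thresholds) {
  tdir <- file.path(out_dir, id)
  th_tag <- function(tau) sprintf("%g", tau)
  list(dir = tdir,
       fasta = file.path(tdir, paste0(id, ".fasta")),
       scan = file.path(tdir, paste0(id, ".scan.tsv")),
       motifs = stats::setNames(
         file.path(tdir, sprintf("%s.motifs.%s.tsv", id,
                                 th_tag(thresholds))),
         th_tag(thresholds)),
       dbn = stats::setNames(
         file.path(tdir, sprintf("%s.%s.dbn", id, th_tag(thresholds))),
         th_tag(thresholds)),
       ct = stats::setNames(
         file.path(tdir, sprintf("%s.%s.ct", id, th_tag(thresholds))),
         th_tag(thresholds)),
       constraints = file.path(tdir, paste0(id, ".constraints.tsv")),
       wig_mfe = file.path(tdir, paste0(id, ".mfe.wig")),
       wig_z = file.path(tdir, paste0(id, ".zscore.wig")),
       wig_ed = file.path(tdir, paste0(id, ".ed.wig")),
       arcs = file.path(tdir, paste0(id, ".arcs.bed")),
       manifest = file.path(tdir, paste0(id, ".manifest.txt")))
}

# transcript-coordinate stand-in annotation when no gene model is supplied
identity_annotation <- function(id, length) {
  region_annotation(id, id, 1L, as.integer(length), "+",
                    data.frame(kind = "exon", start = 1L,
                               end = as.integer(length)))
}

#' Run the full scanning and dictionary pipeline
#'
#' For every accepted transcript: sliding-window scan, Zsum/Znorm
#' consensus, threshold-filtered structures, motif dictionaries with
#' refolded metrics (and region labels when a GFF3 is given),
#' per-nucleotide WIG tracks (MFE, z-score, ED), an arc track, a
#' constraint file, and a plain-text manifest recording the configuration
#' and warning counts. Outputs are byte-deterministic for a fixed seed. A
#' stage failure marks the bundle incomplete in the manifest but retains
#' the partial outputs.
#'
#' @param fasta Path to a FASTA file, or a named character vector of
#'   sequences.
#' @param gff Optional path to a GFF3 with gene models for the transcript
#'   ids (pre-mRNA layout). Without it, tracks are anchored at transcript
#'   coordinate 1 on a synthetic plus-strand span.
#' @param config A `pipeline_config`.
#' @param engine A `fold_engine`.
#' @return Invisibly, a list with `manifest` (data.frame, one row per
#'   transcript), `rejected`, and `out_dir`.
#' @export
run_full_pipeline <- function(fasta, gff = NULL,
                              config = pipeline_config(),
                              engine = default_engine()) {
  seqs <- if (is.character(fasta) && length(fasta) == 1L &&
              file.exists(fasta)) read_fasta(fasta) else fasta
  seqs <- vapply(seqs, normalize_sequence, character(1))
  flt <- filter_transcripts(seqs)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest_rows <- list()
  for (id in names(flt$accepted)) {
    sequence <- flt$accepted[[id]]
    paths <- bundle_paths(config$out_dir, id, config$thresholds)
    dir.create(paths$dir, recursive = TRUE, showWarnings = FALSE)
    warnings_seen <- character(0)
    status <- "complete"
    failed_stage <- ""
    res <- tryCatch({
      gene <- if (is.null(gff)) identity_annotation(id, nchar(sequence))
              else read_gff_regions(gff, id)

      write_fasta(stats::setNames(sequence, id), paths$fasta)

      scan <- withCallingHandlers(
        scan_transcript(sequence, config$scan, engine),
        warning = function(w) {
          warnings_seen <<- c(warnings_seen, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      write_scan_tsv(scan, paths$scan)

      evidence <- accumulate_pair_evidence(scan, nchar(sequence))
      consensus <- select_consensus(evidence, nchar(sequence),
                                    znorm_mode = config$znorm_mode)
      write_constraints(consensus, paths$constraints)

      for (tau in config$thresholds) {
        tag <- sprintf("%g", tau)
        filt <- apply_threshold(consensus, tau)
        db <- consensus_to_dotbracket(filt)
        write_dbn(sequence, db, paths$dbn[[tag]],
                  id = sprintf("%s znorm<=%s", id, tag))
        write_ct(sequence, db, paths$ct[[tag]],
                 energy = sum(filt$pairs$znorm), id = id)
        motifs <- extract_submotifs(db, sequence, flank = config$flank,
                                    transcript_id = id)
        motifs <- annotate_motif_metrics(motifs, engine)
        motifs <- assign_motif_regions(motifs, gene)
        write_motif_tsv(motifs, paths$motifs[[tag]])
      }

      prof <- per_nucleotide_profiles(scan, nchar(sequence))
      write_wig(prof$mean_mfe, gene, paths$wig_mfe,
                name = paste0(id, " mean MFE"))
      write_wig(prof$mean_zscore, gene, paths$wig_z,
                name = paste0(id, " mean z-score"))
      write_wig(prof$mean_ed, gene, paths$wig_ed,
                name = paste0(id, " mean ED"))
      write_arc_track(consensus, gene, paths$arcs)
      TRUE
    }, error = function(e) {
      status <<- "incomplete"
      failed_stage <<- conditionMessage(e)
      FALSE
    })

    manifest <- c(
      sprintf("transcript\t%s", id),
      sprintf("length\t%d", nchar(sequence)),
      sprintf("status\t%s", status),
      if (nzchar(failed_stage)) sprintf("failed_stage\t%s", failed_stage),
      sprintf("package_version\t%s", as.character(packageVersion("thermoscan"))),
      sprintf("engine\t%s", engine$name %||% "custom"),
      sprintf("window_length\t%d", config$scan$window_length),
      sprintf("step\t%d", config$scan$step),
      sprintf("n_shuffles\t%d", config$scan$n_shuffles),
      sprintf("shuffle_kind\t%s", config$scan$shuffle_kind),
      sprintf("seed\t%d", config$scan$seed),
      sprintf("thresholds\t%s", paste(config$thresholds, collapse = ",")),
      sprintf("flank\t%d", config$flank),
      sprintf("znorm_mode\t%s", config$znorm_mode),
      sprintf("n_warnings\t%d", length(warnings_seen)),
      if (length(warnings_seen))
        sprintf("warning\t%s", unique(warnings_seen)))
    con <- file(paths$manifest, "wb")
    writeLines(manifest, con)
    close(con)

    manifest_rows[[id]] <- data.frame(id = id, length = nchar(sequence),
                                      status = status,
                                      n_warnings = length(warnings_seen),
                                      stringsAsFactors = FALSE)
  }

  run_manifest <- file.path(config$out_dir, "run_manifest.txt")
  con <- file(run_manifest, "wb")
  writeLines(c(sprintf("accepted\t%d", length(flt$accepted)),
               sprintf("rejected\t%d", nrow(flt$rejected)),
               if (nrow(flt$rejected))
                 sprintf("rejected_transcript\t%s\t%d\t%s",
                         flt$rejected$id, flt$rejected$length,
                         flt$rejected$reason)), con)
  close(con)

  invisible(list(
    manifest = if (length(manifest_rows)) do.call(rbind, manifest_rows)
               else data.frame(id = character(0)),
    rejected = flt$rejected,
    out_dir = config$out_dir))
}
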
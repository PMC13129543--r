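# Consensus building: aggregate per-window structures into per-pair
# z-score evidence (Zsum), normalize by window coverage (Znorm), select
# each nucleotide's most favoured partner, and keep the mutually agreeing,
# non-crossing pair set.

#' Accumulate per-pair z-score evidence from a window scan
#'
#' Every base pair predicted in a window contributes that window's z-score
#' to the pair's running sum (Zsum); the number of contributing windows is
#' tracked, and Znorm = Zsum / count (the per-pair-count policy; see
#' `znorm_mode` in [select_consensus()] for the per-nucleotide ranking
#' alternative).
#'
#' @param records A `scan_table` from [scan_transcript()].
#' @param length Transcript length; defaults to the largest window end.
#' @return A data.frame of class `pair_evidence` with columns `i`, `j`,
#'   `zsum`, `count`, `znorm`, ordered by `(i, j)`.
#' @export
accumulate_pair_evidence <- function(records,
                                     length = max(records$end, 0L)) {
  ii <- integer(0); jj <- integer(0); zz <- numeric(0)
  for (k in seq_len(nrow(records))) {
    prs <- db_pairs(records$structure[k])
    if (!nrow(prs)) next
    off <- records$start[k] - 1L
    gi <- prs[, 1] + off
    gj <- prs[, 2] + off
    if (any(gj > records$end[k])) {
      stop(sprintf("window %d-%d predicts pairs outside its span",
                   records$start[k], records$end[k]), call. = FALSE)
    }
    ii <- c(ii, gi); jj <- c(jj, gj)
    zz <- c(zz, rep(records$zscore[k], nrow(prs)))
  }
  if (!length(ii)) {
    out <- data.frame(i = integer(0), j = integer(0), zsum = numeric(0),
                      count = integer(0), znorm = numeric(0))
  } else {
    key <- paste(ii, jj)
    zsum <- tapply(zz, key, sum)
    count <- tapply(zz, key, length)
    ord <- names(zsum)
    parts <- do.call(rbind, strsplit(ord, " ", fixed = TRUE))
    out <- data.frame(i = as.integer(parts[, 1]), j = as.integer(parts[, 2]),
                      zsum = as.numeric(zsum), count = as.integer(count))
    out$znorm <- out$zsum / out$count
    out <- out[order(out$i, out$j), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "length") <- as.integer(length)
  class(out) <- c("pair_evidence", "data.frame")
  out
}

#' Select the z-score-weighted consensus structure
#'
#' Per nucleotide, the partner minimizing Znorm is proposed; a pair is
#' retained only when the choice is mutual. A nucleotide whose minimal
#' Znorm is attained by more than one partner is left unpaired (competing
#' partners are dropped rather than guessed). Crossing conflicts among the
#' surviving pairs are resolved deterministically by processing candidates
#' in ascending Znorm (strongest evidence first; ties broken by the smaller
#' 5' index) and dropping any pair that crosses an already-kept one.
#'
#' @param evidence A `pair_evidence` table.
#' @param length Transcript length; defaults to the evidence attribute.
#' @param znorm_mode `"pair"` (default): partners ranked by
#'   Zsum / count(i,j). `"nucleotide"`: partner ranking for nucleotide `i`
#'   divides by the number of windows in which `i` is paired to any
#'   partner; stored Znorm values are per-pair in both modes.
#' @return A list of class `consensus_structure` with `length`, `pairs`
#'   (data.frame `i`, `j`, `znorm`, `zsum`, `count`) and `threshold`
#'   (`NA` until [apply_threshold()] is used).
#' @export
select_consensus <- function(evidence, length = attr(evidence, "length"),
                             znorm_mode = c("pair", "nucleotide")) {
  znorm_mode <- match.arg(znorm_mode)
  ev <- as.data.frame(evidence)
  n <- as.integer(length)
  tol <- 1e-9

  if (nrow(ev)) {
    if (znorm_mode == "nucleotide") {
      paired_windows <- tapply(rep(ev$count, 2L), c(ev$i, ev$j), sum)
      # rank value seen from nucleotide p for pair row r
      rank_of <- function(p, r) ev$zsum[r] / paired_windows[[as.character(p)]]
    } else {
      rank_of <- function(p, r) ev$znorm[r]
    }
    best <- rep(NA_integer_, n)
    ambiguous <- rep(FALSE, n)
    for (p in sort(unique(c(ev$i, ev$j)))) {
      rows <- which(ev$i == p | ev$j == p)
      vals <- vapply(rows, function(r) rank_of(p, r), numeric(1))
      m <- min(vals)
      hits <- rows[vals <= m + tol]
      if (length(hits) > 1L) {
        ambiguous[p] <- TRUE
      } else {
        best[p] <- ifelse(ev$i[hits] == p, ev$j[hits], ev$i[hits])
      }
    }
    mutual <- which(vapply(seq_len(nrow(ev)), function(r) {
      i <- ev$i[r]; j <- ev$j[r]
      !ambiguous[i] && !ambiguous[j] &&
        !is.na(best[i]) && !is.na(best[j]) &&
        best[i] == j && best[j] == i
    }, logical(1)))
    cand <- ev[mutual, , drop = FALSE]
    cand <- cand[order(cand$znorm, cand$i), , drop = FALSE]
    keep <- logical(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      i <- cand$i[r]; j <- cand$j[r]
      crosses <- FALSE
      kept <- which(keep)
      if (length(kept)) {
        ki <- cand$i[kept]; kj <- cand$j[kept]
        crosses <- any((ki < i & i < kj & kj < j) |
                         (i < ki & ki < j & j < kj))
      }
      keep[r] <- !crosses
    }
    pairs <- cand[keep, c("i", "j", "znorm", "zsum", "count"), drop = FALSE]
    pairs <- pairs[order(pairs$i), , drop = FALSE]
    rownames(pairs) <- NULL
  } else {
    pairs <- data.frame(i = integer(0), j = integer(0), znorm = numeric(0),
                        zsum = numeric(0), count = integer(0))
  }
  structure(list(length = n, pairs = pairs, threshold = NA_real_),
            class = "consensus_structure")
}

#' Filter a consensus structure at a Znorm threshold
#'
#' Retains exactly the pairs with Znorm at or below `tau`. The standard
#' pipeline produces filtered structures at tau = -1 and tau = -2; the
#' threshold sets are nested by construction.
#'
#' @param consensus A `consensus_structure`.
#' @param tau Znorm cutoff (e.g. -1 or -2).
#' @return A new `consensus_structure` with `threshold = tau`.
#' @export
apply_threshold <- function(consensus, tau) {
  stopifnot(inherits(consensus, "consensus_structure"))
  pairs <- consensus$pairs[consensus$pairs$znorm <= tau, , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(length = consensus$length, pairs = pairs,
                 threshold = as.numeric(tau)),
            class = "consensus_structure")
}

#' Dot-bracket string of a consensus structure
#'
#' @param consensus A `consensus_structure`.
#' @return Dot-bracket string of length `consensus$length`.
#' @export
consensus_to_dotbracket <- function(consensus) {
  pairs_to_db(as.matrix(consensus$pairs[, c("i", "j")]), consensus$length)
}

#' @export
print.consensus_structure <- function(x, ...) {
  cat(sprintf("consensus structure: %d nt, %d pairs, threshold %s\n",
              x$length, nrow(x$pairs),
              ifelse(is.na(x$threshold), "none", format(x$threshold))))
  invisible(x)
}

#' Per-nucleotide metric profiles
#'
#' The value at a position is the arithmetic mean of the per-window metric
#' over all windows covering that position; coverage is the number of such
#' windows. With step 1, interior positions are covered by `window_length`
#' windows and coverage ramps linearly at the transcript ends — the edge
#' effect that motivates coverage normalization of Zsum.
#'
#' @param records A `scan_table`.
#' @param length Transcript length.
#' @return A data.frame of class `nucleotide_profile` with columns
#'   `position`, `coverage`, `mean_mfe`, `mean_zscore`, `mean_ed`
#'   (`NA` where no window covers the position).
#' @export
per_nucleotide_profiles <- function(records, length) {
  n <- as.integer(length)
  cov <- integer(n)
  acc_mfe <- numeric(n); acc_z <- numeric(n); acc_ed <- numeric(n)
  for (k in seq_len(nrow(records))) {
    idx <- records$start[k]:records$end[k]
    cov[idx] <- cov[idx] + 1L
    acc_mfe[idx] <- acc_mfe[idx] + records$native_mfe[k]
    acc_z[idx] <- acc_z[idx] + records$zscore[k]
    acc_ed[idx] <- acc_ed[idx] + records$ed[k]
  }
  covered <- cov > 0L
  out <- data.frame(position = seq_len(n), coverage = cov,
                    mean_mfe = ifelse(covered, acc_mfe / cov, NA_real_),
                    mean_zscore = ifelse(covered, acc_z / cov, NA_real_),
                    mean_ed = ifelse(covered, acc_ed / cov, NA_real_))
  class(out) <- c("nucleotide_profile", "data.frame")
  out
}

#' Write a constraint file listing retained consensus pairs
#'
#' Three tab-separated columns (`i`, `j`, `znorm`), one retained pair per
#' line, for downstream constrained folding by external tools.
#'
#' @param consensus A `consensus_structure`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_constraints <- function(consensus, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("i\tj\tznorm", con)
  p <- consensus$pairs
  if (nrow(p)) {
    writeLines(paste(p$i, p$j, fmt_num(p$znorm), sep = "\t"), con)
  }
  invisible(path)
}
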
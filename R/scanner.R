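# Sliding-window thermodynamic scan: fold each window, fold composition-
# matched shuffled versions of it, and express the native stability as a
# z-score against that shuffle null.

MAX_TRANSCRIPT_LEN <- 200000L
MIN_TRANSCRIPT_LEN <- 120L

#' Scan parameters
#'
#' @param window_length Window size in nucleotides (default 120).
#' @param step Step size between window starts (default 1).
#' @param n_shuffles Number of shuffled sequences folded per window
#'   (default 50).
#' @param shuffle_kind `"mononucleotide"` (random permutation) or
#'   `"dinucleotide"` (exact dinucleotide-count-preserving shuffle).
#' @param seed Master seed; every window derives its own substream from
#'   `(seed, window start)` so scans are order-independent.
#' @return An object of class `scan_params`.
#' @export
scan_params <- function(window_length = 120L, step = 1L, n_shuffles = 50L,
                        shuffle_kind = c("mononucleotide", "dinucleotide"),
                        seed = 1L) {
  shuffle_kind <- match.arg(shuffle_kind)
  window_length <- as.integer(window_length)
  step <- as.integer(step)
  n_shuffles <- as.integer(n_shuffles)
  if (window_length < 2L) stop("window_length must be >= 2", call. = FALSE)
  if (step < 1L) stop("step must be >= 1", call. = FALSE)
  if (n_shuffles < 2L) stop("n_shuffles must be >= 2", call. = FALSE)
  structure(list(window_length = window_length, step = step,
                 n_shuffles = n_shuffles, shuffle_kind = shuffle_kind,
                 seed = as.integer(seed)),
            class = "scan_params")
}

#' Window coordinates of a sliding scan
#'
#' Windows start at 1, 1+step, ... while they still fit inside the
#' sequence; a sequence shorter than the window is refused, mirroring the
#' pipeline's exclusion of transcripts under the window length.
#'
#' @param length Sequence length.
#' @param params A `scan_params` object.
#' @return A data.frame with columns `start`, `end` (1-based inclusive).
#' @export
sliding_windows <- function(length, params) {
  length <- as.integer(length)
  w <- params$window_length
  if (length < w) {
    stop(sprintf("sequence length %d is shorter than the window (%d)",
                 length, w), call. = FALSE)
  }
  starts <- seq.int(1L, length - w + 1L, by = params$step)
  data.frame(start = starts, end = starts + w - 1L)
}

#' Mononucleotide shuffle
#'
#' Uniform random permutation of the sequence; nucleotide composition is
#' preserved exactly. Uses the current RNG state.
#'
#' @param sequence Nucleotide string.
#' @return Shuffled sequence string.
#' @export
mononucleotide_shuffle <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (length(chars) < 2L) return(sequence)
  paste(chars[sample.int(length(chars))], collapse = "")
}

#' Dinucleotide shuffle (Altschul-Erickson)
#'
#' Produces a random sequence with exactly the same dinucleotide count
#' multiset as the input, using the Altschul-Erickson Eulerian-path
#' construction: a random "last edge" in-tree to the terminal letter is
#' drawn, the remaining edge lists are permuted, and the resulting Eulerian
#' walk is read off. The first and last nucleotides are preserved. Uses the
#' current RNG state.
#'
#' @param sequence Nucleotide string of length >= 2.
#' @return Shuffled sequence string.
#' @export
dinucleotide_shuffle <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 2L) stop("dinucleotide shuffle needs length >= 2", call. = FALSE)
  if (n <= 3L) return(sequence)
  verts <- unique(chars)
  last <- chars[n]
  edges <- split(chars[-1], chars[-n]) # out-edge target lists per vertex
  inner <- setdiff(names(edges), last)

  pick_last <- function() {
    le <- vapply(inner, function(v) {
      tg <- edges[[v]]
      tg[sample.int(length(tg), 1L)]
    }, character(1))
    names(le) <- inner
    le
  }
  reaches_last <- function(le) {
    for (v in inner) {
      cur <- v
      for (hop in seq_len(length(verts) + 1L)) {
        if (cur == last) break
        cur <- le[[cur]]
        if (is.null(cur) || is.na(cur)) return(FALSE)
      }
      if (cur != last) return(FALSE)
    }
    TRUE
  }

  le <- NULL
  for (try in seq_len(10000L)) {
    cand <- pick_last()
    if (!length(inner) || reaches_last(cand)) {
      le <- cand
      break
    }
  }
  if (is.null(le) && length(inner)) {
    stop("failed to sample a valid Eulerian last-edge tree", call. = FALSE)
  }

  order_edges <- function(v) {
    tg <- edges[[v]]
    if (v %in% inner) {
      drop <- match(le[[v]], tg)
      rest <- tg[-drop]
      if (length(rest) > 1L) rest <- rest[sample.int(length(rest))]
      c(rest, le[[v]])
    } else {
      if (length(tg) > 1L) tg <- tg[sample.int(length(tg))]
      tg
    }
  }
  ordered <- lapply(stats::setNames(names(edges), names(edges)), order_edges)
  used <- stats::setNames(integer(length(ordered)), names(ordered))
  out <- character(n)
  out[1] <- chars[1]
  cur <- chars[1]
  for (k in 2:n) {
    used[[cur]] <- used[[cur]] + 1L
    nxt <- ordered[[cur]][used[[cur]]]
    out[k] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Thermodynamic z-score of a window
#'
#' `z = (native - mean(shuffled)) / sd(shuffled)` with the population
#' (divide-by-n) standard deviation. Negative z means the native sequence
#' is more stable than composition-matched random sequences. A degenerate
#' null (sd below 1e-9, e.g. a homopolymer window) yields z = 0 with a
#' warning.
#'
#' @param native_mfe Native window MFE (kcal/mol).
#' @param shuffled_mfes Numeric vector (length >= 2) of shuffle MFEs.
#' @return A single finite number.
#' @export
window_zscore <- function(native_mfe, shuffled_mfes) {
  if (length(shuffled_mfes) < 2L) {
    stop("need at least two shuffled MFEs", call. = FALSE)
  }
  mu <- mean(shuffled_mfes)
  sdv <- sqrt(mean((shuffled_mfes - mu)^2))
  if (sdv < 1e-9) {
    warning("degenerate shuffle null (sd ~ 0); z-score set to 0",
            call. = FALSE)
    return(0)
  }
  (native_mfe - mu) / sdv
}

#' Sliding-window thermodynamic scan of a transcript
#'
#' For every window: fold the native subsequence, fold `n_shuffles`
#' shuffled versions, compute the thermodynamic z-score, and compute the
#' ensemble diversity from the partition function. Reproducible: each
#' window seeds its own RNG substream from `(params$seed, start)`, and the
#' caller's RNG state is left untouched.
#'
#' @param sequence Transcript sequence (RNA or DNA alphabet), length within
#'   `[window_length, 200000]`.
#' @param params A `scan_params` object.
#' @param engine A `fold_engine` (default [default_engine()]).
#' @return A data.frame of class `scan_table` with one row per window and
#'   columns `start`, `end`, `native_mfe`, `shuffle_mean`, `shuffle_sd`,
#'   `zscore`, `ed`, `structure`.
#' @export
scan_transcript <- function(sequence, params = scan_params(),
                            engine = default_engine()) {
  seqn <- normalize_sequence(sequence)
  n <- nchar(seqn)
  if (n < params$window_length) {
    stop(sprintf("transcript length %d below the window length %d", n,
                 params$window_length), call. = FALSE)
  }
  if (n > MAX_TRANSCRIPT_LEN) {
    stop(sprintf("transcript length %d above the %d-nt limit", n,
                 MAX_TRANSCRIPT_LEN), call. = FALSE)
  }
  win <- sliding_windows(n, params)
  shuffle_fun <- switch(params$shuffle_kind,
                        mononucleotide = mononucleotide_shuffle,
                        dinucleotide = dinucleotide_shuffle)
  rows <- vector("list", nrow(win))
  for (k in seq_len(nrow(win))) {
    start <- win$start[k]
    end <- win$end[k]
    sub <- substr(seqn, start, end)
    native <- engine$fold(sub)
    shuf_mfe <- with_local_seed(derive_window_seed(params$seed, start), {
      vapply(seq_len(params$n_shuffles),
             function(i) engine$fold(shuffle_fun(sub))$energy, numeric(1))
    })
    mu <- mean(shuf_mfe)
    sdv <- sqrt(mean((shuf_mfe - mu)^2))
    z <- if (sdv < 1e-9) {
      warning(sprintf("window %d-%d: degenerate shuffle null; z = 0",
                      start, end), call. = FALSE)
      0
    } else {
      (native$energy - mu) / sdv
    }
    ed <- ensemble_diversity(engine$pair_probs(sub))
    rows[[k]] <- data.frame(start = start, end = end,
                            native_mfe = native$energy,
                            shuffle_mean = mu, shuffle_sd = sdv,
                            zscore = z, ed = ed,
                            structure = native$structure,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("scan_table", "data.frame")
  out
}

#' Write / read a scan table as TSV
#'
#' Tab-separated with a header line; numeric columns are written with six
#' decimals so output is byte-deterministic.
#'
#' @param scan A `scan_table` from [scan_transcript()].
#' @param path File path.
#' @return `path` invisibly (writer); a `scan_table` (reader).
#' @export
write_scan_tsv <- function(scan, path) {
  df <- as.data.frame(scan)
  for (col in c("native_mfe", "shuffle_mean", "shuffle_sd", "zscore", "ed")) {
    df[[col]] <- fmt_num(df[[col]])
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = "\t"), con)
  if (nrow(df)) {
    writeLines(do.call(paste, c(unname(as.list(df)), sep = "\t")), con)
  }
  invisible(path)
}

#' @rdname write_scan_tsv
#' @export
read_scan_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c("integer", "integer", "numeric", "numeric",
                                  "numeric", "numeric", "numeric",
                                  "character"))
  class(df) <- c("scan_table", "data.frame")
  df
}
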
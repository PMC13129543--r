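# Structural element census: decompose a dot-bracket into stems, hairpin
# loops, bulges, symmetric/asymmetric internal loops, multibranch loops and
# the exterior loop; derive hairpin records (apical loop properties,
# substructure distances), region-level percentage tables, stem GC-vs-length
# summaries and position frequency matrices for LOGO rendering.

ELEMENT_KINDS <- c("stem", "hairpin_loop", "bulge", "symmetric_internal_loop",
                   "asymmetric_internal_loop", "multibranch_loop",
                   "exterior_loop")

#' Decompose a dot-bracket into typed structural elements
#'
#' A stem is a maximal run of stacked base pairs. Every unpaired position
#' belongs to exactly one loop element: the hairpin loop of its closing
#' pair, one side of a bulge (unpaired nucleotides on one side only) or
#' internal loop (symmetric when both sides are equal, asymmetric
#' otherwise), a multibranch loop (closed by a pair enclosing two or more
#' branch pairs), or the exterior loop — which is classified separately and
#' never counted as a multibranch loop, however many top-level stems it
#' carries.
#'
#' @param structure Balanced dot-bracket string.
#' @return An object of class `element_catalog`: a list with `structure`,
#'   `length`, `ptable`, `stems` (list of 2-column pair matrices ordered
#'   outermost to innermost) and `elements` (list of element records with
#'   `kind`, `positions`, `enclosing_pair`, `enclosed_pairs` and length
#'   attributes).
#' @export
parse_elements <- function(structure) {
  pt <- pair_table(structure) # errors on unbalanced input
  n <- length(pt)
  opens <- which(pt > seq_len(max(n, 1L)))

  # stems: group pairs stacked on each other
  stem_id <- integer(n) # per opening position
  stems <- list()
  for (i in opens) {
    j <- pt[i]
    prev_stacked <- i > 1L && pt[i - 1L] == j + 1L
    if (prev_stacked) {
      stem_id[i] <- stem_id[i - 1L]
      stems[[stem_id[i]]] <- rbind(stems[[stem_id[i]]], c(i, j))
    } else {
      stems[[length(stems) + 1L]] <- matrix(c(i, j), ncol = 2)
      stem_id[i] <- length(stems)
    }
  }

  children_of <- function(i, j) {
    out <- NULL
    k <- i + 1L
    unp <- integer(0)
    while (k < j) {
      if (pt[k] > k) {
        out <- rbind(out, c(k, pt[k]))
        k <- pt[k] + 1L
      } else {
        unp <- c(unp, k)
        k <- k + 1L
      }
    }
    list(branches = out, unpaired = unp)
  }

  elements <- list()
  add <- function(rec) elements[[length(elements) + 1L]] <<- rec

  for (s in seq_along(stems)) {
    mat <- stems[[s]]
    colnames(mat) <- c("i", "j")
    add(list(kind = "stem",
             positions = sort(c(mat[, 1], mat[, 2])),
             enclosing_pair = mat[1, ],
             enclosed_pairs = mat,
             stem_bp = nrow(mat)))
  }

  for (i in opens) {
    j <- pt[i]
    ch <- children_of(i, j)
    nb <- NROW(ch$branches)
    if (nb == 0L) {
      add(list(kind = "hairpin_loop", positions = ch$unpaired,
               enclosing_pair = c(i, j), enclosed_pairs = NULL,
               loop_len = length(ch$unpaired)))
    } else if (nb == 1L) {
      k <- ch$branches[1, 1]; l <- ch$branches[1, 2]
      side5 <- k - i - 1L
      side3 <- j - l - 1L
      if (side5 == 0L && side3 == 0L) next # stacked pair, part of a stem
      kind <- if (side5 == 0L || side3 == 0L) {
        "bulge"
      } else if (side5 == side3) {
        "symmetric_internal_loop"
      } else {
        "asymmetric_internal_loop"
      }
      add(list(kind = kind, positions = ch$unpaired,
               enclosing_pair = c(i, j), enclosed_pairs = ch$branches,
               side5 = side5, side3 = side3))
    } else {
      add(list(kind = "multibranch_loop", positions = ch$unpaired,
               enclosing_pair = c(i, j), enclosed_pairs = ch$branches,
               n_branches = nb, loop_len = length(ch$unpaired)))
    }
  }

  # exterior loop: depth-zero unpaired positions and top-level branches
  ext_branches <- NULL
  ext_unpaired <- integer(0)
  k <- 1L
  while (k <= n) {
    if (pt[k] > k) {
      ext_branches <- rbind(ext_branches, c(k, pt[k]))
      k <- pt[k] + 1L
    } else {
      ext_unpaired <- c(ext_unpaired, k)
      k <- k + 1L
    }
  }
  add(list(kind = "exterior_loop", positions = ext_unpaired,
           enclosing_pair = NULL, enclosed_pairs = ext_branches,
           loop_len = length(ext_unpaired)))

  structure(list(structure = structure, length = n, ptable = pt,
                 stems = stems, elements = elements),
            class = "element_catalog")
}

#' Summarize an element catalog as a data.frame
#'
#' @param x An `element_catalog`.
#' @param ... Unused.
#' @return One row per element: `kind`, `start`, `end`, `n_positions`,
#'   plus kind-specific lengths (`stem_bp`, `loop_len`, `side5`, `side3`).
#' @method as.data.frame element_catalog
#' @export
as.data.frame.element_catalog <- function(x, ...) {
  rows <- lapply(x$elements, function(e) {
    all_pos <- c(e$positions, e$enclosing_pair, e$enclosed_pairs)
    span <- if (length(all_pos)) range(all_pos) else c(NA_integer_, NA_integer_)
    data.frame(kind = e$kind,
               start = if (is.finite(span[1])) span[1] else NA_integer_,
               end = if (is.finite(span[2])) span[2] else NA_integer_,
               n_positions = length(e$positions),
               stem_bp = e$stem_bp %||% NA_integer_,
               loop_len = e$loop_len %||% NA_integer_,
               side5 = e$side5 %||% NA_integer_,
               side3 = e$side3 %||% NA_integer_)
  })
  do.call(rbind, rows)
}

#' Rebuild the dot-bracket from an element catalog
#'
#' Inverse of [parse_elements()]: reconstructs the structure from the stem
#' pair sets alone.
#'
#' @param catalog An `element_catalog`.
#' @return Dot-bracket string.
#' @export
rebuild_structure <- function(catalog) {
  pairs <- do.call(rbind, catalog$stems)
  pairs_to_db(pairs %||% matrix(integer(0), ncol = 2), catalog$length)
}

#' Classify hairpin systems
#'
#' One record per hairpin loop: the helix system is walked from the
#' apical-loop-closing pair outward through any bulges and internal loops
#' until it reaches a multibranch loop or the exterior loop. A system is
#' `fully_paired` when no bulge or internal loop interrupts it.
#' Substructure distances are measured in stacked base pairs: the number of
#' base pairs strictly between the apical-loop-closing pair and the
#' feature's apical-side boundary pair (a bulge directly under the closing
#' pair of a 3-bp apical stem is at distance 2).
#'
#' @param catalog An `element_catalog`.
#' @param sequence The nucleotide sequence the structure belongs to.
#' @return A data.frame of class `hairpin_records` with columns
#'   `apical_i`, `apical_j`, `stem_length` (total bp in the system),
#'   `apical_loop_length`, `apical_loop_sequence`, `fully_paired`,
#'   `gc_fraction`, and a list-column `substructures` of data.frames
#'   (`kind`, `distance`).
#' @export
classify_hairpins <- function(catalog, sequence) {
  seqn <- strsplit(normalize_sequence(sequence), "", fixed = TRUE)[[1]]
  if (length(seqn) != catalog$length) {
    stop("sequence and catalog lengths differ", call. = FALSE)
  }
  # index: opening position -> stem number; pair -> parent loop element
  stem_of <- integer(catalog$length)
  for (s in seq_along(catalog$stems)) stem_of[catalog$stems[[s]][, 1]] <- s
  parent_of <- list() # keyed by opening position of a branch pair
  for (e in catalog$elements) {
    if (e$kind %in% c("bulge", "symmetric_internal_loop",
                      "asymmetric_internal_loop", "multibranch_loop",
                      "exterior_loop") && !is.null(e$enclosed_pairs)) {
      for (r in seq_len(nrow(e$enclosed_pairs))) {
        parent_of[[as.character(e$enclosed_pairs[r, 1])]] <- e
      }
    }
  }

  hp <- Filter(function(e) e$kind == "hairpin_loop", catalog$elements)
  recs <- lapply(hp, function(h) {
    ci <- h$enclosing_pair[1]; cj <- h$enclosing_pair[2]
    bp_total <- 0L
    subs <- data.frame(kind = character(0), distance = integer(0))
    stem_positions <- integer(0)
    s <- stem_of[ci] # apical stem (its innermost pair closes the loop)
    repeat {
      mat <- catalog$stems[[s]]
      bp_total <- bp_total + nrow(mat)
      stem_positions <- c(stem_positions, mat[, 1], mat[, 2])
      outer <- mat[1, ] # outermost pair of this stem
      par <- parent_of[[as.character(outer[1])]]
      if (is.null(par) ||
          par$kind %in% c("multibranch_loop", "exterior_loop")) break
      # bulge or internal loop: record and continue outward
      subs <- rbind(subs, data.frame(kind = par$kind,
                                     distance = bp_total - 1L))
      s <- stem_of[par$enclosing_pair[1]]
    }
    gc <- mean(seqn[stem_positions] %in% c("G", "C"))
    data.frame(apical_i = ci, apical_j = cj, stem_length = bp_total,
               apical_loop_length = h$loop_len,
               apical_loop_sequence = paste(seqn[h$positions],
                                            collapse = ""),
               fully_paired = nrow(subs) == 0L,
               gc_fraction = gc,
               substructures = I(list(subs)),
               stringsAsFactors = FALSE)
  })
  out <- if (length(recs)) do.call(rbind, recs) else {
    data.frame(apical_i = integer(0), apical_j = integer(0),
               stem_length = integer(0), apical_loop_length = integer(0),
               apical_loop_sequence = character(0),
               fully_paired = logical(0), gc_fraction = numeric(0),
               substructures = I(list()))
  }
  class(out) <- c("hairpin_records", "data.frame")
  out
}

#' Distance from the apical loop to the nearest substructure
#'
#' @param record One row of a `hairpin_records` table (or a list with a
#'   `substructures` data.frame).
#' @return A list with `distance` (stacked base pairs) and `kind`, or
#'   `NULL` for a fully paired hairpin. Multiple substructures return the
#'   minimum distance with the closer feature's kind.
#' @export
nearest_feature_distance <- function(record) {
  subs <- if (is.data.frame(record)) record$substructures[[1]]
          else record$substructures
  if (is.null(subs) || nrow(subs) == 0L) return(NULL)
  best <- which.min(subs$distance)
  list(distance = subs$distance[best], kind = subs$kind[best])
}

#' Percentage tables of structural categories per transcript region
#'
#' `unit = "motif"` (default): the counting unit is one motif (dictionary
#' entry); a motif counts once towards every category it contains at least
#' one element of, and percentages are of the total motifs in the region.
#' `unit = "element"`: percentages are of element occurrences, so rows over
#' a mutually exclusive category set sum to 100.
#'
#' @param elements A data.frame with columns `region`, `kind` and
#'   `motif_id`.
#' @param unit Counting unit (see above).
#' @param kinds Category columns to report (default all element kinds).
#' @return A data.frame: one row per region, one column per category, plus
#'   `n` (total counting units). Empty regions are omitted with a message.
#' @export
tally_by_region <- function(elements, unit = c("motif", "element"),
                            kinds = ELEMENT_KINDS) {
  unit <- match.arg(unit)
  stopifnot(all(c("region", "kind", "motif_id") %in% names(elements)))
  regions <- sort(unique(elements$region))
  empty <- setdiff(MOTIF_REGIONS[MOTIF_REGIONS != "multi_region"], regions)
  if (length(empty)) {
    message("regions with no structures omitted: ",
            paste(empty, collapse = ", "))
  }
  rows <- lapply(regions, function(rg) {
    sub <- elements[elements$region == rg, , drop = FALSE]
    if (unit == "motif") {
      total <- length(unique(sub$motif_id))
      pct <- vapply(kinds, function(k) {
        100 * length(unique(sub$motif_id[sub$kind == k])) / total
      }, numeric(1))
    } else {
      total <- nrow(sub)
      pct <- vapply(kinds, function(k) {
        100 * sum(sub$kind == k) / total
      }, numeric(1))
    }
    cbind(data.frame(region = rg, n = total), as.data.frame(as.list(pct)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stem GC content by stem length
#'
#' GC fraction of a stem is `(#G + #C) / (2 * stem_length)` over both
#' strands.
#'
#' @param stems A data.frame with columns `length_bp` and `gc_fraction`
#'   (one row per stem), e.g. from [stem_table()].
#' @return A data.frame `length_bp`, `count`, `mean_gc` ordered by length.
#' @export
stem_gc_by_length <- function(stems) {
  agg <- split(stems$gc_fraction, stems$length_bp)
  out <- data.frame(length_bp = as.integer(names(agg)),
                    count = vapply(agg, length, integer(1)),
                    mean_gc = vapply(agg, mean, numeric(1)))
  out <- out[order(out$length_bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stem records of a structure
#'
#' @param catalog An `element_catalog`.
#' @param sequence Matching nucleotide sequence.
#' @return A data.frame with one row per stem: `start`, `end`,
#'   `length_bp`, `gc_fraction`.
#' @export
stem_table <- function(catalog, sequence) {
  seqn <- strsplit(normalize_sequence(sequence), "", fixed = TRUE)[[1]]
  rows <- lapply(catalog$stems, function(mat) {
    nts <- seqn[c(mat[, 1], mat[, 2])]
    data.frame(start = min(mat), end = max(mat), length_bp = nrow(mat),
               gc_fraction = mean(nts %in% c("G", "C")))
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(start = integer(0), end = integer(0), length_bp = integer(0),
               gc_fraction = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Position frequency matrix with information content
#'
#' Counts per position over equal-length sequences, and per-position
#' information content in bits: `IC = 2 - H`, with `H` the Shannon entropy
#' of the column's base frequencies. No pseudocounts.
#'
#' @param sequences Character vector of equal-length nucleotide strings.
#' @return A list of class `position_frequency_matrix` with `counts`
#'   (length x 4 matrix, columns A/C/G/U) and `information_content`
#'   (bits per position).
#' @export
position_frequency_matrix <- function(sequences) {
  if (!length(sequences)) stop("need at least one sequence", call. = FALSE)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    stop("sequences must all have the same length", call. = FALSE)
  }
  L <- lens[1]
  mat <- matrix(0L, nrow = L, ncol = 4,
                dimnames = list(NULL, RNA_BASES))
  for (s in sequences) {
    chars <- strsplit(normalize_sequence(s), "", fixed = TRUE)[[1]]
    for (p in seq_len(L)) {
      mat[p, chars[p]] <- mat[p, chars[p]] + 1L
    }
  }
  freq <- mat / length(sequences)
  H <- apply(freq, 1, function(f) {
    f <- f[f > 0]
    -sum(f * log2(f))
  })
  structure(list(counts = mat, information_content = 2 - H),
            class = "position_frequency_matrix")
}

#' Write a position frequency matrix as plain text
#'
#' A tab-separated matrix with a header (`pos`, `A`, `C`, `G`, `U`, `IC`),
#' consumable by standard logo-rendering tools.
#'
#' @param pfm A `position_frequency_matrix`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(pfm, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("pos\tA\tC\tG\tU\tIC", con)
  for (p in seq_len(nrow(pfm$counts))) {
    writeLines(paste(c(p, pfm$counts[p, ],
                       fmt_num(pfm$information_content[p], 4L)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Element census of a motif dictionary
#'
#' Convenience wrapper: parses every motif structure (core span, flanks
#' excluded) and returns one row per element with the motif's region label
#' attached, ready for [tally_by_region()]. Unbalanced motif structures
#' raise the parser's structured error.
#'
#' @param motifs A `motif_table` with a `region` column.
#' @return A data.frame with columns `motif_id`, `region`, `kind` and the
#'   element length attributes.
#' @export
census_motifs <- function(motifs) {
  rows <- lapply(seq_len(nrow(motifs)), function(k) {
    core <- substr(motifs$structure[k],
                   motifs$core_start[k] - motifs$start[k] + 1L,
                   motifs$core_end[k] - motifs$start[k] + 1L)
    cat <- parse_elements(core)
    df <- as.data.frame(cat)
    df$motif_id <- k
    df$region <- motifs$region[k]
    df
  })
  do.call(rbind, rows)
}
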
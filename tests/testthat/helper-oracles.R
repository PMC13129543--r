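# Independent oracles used to validate the package implementations. These
# deliberately re-derive results by different algorithms (brute force,
# direct counting, O(n^2) scans) and never call the code paths they check.

# 16-bin dinucleotide count map
oracle_dinuc_counts <- function(sequence) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  di <- paste0(ch[-length(ch)], ch[-1])
  bins <- as.vector(outer(c("A", "C", "G", "U"), c("A", "C", "G", "U"),
                          paste0))
  vapply(bins, function(b) sum(di == b), integer(1))
}

# independent recursive count of legal pair sets (no enumeration)
oracle_count_structures <- function(sequence, minhp = 3L) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  can <- function(a, b) paste0(ch[a], ch[b]) %in%
    c("AU", "UA", "CG", "GC", "GU", "UG")
  n <- length(ch)
  memo <- new.env(parent = emptyenv())
  cnt <- function(i, j) {
    if (j - i < minhp + 1L) return(1)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    total <- cnt(i + 1L, j)
    for (k in (i + minhp + 1L):j) {
      if (can(i, k)) total <- total + cnt(i + 1L, k - 1L) * cnt(k + 1L, j)
    }
    memo[[key]] <- total
    total
  }
  cnt(1L, n)
}

# expected symmetric-difference distance between two independent ensemble
# draws, by explicit double summation over the enumerated ensemble
oracle_ensemble_diversity <- function(sequence, model) {
  enum <- enumerate_all_structures(sequence, model)
  rt <- 0.0019872 * model$temperature
  w <- exp(-enum$energy / rt)
  w[!is.finite(enum$energy)] <- 0
  w <- w / sum(w)
  pair_sets <- lapply(enum$structure, function(db) {
    p <- db_pairs(db)
    if (nrow(p)) paste(p[, 1], p[, 2]) else character(0)
  })
  ed <- 0
  for (a in seq_along(pair_sets)) {
    for (b in seq_along(pair_sets)) {
      d <- length(setdiff(pair_sets[[a]], pair_sets[[b]])) +
        length(setdiff(pair_sets[[b]], pair_sets[[a]]))
      ed <- ed + w[a] * w[b] * d
    }
  }
  ed
}

# per-pair Boltzmann probabilities by enumeration
oracle_pair_probs <- function(sequence, model) {
  enum <- enumerate_all_structures(sequence, model)
  rt <- 0.0019872 * model$temperature
  w <- exp(-enum$energy / rt)
  w[!is.finite(enum$energy)] <- 0
  n <- nchar(sequence)
  P <- matrix(0, n, n)
  for (k in seq_len(nrow(enum))) {
    if (w[k] == 0) next
    prs <- db_pairs(enum$structure[k])
    if (nrow(prs)) {
      P[prs] <- P[prs] + w[k]
    }
  }
  list(prob = P / sum(w), logZ = log(sum(w)))
}

# depth-zero splitting of a dot-bracket into maximal depth-positive
# intervals, by cumulative sums (independent of the bond-order walk)
oracle_submotif_spans <- function(structure) {
  ch <- strsplit(structure, "", fixed = TRUE)[[1]]
  delta <- (ch == "(") - (ch == ")")
  depth_after <- cumsum(delta)
  inside <- depth_after > 0 | (ch == ")" & depth_after == 0)
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

# independent O(n^2) structural element parser
ref_parse_elements <- function(structure) {
  pt <- pair_table(structure)
  n <- length(pt)
  pairs <- which(pt > seq_len(max(n, 1L)))
  key <- function(i, j) paste(i, j)
  pair_set <- new.env(parent = emptyenv())
  for (i in pairs) assign(key(i, pt[i]), TRUE, envir = pair_set)
  has_pair <- function(i, j) {
    i >= 1L && j <= n && !is.null(pair_set[[key(i, j)]])
  }

  # stems: a pair starts a stem iff it is not stacked on an outer pair
  stems <- list()
  for (i in pairs) {
    if (!has_pair(i - 1L, pt[i] + 1L)) {
      run <- NULL
      a <- i; b <- pt[i]
      while (has_pair(a, b)) {
        run <- rbind(run, c(a, b))
        a <- a + 1L; b <- b - 1L
      }
      stems[[length(stems) + 1L]] <- run
    }
  }

  # direct children of a pair: enclosed pairs with no intermediate enclosure
  children <- function(i, j) {
    out <- NULL
    for (c1 in pairs) {
      d1 <- pt[c1]
      if (!(i < c1 && d1 < j)) next
      direct <- TRUE
      for (m in pairs) {
        if (m == c1) next
        if (i < m && m < c1 && d1 < pt[m] && pt[m] < j) {
          direct <- FALSE
          break
        }
      }
      if (direct) out <- rbind(out, c(c1, d1))
    }
    out
  }

  loops <- list()
  for (i in pairs) {
    j <- pt[i]
    ch_ <- children(i, j)
    nb <- NROW(ch_)
    unp <- setdiff((i + 1L):(j - 1L),
                   unlist(lapply(seq_len(nb), function(r) {
                     ch_[r, 1]:ch_[r, 2]
                   })))
    if (j - i == 1L) unp <- integer(0)
    if (nb == 0L) {
      loops[[length(loops) + 1L]] <-
        list(kind = "hairpin_loop", closing = c(i, j), positions = unp)
    } else if (nb == 1L) {
      s5 <- ch_[1, 1] - i - 1L
      s3 <- j - ch_[1, 2] - 1L
      if (s5 + s3 == 0L) next
      kind <- if (s5 == 0L || s3 == 0L) "bulge"
              else if (s5 == s3) "symmetric_internal_loop"
              else "asymmetric_internal_loop"
      loops[[length(loops) + 1L]] <-
        list(kind = kind, closing = c(i, j), positions = unp)
    } else {
      loops[[length(loops) + 1L]] <-
        list(kind = "multibranch_loop", closing = c(i, j), positions = unp)
    }
  }
  top_unp <- which(pt == 0L)
  for (i in pairs) top_unp <- setdiff(top_unp, i:pt[i])
  loops[[length(loops) + 1L]] <-
    list(kind = "exterior_loop", closing = NULL, positions = top_unp)
  list(stems = stems, loops = loops)
}

# canonical string fingerprints for comparing two element decompositions
element_fingerprint <- function(stems, loops) {
  s <- vapply(stems, function(m) paste(t(m), collapse = ","), character(1))
  l <- vapply(loops, function(e) {
    paste(e$kind, paste(e$closing, collapse = ","),
          paste(sort(e$positions), collapse = ","), sep = "|")
  }, character(1))
  sort(c(paste0("S:", s), paste0("L:", l)))
}

catalog_fingerprint <- function(catalog) {
  loops <- Filter(function(e) e$kind != "stem", catalog$elements)
  loops <- lapply(loops, function(e) {
    list(kind = e$kind, closing = e$enclosing_pair, positions = e$positions)
  })
  element_fingerprint(catalog$stems, loops)
}

# exhaustive consensus oracle: mutual-best filtering, then the
# maximum-|znorm| non-crossing subset by full subset enumeration
oracle_consensus_pairs <- function(evidence) {
  ev <- as.data.frame(evidence)
  tol <- 1e-9
  best <- list()
  ambiguous <- character(0)
  for (p in sort(unique(c(ev$i, ev$j)))) {
    rows <- which(ev$i == p | ev$j == p)
    vals <- ev$znorm[rows]
    hits <- rows[vals <= min(vals) + tol]
    if (length(hits) > 1L) ambiguous <- c(ambiguous, as.character(p))
    else best[[as.character(p)]] <- ifelse(ev$i[hits] == p, ev$j[hits],
                                           ev$i[hits])
  }
  ok <- vapply(seq_len(nrow(ev)), function(r) {
    i <- as.character(ev$i[r]); j <- as.character(ev$j[r])
    !(i %in% ambiguous) && !(j %in% ambiguous) &&
      !is.null(best[[i]]) && !is.null(best[[j]]) &&
      best[[i]] == ev$j[r] && best[[j]] == ev$i[r]
  }, logical(1))
  cand <- ev[ok, , drop = FALSE]
  m <- nrow(cand)
  if (m == 0L) return(cand)
  stopifnot(m <= 12L) # subset enumeration guard
  crossing <- function(a, b) {
    i <- cand$i[a]; j <- cand$j[a]; k <- cand$i[b]; l <- cand$j[b]
    (i < k && k < j && j < l) || (k < i && i < l && l < j)
  }
  best_mass <- -Inf
  best_sub <- integer(0)
  for (mask in 0:(2^m - 1L)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0)
    feasible <- TRUE
    if (length(sel) > 1L) {
      for (a in seq_along(sel)[-1]) {
        for (b in seq_len(a - 1L)) {
          if (crossing(sel[a], sel[b])) {
            feasible <- FALSE
            break
          }
        }
        if (!feasible) break
      }
    }
    if (!feasible) next
    mass <- sum(abs(cand$znorm[sel]))
    if (mass > best_mass + 1e-12) {
      best_mass <- mass
      best_sub <- sel
    }
  }
  out <- cand[best_sub, , drop = FALSE]
  out[order(out$i), , drop = FALSE]
}

# build a scan_table by hand from (start, zscore, structure) rows
fake_scan <- function(starts, zscores, structures,
                      window_length = nchar(structures[1])) {
  data.frame(start = starts, end = starts + window_length - 1L,
             native_mfe = -10, shuffle_mean = -5, shuffle_sd = 2,
             zscore = zscores, ed = 1, structure = structures,
             stringsAsFactors = FALSE)
}
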
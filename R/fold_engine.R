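# Folding engine: user-facing wrappers around the compiled
# dynamic-programming core, the exhaustive enumeration oracle, and the
# pluggable engine interface consumed by the scanner.

unpack_model <- function(model) {
  validate_energy_model(model)
  list(stack = model$stack_energies,
       hp = model$hairpin_penalty,
       bu = model$bulge_penalty,
       il = model$internal_penalty,
       coef = model$loop_log_coef,
       ml = unname(model$multiloop_affine),
       minhp = as.integer(model$min_hairpin_loop),
       maxspan = as.integer(model$max_internal_span),
       rt = model_rt(model))
}

#' Minimum free energy structure of an RNA sequence
#'
#' Computes the minimum-free-energy secondary structure under the
#' nearest-neighbour model by dynamic programming. DNA input is accepted
#' and transcribed (`T` to `U`); any other non-nucleotide character is an
#' error reporting its position. Ties between equal-energy structures are
#' broken deterministically in favour of pairs with the smaller 5' index
#' during traceback.
#'
#' @param sequence Nucleotide string (RNA or DNA alphabet).
#' @param model An `energy_model`; defaults to [default_energy_model()].
#' @return A list of class `fold_result` with elements `structure`
#'   (dot-bracket) and `energy` (kcal/mol). A sequence that admits no legal
#'   pair returns the open chain at energy 0.
#' @export
#' @examples
#' mfe_fold("GGGGAAAACCCC")
mfe_fold <- function(sequence, model = default_energy_model()) {
  s <- seq_to_int(sequence)
  p <- unpack_model(model)
  res <- c_mfe_fold(s, p$stack, p$hp, p$bu, p$il, p$coef, p$ml,
                    p$minhp, p$maxspan)
  out <- list(structure = res$structure, energy = res$energy)
  class(out) <- "fold_result"
  out
}

#' Partition function and base-pair probabilities
#'
#' McCaskill-style inside-outside computation over the same model as
#' [mfe_fold()]: `p(i,j)` is the Boltzmann-weighted fraction of all legal
#' structures that contain pair `(i,j)` at the model temperature.
#'
#' @inheritParams mfe_fold
#' @return A list of class `pair_prob_matrix` with `probabilities` (an
#'   `n x n` upper-triangular matrix) and `log_partition` (log of the
#'   partition function; 0 when only the open chain exists).
#' @export
partition_function <- function(sequence, model = default_energy_model()) {
  s <- seq_to_int(sequence)
  p <- unpack_model(model)
  res <- c_partition(s, p$stack, p$hp, p$bu, p$il, p$coef, p$ml,
                     p$minhp, p$maxspan, p$rt)
  out <- list(probabilities = res$prob, log_partition = res$log_partition)
  class(out) <- "pair_prob_matrix"
  out
}

#' Ensemble diversity of a base-pair probability matrix
#'
#' `ED = 2 * sum_{i<j} p(i,j) * (1 - p(i,j))`, the expected base-pair
#' (symmetric-difference) distance between two independent draws from the
#' Boltzmann ensemble. Low values indicate a single dominant conformation.
#'
#' @param probs A `pair_prob_matrix` from [partition_function()], or a bare
#'   upper-triangular probability matrix.
#' @return A single non-negative number.
#' @export
ensemble_diversity <- function(probs) {
  p <- if (inherits(probs, "pair_prob_matrix")) probs$probabilities else probs
  stopifnot(is.matrix(p))
  up <- p[upper.tri(p)]
  if (any(up < -1e-12 | up > 1 + 1e-12)) {
    stop("pair probabilities must lie in [0, 1]", call. = FALSE)
  }
  2 * sum(up * (1 - up))
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$structure, "\n", sprintf("energy: %.2f kcal/mol", x$energy), "\n",
      sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Exhaustive enumeration (test oracle, exponential time)

#' Enumerate every legal secondary structure of a short sequence
#'
#' Generates every pseudoknot-free structure satisfying the pairing alphabet
#' and minimum-hairpin-loop constraints, with its model energy. Exponential
#' in sequence length; refused above `max_length`. This is the brute-force
#' oracle used to validate the dynamic-programming engine, and is kept
#' deliberately independent of it: energies come from [structure_energy()].
#'
#' @inheritParams mfe_fold
#' @param max_length Combinatorial guard (default 22).
#' @return A data.frame with columns `structure` and `energy`; structures
#'   whose energy is infinite under the model (internal loops beyond the
#'   span cap) are retained with `energy = Inf`.
#' @export
enumerate_all_structures <- function(sequence, model = default_energy_model(),
                                     max_length = 22L) {
  s <- seq_to_int(sequence)
  n <- length(s)
  if (n > max_length) {
    stop(sprintf("length %d exceeds the enumeration guard (%d)", n,
                 max_length), call. = FALSE)
  }
  minhp <- model$min_hairpin_loop
  can <- function(a, b) !is.na(pair_type(RNA_BASES[a + 1], RNA_BASES[b + 1]))

  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i > j) return(list(NULL))
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- lapply(rec(i + 1L, j), identity) # i unpaired
    ks <- seq_len(j)
    ks <- ks[ks >= i + minhp + 1L]
    for (k in ks) {
      if (!can(s[i], s[k])) next
      inner <- rec(i + 1L, k - 1L)
      outer <- rec(k + 1L, j)
      for (L in inner) for (R in outer) {
        out[[length(out) + 1L]] <- rbind(c(i, k), L, R)
      }
    }
    memo[[key]] <- out
    out
  }
  structs <- if (n == 0L) list(NULL) else rec(1L, n)
  db <- vapply(structs, pairs_to_db, character(1), length = n)
  seqn <- normalize_sequence(sequence)
  en <- vapply(db, function(d) structure_energy(seqn, d, model), numeric(1),
               USE.NAMES = FALSE)
  data.frame(structure = db, energy = en, stringsAsFactors = FALSE)
}

#' Loop-decomposition energy of a given structure
#'
#' Scores a (sequence, dot-bracket) pair by direct loop decomposition under
#' the model: hairpin/bulge/internal initiation penalties, stacking terms,
#' and the affine multibranch cost. Independent of the dynamic-programming
#' engine, which makes it usable as an oracle against it. Structures
#' containing an internal loop above the model's span cap score `Inf`
#' (disallowed); a hairpin loop below the minimum loop length is an error.
#'
#' @inheritParams mfe_fold
#' @param structure Dot-bracket string of the same length as `sequence`.
#' @return Energy in kcal/mol (possibly `Inf`).
#' @export
structure_energy <- function(sequence, structure,
                             model = default_energy_model()) {
  seqn <- normalize_sequence(sequence)
  chars <- strsplit(seqn, "", fixed = TRUE)[[1]]
  pt <- pair_table(structure)
  if (length(pt) != length(chars)) {
    stop("sequence and structure lengths differ", call. = FALSE)
  }
  ml <- model$multiloop_affine
  energy <- 0
  opens <- which(pt > seq_along(pt))
  for (i in opens) {
    j <- pt[i]
    ptype_out <- pair_type(chars[i], chars[j])
    if (is.na(ptype_out)) {
      stop(sprintf("pair (%d,%d) joins non-complementary bases %s-%s",
                   i, j, chars[i], chars[j]), call. = FALSE)
    }
    # children: pairs directly enclosed by (i,j)
    children <- matrix(integer(0), ncol = 2)
    unpaired <- 0L
    k <- i + 1L
    while (k < j) {
      if (pt[k] > k) {
        children <- rbind(children, c(k, pt[k]))
        k <- pt[k] + 1L
      } else {
        unpaired <- unpaired + 1L
        k <- k + 1L
      }
    }
    nb <- nrow(children)
    if (nb == 0L) {
      len <- j - i - 1L
      if (len < model$min_hairpin_loop) {
        stop(sprintf("hairpin loop closed by (%d,%d) shorter than %d nt",
                     i, j, model$min_hairpin_loop), call. = FALSE)
      }
      energy <- energy + loop_energy(model$hairpin_penalty, len,
                                     model$loop_log_coef)
    } else if (nb == 1L) {
      k <- children[1, 1]; l <- children[1, 2]
      l1 <- k - i - 1L
      l2 <- j - l - 1L
      ptype_in <- pair_type(chars[k], chars[l])
      if (l1 == 0L && l2 == 0L) {
        energy <- energy + model$stack_energies[ptype_out, ptype_in]
      } else if (l1 + l2 > model$max_internal_span) {
        return(Inf)
      } else if (l1 == 0L || l2 == 0L) {
        energy <- energy + loop_energy(model$bulge_penalty, l1 + l2,
                                       model$loop_log_coef)
      } else {
        energy <- energy + loop_energy(model$internal_penalty, l1 + l2,
                                       model$loop_log_coef)
      }
    } else {
      energy <- energy + ml[["close"]] + ml[["branch"]] * (nb + 1L) +
        ml[["unpaired"]] * unpaired
    }
  }
  energy
}

# ---------------------------------------------------------------------------
# Pluggable engine interface

#' Construct the default folding engine
#'
#' An engine bundles the callables the scanner and downstream modules need:
#' `fold(sequence)` returning a `fold_result`, and `pair_probs(sequence)`
#' returning a `pair_prob_matrix`. The default engine closes over the
#' built-in dynamic-programming core and an energy model.
#'
#' @param model Energy model used by all calls.
#' @return An object of class `fold_engine`.
#' @export
default_engine <- function(model = default_energy_model()) {
  structure(list(
    fold = function(sequence) mfe_fold(sequence, model),
    pair_probs = function(sequence) partition_function(sequence, model),
    model = model,
    name = "nearest-neighbour DP"
  ), class = "fold_engine")
}

#' Adapter engine delegating to an external RNAfold binary
#'
#' Optional convenience for users who want production Turner-model energies:
#' delegates folding to an installed `RNAfold` executable (ViennaRNA).
#' Ensemble quantities still come from the built-in partition function, so
#' the adapter only replaces the MFE call. No part of the package requires
#' this adapter; it exists because window structures and energies are the
#' only engine products the scan statistics consume.
#'
#' @param binary Path to the `RNAfold` executable.
#' @param model Model used for the partition-function side of the engine.
#' @return A `fold_engine`.
#' @export
rnafold_engine <- function(binary = "RNAfold",
                           model = default_energy_model()) {
  if (!nzchar(Sys.which(binary))) {
    stop("RNAfold binary not found: ", binary, call. = FALSE)
  }
  fold <- function(sequence) {
    seqn <- normalize_sequence(sequence)
    out <- system2(binary, args = c("--noPS"), input = seqn, stdout = TRUE)
    line <- out[2]
    m <- regmatches(line, regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)", line))[[1]]
    if (length(m) != 3) stop("unparseable RNAfold output: ", line,
                             call. = FALSE)
    structure(list(structure = m[2], energy = as.numeric(m[3])),
              class = "fold_result")
  }
  structure(list(
    fold = fold,
    pair_probs = function(sequence) partition_function(sequence, model),
    model = model,
    name = paste0("RNAfold adapter (", binary, ")")
  ), class = "fold_engine")
}
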
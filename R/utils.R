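# Shared low-level helpers: alphabet handling, dot-bracket primitives,
# deterministic per-window seeding.

RNA_BASES <- c("A", "C", "G", "U")

# gas constant in kcal/(mol*K); shared with the C++ engine
RGAS <- 0.0019872

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a nucleotide sequence to the RNA alphabet
#'
#' Uppercases the input and transcribes `T` to `U`. Any character outside
#' `A`, `C`, `G`, `U` after normalization is an error reporting the
#' 1-based position of the first offending symbol.
#'
#' @param sequence A single character string.
#' @return Normalized sequence string over `A/C/G/U`.
#' @export
normalize_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- chartr("t", "u", toupper(sequence))
  s <- chartr("T", "U", s)
  bad <- regexpr("[^ACGU]", s)
  if (bad > 0L) {
    stop(sprintf("non-nucleotide character '%s' at position %d",
                 substr(s, bad, bad), bad), call. = FALSE)
  }
  s
}

# sequence string -> 0-based integer codes (A=0, C=1, G=2, U=3)
seq_to_int <- function(sequence) {
  s <- normalize_sequence(sequence)
  match(strsplit(s, "", fixed = TRUE)[[1]], RNA_BASES) - 1L
}

#' Base-pair table of a dot-bracket string
#'
#' @param structure Dot-bracket string using `(`, `)`, `.`.
#' @return Integer vector `p` with `p[i]` the partner of position `i`
#'   (0 when unpaired).
#' @export
pair_table <- function(structure) {
  chars <- strsplit(structure, "", fixed = TRUE)[[1]]
  if (length(chars) && !all(chars %in% c("(", ")", "."))) {
    bad <- which(!chars %in% c("(", ")", "."))[1]
    stop(sprintf("invalid structure character '%s' at position %d",
                 chars[bad], bad), call. = FALSE)
  }
  n <- length(chars)
  pt <- integer(n)
  stack <- integer(0)
  for (k in seq_len(n)) {
    if (chars[k] == "(") {
      stack <- c(stack, k)
    } else if (chars[k] == ")") {
      if (!length(stack)) {
        stop(sprintf("unbalanced structure: unmatched ')' at position %d", k),
             call. = FALSE)
      }
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- k
      pt[k] <- i
    }
  }
  if (length(stack)) {
    stop(sprintf("unbalanced structure: unmatched '(' at position %d",
                 stack[1]), call. = FALSE)
  }
  pt
}

# pair table -> 2-column matrix of pairs (i < j), ordered by i
pairs_from_table <- function(pt) {
  i <- which(pt > seq_along(pt))
  cbind(i = i, j = pt[i])
}

#' Base pairs of a dot-bracket string
#'
#' @inheritParams pair_table
#' @return Two-column integer matrix of pairs `(i, j)` with `i < j`.
#' @export
db_pairs <- function(structure) pairs_from_table(pair_table(structure))

# pairs (2-col matrix, 1-based) -> dot-bracket of given length
pairs_to_db <- function(pairs, length) {
  chars <- rep(".", length)
  if (NROW(pairs)) {
    chars[pairs[, 1]] <- "("
    chars[pairs[, 2]] <- ")"
  }
  paste(chars, collapse = "")
}

# TRUE when no two pairs cross: forbids i < k < j < l
pairs_noncrossing <- function(pairs) {
  m <- NROW(pairs)
  if (m < 2L) return(TRUE)
  for (a in seq_len(m - 1L)) {
    for (b in (a + 1L):m) {
      i <- pairs[a, 1]; j <- pairs[a, 2]
      k <- pairs[b, 1]; l <- pairs[b, 2]
      if ((i < k && k < j && j < l) || (k < i && i < l && l < j)) return(FALSE)
    }
  }
  TRUE
}

# Deterministic per-window seed below 2^31, derived from the master seed
# and the window start so scans are order-independent.
derive_window_seed <- function(seed, start) {
  as.integer((abs(as.numeric(seed)) * 69069 + as.numeric(start) * 101) %%
               2147483629) + 1L
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# fixed-format numeric rendering for byte-deterministic writers
fmt_num <- function(x, digits = 6L) {
  out <- sprintf(paste0("%.", digits, "f"), x)
  out[is.na(x)] <- "NA"
  out
}
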
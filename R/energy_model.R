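# Simplified nearest-neighbour energy model.
#
# The model scores a pseudoknot-free secondary structure as a sum over the
# loops closed by its base pairs: stacked-pair energies for helices,
# length-dependent initiation penalties for hairpin/bulge/internal loops
# (with Jacobson-Stockmayer logarithmic extrapolation beyond 30 nt), and an
# affine multibranch-loop term a + b*(branches incl. closing) + c*unpaired.
# Watson-Crick and GU wobble pairs are allowed; dangling ends and coaxial
# stacking are deliberately excluded so that the dynamic-programming engine
# and the exhaustive enumeration oracle share an identical model.

PAIR_LEVELS <- c("AU", "UA", "CG", "GC", "GU", "UG")

#' Default nearest-neighbour energy model
#'
#' Returns the built-in simplified Turner-style parameter set: stacking free
#' energies for all Watson-Crick + GU pair-on-pair combinations, hairpin /
#' bulge / internal loop initiation penalties tabulated for lengths 1..30
#' with a logarithmic extrapolation coefficient beyond 30, an affine
#' multibranch term, a minimum hairpin loop of 3 nt, an internal-loop span
#' cap of 30 unpaired nt, and a temperature of 310.15 K. All energies are in
#' kcal/mol.
#'
#' @return An object of class `energy_model` (a named list).
#' @export
#' @examples
#' m <- default_energy_model()
#' m$stack_energies["GC", "CG"]
default_energy_model <- function() {
  stack <- matrix(c(
    # inner:  AU    UA    CG    GC    GU    UG
    -0.9, -1.1, -2.2, -2.1, -0.6, -1.4, # outer AU
    -1.3, -0.9, -2.4, -2.1, -1.0, -1.3, # outer UA
    -2.1, -2.1, -3.3, -2.4, -1.4, -2.1, # outer CG
    -2.4, -2.2, -3.4, -3.3, -1.5, -2.5, # outer GC
    -1.3, -1.4, -2.5, -2.1, -0.5,  1.3, # outer GU
    -1.0, -0.6, -1.5, -1.4,  0.3, -0.5  # outer UG
  ), nrow = 6, byrow = TRUE, dimnames = list(PAIR_LEVELS, PAIR_LEVELS))

  coef <- 1.75 * RGAS * 310.15 # ~1.079 kcal/mol, Jacobson-Stockmayer slope

  hairpin <- numeric(30)
  hairpin[1:2] <- 99 # below the minimum hairpin loop; never reachable
  hairpin[3:9] <- c(5.4, 5.6, 5.7, 5.4, 6.0, 5.5, 6.4)
  hairpin[10:30] <- 6.4 + coef * log((10:30) / 9)

  bulge <- numeric(30)
  bulge[1:6] <- c(3.8, 2.8, 3.2, 3.6, 4.0, 4.4)
  bulge[7:30] <- 4.4 + coef * log((7:30) / 6)

  internal <- numeric(30)
  internal[1] <- 4.1 # internal loops have >= 2 unpaired nt; placeholder
  internal[2:6] <- c(4.1, 4.3, 4.5, 4.7, 4.9)
  internal[7:30] <- 4.9 + coef * log((7:30) / 6)

  model <- list(
    stack_energies   = stack,
    hairpin_penalty  = hairpin,
    bulge_penalty    = bulge,
    internal_penalty = internal,
    loop_log_coef    = coef,
    multiloop_affine = c(close = 3.4, branch = 0.4, unpaired = 0.1),
    min_hairpin_loop = 3L,
    max_internal_span = 30L,
    temperature      = 310.15
  )
  class(model) <- "energy_model"
  validate_energy_model(model)
}

#' Validate an energy model
#'
#' Checks the structural invariants: all 36 stack entries present, penalty
#' tables defined for loop lengths 1..30, minimum hairpin loop >= 3, and a
#' positive absolute temperature.
#'
#' @param model An `energy_model` object.
#' @return The model, invisibly usable, or an error.
#' @export
validate_energy_model <- function(model) {
  stopifnot(is.list(model))
  st <- model$stack_energies
  if (!is.matrix(st) || !identical(dim(st), c(6L, 6L)) ||
      !identical(rownames(st), PAIR_LEVELS) ||
      !identical(colnames(st), PAIR_LEVELS) || anyNA(st)) {
    stop("stack_energies must be a complete 6x6 matrix over ",
         paste(PAIR_LEVELS, collapse = ","), call. = FALSE)
  }
  for (tab in c("hairpin_penalty", "bulge_penalty", "internal_penalty")) {
    v <- model[[tab]]
    if (!is.numeric(v) || length(v) != 30L || anyNA(v)) {
      stop(tab, " must be a numeric table for loop lengths 1..30",
           call. = FALSE)
    }
  }
  if (model$min_hairpin_loop < 3L) {
    stop("min_hairpin_loop must be >= 3", call. = FALSE)
  }
  if (length(model$multiloop_affine) != 3L) {
    stop("multiloop_affine must hold (close, branch, unpaired)", call. = FALSE)
  }
  if (model$temperature <= 0) stop("temperature must be positive (kelvin)",
                                   call. = FALSE)
  model
}

# thermal energy RT in kcal/mol at the model temperature
model_rt <- function(model) RGAS * model$temperature

# pair type of bases a, b given as characters; NA when not pairable
pair_type <- function(a, b) {
  key <- paste0(a, b)
  if (key %in% PAIR_LEVELS) key else NA_character_
}

# loop initiation energy with logarithmic extrapolation beyond length 30
loop_energy <- function(table, len, coef) {
  if (len <= 0L) stop("loop length must be positive", call. = FALSE)
  if (len <= 30L) table[len] else table[30] + coef * log(len / 30)
}

#' Write an energy model to a plain-text table
#'
#' One `key<TAB>value` pair per line; keys are `stack.<outer>.<inner>`,
#' `hairpin.<len>`, `bulge.<len>`, `internal.<len>`, `ml.close`,
#' `ml.branch`, `ml.unpaired`, `loop_log_coef`, `min_hairpin_loop`,
#' `max_internal_span` and `temperature`. Values are kcal/mol except the
#' counts and the temperature (kelvin).
#'
#' @param model An `energy_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_energy_model <- function(model, path) {
  validate_energy_model(model)
  lines <- character(0)
  for (o in PAIR_LEVELS) {
    for (i in PAIR_LEVELS) {
      lines <- c(lines, sprintf("stack.%s.%s\t%.6f", o, i,
                                model$stack_energies[o, i]))
    }
  }
  for (tab in c("hairpin", "bulge", "internal")) {
    v <- model[[paste0(tab, "_penalty")]]
    lines <- c(lines, sprintf("%s.%d\t%.6f", tab, 1:30, v))
  }
  ml <- model$multiloop_affine
  lines <- c(lines,
             sprintf("ml.close\t%.6f", ml[["close"]]),
             sprintf("ml.branch\t%.6f", ml[["branch"]]),
             sprintf("ml.unpaired\t%.6f", ml[["unpaired"]]),
             sprintf("loop_log_coef\t%.6f", model$loop_log_coef),
             sprintf("min_hairpin_loop\t%d", model$min_hairpin_loop),
             sprintf("max_internal_span\t%d", model$max_internal_span),
             sprintf("temperature\t%.4f", model$temperature))
  writeLines(lines, path)
  invisible(path)
}

#' Read an energy model from a plain-text table
#'
#' Inverse of [write_energy_model()].
#'
#' @param path File written by [write_energy_model()] (or hand-edited in the
#'   same format).
#' @return An `energy_model` object.
#' @export
read_energy_model <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("key", "value"),
                    colClasses = c("character", "numeric"))
  val <- function(k) {
    hit <- tab$value[tab$key == k]
    if (!length(hit)) stop("energy table missing key: ", k, call. = FALSE)
    hit[1]
  }
  stack <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_LEVELS, PAIR_LEVELS))
  for (o in PAIR_LEVELS) for (i in PAIR_LEVELS) {
    stack[o, i] <- val(sprintf("stack.%s.%s", o, i))
  }
  model <- list(
    stack_energies   = stack,
    hairpin_penalty  = vapply(1:30, function(l) val(sprintf("hairpin.%d", l)),
                              numeric(1)),
    bulge_penalty    = vapply(1:30, function(l) val(sprintf("bulge.%d", l)),
                              numeric(1)),
    internal_penalty = vapply(1:30, function(l) val(sprintf("internal.%d", l)),
                              numeric(1)),
    loop_log_coef    = val("loop_log_coef"),
    multiloop_affine = c(close = val("ml.close"), branch = val("ml.branch"),
                         unpaired = val("ml.unpaired")),
    min_hairpin_loop = as.integer(val("min_hairpin_loop")),
    max_internal_span = as.integer(val("max_internal_span")),
    temperature      = val("temperature")
  )
  class(model) <- "energy_model"
  validate_energy_model(model)
}
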
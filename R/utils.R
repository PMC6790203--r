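# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package operations never
#' disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Numerically stable row-wise softmax of a matrix (or a vector).
softmax <- function(x) {
  if (is.matrix(x)) {
    x <- x - apply(x, 1L, max)
    e <- exp(x)
    e / rowSums(e)
  } else {
    e <- exp(x - max(x))
    e / sum(e)
  }
}

# Half-up decimal rounding (base round() rounds half to even).
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Condition constructors: classed errors so the CLI can map them to exit
# codes (validation -> 2, format -> 2, io -> 3, numeric -> 4).
stop_validation <- function(msg, ...) {
  stop(structure(class = c("hf_validation_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

stop_format <- function(msg, ...) {
  stop(structure(class = c("hf_format_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

stop_io <- function(msg, ...) {
  stop(structure(class = c("hf_io_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == as.integer(x) && x >= min
}
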
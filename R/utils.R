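#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local, restored RNG state
#'
#' All stochastic operations in the package accept an explicit integer seed
#' and sample inside `with_seed()`, so callers' RNG streams are never
#' disturbed and identical seeds give byte-identical outputs.
#'
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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
  expr
}

# Derive a stage seed from a run seed; keeps results < 2^31 and distinct per
# stage without consuming the caller's RNG.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  offsets <- c(reference = 11L, copy_map = 23L, variants = 37L,
               coverage = 53L, vcf = 71L, rna = 89L, misc = 101L)
  off <- offsets[[stage]] %||% 127L
  as.integer((as.numeric(seed) * 48271 + off) %% 2147483587)
}

# assertion helper with sprintf-style message
check_that <- function(ok, fmt, ...) {
  if (!isTRUE(ok)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}

#' Mean depth over a 1-based closed interval of a per-base depth vector,
#' optionally excluding one position.
#' @keywords internal
#' @noRd
interval_mean_depth <- function(depth, start, end, exclude = NA_integer_) {
  n <- length(depth)
  start <- max(1L, start)
  end <- min(n, end)
  if (end < start) return(NA_real_)
  s <- sum(as.numeric(depth[start:end]))
  len <- end - start + 1L
  if (!is.na(exclude) && exclude >= start && exclude <= end) {
    s <- s - depth[exclude]
    len <- len - 1L
  }
  if (len <= 0L) return(NA_real_)
  s / len
}
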
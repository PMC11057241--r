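#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so package functions are deterministic per seed without
#' clobbering the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
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
  expr
}

#' Derive a stage seed from a master seed
#'
#' Fixed integer derivation so pipeline stages can be re-run independently
#' yet reproducibly from one master seed. Result is always in `[1, 2^31-2]`.
#'
#' @param master Master seed (integer).
#' @param stage Stage name (character) or index.
#' @return Integer seed.
#' @export
derive_seed <- function(master, stage) {
  if (is.character(stage)) {
    stage <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  }
  val <- (as.double(master) %% 2147483647) * 48271 + as.double(stage) * 9973
  as.integer(val %% 2147483629 + 1)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Phase levels used throughout the package
#'
#' @return Character vector of the four Fucci-gated classes.
#' @export
phase_levels <- function() c("G1", "earlyS", "SG2M", "DN")
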
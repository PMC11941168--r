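# Internal helpers: condition constructors and seed management.

stop2 <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "dnbscreen_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

warn2 <- function(msg, class) {
  warning(structure(
    class = c(class, "dnbscreen_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

#' Evaluate an expression with a private RNG state
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so package functions never disturb user-level random streams.
#' @noRd
with_seed <- function(seed, expr) {
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
  set.seed(seed)
  expr
}

#' Derive a per-stage child seed from a master seed
#'
#' Deterministic splitting rule used by [generate_stage_series()]: the child
#' for stage `i` is `(seed * 1009 + i * 9973) mod (2^31 - 1)`, computed in
#' double precision so no intermediate overflows 32-bit integer range.
#'
#' @param seed Master seed (integer-valued scalar).
#' @param i Stage index (1-based).
#' @return An integer scalar in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 2147483647 * 1009 + as.double(i) * 9973) %%
               2147483647)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
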
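# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state so callers' random streams are unaffected.
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
  set.seed(seed)
  force(code)
}

#' Derive a reproducible child seed from a master seed
#'
#' Deterministic integer hash so each subject/phase gets an independent,
#' reproducible stream. Result is kept in [0, 2^31 - 1].
#'
#' @param master_seed integer master seed.
#' @param ... integer or character labels identifying the sub-stream.
#' @return a single integer seed.
#' @export
derive_seed <- function(master_seed, ...) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.finite(master_seed))
  labels <- unlist(lapply(list(...), as.character), use.names = FALSE)
  h <- as.double(master_seed) %% 2147483647
  for (lab in labels) {
    for (ch in utf8ToInt(lab)) {
      h <- (h * 31 + ch) %% 2147483647
    }
  }
  as.integer(h)
}

assert_scalar_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
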
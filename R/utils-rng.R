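# Seed plumbing: every generator draws from named sub-streams derived from one
# master seed, so perturbing (say) the isotope stream leaves genotypes intact.

#' Derive per-domain sub-seeds from a master seed
#'
#' @param seed master integer seed.
#' @param n number of sub-seeds.
#' @return integer vector of `n` seeds, each in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seeds <- function(seed, n) {
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Evaluate an expression under a private RNG stream
#'
#' Saves and restores the global RNG state so the stream is isolated.
#'
#' @param seed integer seed for the stream.
#' @param expr expression to evaluate.
#' @keywords internal
with_stream <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(as.integer(seed))
  expr
}
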
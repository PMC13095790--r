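# seed plumbing shared by every stochastic entry point

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Derive a child seed from a root seed
#'
#' Deterministic integer mixing so that every pipeline stage draws from its
#' own reproducible stream while all randomness flows from one root seed.
#'
#' @param root Root seed (integer).
#' @param index Stage index (integer, `>= 0`).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(root, index) {
  # products stay far below 2^53 so doubles carry them exactly
  as.integer(((root %% 100000) * 69069 + index * 30013 + 1) %% 2147483646 + 1)
}
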
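# Seed hygiene: deterministic functions set a local seed and restore the
# caller's RNG stream afterwards, so pipelines compose reproducibly.

local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  invisible(old)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Derive a stream-specific child seed
#'
#' Small deterministic hash keeping results below 2^31 so they remain valid
#' R integer seeds.
#'
#' @param seed Parent integer seed.
#' @param k Stream index.
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, k) {
  s <- (as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483646
  as.integer(s + 1)
}
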
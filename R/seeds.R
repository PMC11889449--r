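# Seed management. One master seed spawns named substreams so that, e.g.,
# enabling noise does not perturb the concentration draws.

SUBSTREAMS <- c(fixtures = 11L, concentrations = 13L, ph = 17L,
                noise = 19L, pka = 23L)

#' Derive a named substream seed from a master seed
#'
#' Deterministic arithmetic derivation kept below 2^31 so the result is a
#' valid R integer seed. Optional `index` gives per-replicate substreams.
#'
#' @param seed master seed (non-negative integer)
#' @param stream one of `"fixtures"`, `"concentrations"`, `"ph"`,
#'   `"noise"`, `"pka"`
#' @param index optional extra offset (e.g. replicate number)
#' @return integer seed
#' @export
substream_seed <- function(seed, stream, index = 0L) {
  stream <- match.arg(stream, names(SUBSTREAMS))
  m <- 2147483629  # largest prime < 2^31
  s <- (as.double(seed) %% m)
  s <- (s * 48271 + SUBSTREAMS[[stream]] * 1299709 + as.double(index)) %% m
  as.integer(s)
}

# Set the RNG to `seed` (when non-NULL) and return a restorer closure;
# with seed = NULL the current stream is used untouched.
.Random.seed_guard <- function(seed) {
  if (is.null(seed)) return(function() invisible(NULL))
  prev <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(prev)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", prev, envir = globalenv())
    invisible(NULL)
  }
}
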
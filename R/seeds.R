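#' Derive a per-stage random seed from a master seed
#'
#' Every generator in the package is a pure function of its configuration,
#' including its seed. Pipelines fan one master seed out into independent
#' per-stage streams so that each stage is individually reproducible: the
#' stream seed is a deterministic mix of the master seed and the stream name.
#'
#' @param seed Master seed, a single integer.
#' @param stream Character stream name, e.g. `"counts"` or `"phantom"`.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' fan_out_seed(1, "counts")
#' fan_out_seed(1, "phantom")
fan_out_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stream),
            length(stream) == 1)
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% m
  s <- (abs(seed) %% m)
  as.integer(((s * 48271) %% m + (h * 16807) %% m) %% (m - 1) + 1)
}

with_seed <- function(seed, code) {
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
  set.seed(seed)
  force(code)
}
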
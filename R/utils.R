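# Internal helpers: seeding, validation, small numerics.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so library calls never disturb a caller's random
#' stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
#' @examples
#' with_seed(1, rnorm(2))
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a deterministic per-substream child seed
#'
#' Maps a parent seed and a stream name to a child seed kept within 32-bit
#' integer range so `set.seed()` accepts it.  Streams are named so that e.g.
#' the spike stream is unaffected by adding noise generation.
#'
#' @param seed Parent integer seed.
#' @param stream Character stream name.
#' @return An integer seed in `[0, 2^31)`.
#' @export
#' @examples
#' child_seed(1, "spikes")
child_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483587L)
}

stopifnot_scalar <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (strict && x <= min) {
    stop(sprintf("`%s` must be > %g", name, min), call. = FALSE)
  }
  if (!strict && x < min) {
    stop(sprintf("`%s` must be >= %g", name, min), call. = FALSE)
  }
  invisible(x)
}

#' Standard error of the mean
#'
#' @param x Numeric vector; `NA`s are dropped.
#' @return `sd(x)/sqrt(n)`, or `NA` when fewer than two values remain (a
#'   single replicate has no dispersion estimate).
#' @export
#' @examples
#' sem(c(2, 4, 6)) # 1.1547
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# Maximal runs of TRUE in a logical vector -> data.frame(i0, i1) of 1-based
# first/last indices.  Shared by every threshold-crossing detector.
true_runs <- function(above) {
  above[is.na(above)] <- FALSE
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(i0 = starts[keep], i1 = ends[keep])
}
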
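#' @keywords internal
"_PACKAGE"

## NULL-default helper
`%||%` <- function(a, b) if (is.null(a)) b else a

## Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
## Every stochastic operation in the package takes an explicit seed and
## routes through here, so there is no hidden global RNG coupling.
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

## largest-remainder apportionment of `total` into integer counts
## proportional to `p` (sums exactly to `total`)
apportion_counts <- function(p, total) {
  stopifnot(all(p >= 0), total >= 0)
  if (sum(p) == 0) return(rep(0L, length(p)))
  p <- p / sum(p)
  raw <- p * total
  counts <- floor(raw)
  short <- as.integer(round(total - sum(counts)))
  if (short > 0) {
    take <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[take] <- counts[take] + 1
  }
  as.integer(counts)
}

assert_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("%s must be within [0, 1]", what), call. = FALSE)
  }
  invisible(x)
}
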
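## Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

#' @keywords internal
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop2(msg)
  invisible(TRUE)
}

## Run expr with a private RNG stream seeded by `seed`, restoring the
## caller's RNG state afterwards. All package randomness funnels through
## this so no function touches global RNG state as a side effect.
with_seed <- function(seed, expr) {
  assert_that(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
              "seed must be a single finite number")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a child seed from a master seed and a stream index, kept well
## below .Machine$integer.max.
child_seed <- function(seed, k) {
  (as.integer(seed) * 97L + as.integer(k) * 1009L) %% 2147480000L
}

## Standardize columns to zero mean / unit variance; constant columns -> 0.
zscore <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
}
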
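## Counter-based seed derivation: one master seed expands into independent
## per-(condition, network, replicate, ...) streams so any job can be
## regenerated in isolation and results are independent of execution order.

.SEED_MOD <- 2147483629  # largest prime < 2^31; keeps products < 2^53 exact

.mixSeed <- function(s, k) {
  (s * 69069 + k + 1) %% .SEED_MOD
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Deterministically mixes a master seed with an arbitrary sequence of
#' numeric or character keys (a counter-based scheme), yielding an integer
#' seed below 2^31 suitable for [set.seed()]. Used throughout the package so
#' that every (condition, network, replicate) job owns an independent,
#' individually regenerable random stream.
#'
#' @param seed Integer master seed.
#' @param ... Numeric vectors or character scalars identifying the stream.
#' @return A single non-negative integer seed.
#' @examples
#' deriveSeed(1, "normal", 3L)
#' @export
deriveSeed <- function(seed, ...) {
  s <- abs(as.numeric(seed)[1]) %% .SEED_MOD
  for (key in list(...)) {
    if (is.character(key)) {
      for (ch in utf8ToInt(paste(key, collapse = "\r"))) s <- .mixSeed(s, ch)
    } else {
      for (v in as.numeric(key)) s <- .mixSeed(s, v %% .SEED_MOD)
    }
    s <- .mixSeed(s, 2654435)
  }
  as.integer(s)
}

## Evaluate expr with a temporarily-seeded RNG, restoring global state after.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
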
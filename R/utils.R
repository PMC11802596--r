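#' @keywords internal
"_PACKAGE"

GROUP_LEVELS <- c("TD", "ASD", "DCD")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Population variance (divide by N)
#'
#' Session-level dispersion features use the population convention
#' (divide by N, not N - 1), so a session of identical gestures has
#' variance exactly 0 regardless of gesture count.
#'
#' @param x numeric vector; NAs removed.
#' @return population variance, or NA if no finite values.
#' @export
pop_var <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  mean((x - mean(x))^2)
}

pop_sd <- function(x) sqrt(pop_var(x))

## quartiles by linear interpolation between order statistics (type 7)
q1 <- function(x) unname(stats::quantile(x, 0.25, type = 7, names = FALSE))
q3 <- function(x) unname(stats::quantile(x, 0.75, type = 7, names = FALSE))

## run fn with a locally seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  fn()
}

## Deterministic per-subject seed derivation (counter-based, < 2^31).
## Arithmetic seed sequences are unsafe: Mersenne-Twister states seeded
## from linearly related integers keep their first draws weakly
## correlated, which imprints a cohort's block layout onto supposedly
## exchangeable subjects. Instead each master seed owns a pool of seeds
## drawn sequentially from its own stream; subject `index` picks pool
## entry `index`, so cohorts are reproducible and stable under resizing.
.seed_pools <- new.env(parent = emptyenv())

derive_seed <- function(master, index) {
  index <- as.integer(index)
  key <- as.character(as.integer(master %% .Machine$integer.max))
  pool <- .seed_pools[[key]]
  if (is.null(pool) || length(pool) < index) {
    size <- max(4096L, 2L^ceiling(log2(index)))
    pool <- with_seed(master, function() sample.int(2147483646L, size))
    .seed_pools[[key]] <- pool
  }
  pool[index]
}
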
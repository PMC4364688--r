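`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a fixed seed without clobbering the caller's RNG
# stream; a NULL seed leaves the current stream in place.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible sub-seed from a base seed and labels
#'
#' Deterministic 31-bit polynomial hash over the concatenated arguments,
#' used to give every grid cell of an experiment -- scenario, imputer,
#' replicate -- its own stable seed, so that partial re-runs and reordered
#' runs reproduce identical results cell by cell.
#'
#' @param baseSeed integer base seed.
#' @param ... labels (coerced to character) identifying the stage, scenario,
#'   imputer and replicate.
#' @return a positive integer seed below 2^31.
#' @examples
#' stableSeed(1, "mask", "low2high", 50, 3)
#' @export
stableSeed <- function(baseSeed, ...) {
  s <- paste(c(as.character(baseSeed), vapply(list(...), function(x)
    paste(as.character(x), collapse = ","), character(1))), collapse = "|")
  h <- 0
  # Horner scheme mod the Mersenne prime 2^31 - 1; exact in doubles since
  # intermediate values stay below 2^53
  for (code in utf8ToInt(s)) h <- (h * 131 + code) %% 2147483647
  as.integer(h + 1)
}

# Column MAF of a 0/1(/NA) matrix.
colMaf <- function(m) {
  p <- colMeans(m, na.rm = TRUE)
  pmin(p, 1 - p)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
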
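#' @keywords internal
"_PACKAGE"

#' @importFrom stats rpois rbinom pbinom runif var phyper p.adjust pt
#' @importFrom utils head modifyList
NULL

# Stable polynomial string hash (mod the Mersenne prime 2^31-1), used to
# derive per-sample RNG streams from a master seed so sample generation
# order never matters. Doubles hold intermediates exactly (< 2^53).
str_hash32 <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  h
}

# Child seed for a named stream; always a valid 32-bit R integer.
child_seed <- function(master_seed, name) {
  as.integer((as.numeric(master_seed) + str_hash32(name)) %% 2147483647)
}

# Run expr under a local RNG stream derived from (seed, name), restoring the
# caller's RNG state afterwards.
with_stream <- function(seed, name, expr) {
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
  set.seed(child_seed(seed, name))
  expr
}

# Cheap deterministic fingerprint of an R object (for run logs).
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  sprintf("%08x", str_hash32(s))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
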
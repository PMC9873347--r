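#' Derive a child seed from a parent seed
#'
#' All stochastic stages take a single integer seed and derive independent
#' child seeds for sub-tasks (records, channels, folds) with a small integer
#' hash, so that one top-level seed reproduces a whole run while each
#' sub-stream stays decoupled from the others.
#'
#' @param seed integer parent seed.
#' @param ... further integers (or strings, hashed by character codes)
#'   identifying the sub-task.
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  parts <- list(...)
  h <- as.double(seed %% 2147483647L)
  for (p in parts) {
    if (is.character(p)) p <- sum(utf8ToInt(paste(p, collapse = ""))) else p <- as.double(p)
    for (v in p) {
      # 32-bit-safe multiplicative mixing in double arithmetic
      h <- (h * 48271 + as.double(v) + 11) %% 2147483647
    }
  }
  as.integer(h)
}

# evaluate expr with a local RNG state seeded at `seed`, restoring the
# caller's state afterwards
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_ehg <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# population standard deviation (divide by N)
sd_pop <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}
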
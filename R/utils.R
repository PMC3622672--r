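# Internal helpers shared across modules.

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package route through this so that a
# user-visible `seed` argument fully determines the output.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a reproducible 31-bit sub-seed from a base seed and an index.
# Double arithmetic: the products stay below 2^53, so the modulus is exact
# where 32-bit integer multiplication would overflow.
derive_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_data <- function(...) stop(..., call. = FALSE)

read_input_lines <- function(path, what) {
  if (!file.exists(path))
    stop_data("cannot read ", what, " file '", path, "': no such file")
  tryCatch(readLines(path, warn = FALSE),
           error = function(e) stop_data("cannot read ", what, " file '", path, "': ",
                                         conditionMessage(e)))
}
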
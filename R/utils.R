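# internal validation helpers

stop_bindgraph <- function(msg, class) {
  stop(structure(
    class = c(class, "bindgraph_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

assert_that <- function(ok, msg, class = "bindgraph_validation_error") {
  if (!isTRUE(ok)) stop_bindgraph(msg, class)
  invisible(TRUE)
}

# Deterministic 31-bit hash of a character string, used to derive
# per-sequence RNG seeds. Polynomial rolling hash mod a Mersenne prime.
str_hash31 <- function(x) {
  codes <- utf8ToInt(x)
  h <- 0
  p <- 2147483647  # 2^31 - 1
  for (c in codes) h <- (h * 131 + c) %% p
  as.integer(h)
}

# run expr with a local RNG state so callers' streams are untouched
with_local_seed <- function(seed, expr) {
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

`%||%` <- function(a, b) if (is.null(a)) b else a
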
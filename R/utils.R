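# Internal helpers: classed conditions and local RNG scoping.

ws_abort <- function(msg, class) {
  stop(structure(
    class = c(class, "wearsense_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

abort_input   <- function(msg) ws_abort(msg, "ws_input_error")
abort_format  <- function(msg) ws_abort(msg, "ws_format_error")
abort_quality <- function(msg) ws_abort(msg, "ws_data_quality_error")
abort_config  <- function(msg) ws_abort(msg, "ws_config_error")

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv),
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Shannon entropy (bits) of a non-negative weight vector; degenerate -> 0.
shannon_bits <- function(w) {
  w <- w[is.finite(w) & w > 0]
  s <- sum(w)
  if (s <= 0) return(0)
  p <- w / s
  -sum(p * log2(p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.ws_env <- new.env(parent = emptyenv())
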
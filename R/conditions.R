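# Classed conditions so callers can distinguish failure modes programmatically.

cp_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "cytopipe_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

cp_warn <- function(class, msg, ...) {
  warning(structure(
    class = c(class, "cytopipe_warning", "warning", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Deterministic 31-bit polynomial hash of a string, used to derive per-sample
# RNG substreams so adding a sample never perturbs another sample's draws.
string_seed <- function(id, seed) {
  h <- 0
  for (k in utf8ToInt(id)) h <- (h * 31 + k) %% 2147483647L
  as.integer((h + as.numeric(seed)) %% 2147483647)
}
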
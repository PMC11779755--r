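#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stream index; stays < 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 69621) %% 2147483587L)
}

stop_degenerate <- function(msg) {
  stop(errorCondition(msg, class = c("shapescission_degenerate", "error")))
}

stop_calibration <- function(msg, best = NA_real_) {
  stop(errorCondition(msg, best_achievable = best,
                      class = c("shapescission_calibration_failure", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
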
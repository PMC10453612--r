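# Internal helpers shared across modules.

# Stop with a classed condition so callers can test on error class rather
# than message wording.
stop_rescuekit <- function(message, class) {
  rlang::abort(message, class = c(class, "rescuekit_error"))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_rescuekit(sprintf("`%s` must be a single finite number.", name),
                   "rescuekit_parameter_error")
  }
  ok_lower <- if (strict_lower) x > lower else x >= lower
  if (!ok_lower || x > upper) {
    stop_rescuekit(
      sprintf("`%s` = %g is outside its allowed range.", name, x),
      "rescuekit_parameter_error"
    )
  }
  invisible(x)
}

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so package functions never perturb user-level randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

geo_mean <- function(x) exp(mean(log(x)))

`%||%` <- rlang::`%||%`
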
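# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded to `seed`, then
#' restores the previous RNG state so callers never perturb (or depend on) the
#' session RNG. All stochastic operations in the package route through this.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a sub-seed from a base seed and a stream index; stays below 2^31 - 1.
mix_seed <- function(seed, stream) {
  as.integer((abs(as.numeric(seed)) * 7919 + as.numeric(stream) * 104729) %%
               2147483647)
}

stop_if_not <- function(cond, ..., class = "eegannot_error") {
  if (!isTRUE(cond)) {
    stop(errorCondition(paste0(...), class = c(class, "error", "condition")))
  }
  invisible(TRUE)
}

# Shortest decimal string that round-trips to the exact double. Keeps CSV
# files human-readable while making write -> read -> write byte-stable.
format_num <- function(x) {
  vapply(x, function(v) {
    if (!is.finite(v)) return(as.character(v))
    for (d in 1:17) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, character(1))
}
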
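# internal helpers shared across modules

pa_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "pennalign_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded at `seed`, then
#' restores the previous RNG state so that library calls do not perturb the
#' caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(seed)
  force(code)
}

# round half away from zero (symmetric for +/- inputs, unlike round())
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# round to 2 decimals, half away from zero (table display convention)
round2 <- function(x) round_half_away(x * 100) / 100

# derive a per-index child seed below 2^31 from a base seed
derive_seed <- function(seed, index) {
  (as.numeric(seed) * 1009 + as.numeric(index) * 9176) %% 2147483647
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
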
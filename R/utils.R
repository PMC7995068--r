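#' @keywords internal
"_PACKAGE"

# Validation helpers shared across modules.  All user-facing errors are
# signalled with a consistent "edgame_error" condition class so the CLI can
# map them to exit codes.

ed_stop <- function(..., class = "edgame_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    ed_stop(sprintf("`%s` must be a single non-missing number", name))
  }
  if (integer && x != trunc(x)) {
    ed_stop(sprintf("`%s` must be an integer, got %s", name, format(x)))
  }
  if (x < lower || x > upper) {
    ed_stop(sprintf("`%s` must be in [%s, %s], got %s",
                    name, format(lower), format(upper), format(x)))
  }
  invisible(x)
}

#' Derive a reproducible sub-stream seed
#'
#' All randomness in the package flows from one top-level seed.  Independent
#' components (deck generation, arrivals, each bot policy, each Monte-Carlo
#' replicate) draw from named sub-streams so that adding a consumer never
#' perturbs the draws of another.  The sub-seed is a deterministic hash of
#' the master seed and the stream name, kept below 2^31.
#'
#' @param seed master integer seed.
#' @param stream character stream name.
#' @return A single integer usable with [set.seed()].
#' @export
substream_seed <- function(seed, stream) {
  assert_scalar_number(seed, "seed", integer = TRUE)
  h <- 0
  for (cp in utf8ToInt(paste0(stream, ":"))) {
    h <- (h * 131 + cp) %% 2147483629
  }
  as.integer((h + (seed %% 2147483629) * 2654435 %% 2147483629) %% 2147483629)
}

# Evaluate an expression with a locally-set RNG state, restoring the caller's.
with_seed <- function(seed, expr) {
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
  })
  set.seed(seed)
  expr
}
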
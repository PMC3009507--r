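# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# state. A NULL seed leaves the RNG alone.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# scalar checks --------------------------------------------------------------

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name),
          class = "funcoh_error_argument")
  }
  too_low <- if (strict_lower) x <= lower else x < lower
  if (too_low || x > upper) {
    abort(sprintf("`%s` = %s is outside its allowed range.", name, format(x)),
          class = "funcoh_error_argument")
  }
  invisible(x)
}

check_file_exists <- function(path, what = "input file") {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    abort(sprintf("%s not found: %s", what,
                  if (is.character(path)) path else "<missing>"),
          class = "funcoh_error_file")
  }
  invisible(path)
}
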
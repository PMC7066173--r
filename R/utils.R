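#' @keywords internal
"_PACKAGE"

# Classed conditions so callers (and the CLI) can distinguish bad input from
# bad usage. value/format/config/input/fit/generation/usage.
ok_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(paste0(class, "_error"), "organoidkit_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

ok_log <- function(level = "INFO", fmt, ...) {
  if (isTRUE(getOption("organoidkit.quiet", TRUE))) return(invisible(NULL))
  message(sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, sprintf(fmt, ...)))
  invisible(NULL)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream. All generators funnel through this, which is what makes
# identical SimSpec => identical output hold.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

stopifnot_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    ok_stop("value", "%s must be a finite number in [%s, %s] (got %s)",
            name, format(lo), format(hi), paste(format(x), collapse = ","))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
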
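# internal helpers shared across modules

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# genus keys are compared case-insensitively after trimming whitespace,
# because taxonomy assignments and lookup exports differ in capitalization
normalize_genus <- function(x) casefold(trimws(as.character(x)), upper = FALSE)

is_wholenumber <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  invisible(x)
}
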
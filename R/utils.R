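`%||%` <- function(x, y) if (is.null(x)) y else x

# classed error helper so callers can distinguish input / schema /
# validation / estimation / configuration failures programmatically
abort_oab <- function(msg, class = "oab_input_error") {
  stop(structure(
    class = c(class, "oabcea_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

warn_oab <- function(msg, class = "oab_warning") {
  warning(warningCondition(msg, class = c(class, "oabcea_warning")))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1)) {
    abort_oab(sprintf("%s: probability out of [0,1]", name))
  }
  invisible(x)
}

# row-stochastic check used throughout (fitted, shifted, loaded matrices)
is_row_stochastic <- function(M, tol = 1e-9) {
  is.matrix(M) && nrow(M) == ncol(M) &&
    all(M >= -tol) && all(M <= 1 + tol) &&
    all(abs(rowSums(M) - 1) <= tol)
}
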
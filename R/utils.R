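# internal assertion helpers

abort_bad_arg <- function(arg, must, value = NULL, class = "menmod_error") {
  msg <- sprintf("`%s` must %s.", arg, must)
  if (!is.null(value)) msg <- paste0(msg, sprintf(" Got %s.", format(value)))
  rlang::abort(msg, class = c(class, "menmod_error"))
}

check_number <- function(x, arg, min = -Inf, max = Inf, allow_inf = FALSE,
                         strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort_bad_arg(arg, "be a single non-missing number")
  }
  if (!allow_inf && !is.finite(x)) abort_bad_arg(arg, "be finite", x)
  if (strict_min && x <= min) {
    abort_bad_arg(arg, sprintf("be greater than %s", format(min)), x)
  }
  if (!strict_min && x < min) {
    abort_bad_arg(arg, sprintf("be at least %s", format(min)), x)
  }
  if (x > max) abort_bad_arg(arg, sprintf("be at most %s", format(max)), x)
  invisible(x)
}

check_numeric_vec <- function(x, arg) {
  if (!is.numeric(x) || anyNA(x)) {
    abort_bad_arg(arg, "be a numeric vector without missing values")
  }
  invisible(x)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
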
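# internal argument checks

abort_if <- function(cond, msg, class = "qamskit_error") {
  if (cond) rlang::abort(msg, class = class)
  invisible(TRUE)
}

check_positive <- function(x, name) {
  abort_if(
    !is.numeric(x) || any(!is.finite(x)) || any(x <= 0),
    sprintf("`%s` must be finite and > 0.", name)
  )
}

check_scalar_positive <- function(x, name) {
  abort_if(length(x) != 1, sprintf("`%s` must be a single value.", name))
  check_positive(x, name)
}

check_columns <- function(data, cols, what) {
  missing <- setdiff(cols, names(data))
  abort_if(
    length(missing) > 0,
    sprintf("%s is missing required column(s): %s.",
            what, paste(missing, collapse = ", "))
  )
}

# significant-figure rounding used by report writers
signif_chr <- function(x, digits) {
  ifelse(is.na(x), NA_character_, formatC(signif(x, digits), format = "fg"))
}
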
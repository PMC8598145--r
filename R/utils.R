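# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ..., class) {
  if (cond) {
    stop(errorCondition(paste0(...), class = c(class, "insertfactor_error")))
  }
  invisible(NULL)
}

#' Format a number with a fixed number of decimals (round-half-even)
#'
#' Report rendering keeps full precision internally and rounds only for
#' display, using R's IEEE round-half-even convention (the same rule used
#' for the 3-decimal factors and 1-decimal monitor units in reports).
#'
#' @param x numeric vector.
#' @param digits decimals to keep.
#' @return character vector.
#' @keywords internal
fmt_dec <- function(x, digits) {
  sprintf(paste0("%.", digits, "f"), round(x, digits))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
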
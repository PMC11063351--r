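`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || all(is.na(a))) b else a

#' Round half up
#'
#' Decimal rounding where ties go away from zero (0.005 -> 0.01 at two
#' decimals), matching the print convention of the packaged measurement
#' tables. Base [round()] rounds half to even, which would disagree with the
#' printed values on tie cells.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.005, 0.015, 2.675), 2)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # round() first to strip float representation noise (e.g. 2.675 * 100)
  sign(x) * floor(round(abs(x) * p, 9) + 0.5) / p
}

# Structured logging to stderr; warnings never change exit status.
log_msg <- function(level, ...) {
  message(sprintf("[%s] %s", level, paste0(...)))
}

is_string <- function(x) is.character(x) && length(x) == 1 && !is.na(x)

stop_dishlabel <- function(class, ...) {
  stop(structure(
    class = c(class, "dishlabel_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

# Preserve the caller's RNG state while running seeded generator code.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
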
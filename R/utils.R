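# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

## Error taxonomy: every user-facing failure is a classed condition so the CLI
## can map validation/format problems to exit code 2 and everything else to 3.
fcakb_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "fcakb_error", "error")))
}
stop_validation <- function(msg) fcakb_stop(msg, "fcakb_validation_error")
stop_format     <- function(msg) fcakb_stop(msg, "fcakb_format_error")
stop_lookup     <- function(msg) fcakb_stop(msg, "fcakb_lookup_error")
stop_coding     <- function(msg) fcakb_stop(msg, "fcakb_coding_error")
stop_size       <- function(msg) fcakb_stop(msg, "fcakb_size_error")

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; similarity scores are displayed
#' rounded half-up (0.0005 -> 0.001) to match conventional clinical-table
#' formatting.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

## "C2" < "C10": order concept ids by numeric suffix when all ids look like
## <letters><number>, otherwise plain lexicographic.
order_ids_natural <- function(ids) {
  num <- suppressWarnings(as.numeric(sub("^[A-Za-z]*", "", ids)))
  if (anyNA(num)) order(ids) else order(num, ids)
}

## Run an expression with a private RNG state so generators are reproducible
## from their own seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Collapse a character set for display.
set_label <- function(x) paste(x, collapse = ", ")
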
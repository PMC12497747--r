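#' @importFrom rlang .data
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Key used to index (condition, iteration) epoch cells in segment lists.
cell_key <- function(condition, iteration) {
  paste0(condition, "#", iteration)
}

# Expand a per-group scalar/length-2 value into a named c(control=, patient=)
# vector.
per_group <- function(x, what) {
  groups <- c("control", "patient")
  if (length(x) == 1L) {
    out <- stats::setNames(rep(x, 2L), groups)
  } else if (length(x) == 2L) {
    out <- if (is.null(names(x))) stats::setNames(as.vector(x), groups) else x[groups]
  } else {
    stop(sprintf("'%s' must have length 1 or 2", what), call. = FALSE)
  }
  if (anyNA(out)) {
    stop(sprintf("'%s' must name groups 'control' and 'patient'", what),
         call. = FALSE)
  }
  out
}
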
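#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy and glance methods
#'
#' `tidy()` on a confusion result gives one row per metric; `glance()`
#' returns the one-row summary. On a sweep, `tidy()` returns the per-row
#' table and `glance()` the best row by F1 (via [select_best()]).
#'
#' @param x A `chim_confusion` or `chim_sweep` object.
#' @param ... Unused.
#' @return A tibble.
#' @name chimbench-tidiers
NULL

#' @rdname chimbench-tidiers
#' @method tidy chim_confusion
#' @export
tidy.chim_confusion <- function(x, ...) {
  tibble(
    metric = c("tp", "fp", "fn", "tn", "precision", "recall", "f1"),
    value = c(x$tp, x$fp, x$fn, x$tn, x$precision, x$recall, x$f1)
  )
}

#' @rdname chimbench-tidiers
#' @method glance chim_confusion
#' @export
glance.chim_confusion <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "chim_confusion")
  out
}

#' @rdname chimbench-tidiers
#' @method tidy chim_sweep
#' @export
tidy.chim_sweep <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "chim_sweep")
  out
}

#' @rdname chimbench-tidiers
#' @method glance chim_sweep
#' @export
glance.chim_sweep <- function(x, ...) {
  base <- attr(x, "base_params") %||% detector_params()
  select_best(x, base)
}
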
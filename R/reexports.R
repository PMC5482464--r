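#' Re-exported generics
#'
#' `tidy()` and `glance()` from generics (the broom verbs) and `autoplot()`
#' from ggplot2, re-exported so drykin methods work without attaching those
#' packages.
#'
#' @name reexports
#' @keywords internal
NULL

#' @rdname reexports
#' @export
generics::tidy

#' @rdname reexports
#' @export
generics::glance

#' @rdname reexports
#' @export
ggplot2::autoplot
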
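#' Re-exported generics
#'
#' `tidy()` and `glance()` from generics, `autoplot()` from ggplot2, so
#' the broom-style methods in this package work without attaching those
#' packages.
#'
#' @name reexports
#' @keywords internal
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
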
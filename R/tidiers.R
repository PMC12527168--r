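#' Broom-style tidiers for zwdc result objects
#'
#' `tidy()` returns the per-row content of a result as a tibble; `glance()`
#' returns a one-row summary. Methods exist for hypothesis-test results
#' (`zw_htest`) and Kaplan-Meier curves (`zw_km`).
#'
#' @param x A `zw_htest` or `zw_km` object.
#' @param ... Ignored.
#' @return A tibble.
#' @name zw_tidiers
NULL
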
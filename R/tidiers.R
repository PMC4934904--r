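#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Mann-Kendall test
#'
#' @param x A `fp_mk` object.
#' @param ... Unused.
#' @return One-row tibble with `statistic` (S), `tau`, `var_s`, `z`,
#'   `p.value`, `n`.
#' @method tidy fp_mk
#' @export
tidy.fp_mk <- function(x, ...) {
  tibble::tibble(statistic = x$s, tau = x$tau, var_s = x$var_s, z = x$z,
                 p.value = x$p_value, n = x$n)
}

#' @rdname tidy.fp_mk
#' @method glance fp_mk
#' @export
glance.fp_mk <- function(x, ...) tidy.fp_mk(x)

#' Tidy a Theil-Sen fit
#'
#' @param x A `fp_theilsen` object.
#' @param ... Unused.
#' @return Two-row tibble in term/estimate form.
#' @method tidy fp_theilsen
#' @export
tidy.fp_theilsen <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @rdname tidy.fp_theilsen
#' @method glance fp_theilsen
#' @export
glance.fp_theilsen <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept, n = x$n)
}
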
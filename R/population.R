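#' Logistic tumour-cell population rate
#'
#' \code{dc/dt = (a1 - a2) c - b c^2} in normal growth mode. Once the
#' apoptosis trigger has fired at a node, the linear growth rate drops to
#' \code{a1_triggered < a2} (complete shutdown by default), after which the
#' only attracting state is extinction. An equivalent variant adds an extra
#' linear death term instead of reducing growth
#' (\code{death_rate_variant = TRUE}); both formulations collapse the
#' population the same way and are exposed for completeness.
#'
#' @param c_t Cell density (c_ref units), >= 0. Vectorized.
#' @param triggered Logical (scalar or per-node): has apoptosis been
#'   triggered at this node.
#' @param p Parameter list carrying \code{a1}, \code{a2}, \code{a1_triggered},
#'   \code{b} in a consistent time unit (e.g. the \code{cord_ndim} set).
#' @param death_rate_variant If \code{TRUE}, triggered nodes keep the normal
#'   growth rate but gain an additional linear death term of magnitude
#'   \code{(a1 - a1_triggered)}, which yields the same net linear
#'   coefficient.
#' @return \code{dc/dt} in the time unit of the rates.
#' @export
population_rate <- function(c_t, triggered, p, death_rate_variant = FALSE) {
  if (any(c_t < 0)) stop("cell density must be non-negative", call. = FALSE)
  a_lin <- ifelse(triggered, p$a1_triggered - p$a2, p$a1 - p$a2)
  ## the death-rate variant reaches the same net linear coefficient by adding
  ## an extra death term rather than cutting growth
  if (death_rate_variant)
    a_lin <- ifelse(triggered, p$a1 - p$a2 - (p$a1 - p$a1_triggered), a_lin)
  a_lin * c_t - p$b * c_t^2
}
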
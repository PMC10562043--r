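#' Gauss error function
#'
#' The error function \eqn{\mathrm{erf}(z) = \frac{2}{\sqrt{\pi}} \int_0^z
#' e^{-t^2}\,dt}, evaluated through the normal CDF identity
#' \eqn{\mathrm{erf}(z) = 2\Phi(z\sqrt{2}) - 1}. It is odd, bounded in
#' (-1, 1) and monotone increasing; penumbra regions of collimated photon
#' beams are well described by sums of scaled, shifted error functions.
#'
#' @param z numeric vector.
#' @return numeric vector of the same length as `z`.
#' @examples
#' erf(0)      # 0
#' erf(1)      # 0.8427008
#' erf(-1)     # -erf(1)
#' @export
erf <- function(z) 2 * stats::pnorm(z * sqrt(2)) - 1

#' Inverse error function
#'
#' Inverse of [erf()], via the normal quantile function.
#'
#' @param y numeric vector in (-1, 1).
#' @return numeric vector with `erf(erfinv(y)) == y`.
#' @export
erfinv <- function(y) stats::qnorm((y + 1) / 2) / sqrt(2)
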
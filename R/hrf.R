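#' Canonical double-gamma haemodynamic response function
#'
#' Evaluates the canonical HRF on a grid of times.  The shape is the usual
#' difference of two gamma densities: a positive response peaking near
#' \code{peak_delay} seconds and an undershoot centred near
#' \code{undershoot_delay} seconds with peak-to-undershoot amplitude ratio
#' \code{ratio}; the response has decayed essentially to zero by ~32 s.
#' The curve is normalised so its continuous-time maximum equals 1.
#'
#' Gamma components are parameterised by their mode: a component with mode
#' \eqn{m} and dispersion \eqn{d} is \code{dgamma(t, shape = m/d + 1, rate = 1/d)}.
#'
#' @param t_grid numeric vector of times in seconds; nonnegative, increasing.
#' @param peak_delay mode of the positive lobe (s).
#' @param undershoot_delay mode of the undershoot lobe (s).
#' @param ratio peak-to-undershoot amplitude ratio.
#' @param dispersion width parameter of both gamma lobes (s).
#' @return numeric vector of response weights, one per grid point.
#' @examples
#' h <- canonical_hrf(seq(0, 32, by = 0.5))
#' @export
canonical_hrf <- function(t_grid, peak_delay = 6, undershoot_delay = 16,
                          ratio = 6, dispersion = 1) {
  if (length(t_grid) == 0L) stop("empty time grid")
  if (any(t_grid < 0)) stop("t_grid must be nonnegative")
  if (is.unsorted(t_grid, strictly = TRUE)) stop("t_grid must be increasing")
  stopifnot(peak_delay > 0, undershoot_delay > peak_delay, ratio > 0,
            dispersion > 0)
  f <- function(t) {
    stats::dgamma(t, shape = peak_delay / dispersion + 1, rate = 1 / dispersion) -
      stats::dgamma(t, shape = undershoot_delay / dispersion + 1,
                    rate = 1 / dispersion) / ratio
  }
  pk <- stats::optimize(f, c(0, undershoot_delay), maximum = TRUE)$objective
  f(t_grid) / pk
}
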
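#' Principal branch of the Lambert-W function
#'
#' Solves \eqn{w e^w = z} for \eqn{w \ge -1}, defined for
#' \eqn{z \ge -e^{-1}}.  Evaluated by Halley's root-finding iteration from a
#' branch-appropriate starting point; the residual \eqn{|w e^w - z|} is
#' driven below \code{1e-12} (relative for large \code{z}).  The value at
#' \code{z = 1} is the Omega constant, \eqn{\Omega \approx 0.5671}.
#'
#' @param z numeric vector, each element \code{>= -exp(-1)}.
#' @return numeric vector of principal-branch values \code{w >= -1}.
#' @examples
#' lambert_w0(1)            # Omega constant 0.567143...
#' lambert_w0(exp(1))       # 1
#' lambert_w0(-exp(-1))     # -1
#' @export
lambert_w0 <- function(z) {
  if (anyNA(z)) stop("'z' contains missing values", call. = FALSE)
  lim <- -exp(-1)
  if (any(z < lim - 1e-15))
    stop(sprintf("lambert_w0 is undefined for z < -1/e (got %g)", min(z)),
         call. = FALSE)
  z <- pmax(z, lim)
  w <- numeric(length(z))
  # starting points by region
  near <- z < -0.25
  big  <- z > 2.5
  mid  <- !near & !big
  if (any(near)) {
    p <- sqrt(2 * (exp(1) * z[near] + 1))
    w[near] <- -1 + p - p^2 / 3 + 11 * p^3 / 72
  }
  if (any(big)) {
    l1 <- log(z[big]); l2 <- log(l1)
    w[big] <- l1 - l2 + l2 / l1
  }
  if (any(mid)) w[mid] <- z[mid] * exp(-z[mid] * 0.5)
  for (it in 1:60) {
    ew <- exp(w)
    f <- w * ew - z
    conv <- abs(f) <= 1e-13 * pmax(1, abs(z))
    if (all(conv)) break
    # Halley step, guarded at the branch point where w = -1
    denom <- ew * (w + 1) - (w + 2) * f / (2 * w + 2)
    step <- ifelse(conv | !is.finite(denom) | denom == 0, 0, f / denom)
    w <- pmax(w - step, -1)
  }
  w
}

#' Piecewise membrane voltage functional
#'
#' A Lambert-W-based description of the membrane potential during an action
#' potential: an initiation branch driven by the principal Lambert-W branch,
#' a rising branch \eqn{t^2 e^t - 1/e}, and a falling branch
#' \eqn{t^2 e^{-t} - 1/e} that relaxes back towards the resting level
#' \eqn{-1/e}.  The branches are defined on the open intervals
#' \eqn{(0, 1/e)}, \eqn{(1/e, (e+1)/e)} and \eqn{((e+1)/e, \infty)}; the
#' breakpoints themselves are left undefined and evaluating there is an
#' error.  The constant \code{c} shifts the initiation branch by
#' \eqn{1/(ce)}.
#'
#' @param t positive time argument(s), excluding the breakpoints
#'   \code{1/e} and \code{(e+1)/e}.
#' @param c nonzero shape constant of the initiation branch.
#' @return numeric vector of voltages.
#' @export
membrane_voltage <- function(t, c = 1) {
  if (!(is.numeric(c) && length(c) == 1L && c != 0))
    stop("'c' must be a single nonzero constant", call. = FALSE)
  if (any(t <= 0)) stop("'t' must be strictly positive", call. = FALSE)
  b1 <- exp(-1); b2 <- (exp(1) + 1) / exp(1)
  if (any(t == b1 | t == b2))
    stop("t lies on a breakpoint (1/e or (e+1)/e) where the functional is undefined",
         call. = FALSE)
  out <- numeric(length(t))
  i1 <- t < b1
  i2 <- t > b1 & t < b2
  i3 <- t > b2
  if (any(i1)) out[i1] <- lambert_w0(t[i1] - b1) - 1 / (c * exp(1))
  if (any(i2)) out[i2] <- t[i2]^2 * exp(t[i2]) - b1
  if (any(i3)) out[i3] <- t[i3]^2 * exp(-t[i3]) - b1
  out
}
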
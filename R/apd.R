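#' Normalization constants of the action potential distribution
#'
#' For shape parameters \eqn{\alpha \in (0, 1]} and \eqn{\beta > 0} the
#' distribution function has the form
#' \eqn{F(s) = A + B\,\mathcal{L}(s)^{1/\alpha} e^{\beta \mathcal{L}(s)}}
#' on a signal rescaled so that \eqn{\mathcal{L}(-\infty) = 1} and
#' \eqn{\mathcal{L}(\infty) = \exp\{W_0(\alpha\beta)/(\alpha\beta)\}}.
#' Writing \eqn{D_1 = \exp\{W_0(\alpha\beta)/(\alpha^2\beta) +
#' \beta e^{W_0(\alpha\beta)/(\alpha\beta)}\}}, the boundary conditions
#' \eqn{F(-\infty) = 0} and \eqn{F(\infty) = 1} force
#' \deqn{B = C = (D_1 - e^\beta)^{-1}, \qquad A = -C e^\beta.}
#' (The sign of \eqn{A} is the one required by the boundary conditions:
#' with \eqn{A = +C e^\beta} the lower limit would be \eqn{2e^\beta C},
#' not 0.)  The constants are computed via \code{expm1} so they stay
#' accurate when \eqn{D_1} and \eqn{e^\beta} are close.
#'
#' @param alpha shape parameter in \code{(0, 1]}.
#' @param beta rate-like parameter, strictly positive.
#' @return a list with elements \code{C}, \code{A}, \code{B}, \code{Lmax}
#'   (the required upper transform limit), and \code{logD1}.
#' @export
normalization_constants <- function(alpha, beta) {
  check_apd_params(alpha, beta)
  ab <- alpha * beta
  ratio <- lambert_w0(ab) / ab            # W0(ab)/(ab), -> 1 as ab -> 0
  Lmax <- exp(ratio)                      # in (1, e)
  logD1 <- ratio / alpha + beta * Lmax
  u_max <- logD1 - beta                   # > 0
  if (!is.finite(u_max) || u_max <= 0)
    stop("degenerate normalization: D1 <= exp(beta) for these parameters",
         call. = FALSE)
  Cc <- exp(-beta) / expm1(u_max)
  if (!is.finite(Cc) || Cc <= 0)
    stop("normalization constant is not finite/positive for these parameters",
         call. = FALSE)
  list(C = Cc, A = -Cc * exp(beta), B = Cc, Lmax = Lmax, logD1 = logD1)
}

check_apd_params <- function(alpha, beta) {
  if (!(is.numeric(alpha) && length(alpha) == 1L && is.finite(alpha) &&
        alpha > 0 && alpha <= 1))
    stop("'alpha' must be a single value in (0, 1]", call. = FALSE)
  if (!(is.numeric(beta) && length(beta) == 1L && is.finite(beta) && beta > 0))
    stop("'beta' must be a single strictly positive value", call. = FALSE)
  invisible(TRUE)
}

#' Rescale a signal to the boundary conditions of the distribution
#'
#' The action potential distribution is defined on a signal whose transform
#' limits are pinned to \eqn{\mathcal{L}(-\infty) = e^{W_0(0)} = 1} and
#' \eqn{\mathcal{L}(\infty) = \exp\{W_0(\alpha\beta)/(\alpha\beta)\}}.
#' Since those limits are the sample minimum and maximum, the pinning is an
#' increasing affine map of the signal, which preserves sample ordering.
#'
#' @param x strictly positive signal with at least two distinct values.
#' @inheritParams normalization_constants
#' @return a \code{"positive_signal"} object (see
#'   [preprocess_to_positive()]) whose values have minimum 1 and maximum
#'   \eqn{\exp\{W_0(\alpha\beta)/(\alpha\beta)\}}.
#' @export
rescale_for_apd <- function(x, alpha, beta) {
  check_apd_params(alpha, beta)
  check_positive_signal(x)
  if (!has_two_distinct(x))
    stop("constant signal cannot carry an action potential distribution",
         call. = FALSE)
  ab <- alpha * beta
  Lmax <- exp(lambert_w0(ab) / ab)
  preprocess_to_positive(x, target_min = 1, target_max = Lmax)
}

#' Action potential distribution on a rescaled signal
#'
#' Binds shape parameters \eqn{(\alpha, \beta)} to a carrier signal and
#' returns a distribution object for the suddency moment \eqn{S} of that
#' signal.  The density is
#' \deqn{f_S(s) = \frac{C}{\alpha}\,(1 + \alpha\beta\mathcal{L}(s))\,
#'   e^{\beta\mathcal{L}(s)}\,\mathcal{L}(s)^{1/\alpha - 1}\,\mathcal{L}'(s),}
#' where \eqn{\mathcal{L}} is the Lehmer transform of the rescaled signal
#' and \eqn{C} the Lambert-W-based normalization constant; the distribution
#' function is \eqn{F(s) = A + B \mathcal{L}(s)^{1/\alpha}
#' e^{\beta\mathcal{L}(s)}} with [normalization_constants()].
#'
#' @param x strictly positive carrier signal (at least two distinct values);
#'   it is rescaled internally via [rescale_for_apd()].
#' @inheritParams normalization_constants
#' @return an object of class \code{"apd"}: a list with the parameters, the
#'   rescaled signal, the rescaling map and the normalization constants.
#' @seealso [apd_pdf()], [apd_cdf()], [apd_quantile()], [apd_sample()],
#'   [fit_apd()]
#' @examples
#' x <- apd_carrier_signal()
#' d <- apd_distribution(x, alpha = 0.5, beta = 1)
#' apd_cdf(d, c(-5, 0, 5))
#' @export
apd_distribution <- function(x, alpha, beta) {
  prep <- rescale_for_apd(x, alpha, beta)
  consts <- normalization_constants(alpha, beta)
  structure(list(alpha = alpha, beta = beta,
                 values = prep$values, lx = log(prep$values),
                 prep = prep, consts = consts),
            class = "apd")
}

#' @export
print.apd <- function(x, ...) {
  cat("Action potential distribution\n")
  cat(sprintf("  alpha = %.4f, beta = %.4f\n", x$alpha, x$beta))
  cat(sprintf("  carrier signal: %d support points, transform range [1, %.4f]\n",
              length(x$values), x$consts$Lmax))
  cat(sprintf("  normalization: C = %.6g, A = %.6g, B = %.6g\n",
              x$consts$C, x$consts$A, x$consts$B))
  invisible(x)
}

#' Density of the action potential distribution
#'
#' @param dist an \code{"apd"} object from [apd_distribution()].
#' @param s numeric vector of suddency moments (may include \code{-Inf},
#'   \code{Inf}, where the density vanishes).
#' @param log if \code{TRUE}, return the log-density.
#' @return numeric vector of (log-)density values.
#' @export
apd_pdf <- function(dist, s, log = FALSE) {
  stopifnot(inherits(dist, "apd"))
  lf <- rep(-Inf, length(s))
  fin <- is.finite(s)
  if (any(fin)) {
    ev <- lehmer_eval(dist$lx, 0, s[fin], deriv = TRUE)
    ab <- dist$alpha * dist$beta
    ldL <- rep(-Inf, length(ev$dL))
    pos <- is.finite(ev$dL) & ev$dL > 0
    ldL[pos] <- log(ev$dL[pos])
    lf[fin] <- log(dist$consts$C) - log(dist$alpha) +
      log1p(ab * ev$L) + dist$beta * ev$L +
      (1 / dist$alpha - 1) * log(ev$L) + ldL
  }
  if (log) lf else exp(lf)
}

#' Distribution function of the action potential distribution
#'
#' Evaluated in the tail-stable form
#' \eqn{F(s) = C e^\beta\,\mathrm{expm1}(u(s))} with
#' \eqn{u(s) = \log\mathcal{L}(s)/\alpha + \beta(\mathcal{L}(s) - 1)}, and
#' the complementary form for the upper tail, so both tails retain relative
#' accuracy.
#'
#' @inheritParams apd_pdf
#' @param lower.tail if \code{FALSE}, return \eqn{1 - F(s)}.
#' @return numeric vector of probabilities in \code{[0, 1]}.
#' @export
apd_cdf <- function(dist, s, lower.tail = TRUE) {
  stopifnot(inherits(dist, "apd"))
  out <- numeric(length(s))
  fin <- is.finite(s)
  if (any(!fin)) {
    hi <- !fin & s > 0
    out[!fin] <- ifelse(hi, 1, 0)
  }
  if (any(fin)) {
    L <- lehmer_eval(dist$lx, 0, s[fin])
    u <- log(L) / dist$alpha + dist$beta * (L - 1)
    u_max <- dist$consts$logD1 - dist$beta
    lower <- dist$consts$C * exp(dist$beta) * expm1(u)
    upper <- -dist$consts$C * exp(dist$consts$logD1) * expm1(u - u_max)
    out[fin] <- ifelse(u < u_max / 2, lower, 1 - upper)
  }
  out <- pmin(pmax(out, 0), 1)
  if (lower.tail) out else 1 - out
}

# Smallest symmetric-ish bracket [s_lo, s_hi] holding all but eps of the mass.
apd_support_bounds <- function(dist, eps = 1e-10) {
  lo <- -1
  while (apd_cdf(dist, lo) > eps && lo > -1e8) lo <- lo * 2
  hi <- 1
  while (apd_cdf(dist, hi, lower.tail = FALSE) > eps && hi < 1e8) hi <- hi * 2
  c(lo, hi)
}

#' Quantile function of the action potential distribution
#'
#' Monotone inversion of [apd_cdf()] by expanding bracket plus vectorised
#' bisection.
#'
#' @inheritParams apd_pdf
#' @param p numeric vector of probabilities in \code{[0, 1]}.
#' @return numeric vector of suddency moments.
#' @export
apd_quantile <- function(dist, p) {
  stopifnot(inherits(dist, "apd"))
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("'p' must lie in [0, 1]", call. = FALSE)
  b <- apd_support_bounds(dist, eps = 1e-12)
  lo <- rep(b[1L], length(p)); hi <- rep(b[2L], length(p))
  for (it in 1:64) {
    mid <- (lo + hi) / 2
    below <- apd_cdf(dist, mid) < p
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  (lo + hi) / 2
}

#' Draw suddency moments from an action potential distribution
#'
#' Inverse-CDF sampling: uniform draws are pushed through [apd_quantile()].
#'
#' @inheritParams apd_pdf
#' @param n number of draws.
#' @param seed optional integer seed; if supplied the draws are reproducible
#'   and the caller's RNG state is restored afterwards.
#' @return numeric vector of \code{n} suddency moments.
#' @export
apd_sample <- function(dist, n, seed = NULL) {
  stopifnot(inherits(dist, "apd"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  apd_quantile(dist, stats::runif(n))
}

#' Default carrier signal for distribution-level work
#'
#' A small geometric progression on \code{[1, 2]}.  Its top two support
#' points keep a fixed ratio, so the transform approaches its limits at a
#' known exponential rate and the density tails decay quickly -- a
#' convenient, fully reproducible carrier for simulation and fitting
#' experiments.
#'
#' @param n number of support points (default 24).
#' @param upper upper end of the progression (default 2).
#' @return numeric vector of \code{n} strictly increasing positive values.
#' @export
apd_carrier_signal <- function(n = 24, upper = 2) {
  exp(seq(0, log(upper), length.out = n))
}
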
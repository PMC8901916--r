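#' Inverse Lehmer transform
#'
#' For a signal with at least two distinct values the transform is strictly
#' increasing in \code{s}, so every statistic \code{t} strictly between
#' \code{min(x)} and \code{max(x)} has a unique finite suddency moment with
#' \eqn{\mathcal{L}(s) = t}; the extremes map to \code{-Inf} and \code{Inf}.
#' The root is located by an expanding bracket followed by
#' \code{\link[stats]{uniroot}} and a Newton polish using the analytic
#' derivative.
#'
#' @inheritParams lehmer_transform
#' @param t a single statistic in \code{[min(x), max(x)]}.
#' @param tol absolute tolerance on \code{|L(s) - t|}.
#' @return the suddency moment \code{s} (possibly \code{-Inf} or \code{Inf}).
#' @examples
#' inverse_lehmer(c(1, 2, 3), 2)   # arithmetic mean -> s = 1
#' inverse_lehmer(c(1, 2, 3), 3)   # maximum -> Inf
#' @export
inverse_lehmer <- function(x, t, tol = 1e-12) {
  check_positive_signal(x)
  if (!has_two_distinct(x))
    stop("constant signal: the transform is not injective, no inverse exists",
         call. = FALSE)
  if (length(t) != 1L || !is.finite(t))
    stop("'t' must be a single finite number", call. = FALSE)
  lo <- min(x); hi <- max(x)
  if (t < lo || t > hi)
    stop(sprintf("t = %g lies outside the attainable range [%g, %g]",
                 t, lo, hi), call. = FALSE)
  if (t == hi) return(Inf)
  if (t == lo) return(-Inf)
  lx <- log(x)
  f <- function(s) lehmer_eval(lx, 0, s) - t
  a <- -1; b <- 1
  while (f(b) < 0 && b < 1e7) { a <- b; b <- b * 2 }
  while (f(a) > 0 && a > -1e7) { b <- a; a <- a * 2 }
  if (f(a) > 0 || f(b) < 0)
    stop("failed to bracket the inverse; t is numerically indistinguishable from an extreme",
         call. = FALSE)
  s <- stats::uniroot(f, c(a, b), tol = .Machine$double.eps^0.75)$root
  # Newton polish with the analytic derivative, down to the noise plateau
  for (k in 1:8) {
    ev <- lehmer_eval(lx, 0, s, deriv = TRUE)
    if (!is.finite(ev$dL) || ev$dL <= 0) break
    step <- (ev$L - t) / ev$dL
    if (!is.finite(step)) break
    s <- s - step
    if (abs(step) < 1e-12 * max(1, abs(s)) || abs(step) < tol * 1e-3) break
  }
  s
}

#' Pointwise inverse transform of a signal (suddency-moment series)
#'
#' Maps every sample of the signal to its own suddency moment,
#' \eqn{s_i = \mathcal{L}^{-1}(x_i)}, producing the signal's representation
#' in the suddency domain.  The extremal samples, whose exact moments are
#' \code{-Inf} and \code{Inf}, are clipped to \code{-clip} and \code{clip};
#' samples whose moments fall beyond the clip are clipped likewise.  The
#' inversion is performed by vectorised bisection on the monotone transform,
#' so long recordings are handled in one pass.
#'
#' @inheritParams lehmer_transform
#' @param clip positive clipping bound for the suddency moments (default 20,
#'   a practical range outside which moments flag anomalous samples).
#' @param targets optional values to invert instead of the samples of
#'   \code{x} themselves.
#' @return numeric vector of suddency moments in \code{[-clip, clip]}, one
#'   per target.
#' @seealso [signal_to_smoments()] for the same operation under the name used
#'   by the density-fitting pipeline.
#' @export
pointwise_inverse_series <- function(x, clip = 20, targets = x) {
  check_positive_signal(x)
  if (!has_two_distinct(x))
    stop("constant signal: the transform is not injective, no inverse exists",
         call. = FALSE)
  if (!(is.numeric(clip) && length(clip) == 1L && clip > 0))
    stop("'clip' must be a single positive number", call. = FALSE)
  lx <- log(x)
  Llo <- lehmer_eval(lx, 0, -clip)
  Lhi <- lehmer_eval(lx, 0, clip)
  s <- numeric(length(targets))
  s[targets <= Llo] <- -clip
  s[targets >= Lhi] <- clip
  inner <- which(targets > Llo & targets < Lhi)
  if (length(inner)) {
    lo <- rep(-clip, length(inner)); hi <- rep(clip, length(inner))
    tt <- targets[inner]
    for (it in 1:46) {
      mid <- (lo + hi) / 2
      Lm <- lehmer_eval(lx, 0, mid)
      below <- Lm < tt
      lo[below] <- mid[below]
      hi[!below] <- mid[!below]
    }
    s[inner] <- (lo + hi) / 2
  }
  s
}

#' @rdname pointwise_inverse_series
#' @export
signal_to_smoments <- function(x, clip = 20) {
  pointwise_inverse_series(x, clip = clip)
}

# truncated product of two polynomials with zero constant term;
# coefficient vectors indexed by degree 1..K
poly_mul_nc <- function(p, q, K) {
  r <- numeric(K)
  for (i in seq_len(K - 1L)) {
    if (p[i] == 0) next
    j <- seq_len(K - i)
    r[i + j] <- r[i + j] + p[i] * q[j]
  }
  r
}

#' Series inverse of the Lehmer transform (Lagrange-Buermann expansion)
#'
#' Computes a truncated power-series inverse of the transform around an
#' expansion point \code{s0}: the Taylor coefficients of
#' \eqn{\mathcal{L}(s)} at \code{s0} are available in closed form (the power
#' sums differentiate termwise), and the series is reverted to give
#' \eqn{s = g(t)} as a polynomial in \eqn{t - \mathcal{L}(s_0)}.  This is a
#' validation and diagnostic path: the production inverse is the
#' root-finding [inverse_lehmer()], whose result the series should approach
#' within its (unknown, empirically finite) convergence region.
#'
#' If the term magnitudes fail to decay the function issues a convergence
#' warning; the returned value then carries the partial sums in the
#' \code{"partial_sums"} attribute.
#'
#' @inheritParams inverse_lehmer
#' @param s0 expansion point, a finite suddency moment with
#'   \eqn{\mathcal{L}(s_0)} near \code{t}.
#' @param K truncation order of the series (default 8).
#' @return the K-term series estimate of the suddency moment.
#' @export
lagrange_burmann_inverse <- function(x, t, s0 = 0, K = 8L) {
  check_positive_signal(x)
  if (!has_two_distinct(x))
    stop("constant signal: no inverse exists", call. = FALSE)
  K <- as.integer(K)
  if (K < 1L) stop("'K' must be a positive integer", call. = FALSE)
  lx <- log(x)
  # exact Taylor coefficients of numerator and denominator power sums at s0
  ws1 <- exp(s0 * lx)          # x^s0
  ws0 <- exp((s0 - 1) * lx)    # x^(s0-1)
  kfact <- factorial(0:K)
  aN <- vapply(0:K, function(k) sum(ws1 * lx^k), numeric(1)) / kfact
  aD <- vapply(0:K, function(k) sum(ws0 * lx^k), numeric(1)) / kfact
  # series division c = aN / aD, coefficients of (s - s0)^k, k = 0..K
  cc <- numeric(K + 1L)
  cc[1L] <- aN[1L] / aD[1L]
  for (k in seq_len(K)) {
    j <- seq_len(k)
    cc[k + 1L] <- (aN[k + 1L] - sum(aD[j + 1L] * cc[k - j + 1L])) / aD[1L]
  }
  L0 <- cc[1L]
  c1 <- cc[2L]
  if (c1 <= 0)
    stop("transform derivative vanishes at s0; series inverse undefined",
         call. = FALSE)
  # series reversion: find b with sum_k cc[k+1] * B(v)^k = v, B = sum b_m v^m
  b <- numeric(K)
  b[1L] <- 1 / c1
  if (K >= 2L) for (m in 2:K) {
    d <- cc[2L] * b
    if (m >= 2L) {
      powk <- b
      for (k in 2:m) {
        powk <- poly_mul_nc(powk, b, K)
        d <- d + cc[k + 1L] * powk
      }
    }
    b[m] <- b[m] - d[m] / c1
  }
  v <- t - L0
  terms <- b * v^seq_len(K)
  g <- s0 + cumsum(terms)
  est <- g[K]
  if (K >= 3L) {
    a <- abs(terms)
    if (a[K] > 0 && a[K] >= a[K - 1L] && a[K - 1L] >= a[K - 2L]) {
      attr(est, "partial_sums") <- g
      warning("Lagrange-Buermann series terms are not decaying; ",
              "t is likely outside the convergence region of this expansion",
              call. = FALSE)
    }
  }
  est
}
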
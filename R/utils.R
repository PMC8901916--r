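# Internal numerical helpers shared across the package.

# Validate a strictly positive signal; report the first offending index.
check_positive_signal <- function(x, arg = "x") {
  if (length(x) == 0L)
    stop(sprintf("'%s' is empty: the transform needs at least one sample", arg),
         call. = FALSE)
  if (anyNA(x) || any(!is.finite(x)))
    stop(sprintf("'%s' contains non-finite values", arg), call. = FALSE)
  bad <- which(x <= 0)
  if (length(bad))
    stop(sprintf("'%s' must be strictly positive; element %d is %g",
                 arg, bad[1L], x[bad[1L]]), call. = FALSE)
  invisible(x)
}

has_two_distinct <- function(x) {
  length(x) >= 2L && (max(x) > min(x))
}

# Core evaluator: Lehmer transform (and optionally its first derivative) of a
# weighted support at a vector of finite suddency moments.  `lx` is log of the
# support points, `logw` the log-weights (0 for a plain sample).  Power sums
# are formed in log space with the extremal exponent factored out (the row
# maximum of s*log(x) sits at an endpoint of the sorted support), so the
# evaluation stays finite for |s| in the hundreds.  Work is chunked so the
# ns x nx intermediate never grows past a few million cells.
lehmer_eval <- function(lx, logw, s, deriv = FALSE, chunk = 4e6) {
  o <- order(lx)
  lx <- lx[o]
  weighted <- length(logw) == length(lx) && any(logw != 0)
  if (weighted) logw <- logw[o]
  nx <- length(lx)
  ns <- length(s)
  l1 <- lx[1L]; ln <- lx[nx]
  L <- numeric(ns)
  dL <- if (deriv) numeric(ns) else NULL
  step <- max(1L, floor(chunk / nx))
  for (start in seq(1L, ns, by = step)) {
    idx <- start:min(start + step - 1L, ns)
    sc <- s[idx]
    ni <- length(sc)
    A <- outer(sc, lx)                       # s * log x
    if (weighted) A <- A + rep(logw, each = ni)
    mx1 <- pmax(sc * l1, sc * ln)
    E1 <- exp(A - mx1)                       # recycles mx1 down the rows
    S1 <- .rowSums(E1, ni, nx)
    mx0 <- pmax((sc - 1) * l1, (sc - 1) * ln)
    E0 <- exp((A - rep(lx, each = ni)) - mx0)
    S0 <- .rowSums(E0, ni, nx)
    L[idx] <- exp(mx1 - mx0) * S1 / S0
    if (deriv) {
      # means of log x under the softmax weights at powers s and s-1
      m1 <- drop(E1 %*% lx) / S1
      m0 <- drop(E0 %*% lx) / S0
      dL[idx] <- L[idx] * (m1 - m0)
    }
  }
  if (deriv) list(L = L, dL = dL) else L
}

# Reduce a long signal to a weighted quantile support that preserves the
# extremes exactly.  Used by the channel featurizer so that transform and
# density evaluations scale with the support size, not the recording length.
compress_signal <- function(x, n_support) {
  n <- length(x)
  if (n <= n_support) return(sort(x))
  probs <- seq(0, 1, length.out = n_support)
  q <- unname(stats::quantile(x, probs = probs, type = 7))
  q[1L] <- min(x)
  q[n_support] <- max(x)
  q <- sort(q)
  # collapse any duplicated quantiles introduced by ties
  q[q <= 0] <- min(x[x > 0])
  q
}

# Deterministic thinning of a vector to at most m evenly spaced elements.
thin_evenly <- function(x, m) {
  n <- length(x)
  if (n <= m) return(x)
  x[unique(round(seq(1, n, length.out = m)))]
}
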
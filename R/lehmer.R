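#' Lehmer transform of a positive signal
#'
#' Maps a strictly positive sample \code{x} and a suddency moment \code{s}
#' to the ratio of consecutive power sums
#' \deqn{\mathcal{L}(s) = \sum_i x_i^s / \sum_i x_i^{s-1},}
#' the Lehmer mean of order \code{s}.  The transform acts as a
#' statistic-generating function: \code{s = 0} gives the harmonic mean,
#' \code{s = 1} the arithmetic mean, \code{s = 2} the contra-harmonic mean,
#' and \code{s = -Inf}/\code{s = Inf} the minimum/maximum.  For a sample of
#' two points, \code{s = 1/2} gives the geometric mean.
#'
#' Power sums are evaluated in log space with the extremal term factored out,
#' so the transform is stable for very large \code{|s|} (hundreds) and for
#' values spanning several orders of magnitude.
#'
#' @param x numeric vector of strictly positive values.
#' @param s numeric vector of suddency moments; \code{-Inf} and \code{Inf}
#'   are allowed and return \code{min(x)} and \code{max(x)}.
#' @return numeric vector, one transform value per element of \code{s},
#'   always within \code{[min(x), max(x)]}.
#' @seealso [lehmer_derivative()], [inverse_lehmer()], [windowed_transform()]
#' @examples
#' lehmer_transform(c(1, 2), 0)      # harmonic mean 4/3
#' lehmer_transform(c(1, 3), 2)      # contra-harmonic mean 2.5
#' lehmer_transform(c(1, 2, 3), Inf) # maximum
#' @export
lehmer_transform <- function(x, s) {
  check_positive_signal(x)
  out <- numeric(length(s))
  fin <- is.finite(s)
  if (any(!fin)) out[!fin] <- ifelse(s[!fin] > 0, max(x), min(x))
  if (any(fin)) out[fin] <- lehmer_eval(log(x), 0, s[fin])
  out
}

#' Derivative of the Lehmer transform with respect to the suddency moment
#'
#' The first derivative has the closed form
#' \deqn{\mathcal{L}'(s) = \mathcal{L}(s)\left[\frac{\sum x_i^s \log x_i}
#'   {\sum x_i^s} - \frac{\sum x_i^{s-1}\log x_i}{\sum x_i^{s-1}}\right],}
#' which is non-negative everywhere and zero only for a constant signal
#' (the transform is monotonously increasing in \code{s}).  Orders above one
#' are computed by nested central differences of the analytic first
#' derivative (step \code{1e-4}); they are provided as a numerical
#' convenience, not a closed form.
#'
#' @inheritParams lehmer_transform
#' @param s numeric vector of finite suddency moments.
#' @param order derivative order, a positive integer (1 is analytic).
#' @return numeric vector of derivative values.
#' @export
lehmer_derivative <- function(x, s, order = 1L) {
  check_positive_signal(x)
  if (any(!is.finite(s)))
    stop("the derivative is defined for finite suddency moments only",
         call. = FALSE)
  order <- as.integer(order)
  if (order < 1L) stop("'order' must be a positive integer", call. = FALSE)
  if (order == 1L)
    return(lehmer_eval(log(x), 0, s, deriv = TRUE)$dL)
  h <- 1e-4
  (lehmer_derivative(x, s + h, order - 1L) -
      lehmer_derivative(x, s - h, order - 1L)) / (2 * h)
}

#' Map an arbitrary real signal onto a strictly positive range
#'
#' Raw EEG potentials are measured in mV and can be zero or negative, while
#' the Lehmer transform is defined on strictly positive samples.  This applies
#' the unique increasing affine map sending the observed minimum and maximum
#' to \code{target_min} and \code{target_max}, and returns the map parameters
#' so the transformation can be inverted later.
#'
#' @param raw numeric vector with at least two distinct finite values.
#' @param target_min,target_max strictly positive bounds of the target range,
#'   \code{0 < target_min < target_max}.
#' @return a list of class \code{"positive_signal"} with elements
#'   \code{values} (the mapped signal), \code{offset} and \code{scale} such
#'   that \code{values = offset + scale * raw}, and the target bounds.
#' @examples
#' p <- preprocess_to_positive(c(-5, 0, 5), 1, 2)
#' p$values                      # 1.0 1.5 2.0
#' (p$values - p$offset) / p$scale  # round-trip to the raw scale
#' @export
preprocess_to_positive <- function(raw, target_min = 1, target_max = 2) {
  if (anyNA(raw) || any(!is.finite(raw)))
    stop("'raw' contains non-finite values", call. = FALSE)
  if (!(target_min > 0 && target_max > target_min))
    stop("need 0 < target_min < target_max", call. = FALSE)
  lo <- min(raw); hi <- max(raw)
  if (hi <= lo)
    stop("degenerate signal: all values identical, affine map undefined",
         call. = FALSE)
  scale <- (target_max - target_min) / (hi - lo)
  offset <- target_min - scale * lo
  structure(list(values = offset + scale * raw,
                 offset = offset, scale = scale,
                 target_min = target_min, target_max = target_max),
            class = "positive_signal")
}

#' Invert the positivity preprocessing
#'
#' @param p a \code{"positive_signal"} object from [preprocess_to_positive()].
#' @param values optional positive-scale values to map back; defaults to the
#'   stored signal.
#' @return numeric vector on the raw scale.
#' @export
undo_preprocess <- function(p, values = p$values) {
  stopifnot(inherits(p, "positive_signal"))
  (values - p$offset) / p$scale
}

#' Sliding-window Lehmer transform of a time series
#'
#' Evaluates the transform at one suddency moment over consecutive windows of
#' the series, yielding a time-indexed summary (one value per window
#' position).  Large positive \code{s} emphasises extreme excursions, making
#' the windowed transform a simple anomaly screen.
#'
#' @param series numeric vector, already strictly positive (see
#'   [preprocess_to_positive()]).
#' @param s a single suddency moment.
#' @param window window length in samples; defaults to 256 (one second at a
#'   256 Hz sampling rate).
#' @param hop step between window starts in samples (default 128).
#' @return numeric vector of length \code{floor((n - window)/hop) + 1} with
#'   the window start index attached as the \code{"start"} attribute.
#' @export
windowed_transform <- function(series, s, window = 256L, hop = 128L) {
  check_positive_signal(series, "series")
  window <- as.integer(window); hop <- as.integer(hop)
  if (window < 1L || hop < 1L)
    stop("'window' and 'hop' must be positive integers", call. = FALSE)
  n <- length(series)
  if (window > n)
    stop(sprintf("window (%d) exceeds series length (%d)", window, n),
         call. = FALSE)
  starts <- seq(1L, n - window + 1L, by = hop)
  out <- vapply(starts,
                function(i) lehmer_transform(series[i:(i + window - 1L)], s),
                numeric(1))
  attr(out, "start") <- starts
  out
}
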
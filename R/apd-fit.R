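#' Maximum-likelihood fit of the action potential distribution
#'
#' Fits the shape parameters \eqn{(\alpha, \beta)} of the action potential
#' distribution to a sample of suddency moments by maximising
#' \eqn{\sum_i \log f_S(s_i;\alpha,\beta)}.  The optimisation runs over the
#' unconstrained parameters \eqn{(\mathrm{logit}\,\alpha, \log\beta)} with
#' Nelder-Mead, and the carrier signal is re-pinned to the boundary
#' conditions of the candidate \eqn{(\alpha,\beta)} at every likelihood
#' evaluation (the conditions depend on \eqn{\alpha\beta}).  A small fixed
#' set of additional starting points hedges against local optima.
#'
#' Observations are typically the pointwise inverse transform of a recorded
#' channel, see [signal_to_smoments()].
#'
#' @param smoments numeric vector of at least 10 finite suddency-moment
#'   observations.
#' @param x strictly positive carrier signal with at least two distinct
#'   values (the signal the moments refer to, possibly compressed).
#' @param init named numeric vector \code{c(alpha = , beta = )} used as the
#'   primary starting point.
#' @param multistart number of starting points (1 to 3); starts beyond the
#'   first are fixed presets spread over the parameter box.
#' @param maxit Nelder-Mead iteration cap per start.
#' @return an object of class \code{"apd_fit"} with components
#'   \code{coefficients} (alpha, beta), \code{logLik}, \code{dist} (the
#'   fitted [apd_distribution()]), \code{smoments}, \code{n_obs},
#'   \code{convergence} and \code{call}.  Standard methods are available:
#'   \code{print}, \code{summary}, \code{coef}, \code{logLik},
#'   \code{simulate}, \code{residuals}, \code{plot}.
#' @examples
#' x <- apd_carrier_signal()
#' d <- apd_distribution(x, alpha = 0.6, beta = 2)
#' s <- apd_sample(d, 500, seed = 1)
#' fit <- fit_apd(s, x)
#' coef(fit)
#' @export
fit_apd <- function(smoments, x,
                    init = c(alpha = 0.5, beta = 1),
                    multistart = 3, maxit = 300) {
  cl <- match.call()
  smoments <- smoments[is.finite(smoments)]
  if (length(smoments) < 10L)
    stop("need at least 10 finite suddency-moment observations", call. = FALSE)
  check_positive_signal(x)
  if (!has_two_distinct(x))
    stop("constant carrier signal: distribution undefined", call. = FALSE)
  if (stats::var(smoments) == 0)
    stop("degenerate observations: all suddency moments identical",
         call. = FALSE)
  alpha0 <- init[["alpha"]]; beta0 <- init[["beta"]]
  check_apd_params(alpha0, beta0)

  nll <- function(theta) {
    alpha <- stats::plogis(theta[1L])
    beta <- exp(theta[2L])
    if (!is.finite(alpha) || !is.finite(beta) || alpha <= 1e-6 || beta > 1e4)
      return(1e10)
    val <- tryCatch({
      d <- apd_distribution(x, alpha, beta)
      lf <- apd_pdf(d, smoments, log = TRUE)
      if (any(!is.finite(lf))) 1e10 else -sum(lf)
    }, error = function(e) 1e10)
    if (!is.finite(val)) 1e10 else val
  }

  to_theta <- function(a, b) c(stats::qlogis(min(a, 1 - 1e-9)), log(b))
  starts <- list(to_theta(alpha0, beta0),
                 to_theta(0.3, 0.5),
                 to_theta(0.85, 2.0))
  starts <- starts[seq_len(max(1L, min(as.integer(multistart), 3L)))]

  best <- NULL
  codes <- integer(0)
  for (th0 in starts) {
    opt <- stats::optim(th0, nll, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-10))
    codes <- c(codes, opt$convergence)
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (all(codes != 0L))
    warning("optimizer hit the iteration cap in every start; ",
            "returning the best parameters found", call. = FALSE)
  # never report worse than the initial point
  if (best$value > nll(starts[[1L]])) {
    best$par <- starts[[1L]]
    best$value <- nll(starts[[1L]])
  }
  alpha <- stats::plogis(best$par[1L])
  beta <- exp(best$par[2L])
  dist <- apd_distribution(x, alpha, beta)
  structure(list(coefficients = c(alpha = unname(alpha), beta = unname(beta)),
                 logLik = -best$value,
                 dist = dist,
                 smoments = smoments,
                 n_obs = length(smoments),
                 convergence = codes,
                 init = c(alpha = alpha0, beta = beta0),
                 call = cl),
            class = "apd_fit")
}

#' @rdname fit_apd
#' @param observations synonym interface kept for pipeline code: identical to
#'   \code{fit_apd(observations, x, ...)}.
#' @param ... passed on to [fit_apd()].
#' @export
fit_apd_mle <- function(observations, x, ...) fit_apd(observations, x, ...)

#' @export
print.apd_fit <- function(x, digits = 4, ...) {
  cat("Action potential distribution fit (maximum likelihood)\n")
  cat(sprintf("  alpha = %.*f, beta = %.*f\n", digits,
              x$coefficients[["alpha"]], digits, x$coefficients[["beta"]]))
  cat(sprintf("  log-likelihood %.*f on %d observations\n",
              digits, x$logLik, x$n_obs))
  invisible(x)
}

#' @export
coef.apd_fit <- function(object, ...) object$coefficients

#' @export
logLik.apd_fit <- function(object, ...) {
  structure(object$logLik, df = 2L, nobs = object$n_obs, class = "logLik")
}

#' @export
summary.apd_fit <- function(object, ...) {
  ent <- differential_entropy(object$dist)
  structure(list(fit = object,
                 entropy = ent,
                 Lmax = object$dist$consts$Lmax,
                 smoment_range = range(object$smoments)),
            class = "summary.apd_fit")
}

#' @export
print.summary.apd_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("  transform range of carrier: [1, %.*f]\n", digits, x$Lmax))
  cat(sprintf("  observed suddency moments in [%.*f, %.*f]\n",
              digits, x$smoment_range[1L], digits, x$smoment_range[2L]))
  cat(sprintf("  differential entropy of fitted density: %.*f nats\n",
              digits, x$entropy))
  invisible(x)
}

#' @export
simulate.apd_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  n <- object$n_obs
  out <- as.data.frame(replicate(nsim, apd_quantile(object$dist,
                                                    stats::runif(n)),
                                 simplify = FALSE),
                       col.names = paste0("sim_", seq_len(nsim)))
  out
}

#' @export
residuals.apd_fit <- function(object, type = c("quantile", "uniform"), ...) {
  type <- match.arg(type)
  u <- apd_cdf(object$dist, object$smoments)
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  if (type == "uniform") u else stats::qnorm(u)
}

#' @export
plot.apd_fit <- function(x, n_grid = 400, ...) {
  s <- x$smoments
  b <- apd_support_bounds(x$dist, eps = 1e-6)
  lo <- max(b[1L], min(s) - 2); hi <- min(b[2L], max(s) + 2)
  grid <- seq(lo, hi, length.out = n_grid)
  f <- apd_pdf(x$dist, grid)
  h <- graphics::hist(s, breaks = "FD", plot = FALSE)
  ylim <- c(0, max(h$density, f) * 1.05)
  graphics::hist(s, breaks = "FD", freq = FALSE, ylim = ylim,
                 col = "grey90", border = "grey60",
                 main = "Fitted action potential distribution",
                 xlab = "suddency moment s", ...)
  graphics::lines(grid, f, lwd = 2)
  invisible(x)
}
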
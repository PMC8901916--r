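#' Constrained modes of an action potential density
#'
#' The five-statistic featurizer splits the suddency axis at the two
#' constrained modes \eqn{m_1 = \arg\max_{s \le 1} f(s)} and
#' \eqn{m_2 = \arg\max_{s \ge 1} f(s)} (the arithmetic-mean moment
#' \eqn{s = 1} is the anchor).  Each mode is located by a grid scan followed
#' by golden-section refinement; when the interior peak ties with the
#' boundary the boundary value 1 is returned.
#'
#' @inheritParams apd_pdf
#' @param search_halfwidth half-width of the scanned interval around 0
#'   (default 50 suddency units).
#' @param step grid step of the initial scan (default 0.01).
#' @return named numeric vector \code{c(m1 = , m2 = )} with
#'   \code{m1 <= 1 <= m2}.
#' @export
find_modes <- function(dist, search_halfwidth = 50, step = 0.01) {
  stopifnot(inherits(dist, "apd"))
  if (!(search_halfwidth > 1)) stop("'search_halfwidth' must exceed 1",
                                    call. = FALSE)
  one_side <- function(lo, hi) {
    grid <- seq(lo, hi, by = step)
    if (grid[length(grid)] != hi) grid <- c(grid, hi)
    f <- apd_pdf(dist, grid, log = TRUE)
    if (any(is.nan(f)))
      stop("non-finite density values in the mode search", call. = FALSE)
    i <- which.max(f)
    a <- grid[max(1L, i - 1L)]; b <- grid[min(length(grid), i + 1L)]
    if (a == b) return(grid[i])
    opt <- stats::optimize(function(s) apd_pdf(dist, s, log = TRUE),
                           interval = c(a, b), maximum = TRUE,
                           tol = 1e-8)
    opt$maximum
  }
  m1 <- one_side(-search_halfwidth, 1)
  m2 <- one_side(1, search_halfwidth)
  f1 <- apd_pdf(dist, 1, log = TRUE)
  # ties (or near-ties at numerical precision) break toward the anchor s = 1
  if (apd_pdf(dist, m1, log = TRUE) <= f1 + 1e-12) m1 <- 1
  if (apd_pdf(dist, m2, log = TRUE) <= f1 + 1e-12) m2 <- 1
  c(m1 = min(m1, 1), m2 = max(m2, 1))
}

# integrand f log f with the 0 log 0 = 0 convention
flogf_integrand <- function(dist) {
  function(s) {
    lf <- apd_pdf(dist, s, log = TRUE)
    ifelse(is.finite(lf), exp(lf) * lf, 0)
  }
}

# adaptive quadrature of f log f over [a, b]; bounds may be -Inf/Inf, which
# are replaced by points carrying < 1e-12 of tail mass (located from the
# closed-form CDF, so no mass is silently dropped).
integrate_flogf <- function(dist, a, b) {
  bounds <- apd_support_bounds(dist, eps = 1e-12)
  lo <- if (is.finite(a)) a else bounds[1L]
  hi <- if (is.finite(b)) b else bounds[2L]
  if (hi <= lo) return(0)
  stats::integrate(flogf_integrand(dist), lo, hi,
                   rel.tol = 1e-9, abs.tol = 1e-11,
                   subdivisions = 400L, stop.on.error = FALSE)$value
}

#' Differential entropy of an action potential distribution
#'
#' Standard differential entropy \eqn{-\int f \log f\,ds}, computed by
#' adaptive quadrature over the effective support (tail mass below
#' \code{1e-12} on each side, located from the closed-form distribution
#' function).  Note the five-statistic featurizer stores the raw integrals
#' \eqn{\int f\log f} (not negated); this function applies the conventional
#' minus sign.
#'
#' @inheritParams apd_pdf
#' @return differential entropy in nats.
#' @export
differential_entropy <- function(dist) {
  -integrate_flogf(dist, -Inf, Inf)
}

#' Five suddency-domain statistics of one recording channel
#'
#' The per-channel pipeline of the featurizer: (1) map the raw channel onto
#' a strictly positive range; (2) take the pointwise inverse Lehmer
#' transform to obtain suddency-moment observations; (3) fit the action
#' potential distribution by maximum likelihood; (4) locate the constrained
#' modes \eqn{m_1 \le 1 \le m_2}; (5) compute the three segment integrals
#' \eqn{\int f\log f} over \eqn{(-\infty, m_1]}, \eqn{[m_1, m_2]},
#' \eqn{[m_2, \infty)} and the two tail probabilities \eqn{F(m_1)} and
#' \eqn{1 - F(m_2)}.
#'
#' For long recordings the carrier signal is compressed to
#' \code{n_support} quantile points (extremes preserved exactly) and the
#' fitted observations are thinned deterministically to \code{max_obs}
#' evenly spaced samples, so cost scales with these caps rather than the
#' recording length.
#'
#' @param y numeric vector, one channel of raw recordings (mV); needs at
#'   least two distinct finite values.
#' @param clip clipping bound for the suddency moments (default 20).
#' @param n_support carrier-compression size (default 128).
#' @param max_obs cap on the number of fitted observations (default 512).
#' @param init,multistart,maxit passed to [fit_apd()].
#' @param search_halfwidth passed to [find_modes()].
#' @param label optional channel identity attached to error messages.
#' @return an object of class \code{"channel_features"}: list with the five
#'   statistics (\code{e_left}, \code{e_mid}, \code{e_right},
#'   \code{tail_left}, \code{tail_right}), the modes, the fitted parameters,
#'   the log-likelihood, the differential entropy, the fitted
#'   \code{"apd"} distribution (\code{dist}), and \code{status}
#'   (\code{"ok"} or \code{"missing"} for a degenerate channel).
#' @export
channel_features <- function(y, clip = 20, n_support = 128, max_obs = 512,
                             init = c(alpha = 0.5, beta = 1),
                             multistart = 1, maxit = 200,
                             search_halfwidth = 50, label = NULL) {
  y <- y[is.finite(y)]
  if (length(unique(y)) < 2L) {
    return(structure(list(e_left = NA_real_, e_mid = NA_real_,
                          e_right = NA_real_, tail_left = NA_real_,
                          tail_right = NA_real_, m1 = NA_real_,
                          m2 = NA_real_, alpha = NA_real_, beta = NA_real_,
                          logLik = NA_real_, entropy = NA_real_,
                          status = "missing", label = label),
                     class = "channel_features"))
  }
  prep <- preprocess_to_positive(y, 1, 2)
  xr <- compress_signal(prep$values, n_support)
  targets <- thin_evenly(prep$values, max_obs)
  sm <- pointwise_inverse_series(xr, clip = clip, targets = targets)
  fit <- tryCatch(
    fit_apd(sm, xr, init = init, multistart = multistart, maxit = maxit),
    error = function(e)
      stop(sprintf("channel %s: density fit failed (%s)",
                   if (is.null(label)) "?" else label,
                   conditionMessage(e)), call. = FALSE))
  dist <- fit$dist
  m <- find_modes(dist, search_halfwidth = search_halfwidth)
  e_left <- integrate_flogf(dist, -Inf, m[["m1"]])
  e_mid <- integrate_flogf(dist, m[["m1"]], m[["m2"]])
  e_right <- integrate_flogf(dist, m[["m2"]], Inf)
  structure(list(e_left = e_left, e_mid = e_mid, e_right = e_right,
                 tail_left = apd_cdf(dist, m[["m1"]]),
                 tail_right = apd_cdf(dist, m[["m2"]], lower.tail = FALSE),
                 m1 = m[["m1"]], m2 = m[["m2"]],
                 alpha = fit$coefficients[["alpha"]],
                 beta = fit$coefficients[["beta"]],
                 logLik = fit$logLik,
                 entropy = -(e_left + e_mid + e_right),
                 dist = dist,
                 status = "ok", label = label),
            class = "channel_features")
}

#' @export
print.channel_features <- function(x, digits = 4, ...) {
  cat("Channel features",
      if (!is.null(x$label)) sprintf("[%s]", x$label), "\n")
  if (x$status != "ok") {
    cat("  status:", x$status, "\n")
    return(invisible(x))
  }
  cat(sprintf("  alpha = %.*f, beta = %.*f (logLik %.*f)\n",
              digits, x$alpha, digits, x$beta, digits, x$logLik))
  cat(sprintf("  modes m1 = %.*f, m2 = %.*f\n", digits, x$m1, digits, x$m2))
  cat(sprintf("  segment integrals of f log f: %.*f | %.*f | %.*f\n",
              digits, x$e_left, digits, x$e_mid, digits, x$e_right))
  cat(sprintf("  tails F(m1) = %.*f, 1 - F(m2) = %.*f\n",
              digits, x$tail_left, digits, x$tail_right))
  cat(sprintf("  differential entropy %.*f nats\n", digits, x$entropy))
  invisible(x)
}

feature_names <- function() {
  c("e_left", "e_mid", "e_right", "tail_left", "tail_right")
}

#' Assemble per-subject feature vectors from a multichannel cohort
#'
#' Runs [channel_features()] over every subject, experiment and channel of a
#' cohort and stacks the five statistics into one fixed-order vector per
#' subject: experiment-major, channel next, the five features innermost, so
#' the length is always \code{5 * experiments * channels} (285 at the
#' defaults of 3 experiments and 19 channels).  Channels belonging to a
#' missing experiment (and degenerate channels) yield \code{NA} entries and
#' are flagged in the mask; optionally they are imputed by the per-feature
#' median over the available subjects.  A subject with every experiment
#' missing is excluded with a warning.
#'
#' @param cohort an \code{"eeg_cohort"} object (see [generate_cohort()]), or
#'   any list with elements \code{subjects} (each a list with
#'   \code{id}, \code{label} and named \code{experiments}, each experiment a
#'   samples-by-channels matrix or \code{NULL}), \code{experiments} and
#'   \code{channel_labels}.
#' @param impute \code{"none"} (keep \code{NA}) or \code{"median"}
#'   (per-feature median over available subjects).  Cross-validated
#'   classification should use \code{"none"} and let [evaluate_cv()] impute
#'   inside training folds.
#' @param ... passed to [channel_features()].
#' @return an object of class \code{"feature_table"}: list with
#'   \code{features} (subjects x 5MJ matrix, named columns),
#'   \code{mask} (logical matrix, \code{TRUE} where the value was missing
#'   before imputation), \code{labels}, \code{subject_ids},
#'   \code{experiments} and \code{channel_labels}.
#' @export
assemble_features <- function(cohort, impute = c("none", "median"), ...) {
  impute <- match.arg(impute)
  exps <- cohort$experiments
  chans <- cohort$channel_labels
  M <- length(exps); J <- length(chans)
  fn <- feature_names()
  grid <- expand.grid(feature = fn, channel = chans, experiment = exps,
                      stringsAsFactors = FALSE)
  cols <- paste(grid$experiment, grid$channel, grid$feature, sep = ".")
  subjects <- cohort$subjects
  all_missing <- vapply(subjects, function(su)
    all(vapply(exps, function(e) is.null(su$experiments[[e]]), logical(1))),
    logical(1))
  if (any(all_missing)) {
    warning(sprintf("excluding %d subject(s) with every experiment missing: %s",
                    sum(all_missing),
                    paste(vapply(subjects[all_missing], `[[`, "", "id"),
                          collapse = ", ")), call. = FALSE)
    subjects <- subjects[!all_missing]
  }
  N <- length(subjects)
  X <- matrix(NA_real_, N, 5L * M * J,
              dimnames = list(vapply(subjects, `[[`, "", "id"), cols))
  for (i in seq_len(N)) {
    su <- subjects[[i]]
    for (mi in seq_len(M)) {
      mat <- su$experiments[[exps[mi]]]
      if (is.null(mat)) next
      for (j in seq_len(J)) {
        cf <- channel_features(mat[, j],
                               label = paste(su$id, exps[mi], chans[j],
                                             sep = "/"), ...)
        if (cf$status != "ok") next
        off <- (mi - 1L) * 5L * J + (j - 1L) * 5L
        X[i, off + 1:5] <- c(cf$e_left, cf$e_mid, cf$e_right,
                             cf$tail_left, cf$tail_right)
      }
    }
  }
  mask <- is.na(X)
  if (impute == "median") X <- impute_median(X)
  structure(list(features = X, mask = mask,
                 labels = vapply(subjects, `[[`, "", "label"),
                 subject_ids = rownames(X),
                 experiments = exps, channel_labels = chans),
            class = "feature_table")
}

# column-median imputation; reference medians may come from a training subset
impute_median <- function(X, medians = NULL) {
  if (is.null(medians))
    medians <- apply(X, 2L, stats::median, na.rm = TRUE)
  medians[!is.finite(medians)] <- 0
  for (j in which(colSums(is.na(X)) > 0L))
    X[is.na(X[, j]), j] <- medians[j]
  X
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table: %d subjects x %d features (%d experiments x %d channels x 5)\n",
              nrow(x$features), ncol(x$features),
              length(x$experiments), length(x$channel_labels)))
  tab <- table(x$labels)
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  cat(sprintf("  missing entries: %d (%.1f%%)\n", sum(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

#' Group-mean differential-entropy heatmaps
#'
#' Aggregates the differential entropy of each channel/experiment cell (the
#' negated sum of the three segment integrals of \eqn{f \log f}) into one
#' channels-by-experiments matrix per group, averaging over the subjects of
#' the group and ignoring missing cells.  These are the scalp-map summaries
#' used to compare overall activation between groups.
#'
#' @param ft a \code{"feature_table"} from [assemble_features()].
#' @param group_labels optional vector of group names per subject; defaults
#'   to the labels stored in the table.
#' @return named list, one channels-by-experiments numeric matrix per group.
#' @export
entropy_heatmap <- function(ft, group_labels = ft$labels) {
  stopifnot(inherits(ft, "feature_table"))
  if (length(group_labels) != nrow(ft$features))
    stop("'group_labels' must have one entry per subject", call. = FALSE)
  groups <- unique(group_labels)
  J <- length(ft$channel_labels); M <- length(ft$experiments)
  out <- vector("list", length(groups)); names(out) <- groups
  for (g in groups) {
    rows <- which(group_labels == g)
    if (!length(rows)) stop(sprintf("group '%s' is empty", g), call. = FALSE)
    H <- matrix(NA_real_, J, M,
                dimnames = list(ft$channel_labels, ft$experiments))
    for (mi in seq_len(M)) for (j in seq_len(J)) {
      off <- (mi - 1L) * 5L * J + (j - 1L) * 5L
      ent <- -(ft$features[rows, off + 1L] + ft$features[rows, off + 2L] +
                 ft$features[rows, off + 3L])
      H[j, mi] <- mean(ent, na.rm = TRUE)
    }
    out[[g]] <- H
  }
  out
}
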
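#' Standard 19-channel electrode labels
#'
#' The 10-20-system electrode names used as default channel labels.
#' @return character vector of length 19.
#' @export
electrode_labels_1020 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' Per-experiment missingness rates of the reference MDD study design
#'
#' A realistic preset for whole-experiment dropout: rows are groups
#' (\code{H} controls, \code{MDD}), columns the three recording conditions
#' (eyes closed, eyes open, task).  Used as a default pattern for
#' [inject_missing()], not as a target to reproduce.
#' @return 2 x 3 numeric matrix of rates.
#' @export
missing_preset_mdd <- function() {
  matrix(c(0.067, 0.033, 0.067,
           0.118, 0.059, 0.029),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("H", "MDD"), c("EC", "EO", "TASK")))
}

#' Configuration of the synthetic EEG-like cohort generator
#'
#' Collects the study-design constants the generator emulates: a two-class
#' cohort (healthy \code{H} vs \code{MDD}), 19 channels per experiment,
#' three recording conditions (EC, EO, TASK), 256 Hz sampling, 10-second
#' recordings, class-specific action-potential parameters, small additive
#' observation noise, and whole-experiment missingness following the
#' reference design's dropout pattern.
#'
#' @param n_per_class subjects per class (default 32).
#' @param channels number of channels (default 19) or a character vector of
#'   channel labels.
#' @param experiments character vector of experiment names
#'   (default \code{c("EC", "EO", "TASK")}).
#' @param sampling_rate sampling rate in Hz (default 256).
#' @param duration_s recording length in seconds (default 10).
#' @param class_params named list with elements \code{H} and \code{MDD},
#'   each either \code{c(alpha =, beta =)} applied to every channel or a
#'   channels-by-2 matrix of per-channel parameters.
#' @param subject_sd named vector \code{c(alpha =, beta =)} of
#'   between-subject standard deviations of the parameters (subject traits
#'   are drawn once and shared across experiments).
#' @param noise_sd additive Gaussian observation noise, expressed as a
#'   fraction of the signal range (default 0.01).
#' @param missing either a group-by-experiment rate matrix (see
#'   [missing_preset_mdd()]), a single rate, or \code{0} for complete data.
#' @param seed integer seed driving all generator randomness.
#' @return object of class \code{"synthetic_config"}.
#' @export
synthetic_config <- function(n_per_class = 32,
                             channels = 19,
                             experiments = c("EC", "EO", "TASK"),
                             sampling_rate = 256,
                             duration_s = 10,
                             class_params = list(
                               H = c(alpha = 0.7, beta = 1.0),
                               MDD = c(alpha = 0.5, beta = 2.0)),
                             subject_sd = c(alpha = 0.04, beta = 0.15),
                             noise_sd = 0.01,
                             missing = missing_preset_mdd(),
                             seed = 1) {
  if (is.numeric(channels) && length(channels) == 1L) {
    labels <- if (channels == 19) electrode_labels_1020()
              else paste0("ch", seq_len(channels))
  } else labels <- as.character(channels)
  stopifnot(n_per_class >= 1, sampling_rate > 0, duration_s > 0,
            length(labels) >= 1, length(experiments) >= 1,
            noise_sd >= 0)
  for (g in c("H", "MDD")) {
    p <- class_params[[g]]
    if (is.matrix(p)) {
      stopifnot(nrow(p) == length(labels), ncol(p) == 2L)
      for (j in seq_len(nrow(p))) check_apd_params(p[j, 1L], p[j, 2L])
    } else check_apd_params(p[["alpha"]], p[["beta"]])
  }
  if (is.numeric(missing) && length(missing) == 1L) {
    stopifnot(missing >= 0, missing < 1)
    missing <- matrix(missing, 2, length(experiments),
                      dimnames = list(c("H", "MDD"), experiments))
  }
  structure(list(n_per_class = n_per_class, channel_labels = labels,
                 experiments = experiments, sampling_rate = sampling_rate,
                 duration_s = duration_s, class_params = class_params,
                 subject_sd = subject_sd, noise_sd = noise_sd,
                 missing = missing, seed = as.integer(seed)),
            class = "synthetic_config")
}

class_param_row <- function(config, group, j) {
  p <- config$class_params[[group]]
  if (is.matrix(p)) c(alpha = p[j, 1L], beta = p[j, 2L])
  else c(alpha = p[["alpha"]], beta = p[["beta"]])
}

#' Draw suddency-moment observations from a known distribution
#'
#' Convenience wrapper pairing [apd_distribution()] with [apd_sample()]:
#' reproducible draws suitable as input to [fit_apd()] for
#' parameter-recovery experiments.
#'
#' @inheritParams normalization_constants
#' @param x carrier signal (default [apd_carrier_signal()]).
#' @param n number of observations.
#' @param seed integer seed.
#' @return numeric vector of \code{n} suddency moments.
#' @export
generate_apd_observations <- function(alpha, beta, n,
                                      x = apd_carrier_signal(), seed = 1) {
  d <- apd_distribution(x, alpha, beta)
  apd_sample(d, n, seed = seed)
}

#' Generate a synthetic two-class multichannel cohort
#'
#' Builds EEG-like recordings by inverse-transform construction: for each
#' subject, experiment and channel, suddency moments are drawn from the
#' subject's action potential distribution (class parameters plus a
#' once-per-subject trait jitter) and mapped through the Lehmer transform
#' of a fixed carrier signal, so the planted suddency-domain structure is
#' exactly the one the analysis pipeline assumes.  Small additive Gaussian
#' noise then perturbs the samples.  Whole experiments are dropped at the
#' configured group-by-experiment missingness rates.
#'
#' @param config a [synthetic_config()].
#' @return object of class \code{"eeg_cohort"}: list with \code{subjects}
#'   (each carrying \code{id}, \code{label}, \code{params} (channels x 2)
#'   and named \code{experiments}, each a samples-by-channels matrix or
#'   \code{NULL} if missing), \code{experiments}, \code{channel_labels},
#'   \code{carrier} (the generator's carrier signal) and \code{config}.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  I <- round(config$sampling_rate * config$duration_s)
  J <- length(config$channel_labels)
  carrier <- apd_carrier_signal()
  subjects <- list()
  for (g in c("H", "MDD")) {
    for (i in seq_len(config$n_per_class)) {
      id <- sprintf("%s%02d", g, i)
      params <- matrix(NA_real_, J, 2L,
                       dimnames = list(config$channel_labels,
                                       c("alpha", "beta")))
      for (j in seq_len(J)) {
        base <- class_param_row(config, g, j)
        a <- min(max(base[["alpha"]] +
                       stats::rnorm(1, 0, config$subject_sd[["alpha"]]),
                     0.05), 1)
        b <- max(base[["beta"]] +
                   stats::rnorm(1, 0, config$subject_sd[["beta"]]), 0.05)
        params[j, ] <- c(a, b)
      }
      exps <- stats::setNames(vector("list", length(config$experiments)),
                              config$experiments)
      for (e in config$experiments) {
        mat <- matrix(NA_real_, I, J,
                      dimnames = list(NULL, config$channel_labels))
        for (j in seq_len(J)) {
          d <- apd_distribution(carrier, params[j, 1L], params[j, 2L])
          s <- apd_quantile(d, stats::runif(I))
          v <- lehmer_eval(d$lx, 0, s)
          if (config$noise_sd > 0) {
            rng <- d$consts$Lmax - 1
            v <- v + stats::rnorm(I, 0, config$noise_sd * rng)
          }
          mat[, j] <- v
        }
        exps[[e]] <- mat
      }
      subjects[[id]] <- list(id = id, label = g, params = params,
                             experiments = exps)
    }
  }
  cohort <- structure(list(subjects = subjects,
                           experiments = config$experiments,
                           channel_labels = config$channel_labels,
                           carrier = carrier, config = config),
                      class = "eeg_cohort")
  if (any(config$missing > 0))
    cohort <- inject_missing(cohort, config$missing,
                             seed = config$seed + 1L)
  cohort
}

#' @export
print.eeg_cohort <- function(x, ...) {
  labs <- vapply(x$subjects, `[[`, "", "label")
  nmiss <- sum(vapply(x$subjects, function(su)
    sum(vapply(x$experiments, function(e) is.null(su$experiments[[e]]),
               logical(1))), integer(1)))
  cat(sprintf("Synthetic EEG cohort: %d subjects (%s), %d experiments x %d channels\n",
              length(x$subjects),
              paste(sprintf("%s=%d", names(table(labs)), table(labs)),
                    collapse = ", "),
              length(x$experiments), length(x$channel_labels)))
  cat(sprintf("  %d of %d subject-experiments missing\n", nmiss,
              length(x$subjects) * length(x$experiments)))
  invisible(x)
}

#' Drop whole subject-experiments at configurable rates
#'
#' Removes entire experiment recordings (all channels) per subject with the
#' given probability, reproducing the whole-experiment dropout typical of
#' clinical EEG studies.  Rates may differ by group and experiment.
#'
#' @param cohort an \code{"eeg_cohort"}.
#' @param rates a single rate in \code{[0, 1]}, or a group-by-experiment
#'   matrix with rownames matching the labels and colnames the experiments.
#' @param seed integer seed.
#' @return the cohort with dropped experiments set to \code{NULL}.  If every
#'   experiment of a subject is dropped a warning names the subject (the
#'   featurizer will exclude it).
#' @export
inject_missing <- function(cohort, rates = missing_preset_mdd(), seed = 1) {
  stopifnot(inherits(cohort, "eeg_cohort"))
  exps <- cohort$experiments
  if (is.numeric(rates) && length(rates) == 1L)
    rates <- matrix(rates, 2, length(exps),
                    dimnames = list(c("H", "MDD"), exps))
  stopifnot(all(rates >= 0), all(rates <= 1))
  set.seed(seed)
  lost <- character(0)
  for (id in names(cohort$subjects)) {
    su <- cohort$subjects[[id]]
    for (e in exps) {
      rate <- rates[su$label, e]
      if (rate > 0 && stats::runif(1) < rate)
        cohort$subjects[[id]]$experiments[[e]] <- NULL
    }
    if (all(vapply(exps, function(e)
      is.null(cohort$subjects[[id]]$experiments[[e]]), logical(1))))
      lost <- c(lost, id)
  }
  if (length(lost))
    warning(sprintf("subject(s) with every experiment missing: %s",
                    paste(lost, collapse = ", ")), call. = FALSE)
  cohort
}
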
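test_that("constrained modes match a brute-force grid search", {
  d <- apd_distribution(fixture_carrier(), 0.5, 1)
  m <- find_modes(d)
  g1 <- seq(-50, 1, by = 1e-3)
  g2 <- seq(1, 50, by = 1e-3)
  expect_equal(m[["m1"]], g1[which.max(apd_pdf(d, g1))], tolerance = 2e-3)
  expect_equal(m[["m2"]], g2[which.max(apd_pdf(d, g2))], tolerance = 2e-3)
  expect_lte(m[["m1"]], 1)
  expect_gte(m[["m2"]], 1)
})

test_that("a peak on one side of the anchor pins the other mode at 1", {
  # this law is unimodal; whichever side misses the peak returns the anchor
  d <- apd_distribution(fixture_carrier(), 0.5, 1)
  m <- find_modes(d)
  peak <- if (m[["m2"]] > 1) "right" else "left"
  if (peak == "right") expect_equal(m[["m1"]], 1) else
    expect_equal(m[["m2"]], 1)
})

test_that("segment integrals are additive and tails match the CDF", {
  d <- apd_distribution(fixture_carrier(), 0.7, 1.5)
  m <- find_modes(d)
  e1 <- suddency:::integrate_flogf(d, -Inf, m[["m1"]])
  e2 <- suddency:::integrate_flogf(d, m[["m1"]], m[["m2"]])
  e3 <- suddency:::integrate_flogf(d, m[["m2"]], Inf)
  full <- suddency:::integrate_flogf(d, -Inf, Inf)
  expect_equal(e1 + e2 + e3, full, tolerance = 1e-6)
  expect_equal(differential_entropy(d), -full, tolerance = 1e-9)
})

test_that("differential entropy is translation invariant and matches Monte Carlo", {
  # two distributions with identical shape parameters on carriers that are
  # scalings of one another have identical (rescaled) densities
  d1 <- apd_distribution(fixture_carrier(), 0.5, 1)
  d2 <- apd_distribution(10 * fixture_carrier(), 0.5, 1)
  expect_equal(differential_entropy(d1), differential_entropy(d2),
               tolerance = 1e-6)
  set.seed(8)
  s <- apd_sample(d1, 2e4)
  mc <- -mean(apd_pdf(d1, s, log = TRUE))
  se <- stats::sd(apd_pdf(d1, s, log = TRUE)) / sqrt(length(s))
  expect_lt(abs(differential_entropy(d1) - mc), 3 * se)
})

test_that("channel features honour their defining identities", {
  set.seed(21)
  y <- rnorm(400)
  cf <- do.call(channel_features, c(list(y), fast_feature_args()))
  expect_s3_class(cf, "channel_features")
  expect_identical(cf$status, "ok")
  expect_equal(cf$entropy, -(cf$e_left + cf$e_mid + cf$e_right),
               tolerance = 1e-9)
  expect_true(cf$tail_left >= 0 && cf$tail_left <= 1)
  expect_true(cf$tail_right >= 0 && cf$tail_right <= 1)
  expect_lte(cf$tail_left + cf$tail_right, 1)
  expect_lte(cf$m1, 1); expect_gte(cf$m2, 1)
  # a constant channel is reported missing, not an error
  cfm <- channel_features(rep(1, 100))
  expect_identical(cfm$status, "missing")
  expect_true(is.na(cfm$e_left))
})

test_that("features estimated from observations of the law match the true features", {
  # with observations genuinely drawn from the law, the fitted density's
  # five statistics approach those of the generating density (estimation
  # error only; bound chosen from the measured spread at this sample size)
  x <- fixture_carrier()
  d <- apd_distribution(x, 0.6, 2)
  m <- find_modes(d)
  five_stats <- function(dd) {
    mm <- find_modes(dd)
    c(suddency:::integrate_flogf(dd, -Inf, mm[["m1"]]),
      suddency:::integrate_flogf(dd, mm[["m1"]], mm[["m2"]]),
      suddency:::integrate_flogf(dd, mm[["m2"]], Inf),
      apd_cdf(dd, mm[["m1"]]),
      apd_cdf(dd, mm[["m2"]], lower.tail = FALSE))
  }
  truth <- five_stats(d)
  for (seed in 1:2) {
    s <- apd_sample(d, 4000, seed = seed)
    fit <- fit_apd(s, x, multistart = 1)
    expect_equal(five_stats(fit$dist), truth, tolerance = 0.1)
  }
})

test_that("feature assembly has the documented shape and ordering", {
  coh <- tiny_cohort(n_per_class = 1, channels = 2, duration_s = 0.4)
  ft <- suppressWarnings(
    do.call(assemble_features, c(list(coh), fast_feature_args())))
  expect_equal(ncol(ft$features), 5 * 3 * 2)   # 5 x M x J
  expect_equal(nrow(ft$features), 2)
  expect_identical(colnames(ft$features)[1:5],
                   paste("EC.ch1", suddency:::feature_names(), sep = "."))
  expect_identical(colnames(ft$features)[6], "EC.ch2.e_left")
  expect_identical(colnames(ft$features)[11], "EO.ch1.e_left")
  expect_false(any(ft$mask))
})

test_that("a missing experiment masks exactly its 5J entries", {
  coh <- tiny_cohort(n_per_class = 2, channels = 2, duration_s = 0.4)
  coh$subjects[["H01"]]$experiments[["EO"]] <- NULL
  ft <- suppressWarnings(
    do.call(assemble_features, c(list(coh), fast_feature_args())))
  expect_equal(sum(ft$mask["H01", ]), 5L * 2L)
  expect_true(all(grepl("^EO\\.", colnames(ft$features)[ft$mask["H01", ]])))
  # median imputation fills the gaps and keeps the mask
  ft2 <- suppressWarnings(do.call(
    assemble_features, c(list(coh, impute = "median"), fast_feature_args())))
  expect_false(anyNA(ft2$features))
  expect_equal(sum(ft2$mask["H01", ]), 5L * 2L)
  # a subject with everything missing is excluded with a warning
  coh$subjects[["H02"]]$experiments[["EC"]] <- NULL
  coh$subjects[["H02"]]$experiments[["EO"]] <- NULL
  coh$subjects[["H02"]]$experiments[["TASK"]] <- NULL
  expect_warning(
    ft3 <- withCallingHandlers(
      do.call(assemble_features, c(list(coh), fast_feature_args())),
      warning = function(w) {
        if (!grepl("excluding", conditionMessage(w)))
          invokeRestart("muffleWarning")
      }),
    "excluding")
  expect_false("H02" %in% rownames(ft3$features))
})

test_that("feature extraction is deterministic for a fixed cohort", {
  coh <- tiny_cohort(n_per_class = 1, channels = 2, duration_s = 0.4)
  ft1 <- suppressWarnings(
    do.call(assemble_features, c(list(coh), fast_feature_args())))
  ft2 <- suppressWarnings(
    do.call(assemble_features, c(list(coh), fast_feature_args())))
  expect_identical(ft1$features, ft2$features)
})

test_that("entropy heatmaps aggregate per group with the right bounds", {
  coh <- tiny_cohort(n_per_class = 2, channels = 2, duration_s = 0.4)
  ft <- suppressWarnings(
    do.call(assemble_features, c(list(coh), fast_feature_args())))
  hm <- entropy_heatmap(ft)
  expect_named(hm, c("H", "MDD"))
  expect_equal(dim(hm$H), c(2L, 3L))
  # single-subject group equals that subject's entropies
  hm1 <- entropy_heatmap(ft, group_labels = ft$subject_ids)
  ent_h01 <- -(ft$features["H01", "EC.ch1.e_left"] +
                 ft$features["H01", "EC.ch1.e_mid"] +
                 ft$features["H01", "EC.ch1.e_right"])
  expect_equal(hm1$H01["ch1", "EC"], ent_h01)
  # group mean lies between the per-subject extremes
  rows <- which(ft$labels == "H")
  ent_all <- vapply(rows, function(i)
    -(ft$features[i, "EC.ch1.e_left"] + ft$features[i, "EC.ch1.e_mid"] +
        ft$features[i, "EC.ch1.e_right"]), numeric(1))
  expect_gte(hm$H["ch1", "EC"], min(ent_all))
  expect_lte(hm$H["ch1", "EC"], max(ent_all))
  expect_error(entropy_heatmap(ft, group_labels = rep("g", 3)), "one entry")
})
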
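make_gaussian_classes <- function(n = 30, delta = 3, p = 6, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n * p), n, p),
             matrix(rnorm(n * p, mean = delta), n, p))
  list(X = X, y = rep(c("H", "MDD"), each = n))
}

test_that("bagged trees separate well-separated classes and are reproducible", {
  d <- make_gaussian_classes()
  fit <- train_badt(d$X, d$y, ntree = 100, seed = 3)
  expect_equal(mean(predict(fit, d$X) == d$y), 1)
  p1 <- predict(train_badt(d$X, d$y, ntree = 50, seed = 7), d$X)
  p2 <- predict(train_badt(d$X, d$y, ntree = 50, seed = 7), d$X)
  expect_identical(p1, p2)
  expect_error(train_badt(d$X, rep("H", nrow(d$X))), "two classes")
  Xna <- d$X; Xna[1, 1] <- NA
  expect_error(train_badt(Xna, d$y), "missing")
})

test_that("permuted labels drive cross-validated accuracy to chance", {
  d <- make_gaussian_classes(n = 20, delta = 3, p = 4)
  set.seed(99)
  y_perm <- sample(d$y)
  rep_null <- evaluate_cv("badt", d$X, y_perm, folds = 5, reps = 20,
                          seed = 2, ntree = 60)
  se <- stats::sd(rep_null$metrics[, "accuracy"]) / sqrt(20)
  expect_lt(abs(rep_null$mean[["accuracy"]] - 0.5), max(3 * se, 0.12))
})

test_that("Gaussian naive Bayes recovers the analytic decision boundary", {
  # equal priors and unit variances: the boundary is the midpoint of means
  set.seed(5)
  n <- 4000
  X <- matrix(c(rnorm(n, 0), rnorm(n, 2)), ncol = 1)
  y <- rep(c("A", "B"), each = n)
  fit <- train_gnb(X, y)
  grid <- matrix(seq(0.5, 1.5, by = 0.005), ncol = 1)
  pred <- predict(fit, grid)
  boundary <- grid[max(which(pred == "A"))]
  expect_equal(as.numeric(boundary), 1, tolerance = 0.1)
  # identical class distributions: accuracy near the majority prior
  X0 <- matrix(rnorm(600), ncol = 2)
  y0 <- rep(c("A", "B"), each = 150)
  r <- evaluate_cv("gnb", X0, y0, folds = 5, reps = 10, seed = 4)
  expect_lt(r$mean[["accuracy"]], 0.65)
  # deterministic given data
  expect_identical(predict(train_gnb(X, y), grid),
                   predict(train_gnb(X, y), grid))
})

test_that("zero-variance features are floored with a warning", {
  X <- cbind(rep(1, 40), rnorm(40))
  y <- rep(c("A", "B"), each = 20)
  expect_warning(fit <- train_gnb(X, y), "floored")
  expect_true(all(is.finite(attr(predict(fit, X, type = "prob"), "dim"))))
})

test_that("confusion-matrix metrics follow their definitions", {
  m <- suddency:::confusion_metrics(tp = 16, fn = 1, tn = 14, fp = 1)
  expect_equal(m[["sensitivity"]], 16 / 17, tolerance = 1e-12)
  expect_equal(m[["specificity"]], 14 / 15, tolerance = 1e-12)
  expect_equal(m[["accuracy"]], 30 / 32, tolerance = 1e-12)
})

test_that("cross-validation reports are reproducible and internally consistent", {
  d <- make_gaussian_classes(n = 15, delta = 2.5, p = 4)
  r1 <- evaluate_cv("badt", d$X, d$y, folds = 5, reps = 5, seed = 11,
                    ntree = 60)
  r2 <- evaluate_cv("badt", d$X, d$y, folds = 5, reps = 5, seed = 11,
                    ntree = 60)
  expect_identical(r1$metrics, r2$metrics)
  expect_true(all(r1$metrics >= 0 & r1$metrics <= 1))
  conf <- r1$confusion
  expect_equal(unname((conf[1, 1] + conf[2, 2]) / sum(conf)),
               mean(r1$metrics[, "accuracy"]), tolerance = 0.05)
  expect_equal(r1$se, apply(r1$metrics, 2, stats::sd) / sqrt(5))
  # a perfectly separated problem scores 1 with zero standard error
  dsep <- make_gaussian_classes(n = 15, delta = 8, p = 4)
  rs <- evaluate_cv("gnb", dsep$X, dsep$y, folds = 5, reps = 3, seed = 1)
  expect_equal(unname(rs$mean), c(1, 1, 1))
  expect_equal(unname(rs$se), c(0, 0, 0))
})

test_that("imputation happens inside training folds", {
  d <- make_gaussian_classes(n = 15, delta = 4, p = 3)
  Xna <- d$X
  Xna[cbind(sample(nrow(Xna), 8), sample(ncol(Xna), 8, replace = TRUE))] <- NA
  r <- evaluate_cv("gnb", Xna, d$y, folds = 5, reps = 3, seed = 2)
  expect_true(all(is.finite(r$mean)))
  expect_gt(r$mean[["accuracy"]], 0.8)
})

test_that("mixed-label augmentation behaves at its boundaries", {
  d <- make_gaussian_classes(n = 20, delta = 6, p = 4)
  expect_identical(mixed_label_augmentation(d$X, d$y, threshold = 0),
                   factor(d$y))
  # wide separation: all out-of-bag margins are large, nothing is relabeled
  aug <- mixed_label_augmentation(d$X, d$y, threshold = 0.1, ntree = 100,
                                  seed = 1)
  expect_identical(as.character(aug), d$y)
  # an intermediate cluster gets flagged as the latent sub-type
  set.seed(13)
  Xm <- rbind(matrix(rnorm(60), 15, 4),
              matrix(rnorm(60, 6), 15, 4),
              matrix(rnorm(24, 3, 0.3), 6, 4))
  ym <- c(rep("H", 15), rep("MDD", 15), rep(c("H", "MDD"), 3))
  aug2 <- mixed_label_augmentation(Xm, ym, threshold = 0.35, ntree = 150,
                                   seed = 2)
  expect_true("Mixed" %in% levels(aug2))
  expect_gt(sum(aug2 == "Mixed"), 0)
  # the augmented pass still scores the binary problem
  r <- evaluate_cv("badt", Xm, ym, folds = 5, reps = 3, seed = 3,
                   ntree = 80, mixed = TRUE, mixed_threshold = 0.35)
  expect_true(all(is.finite(r$mean)))
})
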
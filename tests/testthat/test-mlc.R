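test_that("stratified split respects fractions and determinism", {
  labels <- rep(c("a", "b", "c"), each = 100)
  sp <- split_samples(labels, 0.7, seed = 1)
  expect_length(sp$train, 210)
  expect_length(sp$test, 90)
  expect_length(intersect(sp$train, sp$test), 0)
  for (cl in c("a", "b", "c")) {
    expect_equal(sum(labels[sp$train] == cl), 70)
  }
  sp2 <- split_samples(labels, 0.7, seed = 1)
  expect_identical(sp, sp2)
  expect_error(split_samples(rep(c("a", "b"), c(10, 100)), 0.999, seed = 1),
               "too small")
})

test_that("class estimators are the textbook mean and n-1 covariance", {
  d <- data.frame(class = "a", x = c(0, 2, 1, 3))
  fit <- mlc(class ~ x, rbind(d, data.frame(class = "b", x = c(9, 11, 10, 12))))
  expect_equal(unname(fit$fits$a$mean), 1.5)
  # stored covariance carries the default regularization ridge (1e-6)
  expect_equal(unname(fit$fits$a$cov[1, 1]), var(c(0, 2, 1, 3)),
               tolerance = 1e-5)
})

test_that("two 1-D equal-variance classes split at the midpoint", {
  train <- data.frame(class = rep(c("c1", "c2"), each = 3),
                      x = c(-1, 0, 1, 1, 2, 3))   # means 0 and 2, var 1
  fit <- mlc(class ~ x, train)
  expect_equal(as.character(predict(fit, data.frame(x = 0.9))), "c1")
  expect_equal(as.character(predict(fit, data.frame(x = 1.1))), "c2")
  g <- predict(fit, data.frame(x = 1), type = "discriminant")
  expect_lt(abs(g[1, "c1"] - g[1, "c2"]), 1e-9)
})

test_that("equal spherical covariances reduce to nearest centroid", {
  # cross-shaped cloud: sample covariance exactly spherical (2/3 * I)
  base <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  centers <- list(a = c(0, 0), b = c(4, 0), c = c(0, 4))
  train <- do.call(rbind, lapply(names(centers), function(cl) {
    data.frame(class = cl, x1 = base[, 1] + centers[[cl]][1],
               x2 = base[, 2] + centers[[cl]][2])
  }))
  fit <- mlc(class ~ x1 + x2, train)
  set.seed(3)
  new <- data.frame(x1 = runif(200, -2, 6), x2 = runif(200, -2, 6))
  pred <- as.character(predict(fit, new))
  nearest <- apply(new, 1, function(p) {
    names(centers)[which.min(sapply(centers, function(ce) sum((p - ce)^2)))]
  })
  expect_identical(pred, nearest)
})

test_that("classification matches an independent quadratic-discriminant
          oracle on random pixels", {
  set.seed(4)
  k <- 3
  means <- list(c(0, 0), c(2.5, 1), c(-1, 3))
  mkcov <- function(a, b, r) matrix(c(a, r, r, b), 2)
  covs <- list(mkcov(1, 0.5, 0.2), mkcov(0.6, 1.2, -0.3), mkcov(2, 0.8, 0.5))
  train <- do.call(rbind, lapply(1:k, function(cl) {
    z <- matrix(rnorm(2 * 400), ncol = 2) %*% chol(covs[[cl]])
    data.frame(class = paste0("c", cl), x1 = z[, 1] + means[[cl]][1],
               x2 = z[, 2] + means[[cl]][2])
  }))
  fit <- mlc(class ~ x1 + x2, train, ridge = 0)
  x <- cbind(runif(10000, -4, 6), runif(10000, -3, 6))
  pred <- as.integer(predict(fit, data.frame(x1 = x[, 1], x2 = x[, 2])))
  fitted_means <- lapply(fit$fits, function(f) f$mean)
  fitted_covs <- lapply(fit$fits, function(f) f$cov)
  oracle <- oracle_qda_labels(x, fitted_means, fitted_covs, fit$prior)
  expect_identical(pred, as.integer(oracle))
})

test_that("degenerate covariance is repaired by ridge escalation", {
  train <- data.frame(class = rep(c("a", "b"), each = 6),
                      x1 = c(rnorm(6), rnorm(6) + 5))
  train$x2 <- train$x1                     # duplicated feature -> singular
  expect_warning(fit <- mlc(class ~ x1 + x2, train), "ridge")
  expect_s3_class(fit, "mlc")
})

test_that("decisions are invariant to affine rescaling of a feature", {
  set.seed(6)
  train <- data.frame(class = rep(c("a", "b"), each = 80),
                      x1 = c(rnorm(80), rnorm(80) + 2),
                      x2 = c(rnorm(80, sd = 2), rnorm(80, 1, 2)))
  new <- data.frame(x1 = rnorm(300, 1), x2 = rnorm(300, 0.5, 2))
  fit <- mlc(class ~ x1 + x2, train, ridge = 1e-12)
  p0 <- predict(fit, new)
  tr2 <- train; nw2 <- new
  tr2$x1 <- 3.7 * tr2$x1 - 12; nw2$x1 <- 3.7 * nw2$x1 - 12
  fit2 <- mlc(class ~ x1 + x2, tr2, ridge = 1e-12)
  expect_gte(mean(predict(fit2, nw2) == p0), 1 - 1e-8)
})

test_that("confusion metrics match hand arithmetic and the zero-denominator
          rule", {
  # counts (rows = predicted): [[50, 10], [5, 35]]
  pred <- c(rep("s", 50), rep("s", 10), rep("w", 5), rep("w", 35))
  ref <- c(rep("s", 50), rep("w", 10), rep("s", 5), rep("w", 35))
  cm <- confusion_accuracy(pred, ref)
  expect_equal(cm$oa, 0.85)
  expect_equal(unname(cm$pa), c(50 / 55, 35 / 45), tolerance = 1e-12)
  expect_equal(unname(cm$ua), c(50 / 60, 35 / 40), tolerance = 1e-12)

  perfect <- confusion_accuracy(c("a", "b"), c("a", "b"))
  expect_equal(perfect$oa, 1)
  expect_true(all(perfect$pa == 1) && all(perfect$ua == 1))

  one <- confusion_accuracy(rep("a", 5), rep("a", 5), classes = c("a", "b"))
  expect_equal(one$oa, 1)
  expect_true(is.nan(one$pa[["b"]]))
  expect_error(confusion_accuracy("z", "a", classes = c("a", "b")),
               "outside")
})

test_that("OA equals the reference-frequency-weighted mean of PA", {
  set.seed(8)
  for (rep in 1:10) {
    k <- sample(2:5, 1)
    counts <- matrix(rpois(k * k, 20), k)
    pred <- rep(rep(paste0("c", 1:k), k), as.vector(counts))
    ref <- rep(paste0("c", rep(1:k, each = k)), as.vector(counts))
    cm <- confusion_accuracy(pred, ref)
    w <- colSums(cm$counts) / sum(cm$counts)
    expect_equal(cm$oa, sum(ifelse(w > 0, w * cm$pa, 0)), tolerance = 1e-12)
  }
})

test_that("noiseless distinct class means classify the scene exactly", {
  fr <- c(A_marina = 0.4, R_stylosa = 0.3, soil = 0.3)
  smap <- generate_species_map(60, 60, fr, patch_scale = 10, seed = 11)
  sigs <- list(
    A_marina = species_signature("A_marina", c(0.1, 0.2, 0.1, 0.3, 0.5), 0,
                                 height_mean = 2.4, density = 9280),
    R_stylosa = species_signature("R_stylosa", c(0.05, 0.1, 0.06, 0.35, 0.6),
                                  0, height_mean = 4.7, density = 7480),
    soil = species_signature("soil", c(0.2, 0.22, 0.3, 0.3, 0.3), 0)
  )
  scene <- generate_scene(smap, sigs, seed = 12)
  stack <- scene$bands
  class(stack) <- "feature_stack"
  # train on noiseless pixels: covariance singular, repaired by ridge
  labels <- label_values(smap)
  df <- as.data.frame(stack_matrix(stack, band_names()))
  names(df) <- band_names()
  df$class <- as.vector(labels)
  suppressWarnings(fit <- mlc(class ~ B + G + R + RE + NIR, df))
  pred <- classify_raster(fit, stack)
  expect_equal(attr(pred, "classes")[pred$values],
               as.vector(labels))
})

test_that("combination ranking is deterministic and duplicate-stable", {
  fr <- c(A_marina = 0.5, soil = 0.5)
  smap <- generate_species_map(60, 60, fr, patch_scale = 10, seed = 13)
  scene <- generate_scene(smap, default_signatures(0.02), seed = 14)
  stack <- feature_stack(scene, indices = c("NDVI", "GNDVI"))
  combos <- list(A = c("B", "G", "R"), B = c("B", "G", "R"),
                 C = c("NDVI", "GNDVI"))
  ev <- evaluate_combinations(smap, stack, combos, seed = 15,
                              max_per_class = 500)
  expect_equal(nrow(ev$ranking), 3)
  oa <- ev$ranking$oa[match(c("A", "B"), ev$ranking$combination)]
  expect_equal(oa[1], oa[2])          # duplicates identical under one seed
})
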
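test_that("Pearson screening matches hand arithmetic", {
  d <- data.frame(x = c(1, 2, 3), y = c(3, 2, 1), resp = c(3, 5, 7))
  sc <- pearson_screen(d, "resp", predictors = c("x", "y"))
  expect_equal(sc$r[sc$variable == "x"], 1, tolerance = 1e-12)
  expect_equal(sc$r[sc$variable == "y"], -1, tolerance = 1e-12)

  d2 <- data.frame(x = c(1, 2, 3, 4), resp = c(1, 3, 2, 4))
  sc2 <- pearson_screen(d2, "resp", predictors = "x")
  expect_equal(sc2$r, 0.8, tolerance = 1e-12)

  dz <- data.frame(x = rep(1, 5), resp = rnorm(5))
  expect_error(pearson_screen(dz, "resp", predictors = "x"), "degenerate")
})

test_that("OLS coefficients match the normal-equations oracle", {
  set.seed(1)
  for (rep in 1:10) {
    n <- sample(8:15, 1); p <- sample(1:3, 1)
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("v", 1:p)))
    y <- rnorm(n)
    d <- data.frame(x, resp = y)
    m <- carbon_lm(reformulate(colnames(x), "resp"), d)
    expect_equal(unname(coef(m)), unname(oracle_ols(x, y)),
                 tolerance = 1e-8)
  }
})

test_that("exact lines are recovered with R2 = 1 and rejected null fits", {
  d <- data.frame(x = c(1, 2, 3), resp = c(3, 5, 7))
  m <- suppressWarnings(carbon_lm(resp ~ x, d))   # perfect-fit warning
  expect_equal(unname(coef(m)), c(1, 2), tolerance = 1e-10)
  expect_equal(m$fit_r2, 1, tolerance = 1e-10)

  dconst <- data.frame(x = rnorm(8), resp = rep(2, 8))
  uni <- suppressWarnings(fit_univariate(dconst, "resp", predictors = "x"))
  expect_false(uni$retained)
  expect_null(uni$model)
})

test_that("VIF matches 1/(1 - R2) and flags perfect collinearity", {
  # orthogonal design -> both VIFs 1
  x <- cbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1))
  expect_equal(unname(vif(x)), c(1, 1), tolerance = 1e-12)

  # duplicated predictor -> infinite
  set.seed(2)
  z <- rnorm(10)
  expect_true(all(is.infinite(vif(cbind(a = z, b = z)))))

  # constructed R2 = 0.96 -> VIF 25
  set.seed(3)
  x1 <- rnorm(200)
  e <- rnorm(200)
  e <- residuals(lm(e ~ x1))                       # orthogonalize
  e <- e / sd(e) * sd(x1) * sqrt(1 / 0.96 - 1)     # fix sample R2
  x2 <- x1 + e
  v <- vif(cbind(x1, x2))
  expect_equal(unname(v[2]), 25, tolerance = 0.5)

  expect_error(vif(matrix(rnorm(3), ncol = 3)), "underdetermined")
})

test_that("LOOCV folds match four hand OLS fits", {
  d <- data.frame(x = c(0, 1, 2, 3), resp = c(0, 1, 2, 9))
  cv <- loocv(d, "x", "resp")
  manual <- vapply(1:4, function(i) {
    co <- oracle_ols(d$x[-i], d$resp[-i])
    co[1] + co[2] * d$x[i]
  }, numeric(1))
  expect_equal(cv$predictions, manual, tolerance = 1e-10)
  expect_equal(cv$loocv_rmse, sqrt(mean((d$resp - manual)^2)),
               tolerance = 1e-10)

  # noiseless exact fit: RMSE 0, R2 1
  de <- data.frame(x = 1:6, resp = 2 * (1:6) + 1)
  cve <- loocv(de, "x", "resp")
  expect_equal(cve$loocv_rmse, 0, tolerance = 1e-10)
  expect_equal(cve$loocv_r2, 1, tolerance = 1e-10)
})

test_that("LOOCV R2 of pure noise is negative in expectation", {
  set.seed(4)
  r2 <- replicate(100, {
    d <- data.frame(x = rnorm(10), resp = rnorm(10))
    loocv(d, "x", "resp")$loocv_r2
  })
  expect_lt(mean(r2), 0)
})

test_that("multivariate search applies VIF and significance filters", {
  set.seed(5)
  z <- rnorm(12)
  d <- data.frame(x = z, xc = z, resp = 3 * z + rnorm(12, sd = 0.1))
  res <- fit_multivariate(d, "resp", predictors = c("x", "xc"))
  expect_null(res$model)                    # collinear universe
  expect_true(all(grepl("rejected", res$report$status)))

  a <- rnorm(40); b <- rnorm(40)
  d2 <- data.frame(a = a, b = b, resp = 3 * a - 2 * b + rnorm(40, sd = 0.3))
  res2 <- fit_multivariate(d2, "resp", predictors = c("a", "b"))
  expect_setequal(res2$model$predictors, c("a", "b"))
  expect_gt(coef(res2$model)[["a"]], 0)
  expect_lt(coef(res2$model)[["b"]], 0)

  # cardinality contract: max_terms 2 -> at most 3 coefficients
  d3 <- data.frame(a = a, b = b, cc = rnorm(40),
                   resp = a + b + rnorm(40, sd = 0.2))
  res3 <- fit_multivariate(d3, "resp", predictors = c("a", "b", "cc"),
                           max_terms = 2)
  expect_lte(length(coef(res3$model)), 3)
})

test_that("candidate species groups count 4 singletons plus 11 subsets", {
  set.seed(6)
  sp <- mangrove_species()
  d <- do.call(rbind, lapply(seq_along(sp), function(i) {
    h <- rnorm(10, 2 + i, 0.5)
    data.frame(species = sp[i], H_Mean = h,
               agc = 10 * h + rnorm(10, sd = 1),
               bgc = 3 * h + rnorm(10, sd = 0.5))
  }))
  reg <- select_models(d, responses = "agc")
  expect_equal(nrow(reg$agc$candidates), 15)
  # every species covered exactly once
  covered <- unlist(lapply(reg$agc$models, function(m) m$species_group))
  expect_setequal(covered, sp)
  expect_equal(anyDuplicated(covered), 0)
})

test_that("single-species input yields that species' individual model", {
  set.seed(7)
  h <- rnorm(10, 3, 0.6)
  d <- data.frame(species = "R_stylosa", H_Mean = h,
                  agc = 20 * h + rnorm(10))
  reg <- select_models(d, responses = "agc")
  expect_equal(names(reg$agc$models), "R_stylosa")
})

test_that("model registry JSON round-trips coefficients and routing", {
  reg <- example_model_registry()
  path <- tempfile(fileext = ".json")
  write_model_registry(reg, path)
  reg2 <- read_model_registry(path)
  m <- reg2$agc$models[["A_marina+R_stylosa"]]
  expect_equal(unname(m$coefficients), c(-28.49, 33.50))
  expect_equal(predict(m, data.frame(H_Mean = 2)), 38.51, tolerance = 1e-12)
})
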
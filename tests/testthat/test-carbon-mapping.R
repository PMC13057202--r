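constant_stack <- function(values, nr = 6, nc = 6, px = 1) {
  out <- lapply(values, function(v) raster_create(matrix(v, nr, nc),
                                                  pixel_size = px))
  class(out) <- "feature_stack"
  out
}

label_map <- function(codes, classes, px = 1) {
  r <- raster_create(codes, pixel_size = px)
  attr(r, "classes") <- classes
  r
}

test_that("routed models evaluate the printed equations per pixel", {
  cls <- c("A_marina", "A_corniculatum", "soil")
  codes <- matrix(1L, 4, 4); codes[, 3] <- 2L; codes[, 4] <- 3L
  smap <- label_map(codes, cls)
  stack <- constant_stack(list(H_Mean = 2.0, RE_Mean = 30, B_Var = 0.3,
                               R_Con = 1, NIR_Hom = 0.8, B_Con = 1),
                          nr = 4, nc = 4)
  maps <- apply_models(smap, stack)
  # A. marina pixel, H_Mean = 2: AGC = 33.50*2 - 28.49, BGC = 9.20*2 + 2.75
  expect_equal(maps$agc$values[1, 1], 38.51, tolerance = 1e-12)
  expect_equal(maps$bgc$values[1, 1], 21.15, tolerance = 1e-12)
  # TGC adds the species soil constant
  expect_equal(maps$tgc$values[1, 1] - maps$agc$values[1, 1] -
                 maps$bgc$values[1, 1], 177.37, tolerance = 1e-12)
  # A. corniculatum pixel, RE_Mean = 30: AGC = 20.07*30 - 464.53 = 137.57
  expect_equal(maps$agc$values[1, 3], 20.07 * 30 - 464.53,
               tolerance = 1e-12)
  # soil is not a mangrove: nodata
  expect_true(is.na(maps$agc$values[1, 4]))
})

test_that("negative predictions clamp to zero and are counted", {
  cls <- "A_corniculatum"
  smap <- label_map(matrix(1L, 2, 2), cls)
  stack <- constant_stack(list(RE_Mean = 1), nr = 2, nc = 2)  # 20.07-464.53<0
  maps <- apply_models(smap, stack)
  expect_true(all(maps$agc$values == 0))
  expect_equal(maps$clamp_count, 8)   # 4 px AGC + 4 px BGC
})

test_that("TGC is additive pixel-wise over the whole map", {
  fr <- default_test_fractions()
  smap <- generate_species_map(80, 80, fr, patch_scale = 12, seed = 3)
  stack <- constant_stack(list(H_Mean = 3, RE_Mean = 28, B_Var = 0.25,
                               R_Con = 1.2, NIR_Hom = 0.7, B_Con = 0.9),
                          nr = 80, nc = 80, px = 0.53)
  soil <- soil_carbon_table()
  maps <- apply_models(smap, stack, soil = soil)
  cls <- attr(smap, "classes")
  soil_px <- matrix(soil[cls[smap$values]], 80, 80)
  # bit-identical to recomputing the same sum
  recomputed <- maps$agc$values + maps$bgc$values + soil_px
  expect_identical(maps$tgc$values[!is.na(maps$tgc$values)],
                   recomputed[!is.na(recomputed)])
  expect_error(apply_models(smap, constant_stack(list(H_Mean = 1), 80, 80)),
               "lacks predictor")
})

test_that("uncovered species fail loudly", {
  smap <- label_map(matrix(1L, 2, 2), "A_marina")
  reg <- model_registry(list(
    carbon_model("agc", "R_stylosa", 0, c(H_Mean = 1)),
    carbon_model("bgc", "R_stylosa", 0, c(H_Mean = 1))))
  expect_error(apply_models(smap, constant_stack(list(H_Mean = 1), 2, 2),
                            reg), "A_marina")
})

test_that("species summary is internally consistent", {
  cls <- c("A_marina", "R_stylosa")
  codes <- matrix(1L, 10, 10); codes[6:10, ] <- 2L
  smap <- label_map(codes, cls, px = 20)    # big pixels: 50 px = 2 hm2
  stack <- constant_stack(list(H_Mean = 2), nr = 10, nc = 10, px = 20)
  maps <- apply_models(smap, stack)
  summ <- species_summary(maps, smap)
  expect_equal(summ$area_hm2, c(2, 2))
  # uniform field: mean * area = total, proportions sum to 100
  expect_equal(summ$total_agc_t, summ$mean_agc * summ$area_hm2,
               tolerance = 1e-12)
  expect_equal(sum(summ$pct_agc), 100, tolerance = 1e-9)
  expect_equal(sum(summ$pct_bgc), 100, tolerance = 1e-9)
  # independent accumulation: total equals pixel-wise sum x pixel area
  px_area_hm2 <- 20^2 / 1e4
  for (i in seq_along(cls)) {
    mask <- codes == i
    expect_equal(summ$total_agc_t[summ$species == cls[i]],
                 sum(maps$agc$values[mask]) * px_area_hm2,
                 tolerance = 1e-6)
  }
})

test_that("transects sample distances and pixel values correctly", {
  r <- raster_create(matrix(40, 20, 20), pixel_size = 1)
  line <- rbind(c(0.5, 10), c(10.5, 10))
  tr <- transect_profile(r, line, step_m = 2.5)
  expect_equal(tr$distance, c(0, 2.5, 5, 7.5, 10))
  expect_true(all(tr$value == 40))

  # step-function raster: profile transitions near the crossing point
  m <- matrix(1, 20, 20); m[, 11:20] <- 9
  r2 <- raster_create(m, pixel_size = 1)
  tr2 <- transect_profile(r2, rbind(c(0.5, 5), c(19.5, 5)), step_m = 1)
  crossing <- tr2$distance[min(which(tr2$value == 9))]
  expect_lte(abs(crossing - 9.5), 1)  # boundary at x = 10, start at 0.5

  expect_error(transect_profile(r, rbind(c(100, 100), c(110, 100)), 1),
               "outside")
})
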
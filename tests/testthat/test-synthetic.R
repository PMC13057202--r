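test_that("species map respects fractions, contiguity and determinism", {
  # degenerate fractions: one class everywhere
  m1 <- generate_species_map(20, 20, c(A_marina = 1), patch_scale = 5,
                             seed = 1)
  expect_true(all(m1$values == 1))

  # same seed twice -> identical rasters
  fr <- c(A_marina = 0.5, soil = 0.5)
  a <- generate_species_map(100, 100, fr, patch_scale = 10, seed = 9)
  b <- generate_species_map(100, 100, fr, patch_scale = 10, seed = 9)
  expect_identical(a$values, b$values)

  # realized fraction close to requested across seeds
  for (s in 1:10) {
    m <- generate_species_map(100, 100, fr, patch_scale = 10, seed = s)
    expect_equal(mean(m$values == 1), 0.5, tolerance = 0.05)
  }

  expect_error(generate_species_map(10, 10, c(A_marina = 0.6, soil = 0.5),
                                    seed = 1), "sum to 1")
})

test_that("scene generation reproduces the class distributions", {
  fr <- c(R_stylosa = 0.5, soil = 0.5)
  smap <- generate_species_map(150, 150, fr, patch_scale = 20, seed = 2)
  sigs <- default_signatures(band_sd = 0.01)
  scene <- generate_scene(smap, sigs, seed = 3)

  mask <- smap$values == 1
  expect_gte(sum(mask), 1e4)
  # sample means of band values within 3 SE of the signature means
  for (b in seq_along(band_names())) {
    vals <- scene$bands[[b]]$values[mask]
    se <- 0.01 / sqrt(sum(mask))
    mu <- sigs$R_stylosa$band_means[b]
    # smoothing correlates pixels; allow a generous multiple of the iid SE
    expect_lt(abs(mean(vals) - mu), max(30 * se, 0.003))
  }
  # canopy height: mean of dsm - dtm_true near 4.73 (tall species)
  h <- scene$dsm$values[mask] - scene$dtm_true$values[mask]
  expect_gte(mean(h), 4.5)
  expect_lte(mean(h), 5.0)
  # non-vegetation has zero canopy height
  h0 <- scene$dsm$values[!mask] - scene$dtm_true$values[!mask]
  expect_equal(max(abs(h0)), 0)
  # dsm >= dtm everywhere
  expect_true(all(scene$dsm$values - scene$dtm_true$values >= 0))
})

test_that("noiseless signatures give constant class values", {
  fr <- c(A_marina = 0.6, soil = 0.4)
  smap <- generate_species_map(40, 40, fr, patch_scale = 8, seed = 5)
  sigs <- list(
    A_marina = species_signature("A_marina", c(0.1, 0.2, 0.1, 0.3, 0.5),
                                 band_cov = 0, height_mean = 2.44,
                                 height_sd = 0, density = 9280),
    soil = species_signature("soil", c(0.2, 0.25, 0.3, 0.3, 0.3),
                             band_cov = 0)
  )
  scene <- generate_scene(smap, sigs, seed = 6)
  mask <- smap$values == 1
  for (b in 1:5) {
    expect_equal(stats::sd(scene$bands[[b]]$values[mask]), 0)
  }
  h <- scene$dsm$values - scene$dtm_true$values
  expect_true(all(abs(h[mask] - 2.44) < 1e-12))

  expect_error(generate_scene(smap, sigs["soil"], seed = 1),
               "missing signature")
})

test_that("determinism: same seeds give bit-identical scenes and plots", {
  fr <- default_test_fractions()
  s1 <- generate_scene(generate_species_map(120, 120, fr, 15, seed = 4),
                       default_signatures(), seed = 5)
  s2 <- generate_scene(generate_species_map(120, 120, fr, 15, seed = 4),
                       default_signatures(), seed = 5)
  expect_identical(s1$bands$NIR$values, s2$bands$NIR$values)
  expect_identical(s1$dsm$values, s2$dsm$values)
  p1 <- sample_plots(s1, n_per_species = 3, seed = 7)
  p2 <- sample_plots(s2, n_per_species = 3, seed = 7)
  expect_identical(plots_to_table(p1), plots_to_table(p2))
})

test_that("plot sampling honors the field design", {
  fr <- default_test_fractions()
  smap <- generate_species_map(200, 200, fr, patch_scale = 15, seed = 1)
  scene <- generate_scene(smap, default_signatures(), seed = 2)
  plots <- sample_plots(scene, n_per_species = 10, seed = 3)
  expect_length(plots, 40)                      # 10 plots x 4 species
  tab <- plots_to_table(plots)
  expect_equal(as.vector(table(tab$species)), rep(10L, 4))

  # plots are non-overlapping squares inside the scene
  polys <- lapply(plots, function(p) p$polygon)
  for (i in seq_along(polys)) {
    expect_true(all(polys[[i]][, 1] >= scene$bands$B$xmin))
    expect_true(all(polys[[i]][, 2] <= scene$bands$B$ymax))
    for (j in seq_along(polys)) {
      if (i >= j) next
      ix <- min(polys[[i]][, 1]) < max(polys[[j]][, 1]) &&
        max(polys[[i]][, 1]) > min(polys[[j]][, 1])
      iy <- min(polys[[i]][, 2]) < max(polys[[j]][, 2]) &&
        max(polys[[i]][, 2]) > min(polys[[j]][, 2])
      expect_false(ix && iy)
    }
  }

  # tree counts follow density x area (A. marina: 9280/hm2 * 25 m2 = 23.2)
  am <- tab[tab$species == "A_marina", ]
  expect_gte(mean(am$n_trees), 16)
  expect_lte(mean(am$n_trees), 30)

  # carbon stored on the plots reproduces the registry exactly (closure)
  reg <- default_allometry()
  for (p in plots[c(1, 15, 35)]) {
    cc <- plot_carbon(p$trees, p$species_id, reg, plot_area = 25)
    expect_identical(cc$agc, p$agc)
    expect_identical(cc$bgc, p$bgc)
  }
})

test_that("tree count expectation matches density * area arithmetic", {
  # 100 simulated plots at A. marina density: mean count within [21, 25]
  set.seed(10)
  counts <- rpois(100, 9280 * 25 / 1e4)
  expect_gte(mean(counts), 21)
  expect_lte(mean(counts), 25)
})

test_that("default signatures satisfy the ordinal spectral constraints", {
  sigs <- default_signatures()
  for (sp in mangrove_species()) {
    bm <- sigs[[sp]]$band_means
    expect_gt(bm[["G"]], bm[["R"]])   # G highest of the visible bands
    expect_gt(bm[["G"]], bm[["B"]])
    expect_lt(bm[["B"]], bm[["R"]])   # B lowest
  }
  bm <- function(sp, b) sigs[[sp]]$band_means[[b]]
  expect_true(all(bm("R_stylosa", "R") < sapply(setdiff(mangrove_species(),
    "R_stylosa"), bm, "R")))
  expect_true(all(bm("R_stylosa", "G") < sapply(setdiff(mangrove_species(),
    "R_stylosa"), bm, "G")))
  expect_true(all(bm("B_gymnorrhiza", "R") > sapply(setdiff(
    mangrove_species(), "B_gymnorrhiza"), bm, "R")))
  expect_true(all(bm("A_marina", "B") > sapply(setdiff(mangrove_species(),
    "A_marina"), bm, "B")))
})
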
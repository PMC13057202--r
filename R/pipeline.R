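#' Pipeline configuration
#'
#' Assembles and validates the configuration for the five-stage workflow
#' (`simulate`, `features`, `classify`, `model`, `map`). All randomness
#' derives from the single root `seed` (each stage uses a fixed offset from
#' it).
#'
#' @param nrow,ncol synthetic scene size (pixels).
#' @param pixel_size working resolution (m); 0.53 m default.
#' @param seed root random seed (integer).
#' @param fractions named land-cover fractions for the species map.
#' @param patch_scale patch correlation length (pixels).
#' @param band_sd reflectance noise level (separability dial).
#' @param n_plots_per_species,plot_side field-plot sampling design
#'   (10 plots of 5 m per species by default).
#' @param n_gcps number of ground control points surveyed from the true
#'   terrain.
#' @param idw_power,idw_points terrain interpolation parameters.
#' @param glcm_window,glcm_levels texture parameters.
#' @param combinations feature combinations for the classifier comparison
#'   (default [default_combinations()]).
#' @param vif_detect,vif_accept,p_threshold,max_terms model-selection
#'   thresholds.
#' @param soil per-species soil carbon (t/hm²).
#' @param max_per_class labeled-pixel cap per class in classifier scoring.
#' @return validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(nrow = 200, ncol = 200, pixel_size = 0.53,
                            seed = 1,
                            fractions = c(B_gymnorrhiza = 0.08,
                                          R_stylosa = 0.20,
                                          A_marina = 0.24,
                                          A_corniculatum = 0.13,
                                          soil = 0.15, water = 0.12,
                                          shadow = 0.08),
                            patch_scale = 15, band_sd = 0.01,
                            n_plots_per_species = 10, plot_side = 5,
                            n_gcps = 60, idw_power = 3, idw_points = 3,
                            glcm_window = 3, glcm_levels = 32,
                            combinations = default_combinations(),
                            vif_detect = 10, vif_accept = 3,
                            p_threshold = 0.05, max_terms = 3,
                            soil = soil_carbon_table(),
                            max_per_class = 2000) {
  cfg <- list(nrow = nrow, ncol = ncol, pixel_size = pixel_size,
              seed = as.integer(seed), fractions = fractions,
              patch_scale = patch_scale, band_sd = band_sd,
              n_plots_per_species = n_plots_per_species,
              plot_side = plot_side, n_gcps = n_gcps,
              idw_power = idw_power, idw_points = idw_points,
              glcm_window = glcm_window, glcm_levels = glcm_levels,
              combinations = combinations, vif_detect = vif_detect,
              vif_accept = vif_accept, p_threshold = p_threshold,
              max_terms = max_terms, soil = soil,
              max_per_class = max_per_class)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$nrow >= 20, cfg$ncol >= 20, cfg$pixel_size > 0,
            abs(sum(cfg$fractions) - 1) < 1e-9, cfg$patch_scale > 0,
            cfg$vif_detect > 0, cfg$vif_accept > 0, cfg$p_threshold > 0,
            cfg$n_gcps >= 5, length(cfg$combinations) >= 1,
            all(cfg$soil > 0))
  invisible(TRUE)
}

#' Read / write a pipeline configuration as JSON
#'
#' `parse -> serialize -> parse` is the identity.
#'
#' @param cfg a `pipeline_config`.
#' @param path JSON file path.
#' @return `read_pipeline_config()` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$fractions <- as.list(out$fractions)   # keep names in JSON
  out$soil <- as.list(out$soil)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  raw$fractions <- unlist(raw$fractions)
  raw$soil <- unlist(raw$soil)
  raw$combinations <- lapply(raw$combinations, unlist)
  do.call(pipeline_config, raw)
}

stage_path <- function(out_dir, ...) file.path(out_dir, ...)

write_label_asc <- function(label, path, legend_path) {
  write_asc(label, path)
  jsonlite::write_json(as.list(stats::setNames(
    seq_along(attr(label, "classes")), attr(label, "classes"))),
    legend_path, auto_unbox = TRUE)
  invisible(path)
}

read_label_asc <- function(path, legend_path) {
  r <- read_asc(path)
  legend <- jsonlite::fromJSON(legend_path)
  cls <- names(sort(unlist(legend)))
  attr(r, "classes") <- cls
  r
}

read_scene_dir <- function(out_dir) {
  bands <- lapply(band_names(), function(b)
    read_asc(stage_path(out_dir, paste0("band_", b, ".asc"))))
  names(bands) <- band_names()
  structure(list(
    bands = bands,
    dsm = read_asc(stage_path(out_dir, "dsm.asc")),
    dtm_true = read_asc(stage_path(out_dir, "dtm_true.asc")),
    species_true = read_label_asc(stage_path(out_dir, "species_true.asc"),
                                  stage_path(out_dir, "legend.json")),
    pixel_size = read_asc(stage_path(out_dir, "dsm.asc"))$pixel_size,
    signatures = NULL
  ), class = "scene")
}

require_artifact <- function(stage, path) {
  if (!file.exists(path)) {
    stop("stage '", stage, "' requires missing artifact: ", path,
         call. = FALSE)
  }
  path
}

#' Run the carbon-assessment pipeline
#'
#' Executes the requested stages in canonical order
#' (`simulate -> features -> classify -> model -> map`), reading upstream
#' artifacts from `out_dir` when a stage is run on its own. Every output
#' file is recorded in a JSON manifest (`manifest.json`) with its MD5 hash,
#' the seed and the package version.
#'
#' Stage outputs (all plain text, under `out_dir`):
#' \itemize{
#'   \item simulate: `band_*.asc`, `dsm.asc`, `dtm_true.asc`,
#'     `species_true.asc` + `legend.json`, `gcps.csv`, `trees.csv`,
#'     `plots.csv`
#'   \item features: `dtm_idw.asc`, `chm.asc`, feature layers
#'     `feat_<name>.asc`, `plot_features.csv`
#'   \item classify: `ranking.csv`, `classified.asc` + `legend.json`
#'   \item model: `models.json`, `model_candidates.csv`
#'   \item map: `agc.asc`, `bgc.asc`, `tgc.asc`, `species_summary.csv`,
#'     `transects.csv`
#' }
#'
#' @param config a `pipeline_config`.
#' @param stages subset of
#'   `c("simulate", "features", "classify", "model", "map")` or `"all"`.
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly (list with `seed`, `version`, `stages`,
#'   `files`).
#' @export
run_pipeline <- function(config, stages = "all", out_dir) {
  validate_config(config)
  canonical <- c("simulate", "features", "classify", "model", "map")
  if (identical(stages, "all")) stages <- canonical
  stopifnot(all(stages %in% canonical))
  stages <- canonical[canonical %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  add <- function(...) files <<- c(files, file.path(out_dir, c(...)))
  seed <- config$seed

  if ("simulate" %in% stages) {
    smap <- generate_species_map(config$nrow, config$ncol, config$fractions,
                                 config$patch_scale, seed = seed,
                                 pixel_size = config$pixel_size)
    sigs <- default_signatures(band_sd = config$band_sd)
    scene <- generate_scene(smap, sigs, seed = seed + 1)
    plots <- sample_plots(scene, config$n_plots_per_species,
                          config$plot_side, seed = seed + 2)
    set.seed(seed + 3)
    co <- raster_coords(scene$dsm)
    gi <- cbind(sample(seq_along(co$y), config$n_gcps, replace = TRUE),
                sample(seq_along(co$x), config$n_gcps, replace = TRUE))
    gi <- unique(gi)
    gcps <- data.frame(x = co$x[gi[, 2]], y = co$y[gi[, 1]],
                       z = scene$dtm_true$values[gi])
    for (b in band_names()) {
      write_asc(scene$bands[[b]], stage_path(out_dir,
                                             paste0("band_", b, ".asc")))
    }
    write_asc(scene$dsm, stage_path(out_dir, "dsm.asc"))
    write_asc(scene$dtm_true, stage_path(out_dir, "dtm_true.asc"))
    write_label_asc(scene$species_true,
                    stage_path(out_dir, "species_true.asc"),
                    stage_path(out_dir, "legend.json"))
    utils::write.csv(gcps, stage_path(out_dir, "gcps.csv"),
                     row.names = FALSE)
    utils::write.csv(plots_to_trees(plots),
                     stage_path(out_dir, "trees.csv"), row.names = FALSE)
    utils::write.csv(plots_to_table(plots),
                     stage_path(out_dir, "plots.csv"), row.names = FALSE)
    add(paste0("band_", band_names(), ".asc"), "dsm.asc", "dtm_true.asc",
        "species_true.asc", "legend.json", "gcps.csv", "trees.csv",
        "plots.csv")
  }

  if ("features" %in% stages) {
    require_artifact("features", stage_path(out_dir, "dsm.asc"))
    scene <- read_scene_dir(out_dir)
    gcps <- utils::read.csv(require_artifact("features",
                                             stage_path(out_dir, "gcps.csv")))
    dtm <- idw_interpolate(gcps, scene$dsm, power = config$idw_power,
                           n_points = config$idw_points)
    chm <- compute_chm(scene$dsm, dtm)
    stack <- feature_stack(scene, chm = chm, textures = TRUE,
                           glcm_window = config$glcm_window,
                           glcm_levels = config$glcm_levels)
    write_asc(dtm, stage_path(out_dir, "dtm_idw.asc"))
    write_asc(chm, stage_path(out_dir, "chm.asc"))
    for (nm in names(stack)) {
      write_asc(stack[[nm]], stage_path(out_dir,
                                        paste0("feat_", nm, ".asc")))
    }
    plot_tab <- utils::read.csv(require_artifact(
      "features", stage_path(out_dir, "plots.csv")))
    pf <- aggregate_to_plots(stack, plot_tab)
    utils::write.csv(pf, stage_path(out_dir, "plot_features.csv"),
                     row.names = FALSE)
    add("dtm_idw.asc", "chm.asc", paste0("feat_", names(stack), ".asc"),
        "plot_features.csv")
  }

  if ("classify" %in% stages) {
    truth <- read_label_asc(
      require_artifact("classify", stage_path(out_dir, "species_true.asc")),
      require_artifact("classify", stage_path(out_dir, "legend.json")))
    stack <- read_stack_dir(out_dir, "classify")
    ev <- evaluate_combinations(truth, stack, config$combinations,
                                seed = seed + 4,
                                max_per_class = config$max_per_class)
    utils::write.csv(ev$ranking, stage_path(out_dir, "ranking.csv"),
                     row.names = FALSE)
    best <- ev$ranking$combination[1]
    classified <- classify_raster(ev$details[[best]]$model, stack)
    write_label_asc(classified, stage_path(out_dir, "classified.asc"),
                    stage_path(out_dir, "legend.json"))
    add("ranking.csv", "classified.asc")
  }

  if ("model" %in% stages) {
    pf <- utils::read.csv(require_artifact(
      "model", stage_path(out_dir, "plot_features.csv")))
    registry <- select_models(pf, vif_detect = config$vif_detect,
                              vif_accept = config$vif_accept,
                              p_threshold = config$p_threshold,
                              max_terms = config$max_terms)
    write_model_registry(registry, stage_path(out_dir, "models.json"))
    cand <- do.call(rbind, lapply(registry, function(r) r$candidates))
    utils::write.csv(cand, stage_path(out_dir, "model_candidates.csv"),
                     row.names = FALSE)
    add("models.json", "model_candidates.csv")
  }

  if ("map" %in% stages) {
    registry <- read_model_registry(require_artifact(
      "map", stage_path(out_dir, "models.json")))
    classified <- read_label_asc(
      require_artifact("map", stage_path(out_dir, "classified.asc")),
      require_artifact("map", stage_path(out_dir, "legend.json")))
    stack <- read_stack_dir(out_dir, "map")
    maps <- apply_models(classified, stack, registry, soil = config$soil)
    write_asc(maps$agc, stage_path(out_dir, "agc.asc"))
    write_asc(maps$bgc, stage_path(out_dir, "bgc.asc"))
    write_asc(maps$tgc, stage_path(out_dir, "tgc.asc"))
    summ <- species_summary(maps, classified)
    utils::write.csv(summ, stage_path(out_dir, "species_summary.csv"),
                     row.names = FALSE)
    ext <- dim(classified$values) * classified$pixel_size
    mid_y <- classified$ymax - ext[1] / 2
    mid_x <- classified$xmin + ext[2] / 2
    tr1 <- transect_profile(maps$tgc,
                            rbind(c(classified$xmin, mid_y),
                                  c(classified$xmin + ext[2], mid_y)),
                            step_m = classified$pixel_size * 2)
    tr2 <- transect_profile(maps$tgc,
                            rbind(c(mid_x, classified$ymax),
                                  c(mid_x, classified$ymax - ext[1])),
                            step_m = classified$pixel_size * 2)
    transects <- rbind(cbind(transect = "west_east", tr1),
                       cbind(transect = "north_south", tr2))
    utils::write.csv(transects, stage_path(out_dir, "transects.csv"),
                     row.names = FALSE)
    add("agc.asc", "bgc.asc", "tgc.asc", "species_summary.csv",
        "transects.csv")
  }

  manifest <- list(
    seed = seed,
    version = as.character(utils::packageVersion("mangroveCarbon")),
    stages = stages,
    files = lapply(stats::setNames(files, basename(files)), function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest, stage_path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}

read_stack_dir <- function(out_dir, stage) {
  paths <- list.files(out_dir, pattern = "^feat_.*\\.asc$",
                      full.names = TRUE)
  if (!length(paths)) {
    stop("stage '", stage, "' requires feature layers (run 'features')",
         call. = FALSE)
  }
  stack <- lapply(paths, read_asc)
  names(stack) <- sub("^feat_(.*)\\.asc$", "\\1", basename(paths))
  class(stack) <- "feature_stack"
  stack
}
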
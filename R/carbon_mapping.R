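#' Soil carbon constants
#'
#' Per-species soil carbon densities (t/hm²) joined to the classified map
#' when computing total carbon. Defaults are reference values for
#' *A. marina* (177.37), *R. stylosa* (281.14), *A. corniculatum* (236.18)
#' and *B. gymnorrhiza* (257.67).
#'
#' @param values named numeric vector, t/hm², all positive.
#' @return named numeric vector (validated).
#' @export
soil_carbon_table <- function(values = c(A_marina = 177.37,
                                         R_stylosa = 281.14,
                                         A_corniculatum = 236.18,
                                         B_gymnorrhiza = 257.67)) {
  stopifnot(!is.null(names(values)), all(values > 0))
  values
}

#' Apply species-routed carbon models per pixel
#'
#' Evaluates, for every mangrove pixel, the AGC and BGC model routed to the
#' pixel's species; negative predictions are clamped to 0 (and counted);
#' total carbon is `TGC = AGC + BGC + soil(species)`. Non-mangrove classes
#' (and any class absent from `soil`) become nodata.
#'
#' @param species_map label raster (truth or classification).
#' @param stack `feature_stack` providing every predictor any model needs.
#' @param registry a `model_registry` covering every mangrove species in
#'   the map.
#' @param soil named vector of per-species soil carbon (t/hm²), see
#'   [soil_carbon_table()].
#' @return object of class `"carbon_maps"`: list with `agc`, `bgc`, `tgc`
#'   (`mcraster`s, t/hm²) and `clamp_count`.
#' @export
apply_models <- function(species_map, stack, registry = NULL,
                         soil = soil_carbon_table()) {
  if (is.null(registry)) registry <- example_model_registry()
  cls <- attr(species_map, "classes")
  codes <- species_map$values
  present <- cls[sort(unique(as.vector(codes)))]
  mangroves <- intersect(present, names(soil))
  for (resp in c("agc", "bgc")) {
    covered <- unlist(lapply(registry[[resp]]$models,
                             function(m) m$species_group))
    uncovered <- setdiff(mangroves, covered)
    if (length(uncovered)) {
      stop("no ", resp, " model routed to species: ",
           paste(uncovered, collapse = ", "), call. = FALSE)
    }
  }
  nr <- nrow(codes); nc <- ncol(codes)
  agc <- matrix(NA_real_, nr, nc)
  bgc <- matrix(NA_real_, nr, nc)
  soil_m <- matrix(NA_real_, nr, nc)
  clamp <- 0L
  for (sp in mangroves) {
    mask <- codes == match(sp, cls)
    if (!any(mask)) next
    for (resp in c("agc", "bgc")) {
      m <- NULL
      for (cand in registry[[resp]]$models) {
        if (sp %in% cand$species_group) { m <- cand; break }
      }
      x <- vapply(m$predictors,
                  function(l) {
                    if (!l %in% names(stack)) {
                      stop("stack lacks predictor '", l, "' needed for ",
                           sp, call. = FALSE)
                    }
                    stack[[l]]$values[mask]
                  }, numeric(sum(mask)))
      pred <- drop(cbind(1, matrix(x, ncol = length(m$predictors))) %*%
                     m$coefficients)
      clamp <- clamp + sum(pred < 0, na.rm = TRUE)
      pred[pred < 0] <- 0
      if (resp == "agc") agc[mask] <- pred else bgc[mask] <- pred
    }
    soil_m[mask] <- soil[[sp]]
  }
  template <- species_map
  structure(list(
    agc = raster_like(template, agc),
    bgc = raster_like(template, bgc),
    tgc = raster_like(template, agc + bgc + soil_m),
    clamp_count = clamp
  ), class = "carbon_maps")
}

#' @export
print.carbon_maps <- function(x, ...) {
  cat("<carbon_maps> AGC/BGC/TGC rasters (t/hm2), clamped pixels:",
      x$clamp_count, "\n")
  invisible(x)
}

#' Sample a raster along a transect
#'
#' Nearest-pixel values at points spaced `step_m` apart along a polyline,
#' starting at distance 0 from its first vertex (the endpoint is included
#' when it falls on the step grid).
#'
#' @param raster an `mcraster`.
#' @param polyline 2-column matrix of vertex coordinates (>= 2 rows).
#' @param step_m sampling interval (m), > 0.
#' @return data.frame with `distance` (m) and `value` (`NA` where a point
#'   leaves the raster or hits nodata).
#' @export
transect_profile <- function(raster, polyline, step_m) {
  stopifnot(step_m > 0, nrow(polyline) >= 2)
  seg <- diff(polyline)
  seg_len <- sqrt(rowSums(seg^2))
  total <- sum(seg_len)
  dist <- seq(0, total, by = step_m)
  cum <- c(0, cumsum(seg_len))
  pts <- t(vapply(dist, function(d) {
    i <- max(which(cum <= d + 1e-12))
    i <- min(i, nrow(seg))
    f <- if (seg_len[i] == 0) 0 else (d - cum[i]) / seg_len[i]
    polyline[i, ] + f * seg[i, ]
  }, numeric(2)))
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  col <- floor((pts[, 1] - raster$xmin) / raster$pixel_size) + 1
  row <- floor((raster$ymax - pts[, 2]) / raster$pixel_size) + 1
  inside <- row >= 1 & row <= nr & col >= 1 & col <= nc
  if (!any(inside)) stop("transect lies outside the raster", call. = FALSE)
  val <- rep(NA_real_, length(dist))
  val[inside] <- raster$values[cbind(row[inside], col[inside])]
  data.frame(distance = dist, value = val)
}

#' Per-species carbon stock summary
#'
#' Area, mean carbon density, total stock and stock proportions per
#' species, plus 10 t/hm²-wide histogram counts of the per-pixel AGC and
#' BGC distributions (attribute `"histograms"`).
#'
#' @param maps a `carbon_maps`.
#' @param species_map co-registered label raster.
#' @param species which classes to summarize (default: those with valid
#'   carbon pixels).
#' @return data.frame with `species`, `area_hm2`, `mean_agc`, `mean_bgc`,
#'   `total_agc_t`, `total_bgc_t`, `pct_agc`, `pct_bgc`.
#' @export
species_summary <- function(maps, species_map, species = NULL) {
  stop_unless_coregistered(maps$agc, species_map, "carbon and species maps")
  cls <- attr(species_map, "classes")
  codes <- species_map$values
  if (is.null(species)) {
    valid <- !is.na(maps$agc$values)
    species <- cls[sort(unique(codes[valid]))]
  }
  pix_hm2 <- species_map$pixel_size^2 / 1e4
  hists <- list()
  rows <- lapply(species, function(sp) {
    mask <- codes == match(sp, cls) & !is.na(maps$agc$values)
    n <- sum(mask)
    a <- maps$agc$values[mask]; b <- maps$bgc$values[mask]
    area <- n * pix_hm2
    if (n > 0) {
      brk <- seq(0, 10 * ceiling(max(c(a, b, 10)) / 10), by = 10)
      hists[[sp]] <<- list(
        agc = table(cut(a, brk, right = FALSE)),
        bgc = table(cut(b, brk, right = FALSE)))
    }
    data.frame(species = sp, area_hm2 = area,
               mean_agc = if (n) mean(a) else NaN,
               mean_bgc = if (n) mean(b) else NaN,
               total_agc_t = if (n) mean(a) * area else 0,
               total_bgc_t = if (n) mean(b) * area else 0)
  })
  out <- do.call(rbind, rows)
  out$pct_agc <- 100 * out$total_agc_t / sum(out$total_agc_t)
  out$pct_bgc <- 100 * out$total_bgc_t / sum(out$total_bgc_t)
  rownames(out) <- NULL
  attr(out, "histograms") <- hists
  out
}
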
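#' Canonical feature-layer names
#'
#' The 55 predictor layers: the five bands, nine vegetation indices, mean
#' canopy height (`H_Mean`), and eight texture metrics per band
#' (`<band>_<metric>`).
#'
#' @return character vector of length 55.
#' @export
canonical_layer_names <- function() {
  c(band_names(), index_names(), "H_Mean",
    as.vector(t(outer(band_names(),
                      c("Con", "Cor", "Dis", "Ent", "Hom", "Mean", "Asm",
                        "Var"), paste, sep = "_"))))
}

#' Build a co-registered feature stack from a scene
#'
#' @param scene a `scene`.
#' @param chm canopy height `mcraster` (stored as layer `H_Mean`); when
#'   `NULL` and `scene` carries truth layers, `dsm - dtm_true` is used.
#' @param indices vegetation index names to compute (default all nine).
#' @param textures compute the 40 GLCM texture layers (slower).
#' @param glcm_window,glcm_levels GLCM parameters (see [glcm_metrics()]).
#' @return named list of `mcraster`s (class `"feature_stack"`).
#' @export
feature_stack <- function(scene, chm = NULL, indices = index_names(),
                          textures = FALSE, glcm_window = 3,
                          glcm_levels = 64) {
  stack <- scene$bands
  for (idx in indices) stack[[idx]] <- compute_index(scene, idx)
  if (is.null(chm) && !is.null(scene$dtm_true)) {
    chm <- compute_chm(scene$dsm, scene$dtm_true)
  }
  if (!is.null(chm)) stack[["H_Mean"]] <- chm
  if (isTRUE(textures)) {
    stack <- c(stack, glcm_stack(scene, window = glcm_window,
                                 levels = glcm_levels))
  }
  bad <- setdiff(names(stack), canonical_layer_names())
  if (length(bad)) stop("non-canonical layer name(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  class(stack) <- "feature_stack"
  stack
}

#' Extract stack layers as a pixel matrix
#'
#' @param stack a `feature_stack` (or plain named list of `mcraster`s).
#' @param layer_names layers to extract, in order.
#' @return numeric matrix, one row per pixel (column-major order), one
#'   column per layer.
#' @export
stack_matrix <- function(stack, layer_names) {
  missing <- setdiff(layer_names, names(stack))
  if (length(missing)) stop("stack lacks layer(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  do.call(cbind, lapply(stack[layer_names], function(r) as.vector(r$values)))
}

# Even-odd (ray casting) point-in-polygon; half-open on upper/right
# boundaries by the strict/non-strict inequality pairing.
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Aggregate feature layers over field plots
#'
#' One row per plot: each feature is the mean of the pixels whose centres
#' fall inside the plot polygon (pixel-centre membership; boundary pixels on
#' the right/top edges excluded), plus the contributing pixel count.
#'
#' @param stack a `feature_stack`.
#' @param plots list of `plot_record`s (or a data.frame with `plot_id`,
#'   `species` and `wkt` columns).
#' @return data.frame with `plot_id`, `species`, `n_pixels`, `agc`/`bgc`
#'   when available, and one column per layer.
#' @export
aggregate_to_plots <- function(stack, plots) {
  template <- stack[[1]]
  co <- raster_coords(template)
  nr <- nrow(template$values); nc <- ncol(template$values)
  grid_x <- matrix(rep(co$x, each = nr), nr, nc)
  grid_y <- matrix(rep(co$y, times = nc), nr, nc)
  lay <- names(stack)
  mats <- lapply(stack, function(r) r$values)
  if (is.data.frame(plots)) {
    plots <- lapply(seq_len(nrow(plots)), function(i) {
      list(plot_id = plots$plot_id[i], species_id = plots$species[i],
           polygon = parse_wkt_polygon(plots$wkt[i]), agc = plots$agc[i],
           bgc = plots$bgc[i])
    })
  }
  rows <- lapply(plots, function(p) {
    sel <- points_in_polygon(as.vector(grid_x), as.vector(grid_y), p$polygon)
    if (!any(sel)) {
      stop("plot ", p$plot_id, " captures no pixel centres", call. = FALSE)
    }
    vals <- vapply(mats, function(m) mean(as.vector(m)[sel], na.rm = TRUE),
                   numeric(1))
    out <- data.frame(plot_id = p$plot_id, species = p$species_id,
                      n_pixels = sum(sel))
    if (!is.null(p$agc)) { out$agc <- p$agc; out$bgc <- p$bgc }
    cbind(out, as.data.frame(as.list(vals)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
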
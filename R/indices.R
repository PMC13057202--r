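#' @name vegetation_indices
#' @title Vegetation indices from five-band reflectance
#'
#' @description
#' Pixel-wise spectral indices over the B, G, R, RE (red-edge) and NIR bands.
#' Default formulas (each overridable via `index_formulas()`):
#' \itemize{
#'   \item NDVI  = (NIR − R) / (NIR + R)
#'   \item GNDVI = (NIR − G) / (NIR + G)
#'   \item NDRE  = (NIR − RE) / (NIR + RE)
#'   \item OSAVI = (NIR − R) / (NIR + R + 0.16)
#'   \item LCI   = (NIR − RE) / (NIR + R)
#'   \item RVI   = NIR / R
#'   \item MACI  = NIR / G
#'   \item VREI  = NIR / RE
#'   \item SR    = NIR / B
#' }
#' Pixels whose denominator is zero become nodata.
NULL

.index_formulas <- list(
  NDVI  = function(b) (b$NIR - b$R) / (b$NIR + b$R),
  GNDVI = function(b) (b$NIR - b$G) / (b$NIR + b$G),
  NDRE  = function(b) (b$NIR - b$RE) / (b$NIR + b$RE),
  OSAVI = function(b) (b$NIR - b$R) / (b$NIR + b$R + 0.16),
  LCI   = function(b) (b$NIR - b$RE) / (b$NIR + b$R),
  RVI   = function(b) b$NIR / b$R,
  MACI  = function(b) b$NIR / b$G,
  VREI  = function(b) b$NIR / b$RE,
  SR    = function(b) b$NIR / b$B
)

#' Canonical index names
#' @return character vector of the nine supported vegetation index names.
#' @export
index_names <- function() names(.index_formulas)

band_names <- function() c("B", "G", "R", "RE", "NIR")

#' Compute a vegetation index over a scene
#'
#' @param scene a `scene` (see [generate_scene()]) or a named list of band
#'   `mcraster`s containing at least the bands the index needs.
#' @param index_name one of [index_names()].
#' @param formulas named list of index functions; each receives a named list
#'   of band value matrices. Defaults to the package formulas.
#' @return `mcraster` of the index; division-by-zero pixels are nodata.
#' @export
compute_index <- function(scene, index_name, formulas = .index_formulas) {
  if (!index_name %in% names(formulas)) {
    stop("unknown index name: ", index_name, call. = FALSE)
  }
  bands <- if (inherits(scene, "scene")) scene$bands else scene
  template <- bands[[1]]
  mats <- lapply(bands, function(r) r$values)
  out <- formulas[[index_name]](mats)
  out[!is.finite(out)] <- NA_real_
  raster_like(template, out)
}
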
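#' Gray-level co-occurrence texture metrics
#'
#' Quantizes a band to `levels` gray levels by global min–max scaling over
#' the raster, accumulates a co-occurrence matrix of gray-level pairs at the
#' given pixel offsets within a moving window centred on each pixel
#' (truncated at the image edges), normalizes it to probabilities
#' \eqn{p(i,j)}, and summarizes it with eight metrics:
#' \describe{
#'   \item{Con}{contrast, \eqn{\sum p(i,j)(i-j)^2}}
#'   \item{Cor}{correlation, \eqn{\sum (i-\mu_i)(j-\mu_j)p/(\sigma_i\sigma_j)};
#'     defined as 0 when \eqn{\sigma_i\sigma_j = 0}}
#'   \item{Dis}{dissimilarity, \eqn{\sum p|i-j|}}
#'   \item{Ent}{entropy, \eqn{-\sum p \ln p} with \eqn{0\ln 0 \equiv 0}}
#'   \item{Hom}{homogeneity, \eqn{\sum p/(1+(i-j)^2)}}
#'   \item{Mean}{marginal mean \eqn{\sum_i i\, p_i}}
#'   \item{Asm}{angular second moment, \eqn{\sum p^2}}
#'   \item{Var}{marginal variance \eqn{\sum_i (i-\mathrm{Mean})^2 p_i}}
#' }
#' With `symmetric = TRUE` each ordered pair is also counted reversed, so the
#' matrix (and hence the row/column marginals) is symmetric.
#'
#' @param band an `mcraster` or a numeric matrix.
#' @param window odd window side length `>= 3`, or `NULL` for a single
#'   whole-image co-occurrence matrix.
#' @param levels number of gray levels (`>= 2`).
#' @param offsets integer matrix of `(d_row, d_col)` offsets, one per row.
#' @param symmetric count each pair in both directions.
#' @return for windowed use, a named list of eight `mcraster`s
#'   (`Con, Cor, Dis, Ent, Hom, Mean, Asm, Var`); for `window = NULL`, a
#'   named numeric vector of the eight metrics.
#' @export
glcm_metrics <- function(band, window = 3, levels = 64,
                         offsets = rbind(c(0, 1), c(1, 1), c(1, 0), c(1, -1)),
                         symmetric = TRUE) {
  v <- if (inherits(band, "mcraster")) band$values else as.matrix(band)
  stopifnot(levels >= 2, nrow(offsets) >= 1)
  q <- quantize_band(v, levels)
  offs <- matrix(as.integer(offsets), ncol = 2)
  metric_names <- c("Con", "Cor", "Dis", "Ent", "Hom", "Mean", "Asm", "Var")
  if (is.null(window)) {
    out <- .glcm_window_cpp(q, as.integer(levels), offs, symmetric)
    return(stats::setNames(as.numeric(out[1, ]), metric_names))
  }
  window <- as.integer(window)
  if (window < 3 || window %% 2 == 0) {
    stop("window must be odd and >= 3", call. = FALSE)
  }
  if (window > max(dim(v))) {
    stop("window larger than raster", call. = FALSE)
  }
  res <- .glcm_pixel_cpp(q, as.integer(levels), window, offs, symmetric)
  out <- lapply(seq_along(metric_names), function(m) {
    mat <- matrix(res[, m], nrow = nrow(v), ncol = ncol(v))
    if (inherits(band, "mcraster")) raster_like(band, mat) else
      raster_create(mat)
  })
  names(out) <- metric_names
  out
}

# Global min-max quantization to 0..levels-1; NA -> -1 (nodata code).
quantize_band <- function(v, levels) {
  rng <- range(v, na.rm = TRUE)
  if (!is.finite(rng[1])) stop("band is all nodata", call. = FALSE)
  if (rng[2] > rng[1]) {
    q <- floor((v - rng[1]) / (rng[2] - rng[1]) * levels)
    q[q >= levels] <- levels - 1
  } else {
    q <- array(0, dim = dim(v))
  }
  q[is.na(v)] <- -1L
  storage.mode(q) <- "integer"
  q
}

#' Texture layers for every band of a scene
#'
#' Runs [glcm_metrics()] on each of the five spectral bands and returns the
#' 40 texture layers named `<band>_<metric>` (e.g. `B_Var`, `R_Con`,
#' `NIR_Hom`), matching the canonical predictor-variable names.
#'
#' @param scene a `scene` or named list of band `mcraster`s.
#' @inheritParams glcm_metrics
#' @return named list of 40 `mcraster`s.
#' @export
glcm_stack <- function(scene, window = 3, levels = 64,
                       offsets = rbind(c(0, 1), c(1, 1), c(1, 0), c(1, -1)),
                       symmetric = TRUE) {
  bands <- if (inherits(scene, "scene")) scene$bands else scene
  out <- list()
  for (bn in names(bands)) {
    layers <- glcm_metrics(bands[[bn]], window, levels, offsets, symmetric)
    names(layers) <- paste(bn, names(layers), sep = "_")
    out <- c(out, layers)
  }
  out
}
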
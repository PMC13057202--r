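#' Create a single-band raster
#'
#' Lightweight in-memory raster: a numeric matrix (row 1 is the top of the
#' map, row-major, 0.53 m pixels by default) plus the affine placement of the
#' grid. Missing values are stored as `NA` and written to disk as the
#' configured nodata value.
#'
#' The centre of cell \eqn{(r, c)} (1-based) lies at
#' \eqn{x = x_{min} + (c - 1/2)\,s}, \eqn{y = y_{max} - (r - 1/2)\,s} where
#' \eqn{s} is the pixel size in metres.
#'
#' @param values numeric matrix of cell values (`NA` = nodata).
#' @param xmin x coordinate of the left edge (m).
#' @param ymax y coordinate of the top edge (m).
#' @param pixel_size cell side length (m).
#' @param crs opaque coordinate-system tag carried through unchanged.
#' @return an object of class `"mcraster"`.
#' @export
raster_create <- function(values, xmin = 0, ymax = nrow(values) * pixel_size,
                          pixel_size = 0.53, crs = "") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(pixel_size > 0)
  structure(list(values = values, xmin = xmin, ymax = ymax,
                 pixel_size = pixel_size, crs = crs),
            class = "mcraster")
}

#' @export
print.mcraster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<mcraster> %d x %d @ %.4g m  origin (%.6g, %.6g)\n",
              nrow(v), ncol(v), x$pixel_size, x$xmin, x$ymax))
  ok <- !is.na(v)
  if (any(ok)) {
    cat(sprintf("  values: [%.6g, %.6g]  nodata: %d/%d\n",
                min(v[ok]), max(v[ok]), sum(!ok), length(v)))
  } else {
    cat("  all nodata\n")
  }
  invisible(x)
}

#' @export
dim.mcraster <- function(x) dim(x$values)

raster_like <- function(template, values) {
  raster_create(values, xmin = template$xmin, ymax = template$ymax,
                pixel_size = template$pixel_size, crs = template$crs)
}

#' Cell-centre coordinates
#'
#' @param r an `mcraster`.
#' @return list with numeric vectors `x` (by column) and `y` (by row).
#' @export
raster_coords <- function(r) {
  d <- dim(r$values)
  list(x = r$xmin + (seq_len(d[2]) - 0.5) * r$pixel_size,
       y = r$ymax - (seq_len(d[1]) - 0.5) * r$pixel_size)
}

stop_unless_coregistered <- function(a, b, what = "rasters") {
  if (!identical(dim(a$values), dim(b$values)) ||
      abs(a$xmin - b$xmin) > 1e-9 || abs(a$ymax - b$ymax) > 1e-9 ||
      abs(a$pixel_size - b$pixel_size) > 1e-12) {
    stop(what, " are not co-registered (shape/origin/pixel size differ)",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text `.asc` interchange format (ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value header followed by rows from the top of the map).
#'
#' @param r an `mcraster`.
#' @param path output file path.
#' @param nodata value written for `NA` cells.
#' @export
write_asc <- function(r, path, nodata = -9999) {
  v <- r$values
  nr <- nrow(v); nc <- ncol(v)
  yll <- r$ymax - nr * r$pixel_size
  hdr <- c(sprintf("ncols %d", nc), sprintf("nrows %d", nr),
           sprintf("xllcorner %.10g", r$xmin), sprintf("yllcorner %.10g", yll),
           sprintf("cellsize %.10g", r$pixel_size),
           sprintf("NODATA_value %.10g", nodata))
  v[is.na(v)] <- nodata
  body <- apply(v, 1, function(row) paste(formatC(row, format = "g", digits = 15),
                                          collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path `.asc` file path.
#' @param crs optional coordinate-system tag to attach.
#' @return an `mcraster`.
#' @export
read_asc <- function(path, crs = "") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  stopifnot(length(vals) == nr * nc)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  raster_create(m, xmin = hdr$xllcorner,
                ymax = hdr$yllcorner + nr * hdr$cellsize,
                pixel_size = hdr$cellsize, crs = crs)
}

#' Aggregate a raster to a coarser pixel size by block means
#'
#' Downsampling convention used to bring very-high-resolution imagery to the
#' working resolution: non-overlapping blocks of whole pixels are averaged.
#' The aggregation factor is the nearest integer to
#' `target_pixel_size / pixel_size`; the achieved pixel size
#' (`factor * native`) is stored on the result. A coarse cell becomes nodata
#' when more than half of its contributing fine pixels are nodata; otherwise
#' the mean is taken over the valid pixels. Trailing partial blocks are
#' dropped.
#'
#' @param r an `mcraster`.
#' @param target_pixel_size requested coarse pixel size (m), `>=` native.
#' @return aggregated `mcraster`.
#' @export
resample_raster <- function(r, target_pixel_size) {
  f <- target_pixel_size / r$pixel_size
  if (f < 1 - 1e-9) stop("upsampling is not supported", call. = FALSE)
  f <- max(1L, as.integer(round(f)))
  if (f == 1L) return(r)
  v <- r$values
  nr <- (nrow(v) %/% f) * f
  nc <- (ncol(v) %/% f) * f
  if (nr == 0 || nc == 0) stop("raster smaller than one block", call. = FALSE)
  v <- v[seq_len(nr), seq_len(nc), drop = FALSE]
  # block sums via row-group then column-group matrix products
  gr <- (seq_len(nr) - 1L) %/% f
  gc <- (seq_len(nc) - 1L) %/% f
  ok <- !is.na(v)
  vz <- v; vz[!ok] <- 0
  sum_blk <- rowsum(t(rowsum(vz, gr)), gc)          # nc/f x nr/f
  n_blk <- rowsum(t(rowsum(ok + 0, gr)), gc)
  out <- t(sum_blk / n_blk)
  out[t(n_blk) < f * f / 2] <- NA_real_
  out[t(n_blk) == 0] <- NA_real_
  dimnames(out) <- NULL
  raster_create(out, xmin = r$xmin, ymax = r$ymax,
                pixel_size = r$pixel_size * f, crs = r$crs)
}

#' Canopy height model from surface and terrain models
#'
#' CHM = DSM − DTM, with negative differences (terrain interpolation
#' overshooting the canopy surface) clamped to zero. The number of clamped
#' cells is recorded in the `"clamp_count"` attribute.
#'
#' @param dsm digital surface model (`mcraster`, m).
#' @param dtm digital terrain model (`mcraster`, m).
#' @return `mcraster` of canopy height (m).
#' @export
compute_chm <- function(dsm, dtm) {
  stop_unless_coregistered(dsm, dtm, "DSM and DTM")
  h <- dsm$values - dtm$values
  clamped <- sum(h < 0, na.rm = TRUE)
  h[h < 0] <- 0
  out <- raster_like(dsm, h)
  attr(out, "clamp_count") <- clamped
  out
}
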
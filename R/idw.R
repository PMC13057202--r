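#' Inverse-distance-weighted terrain interpolation
#'
#' Predicts ground elevation at arbitrary points from a ground-control-point
#' (GCP) table: \eqn{\hat z(x) = \sum_i w_i z_i / \sum_i w_i} over the
#' `n_points` nearest GCPs, with \eqn{w_i = d_i^{-power}}. A query closer
#' than 1e-9 m to a GCP returns that GCP's elevation exactly.
#'
#' @param gcps data.frame with numeric columns `x`, `y`, `z` (m); at least
#'   one row, unique (x, y).
#' @param x,y numeric vectors of query coordinates (recycled to equal length).
#' @param power positive inverse-distance exponent.
#' @param n_points number of nearest GCPs used per query (`1..nrow(gcps)`).
#' @return numeric vector of predicted elevations.
#' @export
idw_predict <- function(gcps, x, y, power = 3, n_points = 3) {
  check_gcps(gcps)
  stopifnot(power > 0, n_points >= 1, n_points <= nrow(gcps))
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    d <- sqrt((gcps$x - x[i])^2 + (gcps$y - y[i])^2)
    if (any(d < 1e-9)) {
      out[i] <- gcps$z[which.min(d)]
      next
    }
    idx <- order(d)[seq_len(n_points)]
    w <- d[idx]^(-power)
    out[i] <- sum(w * gcps$z[idx]) / sum(w)
  }
  out
}

check_gcps <- function(gcps) {
  if (is.null(gcps) || nrow(gcps) == 0) {
    stop("empty GCP table", call. = FALSE)
  }
  stopifnot(all(c("x", "y", "z") %in% names(gcps)))
  if (anyDuplicated(gcps[c("x", "y")])) {
    stop("duplicate GCP locations", call. = FALSE)
  }
  invisible(TRUE)
}

#' Interpolate a DTM raster from GCPs
#'
#' @inheritParams idw_predict
#' @param grid either an `mcraster` template (its geometry is reused) or a
#'   list with `xmin`, `ymax`, `nrow`, `ncol`, `pixel_size`.
#' @param pixel_size overrides the grid pixel size when `grid` is a template.
#' @return `mcraster` digital terrain model.
#' @export
idw_interpolate <- function(gcps, grid, power = 3, n_points = 3,
                            pixel_size = NULL) {
  if (inherits(grid, "mcraster")) {
    g <- list(xmin = grid$xmin, ymax = grid$ymax, nrow = nrow(grid$values),
              ncol = ncol(grid$values),
              pixel_size = if (is.null(pixel_size)) grid$pixel_size else pixel_size)
  } else {
    g <- grid
    if (!is.null(pixel_size)) g$pixel_size <- pixel_size
  }
  xs <- g$xmin + (seq_len(g$ncol) - 0.5) * g$pixel_size
  ys <- g$ymax - (seq_len(g$nrow) - 0.5) * g$pixel_size
  pts <- expand.grid(col = seq_len(g$ncol), row = seq_len(g$nrow))
  z <- idw_predict(gcps, xs[pts$col], ys[pts$row], power, n_points)
  m <- matrix(z, nrow = g$nrow, ncol = g$ncol, byrow = TRUE)
  raster_create(m, xmin = g$xmin, ymax = g$ymax, pixel_size = g$pixel_size)
}

#' Select IDW parameters by leave-one-GCP-out RMSE
#'
#' Grid search over candidate `(pixel_size, power, n_points)` triples. For
#' each held-out GCP the prediction is made at the centre of the grid cell
#' that would contain it at that pixel size (grid anchored at the minimum x /
#' maximum y of the GCPs), mirroring validation of a gridded terrain product;
#' the remaining GCPs are the interpolation support. Returns the candidate
#' with the lowest RMSE; ties broken by smaller power, then fewer points,
#' then smaller pixel size.
#'
#' @param gcps GCP table (`x`, `y`, `z`), at least 5 rows.
#' @param pixel_sizes,powers,n_points numeric vectors of candidate values.
#' @return list with `best` (one-row data.frame) and `rmse_table`
#'   (data.frame of all candidates with their RMSE, sorted ascending).
#' @export
select_idw_params <- function(gcps, pixel_sizes = 3.5, powers = 1:4,
                              n_points = 2:6) {
  check_gcps(gcps)
  if (nrow(gcps) < 5) stop("need at least 5 GCPs for holdout", call. = FALSE)
  if (length(unique(gcps$x)) == 1 || length(unique(gcps$y)) == 1) {
    stop("degenerate GCP geometry (collinear along an axis)", call. = FALSE)
  }
  cand <- expand.grid(pixel_size = pixel_sizes, power = powers,
                      n_points = n_points)
  cand <- cand[cand$n_points <= nrow(gcps) - 1, , drop = FALSE]
  if (nrow(cand) == 0) stop("empty candidate grid", call. = FALSE)
  x0 <- min(gcps$x); y1 <- max(gcps$y)
  rmse <- vapply(seq_len(nrow(cand)), function(k) {
    ps <- cand$pixel_size[k]
    # cell-centre query coordinates for every GCP at this pixel size
    qx <- x0 + (floor((gcps$x - x0) / ps) + 0.5) * ps
    qy <- y1 - (floor((y1 - gcps$y) / ps) + 0.5) * ps
    err <- vapply(seq_len(nrow(gcps)), function(i) {
      pred <- idw_predict(gcps[-i, , drop = FALSE], qx[i], qy[i],
                          power = cand$power[k], n_points = cand$n_points[k])
      pred - gcps$z[i]
    }, numeric(1))
    sqrt(mean(err^2))
  }, numeric(1))
  tab <- cbind(cand, rmse = rmse)
  ord <- order(tab$rmse, tab$power, tab$n_points, tab$pixel_size)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  list(best = tab[1, , drop = FALSE], rmse_table = tab)
}
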
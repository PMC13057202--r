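#' Species signature
#'
#' Per-class generative parameters for the synthetic scene: mean reflectance
#' and covariance over the five bands (B, G, R, RE, NIR; unitless 0–1),
#' canopy height distribution (m), a spatial correlation length
#' (`texture_scale`, pixels) that induces class-distinct image texture, and
#' stand density (trees per hectare). Non-vegetation classes use
#' `height_mean = 0`.
#'
#' @param species_id class label.
#' @param band_means numeric length-5 vector in `[0, 1]` (B, G, R, RE, NIR).
#' @param band_cov 5x5 symmetric positive semi-definite covariance, or a
#'   single number taken as a common per-band standard deviation.
#' @param height_mean,height_sd canopy height distribution (m).
#' @param texture_scale Gaussian correlation length of the within-class
#'   noise field, in pixels; `0` gives white noise.
#' @param density stems per hectare (vegetation classes).
#' @param measure which diameter is recorded for simulated trees
#'   (`"dbh"` or `"basal_diameter"`).
#' @param diam_mean,diam_sd diameter distribution (cm) for simulated trees.
#' @return object of class `"species_signature"`.
#' @export
species_signature <- function(species_id, band_means, band_cov = 0.01,
                              height_mean = 0, height_sd = 0,
                              texture_scale = 0, density = 0,
                              measure = "dbh", diam_mean = 0, diam_sd = 0) {
  band_means <- as.numeric(band_means)
  stopifnot(length(band_means) == 5, all(band_means >= 0 & band_means <= 1),
            height_sd >= 0, height_mean >= 0)
  if (length(band_cov) == 1) band_cov <- diag(rep(band_cov^2, 5))
  band_cov <- as.matrix(band_cov)
  stopifnot(identical(dim(band_cov), c(5L, 5L)))
  if (max(abs(band_cov - t(band_cov))) > 1e-12) {
    stop("band_cov must be symmetric", call. = FALSE)
  }
  if (min(eigen(band_cov, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-10) {
    stop("band_cov must be positive semi-definite", call. = FALSE)
  }
  names(band_means) <- band_names()
  structure(list(species_id = species_id, band_means = band_means,
                 band_cov = band_cov, height_mean = height_mean,
                 height_sd = height_sd, texture_scale = texture_scale,
                 density = density, measure = measure,
                 diam_mean = diam_mean, diam_sd = diam_sd),
            class = "species_signature")
}

#' Species identifiers used throughout the package
#' @return character vector of the four mangrove species labels.
#' @export
mangrove_species <- function() {
  c("A_marina", "A_corniculatum", "R_stylosa", "B_gymnorrhiza")
}

nonveg_classes <- function() c("soil", "water", "shadow")

#' Default class signatures
#'
#' Encodes the field structure of a mixed mangrove stand: per-species canopy
#' height distributions and stand densities from ground-survey community
#' statistics (*A. marina* 2.44 ± 0.50 m at 9280 trees/hm²,
#' *A. corniculatum* 1.83 ± 0.46 m at 133200 trees/hm², *R. stylosa*
#' 4.73 ± 0.72 m at 7480 trees/hm², *B. gymnorrhiza* 2.51 ± 0.65 m at
#' 8320 trees/hm²), and reflectance means satisfying the reported ordinal
#' spectral constraints (every species brightest in G and darkest in B among
#' the visible bands; *B. gymnorrhiza* highest in R and G, *R. stylosa*
#' lowest in R and G, *A. marina* highest in B, *A. marina* and
#' *A. corniculatum* intermediate and similar in R and G). Absolute
#' reflectance values are synthetic; only the ordering is anchored.
#'
#' @param band_sd common per-band reflectance standard deviation; the
#'   separability dial (smaller = more separable classes).
#' @return named list of `species_signature`s covering the four mangrove
#'   species plus soil, water and shadow.
#' @export
default_signatures <- function(band_sd = 0.01) {
  sig <- list(
    A_marina = species_signature("A_marina",
      band_means = c(0.060, 0.110, 0.080, 0.300, 0.480), band_cov = band_sd,
      height_mean = 2.44, height_sd = 0.50, texture_scale = 1.5,
      density = 9280, measure = "dbh", diam_mean = 7.45, diam_sd = 2.82),
    A_corniculatum = species_signature("A_corniculatum",
      band_means = c(0.050, 0.112, 0.082, 0.260, 0.420), band_cov = band_sd,
      height_mean = 1.83, height_sd = 0.46, texture_scale = 1.0,
      density = 133200, measure = "basal_diameter", diam_mean = 4.0,
      diam_sd = 1.2),
    R_stylosa = species_signature("R_stylosa",
      band_means = c(0.040, 0.085, 0.055, 0.320, 0.550), band_cov = band_sd,
      height_mean = 4.73, height_sd = 0.72, texture_scale = 3.0,
      density = 7480, measure = "dbh", diam_mean = 13.85, diam_sd = 10.05),
    B_gymnorrhiza = species_signature("B_gymnorrhiza",
      band_means = c(0.045, 0.130, 0.095, 0.270, 0.520), band_cov = band_sd,
      height_mean = 2.51, height_sd = 0.65, texture_scale = 2.0,
      density = 8320, measure = "dbh", diam_mean = 13.51, diam_sd = 5.95),
    soil = species_signature("soil",
      band_means = c(0.180, 0.220, 0.260, 0.280, 0.300), band_cov = band_sd,
      texture_scale = 4.0),
    water = species_signature("water",
      band_means = c(0.060, 0.050, 0.040, 0.030, 0.020), band_cov = band_sd,
      texture_scale = 6.0),
    shadow = species_signature("shadow",
      band_means = c(0.020, 0.020, 0.020, 0.030, 0.040), band_cov = band_sd,
      texture_scale = 1.0)
  )
  sig
}

#' Pairwise Mahalanobis separation between class signatures
#'
#' \eqn{d_{ab} = \sqrt{\Delta^\top ((\Sigma_a+\Sigma_b)/2)^{-1} \Delta}} over
#' the band means; the standard two-class separability measure for Gaussian
#' classifiers.
#'
#' @param signatures named list of `species_signature`s.
#' @return symmetric matrix of pairwise distances.
#' @export
mahalanobis_separation <- function(signatures) {
  k <- length(signatures)
  d <- matrix(0, k, k, dimnames = list(names(signatures), names(signatures)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i >= j) next
    del <- signatures[[i]]$band_means - signatures[[j]]$band_means
    s <- (signatures[[i]]$band_cov + signatures[[j]]$band_cov) / 2
    d[i, j] <- d[j, i] <- sqrt(drop(t(del) %*% solve(s, del)))
  }
  d
}

# Gaussian smoothing with edge renormalization (separable, exact kernels
# via row/column weight matrices).
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  smooth_1d <- function(n) {
    idx <- seq_len(n)
    k <- outer(idx, idx, function(i, j) exp(-(i - j)^2 / (2 * sigma^2)))
    k / rowSums(k)
  }
  kr <- smooth_1d(nrow(m))
  kc <- smooth_1d(ncol(m))
  kr %*% m %*% t(kc)
}

# Standardized (mean 0, sd 1 over the whole grid) smoothed Gaussian field.
random_field <- function(nr, nc, scale) {
  f <- gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc), scale)
  s <- stats::sd(f)
  if (s == 0) return(matrix(0, nr, nc))
  (f - mean(f)) / s
}

#' Generate a synthetic species/land-cover map
#'
#' A Gaussian-smoothed white-noise field is thresholded at the empirical
#' quantiles of the cumulative class fractions, giving spatially contiguous
#' patches whose realized areas match the requested fractions to pixel
#' rounding.
#'
#' @param nrow,ncol grid size in pixels.
#' @param fractions named numeric vector over land-cover classes, summing to
#'   1 (tolerance 1e-9); zero-fraction classes are allowed.
#' @param patch_scale correlation length of the patch field, pixels (> 0).
#' @param seed integer random seed.
#' @param pixel_size pixel side (m).
#' @param xmin,ymax map placement.
#' @return label raster: an `mcraster` of integer class codes with a
#'   `"classes"` attribute naming them.
#' @export
generate_species_map <- function(nrow, ncol, fractions, patch_scale = 15,
                                 seed = 1, pixel_size = 0.53, xmin = 0,
                                 ymax = nrow * pixel_size) {
  stopifnot(patch_scale > 0, !is.null(names(fractions)))
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("class fractions must sum to 1", call. = FALSE)
  }
  if (any(fractions < 0)) stop("negative class fraction", call. = FALSE)
  set.seed(seed)
  f <- random_field(nrow, ncol, patch_scale)
  npix <- nrow * ncol
  counts <- diff(c(0, round(cumsum(fractions) * npix)))
  ord <- order(f)           # ascending field value -> class bands
  codes <- integer(npix)
  codes[ord] <- rep.int(seq_along(fractions), counts)
  m <- matrix(codes, nrow, ncol)
  out <- raster_create(m, xmin = xmin, ymax = ymax, pixel_size = pixel_size)
  attr(out, "classes") <- names(fractions)
  out
}

#' Labels present in a label raster
#' @param label_raster raster produced by [generate_species_map()] or
#'   [classify_raster()].
#' @return character vector of class names for each cell (matrix shape kept).
#' @export
label_values <- function(label_raster) {
  cls <- attr(label_raster, "classes")
  m <- label_raster$values
  out <- matrix(cls[m], nrow(m), ncol(m))
  out
}

#' Generate a synthetic five-band scene with surface model and truth layers
#'
#' Per pixel, reflectance is drawn from the label's multivariate normal
#' (spatially correlated at the class `texture_scale`, clipped to `[0, 1]`);
#' canopy height from the class height distribution (smoothed at the same
#' scale, clipped at 0); the true terrain is a smooth low-relief surface and
#' `dsm = dtm_true + height`. Truth layers (`dtm_true`, `species_true`) are
#' kept on the result.
#'
#' The correlated noise is built from standardized smoothed fields, so class
#' sample means match `band_means` and marginal variances match `band_cov`
#' up to sampling error regardless of `texture_scale`.
#'
#' @param species_map label raster from [generate_species_map()].
#' @param signatures named list of `species_signature`s covering every label
#'   present in the map.
#' @param seed integer random seed.
#' @param relief amplitude (m) of the true terrain undulation.
#' @return object of class `"scene"`: list with `bands` (named list of five
#'   `mcraster`s), `dsm`, `dtm_true`, `species_true`, `pixel_size`,
#'   `signatures`.
#' @export
generate_scene <- function(species_map, signatures, seed = 1, relief = 0.3) {
  cls <- attr(species_map, "classes")
  present <- cls[sort(unique(as.vector(species_map$values)))]
  missing <- setdiff(present, names(signatures))
  if (length(missing)) {
    stop("missing signature for label(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  set.seed(seed)
  nr <- nrow(species_map$values); nc <- ncol(species_map$values)
  bands <- replicate(5, matrix(NA_real_, nr, nc), simplify = FALSE)
  names(bands) <- band_names()
  height <- matrix(0, nr, nc)
  dtm <- 1 + relief * random_field(nr, nc, max(nr, nc) / 6)
  for (lab in cls) {                     # fixed order => determinism
    code <- match(lab, cls)
    mask <- species_map$values == code
    if (!any(mask)) next
    sg <- signatures[[lab]]
    sds <- sqrt(diag(sg$band_cov))
    if (any(sds > 0)) {
      ef <- vapply(1:5, function(b) {
        if (sds[b] > 0) as.vector(random_field(nr, nc, sg$texture_scale))
        else numeric(nr * nc)
      }, numeric(nr * nc))
      cl <- chol(sg$band_cov + diag(1e-12, 5))
      z <- ef %*% cl
    } else {
      z <- matrix(0, nr * nc, 5)
    }
    for (b in 1:5) {
      vals <- sg$band_means[b] + z[, b]
      bands[[b]][mask] <- pmin(1, pmax(0, vals[as.vector(mask)]))
    }
    if (sg$height_mean > 0) {
      hnoise <- if (sg$height_sd > 0) {
        sg$height_sd * random_field(nr, nc, sg$texture_scale)
      } else {
        matrix(0, nr, nc)
      }
      hmat <- pmax(0, sg$height_mean + hnoise)
      height[mask] <- hmat[mask]
    }
  }
  mk <- function(m) raster_like(species_map, m)
  structure(list(
    bands = lapply(bands, mk),
    dsm = mk(dtm + height),
    dtm_true = mk(dtm),
    species_true = species_map,
    pixel_size = species_map$pixel_size,
    signatures = signatures
  ), class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  d <- dim(x$bands[[1]]$values)
  cat(sprintf("<scene> %d x %d px @ %.3g m; bands %s\n", d[1], d[2],
              x$pixel_size, paste(names(x$bands), collapse = ",")))
  invisible(x)
}

#' Sample square field plots with simulated tree records
#'
#' Places `n_per_species` non-overlapping square plots per mangrove species
#' inside patches that are at least `purity` single-species (by pixel-centre
#' labels). Per plot, the tree count is Poisson with mean
#' `density * plot area`, heights are drawn from the species height
#' distribution (truncated at 0.1 m), diameters from the species diameter
#' distribution, and plot AGC/BGC are derived through the allometric
#' `registry` so the generative carbon is known exactly.
#'
#' @param scene a `scene` with truth layers.
#' @param n_per_species plots per species (default 10, i.e. 40 plots for the
#'   four species).
#' @param plot_side plot side length (m), default 5.
#' @param seed integer random seed.
#' @param registry allometric registry (see [allometry_registry()]); default
#'   the shipped example registry.
#' @param purity minimum single-species pixel fraction inside a plot.
#' @param max_tries placement attempts per species before failing.
#' @param species which species to sample (default the mangrove species
#'   present in the scene).
#' @return list of `plot_record`s (fields `plot_id`, `species_id`, `polygon`
#'   — 4x2 corner matrix, closed counter-clockwise —, `trees` data.frame,
#'   `agc`, `bgc` in t/hm²).
#' @export
sample_plots <- function(scene, n_per_species = 10, plot_side = 5, seed = 1,
                         registry = default_allometry(), purity = 0.9,
                         max_tries = 5000, species = NULL) {
  set.seed(seed)
  sm <- scene$species_true
  cls <- attr(sm, "classes")
  if (is.null(species)) {
    present <- cls[sort(unique(as.vector(sm$values)))]
    species <- intersect(mangrove_species(), present)
  }
  px <- scene$pixel_size
  nr <- nrow(sm$values); nc <- ncol(sm$values)
  span <- ceiling(plot_side / px)       # pixels per plot side (upper bound)
  if (span > min(nr, nc)) stop("plot larger than scene extent", call. = FALSE)
  placed <- list()                      # accepted [r0, c0] windows
  plots <- list()
  pid <- 0L
  n_inside <- floor(plot_side / px + 0.5)
  # window purity via cumulative sums (integral image) per species
  window_fraction <- function(code) {
    z <- (sm$values == code) + 0
    cs <- apply(apply(z, 2, cumsum), 1, cumsum)  # t(integral image)
    ii <- rbind(0, cbind(0, t(cs)))              # (nr+1) x (nc+1)
    k <- n_inside
    r <- seq_len(nr - k + 1L); c <- seq_len(nc - k + 1L)
    (ii[r + k, c + k, drop = FALSE] + ii[r, c, drop = FALSE] -
       ii[r + k, c, drop = FALSE] - ii[r, c + k, drop = FALSE]) / (k * k)
  }
  for (sp in species) {
    sg <- scene$signatures[[sp]]
    code <- match(sp, cls)
    frac <- window_fraction(code)
    elig <- which(frac >= purity, arr.ind = TRUE)
    if (nrow(elig) < n_per_species) {
      stop("insufficient pure patches for species ", sp, call. = FALSE)
    }
    # deterministic greedy packing along the patch (dense row-major scan)
    elig <- elig[order(elig[, 1], elig[, 2]), , drop = FALSE]
    got <- 0L
    i <- 0L
    while (got < n_per_species) {
      i <- i + 1L
      if (i > nrow(elig) || i > max_tries) {
        stop("insufficient pure patches for species ", sp, call. = FALSE)
      }
      r0 <- elig[i, 1]; c0 <- elig[i, 2]
      overlap <- any(vapply(placed, function(p) {
        abs(p[1] - r0) < span && abs(p[2] - c0) < span
      }, logical(1)))
      if (overlap) next
      placed[[length(placed) + 1L]] <- c(r0, c0)
      pid <- pid + 1L
      got <- got + 1L
      x0 <- sm$xmin + (c0 - 1L) * px
      y0 <- sm$ymax - (r0 - 1L) * px
      poly <- rbind(c(x0, y0 - plot_side), c(x0 + plot_side, y0 - plot_side),
                    c(x0 + plot_side, y0), c(x0, y0))
      area <- plot_side^2
      ntree <- stats::rpois(1, sg$density * area / 1e4)
      h <- pmax(0.1, stats::rnorm(ntree, sg$height_mean, sg$height_sd))
      diam <- pmax(0.5, stats::rnorm(ntree, sg$diam_mean, sg$diam_sd))
      trees <- data.frame(
        height = h,
        dbh = if (identical(sg$measure, "dbh")) diam else NA_real_,
        basal_diameter = if (identical(sg$measure, "basal_diameter")) diam
                         else NA_real_,
        stem_count = rep(1L, ntree)
      )
      carbon <- plot_carbon(trees, sp, registry, plot_area = area)
      plots[[pid]] <- structure(list(
        plot_id = sprintf("P%03d", pid), species_id = sp, polygon = poly,
        trees = trees, agc = carbon$agc, bgc = carbon$bgc
      ), class = "plot_record")
    }
  }
  plots
}

#' Flatten plot records to per-tree and per-plot tables
#'
#' @param plots list of `plot_record`s.
#' @return `plots_to_trees()`: one row per tree with plot and species ids;
#'   `plots_to_table()`: one row per plot with carbon and a WKT polygon.
#' @export
plots_to_trees <- function(plots) {
  do.call(rbind, lapply(plots, function(p) {
    cbind(plot_id = p$plot_id, species = p$species_id, p$trees)
  }))
}

#' @rdname plots_to_trees
#' @export
plots_to_table <- function(plots) {
  do.call(rbind, lapply(plots, function(p) {
    data.frame(plot_id = p$plot_id, species = p$species_id,
               agc = p$agc, bgc = p$bgc, n_trees = nrow(p$trees),
               wkt = polygon_wkt(p$polygon))
  }))
}

polygon_wkt <- function(poly) {
  ring <- rbind(poly, poly[1, ])
  sprintf("POLYGON ((%s))",
          paste(sprintf("%.6f %.6f", ring[, 1], ring[, 2]), collapse = ", "))
}

parse_wkt_polygon <- function(wkt) {
  inner <- sub("^POLYGON\\s*\\(\\(", "", trimws(wkt))
  inner <- sub("\\)\\)$", "", inner)
  pts <- strsplit(strsplit(inner, ",")[[1]], "[[:space:]]+")
  xy <- t(vapply(pts, function(p) as.numeric(p[p != ""]), numeric(2)))
  if (all(abs(xy[1, ] - xy[nrow(xy), ]) < 1e-12)) xy <- xy[-nrow(xy), ]
  xy
}
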
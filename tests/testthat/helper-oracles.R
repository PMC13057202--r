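# Independent brute-force oracles used to validate the package's
# implementations. These deliberately share no code with the package.

# Whole-image GLCM metrics by direct pair enumeration and a dense
# co-occurrence matrix.
oracle_glcm <- function(img, levels, offsets, symmetric = TRUE) {
  rng <- range(img)
  q <- if (rng[2] > rng[1]) {
    pmin(floor((img - rng[1]) / (rng[2] - rng[1]) * levels), levels - 1)
  } else {
    array(0, dim = dim(img))
  }
  counts <- matrix(0, levels, levels)
  nr <- nrow(img); nc <- ncol(img)
  for (o in seq_len(nrow(offsets))) {
    dr <- offsets[o, 1]; dc <- offsets[o, 2]
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      i <- q[r, c] + 1; j <- q[r2, c2] + 1
      counts[i, j] <- counts[i, j] + 1
      if (symmetric) counts[j, i] <- counts[j, i] + 1
    }
  }
  p <- counts / sum(counts)
  lv <- 0:(levels - 1)
  dif <- outer(lv, lv, "-")
  pi_ <- rowSums(p); pj <- colSums(p)
  mui <- sum(lv * pi_); muj <- sum(lv * pj)
  vari <- sum((lv - mui)^2 * pi_); varj <- sum((lv - muj)^2 * pj)
  ent <- -sum(ifelse(p > 0, p * log(p), 0))
  cor <- if (vari * varj > 0) {
    sum(outer(lv - mui, lv - muj) * p) / sqrt(vari * varj)
  } else 0
  c(Con = sum(p * dif^2), Cor = cor, Dis = sum(p * abs(dif)),
    Ent = ent, Hom = sum(p / (1 + dif^2)), Mean = mui,
    Asm = sum(p^2), Var = vari)
}

# Quadratic discriminant scores computed the long way (explicit inverse and
# determinant), for checking the classifier.
oracle_qda_labels <- function(x, means, covs, priors) {
  k <- length(means)
  g <- sapply(seq_len(k), function(cl) {
    s <- covs[[cl]]
    si <- solve(s)
    ld <- determinant(s, logarithm = TRUE)$modulus
    apply(x, 1, function(row) {
      d <- row - means[[cl]]
      log(priors[cl]) - 0.5 * ld - 0.5 * drop(t(d) %*% si %*% d)
    })
  })
  apply(g, 1, which.max)
}

# OLS coefficients by the normal equations.
oracle_ols <- function(x, y) {
  xx <- cbind(1, as.matrix(x))
  drop(solve(t(xx) %*% xx, t(xx) %*% y))
}

# IDW prediction (plain re-implementation).
oracle_idw <- function(gcps, qx, qy, power, n_points) {
  d <- sqrt((gcps$x - qx)^2 + (gcps$y - qy)^2)
  if (any(d < 1e-9)) return(gcps$z[which.min(d)])
  idx <- order(d)[seq_len(n_points)]
  w <- d[idx]^(-power)
  sum(w * gcps$z[idx]) / sum(w)
}

# Small two-species scene where spectra are identical and only height
# differs; used to show the value of the structural layer.
height_contrast_scene <- function(seed, n = 100) {
  fr <- c(A_marina = 0.5, R_stylosa = 0.5)
  smap <- generate_species_map(n, n, fr, patch_scale = 12, seed = seed)
  sig <- list(
    A_marina = species_signature("A_marina",
      band_means = c(0.06, 0.11, 0.08, 0.30, 0.48), band_cov = 0.04,
      height_mean = 2.44, height_sd = 0.50, texture_scale = 1,
      density = 9280),
    R_stylosa = species_signature("R_stylosa",
      band_means = c(0.06, 0.11, 0.08, 0.30, 0.48), band_cov = 0.04,
      height_mean = 4.73, height_sd = 0.72, texture_scale = 1,
      density = 7480)
  )
  generate_scene(smap, sig, seed = seed + 100)
}

default_test_fractions <- function() {
  c(B_gymnorrhiza = 0.08, R_stylosa = 0.20, A_marina = 0.24,
    A_corniculatum = 0.13, soil = 0.15, water = 0.12, shadow = 0.08)
}
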
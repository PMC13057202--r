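#' Stratified train/validation split
#'
#' Random split of labeled samples, stratified by class (70/30 by default).
#'
#' @param labels factor or character vector of class labels.
#' @param train_fraction fraction per class assigned to training,
#'   in (0, 1).
#' @param seed integer random seed.
#' @param min_train minimum training samples any class must retain.
#' @return list with integer index vectors `train` and `test` (disjoint).
#' @export
split_samples <- function(labels, train_fraction = 0.7, seed = 1,
                          min_train = 2) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  set.seed(seed)
  labels <- as.character(labels)
  train <- integer(0); test <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_tr <- round(length(idx) * train_fraction)
    if (n_tr < min_train || n_tr >= length(idx)) {
      stop("class '", cl, "' too small for a ", train_fraction,
           " stratified split", call. = FALSE)
    }
    pick <- sample(idx, n_tr)
    train <- c(train, pick)
    test <- c(test, setdiff(idx, pick))
  }
  list(train = sort(train), test = sort(test))
}

#' Gaussian maximum-likelihood classifier
#'
#' Fits one multivariate normal per class: sample mean, sample covariance
#' (denominator \eqn{n-1}) and a class prior. Classification assigns each
#' observation to the class maximizing the quadratic discriminant
#' \deqn{g_k(x) = \ln \pi_k - \tfrac12 \ln|\Sigma_k|
#'   - \tfrac12 (x-\mu_k)^\top \Sigma_k^{-1} (x-\mu_k).}
#' A ridge `ridge` is added to the covariance diagonal and escalated
#' (x10, up to `max_ridge`) until the Cholesky factorization succeeds, with
#' a warning when escalation was needed.
#'
#' @param formula model formula `class ~ feat1 + feat2` (or `class ~ .`).
#' @param data data.frame of training samples.
#' @param prior `"equal"`, `"frequency"`, or a named numeric vector summing
#'   to 1.
#' @param ridge initial ridge added to each covariance diagonal.
#' @param max_ridge escalation cap.
#' @return object of class `"mlc"` with per-class `mean`, `cov` (after
#'   regularization), `prior`, plus `features` and `classes`.
#' @export
mlc <- function(formula, data, prior = "equal", ridge = 1e-6,
                max_ridge = 1e3) {
  mf <- stats::model.frame(formula, data)
  y <- as.character(mf[[1]])
  x <- as.matrix(mf[, -1, drop = FALSE])
  storage.mode(x) <- "double"
  classes <- sort(unique(y))
  k <- length(classes); d <- ncol(x)
  pri <- switch(if (is.character(prior)) prior else "vector",
    equal = stats::setNames(rep(1 / k, k), classes),
    frequency = table(factor(y, classes)) / length(y),
    vector = prior[classes]
  )
  pri <- as.numeric(pri) / sum(as.numeric(pri))
  fits <- list()
  escalated <- FALSE
  for (i in seq_len(k)) {
    xi <- x[y == classes[i], , drop = FALSE]
    if (nrow(xi) < d + 2) {
      stop("class '", classes[i], "' has fewer than d + 2 = ", d + 2,
           " training samples", call. = FALSE)
    }
    mu <- colMeans(xi)
    sig <- stats::cov(xi)
    if (is.null(tryCatch(chol(sig), error = function(e) NULL))) {
      escalated <- TRUE       # raw covariance singular: ridge is repairing
    }
    eps <- ridge
    repeat {
      ch <- tryCatch(chol(sig + diag(eps, d)), error = function(e) NULL)
      if (!is.null(ch)) break
      eps <- if (eps == 0) 1e-10 else eps * 10
      if (eps > max_ridge) {
        stop("covariance for class '", classes[i],
             "' not repairable by ridge escalation", call. = FALSE)
      }
    }
    fits[[classes[i]]] <- list(mean = mu, cov = sig + diag(eps, d),
                               chol = ch, n = nrow(xi), ridge = eps)
  }
  if (escalated) warning("singular class covariance repaired by ridge ",
                         "escalation", call. = FALSE)
  structure(list(classes = classes, features = colnames(x), fits = fits,
                 prior = stats::setNames(pri, classes), call = match.call()),
            class = "mlc")
}

#' @export
print.mlc <- function(x, ...) {
  cat("Gaussian maximum-likelihood classifier\n")
  cat("  classes :", paste(x$classes, collapse = ", "), "\n")
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  n <- vapply(x$fits, function(f) f$n, numeric(1))
  cat("  n train :", paste(n, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.mlc <- function(object, ...) {
  print(object)
  for (cl in object$classes) {
    cat("\nclass", cl, "mean:\n")
    print(round(object$fits[[cl]]$mean, 4))
  }
  invisible(object)
}

#' Per-observation quadratic discriminants
#'
#' @param object fitted `"mlc"`.
#' @param x numeric matrix (columns = model features).
#' @return matrix of \eqn{g_k(x)}, one column per class.
#' @export
mlc_discriminants <- function(object, x) {
  x <- as.matrix(x)
  out <- matrix(NA_real_, nrow(x), length(object$classes),
                dimnames = list(NULL, object$classes))
  for (cl in object$classes) {
    f <- object$fits[[cl]]
    ch <- f$chol
    logdet <- 2 * sum(log(diag(ch)))
    cent <- sweep(x, 2, f$mean)
    # quadratic form via triangular solve: ||L^-T z||^2
    z <- backsolve(ch, t(cent), transpose = TRUE)
    q <- colSums(z^2)
    out[, cl] <- log(object$prior[cl]) - 0.5 * logdet - 0.5 * q
  }
  out
}

#' Predict method for `mlc`
#'
#' Ties are broken toward the lowest class index (first in sorted class
#' order); rows with any missing feature get `NA`.
#'
#' @param object fitted `"mlc"`.
#' @param newdata data.frame or matrix carrying the model features.
#' @param type `"class"` (factor) or `"discriminant"` (matrix of
#'   \eqn{g_k}).
#' @param ... unused.
#' @export
predict.mlc <- function(object, newdata, type = c("class", "discriminant"),
                        ...) {
  type <- match.arg(type)
  x <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  ok <- stats::complete.cases(x)
  g <- matrix(NA_real_, nrow(x), length(object$classes),
              dimnames = list(NULL, object$classes))
  if (any(ok)) g[ok, ] <- mlc_discriminants(object, x[ok, , drop = FALSE])
  if (type == "discriminant") return(g)
  lab <- rep(NA_integer_, nrow(x))
  lab[ok] <- apply(g[ok, , drop = FALSE], 1, which.max)  # first max = tie rule
  factor(object$classes[lab], levels = object$classes)
}

#' Classify a raster stack
#'
#' @param object fitted `"mlc"`.
#' @param stack `feature_stack` providing every model feature.
#' @return label raster (`mcraster` of class codes with a `"classes"`
#'   attribute); nodata pixels propagate.
#' @export
classify_raster <- function(object, stack) {
  x <- stack_matrix(stack, object$features)
  lab <- predict(object, as.data.frame(x))
  template <- stack[[1]]
  m <- matrix(as.integer(lab), nrow(template$values), ncol(template$values))
  out <- raster_like(template, m)
  attr(out, "classes") <- object$classes
  out
}

#' Confusion matrix and accuracy metrics
#'
#' Counts are predicted (rows) by reference (columns). Overall accuracy
#' (OA) is trace/total; producer's accuracy (PA) per class is the correct
#' fraction of that class's reference samples (column-wise); user's
#' accuracy (UA) the correct fraction of its predictions (row-wise).
#' Zero-denominator ratios are `NaN` and excluded from any averaging.
#'
#' @param predicted,reference label vectors of equal length.
#' @param classes class set (default: union of the two vectors, sorted).
#' @return object of class `"confusion"`: list with `counts`, `oa`, `pa`,
#'   `ua`.
#' @export
confusion_accuracy <- function(predicted, reference, classes = NULL) {
  predicted <- as.character(predicted)
  reference <- as.character(reference)
  stopifnot(length(predicted) == length(reference))
  if (is.null(classes)) classes <- sort(unique(c(predicted, reference)))
  bad <- setdiff(stats::na.omit(c(predicted, reference)), classes)
  if (length(bad)) stop("label(s) outside class set: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  counts <- table(factor(predicted, classes), factor(reference, classes))
  counts <- matrix(as.integer(counts), length(classes),
                   dimnames = list(predicted = classes, reference = classes))
  diagn <- diag(counts)
  structure(list(counts = counts,
                 oa = sum(diagn) / sum(counts),
                 pa = diagn / colSums(counts),
                 ua = diagn / rowSums(counts)),
            class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  cat(sprintf("Overall accuracy: %.4f\n", x$oa))
  print(x$counts)
  tab <- rbind(PA = x$pa, UA = x$ua)
  print(round(tab, 4))
  invisible(x)
}

#' Default feature combinations
#'
#' Fifteen named spectral/structural feature combinations used to compare
#' classifier inputs: visible bands alone and with red-edge/NIR (V1–V4),
#' vegetation-index sets (V5–V7), each of those plus canopy height
#' (V8–V11), bands plus indices (V12–V14 variants) and the full fusion
#' V15 (five bands, nine indices, `H_Mean`). All are configuration —
#' replace or extend the returned list freely.
#'
#' @return named list of character vectors of layer names.
#' @export
default_combinations <- function() {
  idx <- index_names()
  v1 <- c("R", "G", "B")
  v5 <- c("NDVI", "GNDVI")
  v6 <- c("NDVI", "NDRE")
  v7 <- c("NDVI", "GNDVI", "NDRE", "OSAVI", "LCI")
  bands <- band_names()
  re_based <- c("NDRE", "LCI", "VREI")
  list(
    V1 = v1,
    V2 = c(v1, "RE"),
    V3 = c(v1, "NIR"),
    V4 = c(v1, "RE", "NIR"),
    V5 = v5,
    V6 = v6,
    V7 = v7,
    V8 = c(v1, "H_Mean"),
    V9 = c(v6, "H_Mean"),
    V10 = c(v5, "H_Mean"),
    V11 = c(v7, "H_Mean"),
    V12 = c(bands, idx),
    V13 = c(bands, setdiff(idx, re_based)),
    V14 = c(bands, v7, "H_Mean"),
    V15 = c(bands, idx, "H_Mean")
  )
}

#' Train and score the classifier over feature combinations
#'
#' For each combination: stratified 70/30 split of the labeled pixels, fit
#' [mlc()] on the training stratum, classify the validation stratum, and
#' score with [confusion_accuracy()]. Pixels are drawn from the truth
#' label raster (optionally capped per class).
#'
#' @param truth label raster (ground truth).
#' @param stack `feature_stack` with every layer any combination needs.
#' @param combinations named list of layer-name vectors
#'   (default [default_combinations()]).
#' @param seed integer random seed (split and per-class subsampling).
#' @param train_fraction training fraction of the split.
#' @param max_per_class cap on labeled pixels sampled per class
#'   (`Inf` = all).
#' @return list with `ranking` (data.frame sorted by OA descending: one row
#'   per combination with OA and per-class PA/UA) and `details` (per
#'   combination: the `confusion` object and fitted model).
#' @export
evaluate_combinations <- function(truth, stack,
                                  combinations = default_combinations(),
                                  seed = 1, train_fraction = 0.7,
                                  max_per_class = 3000) {
  stopifnot(length(combinations) >= 1)
  cls <- attr(truth, "classes")
  labels_all <- as.vector(truth$values)
  set.seed(seed)
  keep <- integer(0)
  for (code in sort(unique(labels_all))) {
    idx <- which(labels_all == code)
    if (length(idx) > max_per_class) idx <- sample(idx, max_per_class)
    keep <- c(keep, idx)
  }
  keep <- sort(keep)
  labels <- cls[labels_all[keep]]
  all_layers <- unique(unlist(combinations))
  feat <- as.data.frame(stack_matrix(stack, all_layers))[keep, , drop = FALSE]
  sp <- split_samples(labels, train_fraction, seed = seed)
  details <- list()
  rows <- list()
  for (nm in names(combinations)) {
    layers <- combinations[[nm]]
    tr <- cbind(class = labels[sp$train],
                feat[sp$train, layers, drop = FALSE])
    fit <- tryCatch(
      mlc(class ~ ., data = tr),
      error = function(e) stop("combination ", nm, ": ", conditionMessage(e),
                               call. = FALSE))
    pred <- predict(fit, feat[sp$test, layers, drop = FALSE])
    cm <- confusion_accuracy(pred, labels[sp$test], classes = fit$classes)
    details[[nm]] <- list(confusion = cm, model = fit)
    row <- data.frame(combination = nm, n_features = length(layers),
                      oa = cm$oa)
    for (cl in names(cm$pa)) {
      row[[paste0("pa_", cl)]] <- cm$pa[[cl]]
      row[[paste0("ua_", cl)]] <- cm$ua[[cl]]
    }
    rows[[nm]] <- row
  }
  ranking <- do.call(rbind, rows)
  ranking <- ranking[order(-ranking$oa), ]
  rownames(ranking) <- NULL
  list(ranking = ranking, details = details)
}
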
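#' Pearson screening of carbon predictors
#'
#' Pearson correlation (with two-tailed p-value) between each candidate
#' predictor column and the response, ranked by `|r|` descending.
#' Zero-variance predictors are skipped and reported in the `"skipped"`
#' attribute.
#'
#' @param data data.frame of plot-level features and carbon.
#' @param response response column name (e.g. `"agc"`).
#' @param predictors candidate column names (default: all numeric columns
#'   except the response and bookkeeping columns).
#' @return data.frame with `variable`, `r`, `p`, sorted by `|r|`.
#' @export
pearson_screen <- function(data, response, predictors = NULL) {
  if (nrow(data) < 3) stop("need at least 3 plots", call. = FALSE)
  if (is.null(predictors)) {
    num <- names(data)[vapply(data, is.numeric, logical(1))]
    predictors <- setdiff(num, c(response, "agc", "bgc", "n_pixels",
                                 "n_trees"))
  }
  y <- data[[response]]
  skipped <- character(0)
  rows <- list()
  for (v in predictors) {
    x <- data[[v]]
    if (stats::sd(x) == 0 || anyNA(x)) { skipped <- c(skipped, v); next }
    ct <- stats::cor.test(x, y)
    rows[[v]] <- data.frame(variable = v, r = unname(ct$estimate),
                            p = ct$p.value)
  }
  if (!length(rows)) stop("all candidate predictors are degenerate",
                          call. = FALSE)
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$r)), ]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Variance inflation factors
#'
#' \eqn{VIF_j = 1/(1 - R_j^2)} where \eqn{R_j^2} comes from regressing
#' predictor \eqn{j} on the remaining predictors. Perfect collinearity is
#' reported as `Inf`.
#'
#' @param x numeric matrix or data.frame of predictors (>= 2 columns, more
#'   rows than columns).
#' @return named numeric vector of VIFs.
#' @export
vif <- function(x) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (p < 2) stop("VIF needs at least 2 predictors", call. = FALSE)
  if (nrow(x) <= p) stop("underdetermined design (n <= p)", call. = FALSE)
  out <- numeric(p)
  for (j in seq_len(p)) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    tss <- sum((x[, j] - mean(x[, j]))^2)
    rss <- sum(fit$residuals^2)
    r2 <- if (tss == 0) 1 else 1 - rss / tss
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  stats::setNames(out, colnames(x))
}

#' Leave-one-out cross-validation of a linear carbon model
#'
#' For each plot \eqn{i} the model is refit on the remaining \eqn{n-1}
#' plots and used to predict plot \eqn{i}. Reported metrics:
#' \eqn{RMSE = \sqrt{\mathrm{mean}\,(y_i - \hat y_{(-i)})^2}} and the
#' PRESS-based \eqn{R^2 = 1 - \sum(y_i - \hat y_{(-i)})^2 /
#' \sum(y_i - \bar y)^2} (may be negative for uninformative models).
#'
#' @param data data.frame of plots.
#' @param predictors predictor column names.
#' @param response response column name.
#' @return list with `loocv_r2`, `loocv_rmse`, and the vector of held-out
#'   `predictions`.
#' @export
loocv <- function(data, predictors, response) {
  n <- nrow(data)
  if (n < length(predictors) + 3) {
    stop("too few plots for LOOCV with ", length(predictors), " predictors",
         call. = FALSE)
  }
  y <- data[[response]]
  x <- as.matrix(data[, predictors, drop = FALSE])
  pred <- numeric(n)
  for (i in seq_len(n)) {
    xi <- cbind(1, x[-i, , drop = FALSE])
    fit <- stats::lm.fit(xi, y[-i])
    if (any(is.na(fit$coefficients))) {
      stop("singular refit in LOOCV fold ", i, call. = FALSE)
    }
    pred[i] <- drop(c(1, x[i, ]) %*% fit$coefficients)
  }
  press <- sum((y - pred)^2)
  tss <- sum((y - mean(y))^2)
  list(loocv_r2 = 1 - press / tss, loocv_rmse = sqrt(press / n),
       predictions = pred)
}

#' Fit a linear carbon-stock model
#'
#' Ordinary least squares of a carbon response on one or more plot-level
#' feature variables, with the diagnostics used for model screening:
#' per-coefficient two-sided t-test p-values, fit \eqn{R^2}, leave-one-out
#' \eqn{R^2} and RMSE, and the maximum VIF (multivariate fits).
#'
#' @param formula e.g. `agc ~ H_Mean` or `agc ~ B_Var + R_Con`.
#' @param data data.frame of plots.
#' @param species_group species labels the model is routed to (recorded on
#'   the object).
#' @return object of class `"carbon_lm"`.
#' @export
carbon_lm <- function(formula, data, species_group = NULL) {
  mf <- stats::model.frame(formula, data)
  response <- names(mf)[1]
  predictors <- attr(stats::terms(mf), "term.labels")
  n <- nrow(mf)
  if (n < length(predictors) + 2) {
    stop("need n >= p + 2 plots", call. = FALSE)
  }
  fit <- stats::lm(formula, data)
  sm <- summary(fit)
  cv <- if (n >= length(predictors) + 3) {
    loocv(data, predictors, response)
  } else {
    list(loocv_r2 = NA_real_, loocv_rmse = NA_real_)
  }
  mv <- if (length(predictors) >= 2) {
    max(vif(as.matrix(data[, predictors, drop = FALSE])))
  } else NA_real_
  structure(list(
    response = response, predictors = predictors,
    species_group = species_group,
    coefficients = stats::coef(fit),
    p_values = sm$coefficients[, 4],
    fit_r2 = sm$r.squared,
    loocv_r2 = cv$loocv_r2, loocv_rmse = cv$loocv_rmse,
    max_vif = mv, n_plots = n, lm = fit
  ), class = "carbon_lm")
}

#' @export
print.carbon_lm <- function(x, ...) {
  eq <- paste(sprintf("%.4g %s", x$coefficients[-1], x$predictors),
              collapse = " + ")
  cat(sprintf("%s = %s %+.4g\n", toupper(x$response), eq,
              x$coefficients[1]))
  if (length(x$species_group)) {
    cat("  species :", paste(x$species_group, collapse = " + "), "\n")
  }
  cat(sprintf("  fit R2 %.3f | LOOCV R2 %.3f | LOOCV RMSE %.2f t/hm2 | n %d\n",
              x$fit_r2, x$loocv_r2, x$loocv_rmse, x$n_plots))
  if (!is.na(x$max_vif)) cat(sprintf("  max VIF %.2f\n", x$max_vif))
  invisible(x)
}

#' @export
coef.carbon_lm <- function(object, ...) object$coefficients

#' @export
summary.carbon_lm <- function(object, ...) {
  print(object)
  cat("\ncoefficient p-values:\n")
  print(signif(object$p_values, 3))
  invisible(object)
}

#' @export
predict.carbon_lm <- function(object, newdata, ...) {
  x <- as.matrix(as.data.frame(newdata)[, object$predictors, drop = FALSE])
  drop(cbind(1, x) %*% object$coefficients)
}

#' @export
residuals.carbon_lm <- function(object, ...) stats::residuals(object$lm)

#' Univariate model on the top-correlated variable
#'
#' Screens predictors with [pearson_screen()], fits the single best
#' `|r|`-ranked variable, and applies the significance filter
#' (slope p < `p_threshold`).
#'
#' @inheritParams pearson_screen
#' @param p_threshold significance level for retaining the model.
#' @param species_group recorded on the fitted model.
#' @return list with `model` (a `carbon_lm`, or `NULL` when rejected),
#'   `screen` (the correlation table) and `retained` (logical).
#' @export
fit_univariate <- function(data, response, predictors = NULL,
                           p_threshold = 0.05, species_group = NULL) {
  screen <- pearson_screen(data, response, predictors)
  best <- screen$variable[1]
  model <- carbon_lm(stats::reformulate(best, response), data,
                     species_group = species_group)
  retained <- isTRUE(model$p_values[2] < p_threshold)
  list(model = if (retained) model else NULL, screen = screen,
       retained = retained, variable = best)
}

#' Multivariate model search with VIF and significance filtering
#'
#' Enumerates predictor subsets of size 2..`max_terms` drawn from the
#' `top_k` highest-`|r|` candidates. A subset is rejected when its maximum
#' VIF is `>= vif_accept` (with `vif_detect` flagging gross collinearity in
#' the report) or when any slope p-value is `>= p_threshold`; survivors are
#' ranked by LOOCV \eqn{R^2}.
#'
#' @inheritParams fit_univariate
#' @param vif_detect VIF above which a subset is flagged as collinear.
#' @param vif_accept maximum VIF allowed in a retained model (< 3 by
#'   default).
#' @param max_terms maximum number of predictors.
#' @param top_k number of top-correlated candidates fed to the search.
#' @return list with `model` (best surviving `carbon_lm` or `NULL`) and
#'   `report` (one row per subset: predictors, max VIF, max slope p,
#'   LOOCV R2, status).
#' @export
fit_multivariate <- function(data, response, predictors = NULL,
                             vif_detect = 10, vif_accept = 3,
                             p_threshold = 0.05, max_terms = 3, top_k = 8,
                             species_group = NULL) {
  screen <- pearson_screen(data, response, predictors)
  cand <- utils::head(screen$variable, top_k)
  max_terms <- min(max_terms, length(cand), nrow(data) - 3)
  if (max_terms < 2) {
    stop("too few plots or candidates for a multivariate model",
         call. = FALSE)
  }
  rows <- list(); best <- NULL
  for (size in 2:max_terms) {
    if (size > length(cand)) break
    subsets <- utils::combn(cand, size, simplify = FALSE)
    for (s in subsets) {
      key <- paste(s, collapse = "+")
      v <- suppressWarnings(max(vif(as.matrix(data[, s, drop = FALSE]))))
      if (v >= vif_accept) {
        rows[[key]] <- data.frame(predictors = key, max_vif = v,
                                  max_p = NA, loocv_r2 = NA,
                                  status = if (v >= vif_detect)
                                    "rejected: collinear (VIF >= detect)"
                                  else "rejected: VIF >= accept")
        next
      }
      m <- tryCatch(carbon_lm(stats::reformulate(s, response), data,
                              species_group = species_group),
                    error = function(e) NULL)
      if (is.null(m)) {
        rows[[key]] <- data.frame(predictors = key, max_vif = v, max_p = NA,
                                  loocv_r2 = NA, status = "rejected: fit failed")
        next
      }
      maxp <- max(m$p_values[-1])
      if (maxp >= p_threshold) {
        rows[[key]] <- data.frame(predictors = key, max_vif = v,
                                  max_p = maxp, loocv_r2 = m$loocv_r2,
                                  status = "rejected: p >= threshold")
        next
      }
      rows[[key]] <- data.frame(predictors = key, max_vif = v, max_p = maxp,
                                loocv_r2 = m$loocv_r2, status = "retained")
      if (is.null(best) || m$loocv_r2 > best$loocv_r2) best <- m
    }
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(predictors = character(0), max_vif = numeric(0),
               max_p = numeric(0), loocv_r2 = numeric(0),
               status = character(0))
  rownames(report) <- NULL
  list(model = best, report = report)
}

# All set partitions of `items` (restricted-growth-string enumeration).
set_partitions <- function(items) {
  n <- length(items)
  if (n == 0) return(list())
  parts <- list()
  rgs <- function(prefix, maxv) {
    if (length(prefix) == n) {
      k <- max(prefix)
      blocks <- lapply(seq_len(k), function(b) items[prefix == b])
      parts[[length(parts) + 1]] <<- blocks
      return(invisible(NULL))
    }
    for (v in seq_len(maxv + 1)) rgs(c(prefix, v), max(maxv, v))
  }
  rgs(integer(0), 0L)
  parts
}

#' Select best carbon models across species and species combinations
#'
#' Evaluates every candidate species group (all singletons plus every
#' multi-species subset — 15 groups for four species) for each response by
#' pooling the group's plots and fitting both the univariate
#' top-correlation model and the VIF-filtered multivariate model; the
#' group's candidate is the retained fit with the higher LOOCV \eqn{R^2}.
#' The species set is then partitioned into groups (each species covered
#' exactly once) maximizing the mean LOOCV \eqn{R^2} across blocks, with
#' ties broken by fewer groups, then lower summed LOOCV RMSE.
#'
#' @param plot_table plot-level data.frame with `species`, feature columns
#'   and the response columns.
#' @param responses response column names (default `c("agc", "bgc")`).
#' @param predictors candidate predictor columns (default: automatic, see
#'   [pearson_screen()]).
#' @param min_plots minimum pooled plots a group needs to be evaluated.
#' @param ... passed to [fit_multivariate()] (thresholds, `max_terms`,
#'   `top_k`).
#' @return object of class `"model_registry"`: per response, the selected
#'   models (`models`), the chosen partition and a `candidates` report
#'   table covering every evaluated group.
#' @export
select_models <- function(plot_table, responses = c("agc", "bgc"),
                          predictors = NULL, min_plots = 5, ...) {
  species <- sort(unique(plot_table$species))
  if (length(species) < 1) stop("no species in plot table", call. = FALSE)
  groups <- list()
  for (k in seq_along(species)) {
    for (s in utils::combn(species, k, simplify = FALSE)) {
      groups[[paste(s, collapse = "+")]] <- s
    }
  }
  registry <- list()
  for (resp in responses) {
    cand_rows <- list(); cand_models <- list()
    for (gn in names(groups)) {
      rows <- plot_table[plot_table$species %in% groups[[gn]], , drop = FALSE]
      if (nrow(rows) < min_plots) next
      uni <- tryCatch(fit_univariate(rows, resp, predictors,
                                     species_group = groups[[gn]]),
                      error = function(e) NULL)
      multi <- tryCatch(fit_multivariate(rows, resp, predictors,
                                         species_group = groups[[gn]], ...),
                        error = function(e) NULL)
      best <- NULL
      for (m in list(uni$model, multi$model)) {
        if (!is.null(m) && (is.null(best) || m$loocv_r2 > best$loocv_r2)) {
          best <- m
        }
      }
      cand_rows[[gn]] <- data.frame(
        group = gn, response = resp, n_plots = nrow(rows),
        univariate_var = if (!is.null(uni)) uni$variable else NA,
        uni_loocv_r2 = if (!is.null(uni$model)) uni$model$loocv_r2 else NA,
        multi_loocv_r2 = if (!is.null(multi$model))
          multi$model$loocv_r2 else NA,
        best_loocv_r2 = if (!is.null(best)) best$loocv_r2 else NA,
        best_loocv_rmse = if (!is.null(best)) best$loocv_rmse else NA,
        best_predictors = if (!is.null(best))
          paste(best$predictors, collapse = "+") else NA)
      if (!is.null(best)) cand_models[[gn]] <- best
    }
    candidates <- do.call(rbind, cand_rows)
    rownames(candidates) <- NULL
    # choose the best partition of the species set
    best_part <- NULL; best_score <- -Inf; best_len <- Inf; best_rmse <- Inf
    for (part in set_partitions(species)) {
      keys <- vapply(part, paste, "", collapse = "+")
      if (!all(keys %in% names(cand_models))) next
      r2s <- vapply(cand_models[keys], function(m) m$loocv_r2, numeric(1))
      rmses <- vapply(cand_models[keys], function(m) m$loocv_rmse,
                      numeric(1))
      score <- mean(r2s)
      better <- score > best_score + 1e-12 ||
        (abs(score - best_score) <= 1e-12 &&
           (length(keys) < best_len ||
              (length(keys) == best_len && sum(rmses) < best_rmse)))
      if (better) {
        best_part <- keys; best_score <- score
        best_len <- length(keys); best_rmse <- sum(rmses)
      }
    }
    if (is.null(best_part)) {
      stop("no valid species partition for response '", resp,
           "'; see candidate report", call. = FALSE)
    }
    registry[[resp]] <- list(models = cand_models[best_part],
                             partition = best_part,
                             mean_loocv_r2 = best_score,
                             candidates = candidates)
  }
  structure(registry, class = "model_registry")
}

#' @export
print.model_registry <- function(x, ...) {
  for (resp in names(x)) {
    cat(sprintf("== %s (mean LOOCV R2 %.3f) ==\n", toupper(resp),
                x[[resp]]$mean_loocv_r2))
    for (m in x[[resp]]$models) print(m)
  }
  invisible(x)
}

#' Construct a carbon model from fixed coefficients
#'
#' Builds a routed linear model directly from an intercept and named
#' slopes, for use with externally supplied equations (no fit diagnostics).
#'
#' @param response response name (`"agc"` or `"bgc"`).
#' @param species_group character vector of species routed to this model.
#' @param intercept numeric intercept.
#' @param slopes named numeric vector of slopes (names = predictor layers).
#' @return a `carbon_lm`-classed object usable by [predict.carbon_lm()]
#'   and [apply_models()].
#' @export
carbon_model <- function(response, species_group, intercept, slopes) {
  structure(list(
    response = response, predictors = names(slopes),
    species_group = species_group,
    coefficients = c(`(Intercept)` = intercept, slopes),
    p_values = NULL, fit_r2 = NA_real_, loocv_r2 = NA_real_,
    loocv_rmse = NA_real_, max_vif = NA_real_, n_plots = NA_integer_,
    lm = NULL
  ), class = "carbon_lm")
}

#' Assemble a registry from a list of models
#'
#' Validates that each response covers every species exactly once.
#'
#' @param models list of `carbon_lm` objects (each with a `species_group`).
#' @return a `model_registry`.
#' @export
model_registry <- function(models) {
  registry <- list()
  for (m in models) {
    resp <- m$response
    if (is.null(registry[[resp]])) {
      registry[[resp]] <- list(models = list(), partition = character(0),
                               mean_loocv_r2 = NA_real_, candidates = NULL)
    }
    key <- paste(sort(m$species_group), collapse = "+")
    registry[[resp]]$models[[key]] <- m
    registry[[resp]]$partition <- c(registry[[resp]]$partition, key)
  }
  for (resp in names(registry)) {
    sp <- unlist(lapply(registry[[resp]]$models,
                        function(m) m$species_group))
    if (anyDuplicated(sp)) {
      stop("species covered more than once for response ", resp,
           call. = FALSE)
    }
  }
  structure(registry, class = "model_registry")
}

#' Example model registry of published-style carbon equations
#'
#' Species-routed linear models of the shape produced by
#' [select_models()] for a mixed four-species mangrove stand: a pooled
#' canopy-height model for the tall *R. stylosa* / *A. marina* group
#' (AGC = 33.50 H_Mean − 28.49; BGC = 9.20 H_Mean + 2.75), red-edge
#' texture-mean models for *A. corniculatum* (AGC = 20.07 RE_Mean −
#' 464.53; BGC = 8.09 RE_Mean − 187.21) and multivariate texture models
#' for *B. gymnorrhiza* (AGC = 293.07 B_Var − 31.21 R_Con + 17.14;
#' BGC = 95.55 B_Var + 241.071 NIR_Hom − 20.18 B_Con − 54.10). Useful as
#' carbon-mapping defaults and as ground truth for parameter-recovery
#' simulations.
#'
#' @return a `model_registry` covering the four mangrove species for AGC
#'   and BGC.
#' @export
example_model_registry <- function() {
  rs_am <- c("R_stylosa", "A_marina")
  model_registry(list(
    carbon_model("agc", rs_am, -28.49, c(H_Mean = 33.50)),
    carbon_model("bgc", rs_am, 2.75, c(H_Mean = 9.20)),
    carbon_model("agc", "A_corniculatum", -464.53, c(RE_Mean = 20.07)),
    carbon_model("bgc", "A_corniculatum", -187.21, c(RE_Mean = 8.09)),
    carbon_model("agc", "B_gymnorrhiza", 17.14,
                 c(B_Var = 293.07, R_Con = -31.21)),
    carbon_model("bgc", "B_gymnorrhiza", -54.10,
                 c(B_Var = 95.55, NIR_Hom = 241.071, B_Con = -20.18))
  ))
}

#' Write / read a model registry as JSON
#'
#' Schema per entry: `response`, `species_group`, `predictors`,
#' `coefficients` (intercept first), `fit_r2`, `loocv_r2`, `loocv_rmse`,
#' `max_vif`.
#'
#' @param registry a `model_registry`.
#' @param path JSON file path.
#' @return `read_model_registry()` returns a `model_registry`.
#' @export
write_model_registry <- function(registry, path) {
  entries <- list()
  for (resp in names(registry)) {
    for (m in registry[[resp]]$models) {
      entries[[length(entries) + 1]] <- list(
        response = m$response, species_group = m$species_group,
        predictors = m$predictors,
        coefficients = as.list(m$coefficients),
        fit_r2 = m$fit_r2, loocv_r2 = m$loocv_r2,
        loocv_rmse = m$loocv_rmse, max_vif = m$max_vif)
    }
  }
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_model_registry
#' @export
read_model_registry <- function(path) {
  entries <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  models <- lapply(entries, function(e) {
    co <- unlist(e$coefficients)
    m <- carbon_model(e$response, unlist(e$species_group), co[1], co[-1])
    for (f in c("fit_r2", "loocv_r2", "loocv_rmse", "max_vif")) {
      if (!is.null(e[[f]])) m[[f]] <- e[[f]]
    }
    m
  })
  model_registry(models)
}
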
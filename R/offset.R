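#' Climate grid container
#'
#' A plain data.frame raster: one row per cell with `lon`, `lat` and the
#' bioclimatic variables, tagged with epoch / scenario / model labels.
#' Grids that are compared must share an identical cell registry
#' (lon/lat rows in the same order).
#'
#' @param cells data.frame(lon, lat, <variables...>).
#' @param epoch `"current"` or `"future"`.
#' @param scenario emission-scenario label (e.g. `"ssp126"`).
#' @param model climate-model label (e.g. a GCM name).
#' @export
climate_grid <- function(cells, epoch = c("current", "future"),
                         scenario = "none", model = "none") {
  epoch <- match.arg(epoch)
  cells <- as.data.frame(cells)
  assert_that(all(c("lon", "lat") %in% names(cells)),
              "cells need lon and lat columns")
  structure(cells, epoch = epoch, scenario = scenario, model = model,
            class = c("climate_grid", "data.frame"))
}

grid_vars <- function(grid) setdiff(names(grid), c("lon", "lat"))

same_registry <- function(a, b) {
  nrow(a) == nrow(b) && all(a$lon == b$lon) && all(a$lat == b$lat)
}

## ---- regression trees with split bookkeeping ----------------------------

## Exhaustive-best-split CART for tiny n, recording every split's
## (predictor, value, SSE reduction). X: n x p matrix, y: response.
grow_tree <- function(X, y, mtry, min_node, max_depth) {
  splits <- list()
  build <- function(rows, depth) {
    n <- length(rows)
    node_mean <- mean(y[rows])
    if (n < 2 * min_node || depth >= max_depth ||
        stats::var(y[rows]) == 0)
      return(list(leaf = TRUE, value = node_mean))
    cand <- sample.int(ncol(X), min(mtry, ncol(X)))
    best <- NULL
    sse0 <- sum((y[rows] - node_mean)^2)
    for (v in cand) {
      x <- X[rows, v]
      ux <- sort(unique(x))
      if (length(ux) < 2) next
      cuts <- (ux[-1] + ux[-length(ux)]) / 2
      for (cut in cuts) {
        l <- rows[x <= cut]; r <- rows[x > cut]
        if (length(l) < min_node || length(r) < min_node) next
        sse <- sum((y[l] - mean(y[l]))^2) + sum((y[r] - mean(y[r]))^2)
        red <- sse0 - sse
        if (is.null(best) || red > best$red)
          best <- list(v = v, cut = cut, red = red, l = l, r = r)
      }
    }
    if (is.null(best) || best$red <= 0)
      return(list(leaf = TRUE, value = node_mean))
    splits[[length(splits) + 1]] <<- c(var = best$v, cut = best$cut,
                                       red = best$red)
    list(leaf = FALSE, var = best$v, cut = best$cut,
         left = build(best$l, depth + 1), right = build(best$r, depth + 1))
  }
  tree <- build(seq_along(y), 0)
  list(tree = tree, splits = splits)
}

predict_tree <- function(node, Xrow) {
  while (!node$leaf)
    node <- if (Xrow[node$var] <= node$cut) node$left else node$right
  node$value
}

#' Fit a gradient forest on allele frequencies vs environment
#'
#' Per SNP, an ensemble of regression trees predicts its allele frequency
#' from the environmental predictors (bootstrap samples, random predictor
#' subsets, exhaustive split search). Each split's impurity (SSE)
#' reduction is attributed to its predictor at the split value. Per-SNP
#' split importances are averaged over trees, weighted by the SNP's
#' out-of-bag R^2 truncated at zero (R+^2), binned along each predictor's
#' observed range and accumulated into a nondecreasing
#' cumulative-importance step function per predictor.
#'
#' @param freqs units x SNPs allele-frequency matrix (units are typically
#'   populations).
#' @param env units x predictors table (lon/lat/unit columns ignored),
#'   rows aligned with `freqs`.
#' @param n_trees trees per SNP (default 500).
#' @param n_bins importance bins per predictor (default 200).
#' @param seed RNG seed; the fit is reproducible bit-for-bit.
#' @param mtry predictors tried per split (default ceiling(p/3)).
#' @param min_node minimum leaf size (default 2; units are few).
#' @param max_depth maximum tree depth (default 3).
#' @param bootstrap resample units per tree (default TRUE). With FALSE
#'   every tree sees the full data (deterministic splits) and fit quality
#'   falls back to in-sample R^2 — useful for single-tree checks.
#' @return object of class `gradient_forest_model`: per-predictor step
#'   functions (`curves`: pos, imp, cum), per-SNP out-of-bag R^2
#'   (`r2`), total importance per predictor (`importance`) and the
#'   hyperparameters.
#' @export
fit_gradient_forest <- function(freqs, env, n_trees = 500, n_bins = 200,
                                seed = 1, mtry = NULL, min_node = 2,
                                max_depth = 3, bootstrap = TRUE) {
  freqs <- as.matrix(freqs)
  env <- as.data.frame(env)
  vars <- setdiff(names(env)[vapply(env, is.numeric, logical(1))],
                  c("lon", "lat"))
  X <- as.matrix(env[vars])
  assert_that(nrow(X) == nrow(freqs) && nrow(X) >= 2,
              "freqs and env must share >= 2 aligned units")
  p <- ncol(X); n <- nrow(X)
  mtry <- mtry %||% max(1L, ceiling(p / 3))
  edges <- lapply(seq_len(p), function(v)
    seq(min(X[, v]), max(X[, v]), length.out = n_bins + 1))
  mids <- lapply(edges, function(e) (e[-1] + e[-length(e)]) / 2)
  imp <- matrix(0, p, n_bins)
  r2 <- stats::setNames(numeric(ncol(freqs)),
                        colnames(freqs) %||% seq_len(ncol(freqs)))
  with_seed(seed, {
    for (s in seq_len(ncol(freqs))) {
      y <- freqs[, s]
      if (stats::var(y) == 0) next
      oob_sum <- numeric(n); oob_cnt <- integer(n)
      snp_imp <- matrix(0, p, n_bins)
      for (t in seq_len(n_trees)) {
        boot <- if (bootstrap) sample.int(n, replace = TRUE) else seq_len(n)
        oob <- if (bootstrap) setdiff(seq_len(n), unique(boot))
               else seq_len(n)
        fit <- grow_tree(X[boot, , drop = FALSE], y[boot], mtry,
                         min_node, max_depth)
        for (sp in fit$splits) {
          v <- as.integer(sp[["var"]])
          b <- findInterval(sp[["cut"]], edges[[v]], all.inside = TRUE)
          snp_imp[v, b] <- snp_imp[v, b] + sp[["red"]] / n_trees
        }
        for (i in oob) {
          oob_sum[i] <- oob_sum[i] + predict_tree(fit$tree, X[i, ])
          oob_cnt[i] <- oob_cnt[i] + 1L
        }
      }
      seen <- oob_cnt > 0
      if (sum(seen) >= 2 && stats::var(y[seen]) > 0) {
        pred <- oob_sum[seen] / oob_cnt[seen]
        r2[s] <- 1 - sum((y[seen] - pred)^2) /
          sum((y[seen] - mean(y[seen]))^2)
      }
      imp <- imp + max(r2[s], 0) * snp_imp
    }
  })
  if (all(imp == 0))
    warning("no SNP carried positive out-of-bag R^2; all cumulative-importance functions are zero",
            call. = FALSE)
  curves <- lapply(seq_len(p), function(v)
    data.frame(pos = mids[[v]], imp = imp[v, ], cum = cumsum(imp[v, ])))
  names(curves) <- vars
  structure(list(curves = curves, r2 = r2,
                 importance = stats::setNames(rowSums(imp), vars),
                 hyper = list(n_trees = n_trees, n_bins = n_bins,
                              seed = seed, mtry = mtry,
                              min_node = min_node, max_depth = max_depth)),
            class = "gradient_forest_model")
}

#' @export
print.gradient_forest_model <- function(x, ...) {
  cat(sprintf("gradient_forest_model: %d predictors, %d SNPs (mean R+^2 %.3f)\n",
              length(x$curves), length(x$r2), mean(pmax(x$r2, 0))))
  imp <- sort(x$importance, decreasing = TRUE)
  cat("  importance:", paste(sprintf("%s=%.3g", names(imp), imp),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Map environmental values through cumulative-importance functions
#'
#' Step-function evaluation: values below the first importance step give
#' 0, values above the last give the function maximum.
#'
#' @param model a [fit_gradient_forest()] model.
#' @param values data.frame or matrix whose columns cover the model's
#'   predictors (extra columns ignored).
#' @return matrix of transformed values, one column per model predictor.
#' @export
transform_env <- function(model, values) {
  if (is.null(dim(values)) && !is.data.frame(values))
    values <- as.data.frame(as.list(values))  # named vector -> 1-row frame
  values <- as.data.frame(values)
  vars <- names(model$curves)
  missing_v <- setdiff(vars, names(values))
  assert_that(length(missing_v) == 0,
              paste("values lack model predictors:",
                    paste(missing_v, collapse = ", ")))
  out <- sapply(vars, function(v) {
    cv <- model$curves[[v]]
    i <- findInterval(values[[v]], cv$pos)
    c(0, cv$cum)[i + 1]
  })
  out <- matrix(out, nrow = nrow(values), dimnames = list(NULL, vars))
  out
}

#' Genomic offset between current and future climate grids
#'
#' Per cell, the Euclidean distance between the gradient-forest-transformed
#' current and future climate vectors.
#'
#' @param model a [fit_gradient_forest()] model.
#' @param current,future [climate_grid()]s sharing the cell registry.
#' @return data.frame(lon, lat, offset) with scenario/model attributes.
#' @export
compute_offset <- function(model, current, future) {
  assert_that(same_registry(current, future),
              "current and future grids differ in cell registry")
  tc <- transform_env(model, current)
  tf <- transform_env(model, future)
  structure(data.frame(lon = current$lon, lat = current$lat,
                       offset = sqrt(rowSums((tf - tc)^2))),
            scenario = attr(future, "scenario"),
            model = attr(future, "model"))
}

#' Average offset grids across climate models
#'
#' Cellwise arithmetic mean of per-model offset grids for one scenario.
#'
#' @param grids list of [compute_offset()] outputs.
#' @export
average_offsets <- function(grids) {
  assert_that(length(grids) >= 1, "need at least one offset grid")
  ref <- grids[[1]]
  scen <- attr(ref, "scenario")
  for (g in grids[-1]) {
    assert_that(same_registry(ref, g), "offset grids differ in cell registry")
    assert_that(identical(attr(g, "scenario"), scen),
                "offset grids mix scenarios")
  }
  vals <- sapply(grids, function(g) g$offset)
  vals <- matrix(vals, nrow = nrow(ref))
  assert_that(!anyNA(vals), "offset grids contain missing cells")
  structure(data.frame(lon = ref$lon, lat = ref$lat,
                       offset = rowMeans(vals)),
            scenario = scen, model = "ensemble_mean")
}
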
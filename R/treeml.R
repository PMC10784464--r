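#' Encode SNP and environment-factor features for tree ensembles
#'
#' Builds one row per hybrid-by-environment cell: the hybrid's SNP dosages
#' followed by one-hot indicators for location and year (the environment
#' factors that let a single model predict within each environment of a trial
#' series). Column order is deterministic: markers in genotype order, then
#' location indicators, then year indicators. When `cells` carries an `eblue`
#' column it is attached as `response`, so the same function constructs
#' training rows (observed cells) and prediction rows (masked cells).
#'
#' @param hybrids Hybrid [geno_matrix()] with no missing dosages.
#' @param cells Tibble with columns `hybrid`, `environment` and optionally
#'   `eblue` (the response).
#' @param env_info Tibble mapping `environment` to `location` and `year`.
#' @return Tibble with identifier columns `hybrid`, `environment`, an optional
#'   `response`, and the predictor columns; the predictor names are attached
#'   as attribute `predictors`.
#' @export
encode_features <- function(hybrids, cells, env_info) {
  unknown_env <- setdiff(cells$environment, env_info$environment)
  if (length(unknown_env)) {
    abort(paste("unknown environment label:", paste(unknown_env, collapse = ", ")))
  }
  unknown_h <- setdiff(cells$hybrid, rownames(hybrids))
  if (length(unknown_h)) {
    abort(paste("hybrids without genotypes:",
                paste(utils::head(unknown_h, 5), collapse = ", ")))
  }
  m <- unclass(hybrids)[cells$hybrid, , drop = FALSE]
  locs <- sort(unique(env_info$location))
  yrs <- sort(unique(env_info$year))
  ei <- env_info[match(cells$environment, env_info$environment), ]
  loc_mat <- outer(ei$location, locs, `==`) * 1
  yr_mat <- outer(ei$year, yrs, `==`) * 1
  colnames(loc_mat) <- paste0("loc_", locs)
  colnames(yr_mat) <- paste0("year_", yrs)
  preds <- cbind(m, loc_mat, yr_mat)
  rownames(preds) <- NULL
  out <- bind_cols(
    tibble(hybrid = cells$hybrid, environment = cells$environment),
    if ("eblue" %in% names(cells)) tibble(response = cells$eblue) else NULL,
    as_tibble(preds)
  )
  attr(out, "predictors") <- colnames(preds)
  out
}

#' Fit a tree-ensemble genomic predictor
#'
#' Three regression-tree ensembles over SNP-plus-environment features:
#'
#' * **bagging** - `n_trees` (default 500) unpruned trees on bootstrap
#'   resamples, prediction equal to the plain average
#'   \eqn{\hat f(x) = \frac1D \sum_d \hat f^d(x)}; every predictor is a split
#'   candidate.
#' * **random_forest** - the same with `m_try` (default `floor(p/3)`, at least
#'   1) predictors sampled as candidates at each split, which decorrelates the
#'   trees. Bagging is exactly the `m_try = p` special case, and both are
#'   fitted through the same well-tested tree machinery (randomForest),
#'   minimum node size 5, no pruning.
#' * **boosting** - `n_trees` (default 250) depth-limited trees fitted
#'   sequentially to the current residuals and accumulated with shrinkage:
#'   \eqn{\hat f(x) = \bar y + \sum_b \lambda \hat f^b(x)}, learning rate
#'   `learning_rate` (default 0.1) and `depth` (default 3). The baseline is
#'   the training mean, so that zero trees predict the mean. No row
#'   subsampling is used.
#'
#' All three are exactly reproducible under `seed`.
#'
#' @param train Feature table from [encode_features()] with a `response`.
#' @param method One of `"bagging"`, `"random_forest"`, `"boosting"`.
#' @param n_trees Ensemble size; defaults: 500 (bagging, random forest),
#'   250 (boosting).
#' @param m_try Split candidates per node (random forest only); default
#'   `floor(p/3)` counting all predictor columns, minimum 1.
#' @param learning_rate,depth Boosting shrinkage and maximum tree depth.
#' @param min_node Minimum terminal-node size (default 5).
#' @param seed Integer seed.
#' @return Object of class `tree_ensemble`.
#' @export
fit_ensemble <- function(train, method = c("bagging", "random_forest", "boosting"),
                         n_trees = NULL, m_try = NULL, learning_rate = 0.1,
                         depth = 3, min_node = 5, seed = 1L) {
  method <- match.arg(method)
  if (!"response" %in% names(train)) abort("training table has no response column")
  if (nrow(train) == 0) abort("empty training table")
  preds <- attr(train, "predictors") %||%
    setdiff(names(train), c("hybrid", "environment", "response"))
  x <- as.data.frame(train[, preds, drop = FALSE])
  y <- train$response
  p <- length(preds)
  if (learning_rate <= 0 || learning_rate > 1) abort("learning_rate must be in (0, 1]")

  if (method %in% c("bagging", "random_forest")) {
    n_trees <- n_trees %||% 500L
    mtry <- if (method == "bagging") p else (m_try %||% max(1L, floor(p / 3)))
    if (mtry > p) abort(sprintf("m_try = %d exceeds the %d predictors", mtry, p))
    if (mtry < 1) abort("m_try must be >= 1")
    rf <- withr::with_seed(seed, randomForest::randomForest(
      x = x, y = y, ntree = n_trees, mtry = mtry, nodesize = min_node
    ))
    model <- list(rf = rf)
  } else {
    n_trees <- n_trees %||% 250L
    if (n_trees < 1) abort("n_trees must be >= 1")
    baseline <- mean(y)
    r <- y - baseline
    trees <- vector("list", n_trees)
    dat <- x
    ctrl <- rpart::rpart.control(maxdepth = depth, cp = 0, xval = 0,
                                 minsplit = max(2L, 2L * min_node),
                                 minbucket = min_node)
    withr::with_seed(seed, {
      for (b in seq_len(n_trees)) {
        dat$.r <- r
        tr <- rpart::rpart(.r ~ ., data = dat, method = "anova", control = ctrl)
        fitted_b <- predict(tr, newdata = x)
        r <- r - learning_rate * fitted_b
        trees[[b]] <- tr
      }
    })
    model <- list(trees = trees, baseline = baseline, lambda = learning_rate)
  }
  structure(list(method = method, model = model, predictors = preds,
                 n_trees = n_trees,
                 m_try = if (method == "random_forest") (m_try %||% max(1L, floor(p / 3)))
                         else if (method == "bagging") p else NA_integer_,
                 learning_rate = if (method == "boosting") learning_rate else NA_real_,
                 depth = if (method == "boosting") depth else NA_real_,
                 min_node = min_node, seed = seed),
            class = "tree_ensemble")
}

#' Predict from a fitted tree ensemble
#'
#' @param object A `tree_ensemble`.
#' @param newdata Feature table whose predictor columns match the training
#'   ones in name and order (e.g. built by the same [encode_features()] call).
#' @param n_trees For boosting, use only the first `n_trees` trees (handy for
#'   learning-curve checks); default all.
#' @param ... Unused.
#' @return Tibble `hybrid`, `environment`, `method`, `pred` when identifier
#'   columns are present, otherwise a numeric vector.
#' @export
predict.tree_ensemble <- function(object, newdata, n_trees = NULL, ...) {
  preds <- attr(newdata, "predictors") %||%
    setdiff(names(newdata), c("hybrid", "environment", "response"))
  if (!identical(preds, object$predictors)) {
    abort("predictor columns do not match the training feature table")
  }
  x <- as.data.frame(newdata[, preds, drop = FALSE])
  out <- if (object$method == "boosting") {
    use <- seq_len(n_trees %||% object$n_trees)
    contrib <- vapply(object$model$trees[use],
                      function(tr) predict(tr, newdata = x), numeric(nrow(x)))
    if (nrow(x) == 1) contrib <- matrix(contrib, nrow = 1)
    unname(object$model$baseline + object$model$lambda * rowSums(contrib))
  } else {
    as.numeric(predict(object$model$rf, newdata = x))
  }
  if (all(c("hybrid", "environment") %in% names(newdata))) {
    tibble(hybrid = newdata$hybrid, environment = newdata$environment,
           method = object$method, pred = out)
  } else {
    out
  }
}

#' @rdname predict.tree_ensemble
#' @param model A `tree_ensemble` (alias taking the model first, matching the
#'   fit/predict naming of the other modules).
#' @param cells Feature rows to predict.
#' @export
predict_ensemble <- function(model, cells, ...) predict(model, cells, ...)

#' @export
print.tree_ensemble <- function(x, ...) {
  cat(sprintf("<tree_ensemble> %s, %d trees", x$method, x$n_trees))
  if (x$method == "random_forest") cat(sprintf(", m_try = %d", x$m_try))
  if (x$method == "boosting") {
    cat(sprintf(", lambda = %g, depth = %g", x$learning_rate, x$depth))
  }
  cat(sprintf(", %d predictors\n", length(x$predictors)))
  invisible(x)
}
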
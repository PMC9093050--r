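#' Select the features with the smallest p-value
#'
#' Returns every candidate column achieving the minimal p (ties are all
#' included), mirroring a smallest-p feature-selection rule.
#'
#' @param p_values named numeric vector of per-feature p-values.
#' @return Character vector of selected feature names.
#' @export
select_features <- function(p_values) {
  if (!length(p_values)) stop("no candidate features")
  names(p_values)[p_values == min(p_values)]
}

# scaling + PCA fitted on the training rows only; returns transform closures
fit_reduction <- function(X_train, n_components) {
  mu <- colMeans(X_train)
  sdv <- apply(X_train, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  Xs <- sweep(sweep(X_train, 2L, mu), 2L, sdv, `/`)
  k <- max(1L, min(n_components, ncol(Xs), nrow(Xs)))
  rot <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)$rotation[, seq_len(k), drop = FALSE]
  list(transform = function(X) {
    Xs <- sweep(sweep(as.matrix(X), 2L, mu), 2L, sdv, `/`)
    Xs %*% rot
  }, k = k)
}

rmse <- function(a, b) sqrt(mean((a - b)^2))

#' Nested leave-one-out cross-validated linear SVM
#'
#' Outer LOOCV leaves out one row (`folds = "row"`, the default: one
#' recording per fold) or one subject's both rows (`folds = "subject"`). The
#' inner LOOCV grid-searches the SVM cost over the training rows only; feature
#' scaling and PCA are refitted inside every training fold, so no statistic of
#' the held-out data ever reaches a fit. The AUC is computed from the decision
#' scores pooled across outer folds.
#'
#' @param table data frame with columns `subject`, `condition` (two classes)
#'   and numeric feature columns.
#' @param features feature column names (default: all numeric non-id columns).
#' @param n_components principal components retained (default 2).
#' @param C_grid cost grid (default `c(0.01, 0.1, 1, 10, 100)`).
#' @param folds `"row"` or `"subject"`.
#' @param seed integer seed (the procedure is deterministic; the seed guards
#'   any RNG used by the SVM backend).
#' @return A `cv_evaluation` with per-fold predictions, pooled `auc`, and the
#'   chosen cost and fit coefficients per fold.
#' @export
nested_loocv_svm <- function(table, features = NULL, n_components = 2,
                             C_grid = c(0.01, 0.1, 1, 10, 100),
                             folds = c("row", "subject"), seed = NULL) {
  folds <- match.arg(folds)
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  if (is.null(features))
    features <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                        c("subject", "condition"))
  X <- as.matrix(table[, features, drop = FALSE])
  yl <- factor(table$condition)
  if (nlevels(yl) != 2) stop("`condition` must have exactly two classes")
  fold_ids <- if (folds == "row") seq_len(nrow(table)) else
    match(table$subject, unique(table$subject))
  preds <- numeric(nrow(table))
  fold_info <- list()
  for (f in unique(fold_ids)) {
    test <- which(fold_ids == f)
    train <- setdiff(seq_len(nrow(table)), test)
    if (nlevels(droplevels(yl[train])) != 2) stop("a class is absent in a training fold")
    best <- select_cost_svm(X[train, , drop = FALSE], yl[train], n_components, C_grid)
    red <- fit_reduction(X[train, , drop = FALSE], n_components)
    fit <- e1071::svm(red$transform(X[train, , drop = FALSE]), yl[train],
                      kernel = "linear", cost = best, scale = FALSE)
    dv <- attr(stats::predict(fit, red$transform(X[test, , drop = FALSE]),
                              decision.values = TRUE), "decision.values")
    # orient the score toward the second factor level
    flip <- if (grepl(paste0("^", levels(yl)[1], "/"), colnames(dv)[1])) -1 else 1
    preds[test] <- flip * dv[, 1]
    fold_info[[length(fold_info) + 1L]] <- list(
      fold = f, cost = best,
      coefs = as.numeric(crossprod(fit$coefs, fit$SV)), rho = fit$rho)
  }
  auc <- as.numeric(pROC::auc(pROC::roc(response = yl, predictor = preds,
                                        levels = levels(yl), direction = "<",
                                        quiet = TRUE)))
  structure(list(
    predictions = tibble::tibble(subject = table$subject,
                                 condition = as.character(yl),
                                 score = preds, fold = fold_ids),
    auc = auc, folds = folds, fold_info = fold_info, task = "classification"),
    class = "cv_evaluation")
}

select_cost_svm <- function(X, y, n_components, C_grid) {
  if (length(C_grid) == 1L) return(C_grid)
  n <- nrow(X)
  acc <- vapply(C_grid, function(C) {
    ok <- 0
    for (i in seq_len(n)) {
      tr <- setdiff(seq_len(n), i)
      if (nlevels(droplevels(y[tr])) != 2) next
      red <- fit_reduction(X[tr, , drop = FALSE], n_components)
      fit <- e1071::svm(red$transform(X[tr, , drop = FALSE]), y[tr],
                        kernel = "linear", cost = C, scale = FALSE)
      pr <- stats::predict(fit, red$transform(X[i, , drop = FALSE]))
      ok <- ok + (pr == y[i])
    }
    ok / n
  }, numeric(1))
  C_grid[which.max(acc)]
}

#' Nested leave-one-out cross-validated linear SVR
#'
#' As [nested_loocv_svm()] but for outcome regression: one retained principal
#' component by default, a grid over cost and epsilon, and RMSE plus the
#' predicted-actual correlation as pooled metrics. Setting `exclude` reports
#' an additional RMSE with the named subjects' predictions left out (no
#' automatic outlier detection).
#'
#' @param table data frame with columns `subject`, `outcome` and feature
#'   columns.
#' @param features feature column names.
#' @param n_components principal components retained (default 1).
#' @param C_grid,eps_grid hyperparameter grids.
#' @param exclude optional subject identifiers excluded from `rmse_excluded`.
#' @param seed integer seed.
#' @return A `cv_evaluation` with `rmse`, `cor`, optional `rmse_excluded`.
#' @export
nested_loocv_svr <- function(table, features = NULL, n_components = 1,
                             C_grid = c(0.01, 0.1, 1, 10, 100),
                             eps_grid = c(0.01, 0.1, 1),
                             exclude = NULL, seed = NULL) {
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  if (nrow(table) < 3) stop("need at least 3 subjects")
  if (stats::sd(table$outcome) == 0) stop("constant outcome")
  if (is.null(features))
    features <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                        c("subject", "outcome"))
  X <- as.matrix(table[, features, drop = FALSE])
  y <- table$outcome
  n <- nrow(table)
  preds <- numeric(n)
  fold_info <- list()
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    best <- select_params_svr(X[tr, , drop = FALSE], y[tr], n_components,
                              C_grid, eps_grid)
    red <- fit_reduction(X[tr, , drop = FALSE], n_components)
    fit_at <- function(eps) e1071::svm(red$transform(X[tr, , drop = FALSE]), y[tr],
                                       type = "eps-regression", kernel = "linear",
                                       cost = best["cost"], epsilon = eps,
                                       scale = FALSE)
    pred_i <- tryCatch(stats::predict(fit_at(best["epsilon"]),
                                      red$transform(X[i, , drop = FALSE])),
                       error = function(e) NULL)
    if (is.null(pred_i)) {   # empty epsilon tube on this fold: tighten it
      best["epsilon"] <- min(eps_grid)
      pred_i <- stats::predict(fit_at(best["epsilon"]),
                               red$transform(X[i, , drop = FALSE]))
    }
    fit <- fit_at(best["epsilon"])
    preds[i] <- pred_i
    fold_info[[i]] <- list(fold = i, cost = best["cost"],
                           epsilon = best["epsilon"],
                           coefs = as.numeric(crossprod(fit$coefs, fit$SV)),
                           rho = fit$rho)
  }
  out <- structure(list(
    predictions = tibble::tibble(subject = table$subject, actual = y,
                                 predicted = preds, fold = seq_len(n)),
    rmse = rmse(preds, y),
    cor = stats::cor(preds, y),
    fold_info = fold_info, task = "regression"),
    class = "cv_evaluation")
  if (!is.null(exclude)) {
    keep <- !(table$subject %in% exclude)
    out$rmse_excluded <- rmse(preds[keep], y[keep])
    out$excluded <- exclude
  }
  out
}

select_params_svr <- function(X, y, n_components, C_grid, eps_grid) {
  n <- nrow(X)
  grid <- expand.grid(cost = C_grid, epsilon = eps_grid)
  if (nrow(grid) == 1L) return(c(cost = grid$cost[1], epsilon = grid$epsilon[1]))
  err <- vapply(seq_len(nrow(grid)), function(g) {
    pr <- vapply(seq_len(n), function(i) {
      tr <- setdiff(seq_len(n), i)
      red <- fit_reduction(X[tr, , drop = FALSE], n_components)
      # an epsilon tube wide enough to hold every point leaves no support
      # vectors; treat such fits as unusable for this grid point
      tryCatch({
        fit <- e1071::svm(red$transform(X[tr, , drop = FALSE]), y[tr],
                          type = "eps-regression", kernel = "linear",
                          cost = grid$cost[g], epsilon = grid$epsilon[g],
                          scale = FALSE)
        stats::predict(fit, red$transform(X[i, , drop = FALSE]))
      }, error = function(e) NA_real_)
    }, numeric(1))
    if (anyNA(pr)) Inf else rmse(pr, y)
  }, numeric(1))
  best <- which.min(err)
  c(cost = grid$cost[best], epsilon = grid$epsilon[best])
}

#' @export
print.cv_evaluation <- function(x, ...) {
  if (x$task == "classification") {
    cat(sprintf("<cv_evaluation> nested-LOOCV SVM (%s folds): AUC = %.3f\n",
                x$folds, x$auc))
  } else {
    cat(sprintf("<cv_evaluation> nested-LOOCV SVR: RMSE = %.3f, r = %.3f\n",
                x$rmse, x$cor))
  }
  invisible(x)
}
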
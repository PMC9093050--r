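#' Tidy a permutation test result
#'
#' @param x a `perm_result`.
#' @param ... unused.
#' @return One-row tibble: statistic, p, permutation count and mode.
#' @export
tidy.perm_result <- function(x, ...) {
  tibble::tibble(design = x$design, stat = x$stat, statistic = x$statistic,
                 p.value = x$p, n_perm = x$n_perm, exhaustive = x$exhaustive)
}

#' @rdname tidy.perm_result
#' @export
glance.perm_result <- function(x, ...) tidy.perm_result(x)

#' Tidy an NBS result: one row per connected component
#'
#' @param x an `nbs_result`.
#' @param ... unused.
#' @export
tidy.nbs_result <- function(x, ...) {
  dplyr::mutate(x$components, n_edges = purrr::map_int(.data$edges, nrow))
}

#' @rdname tidy.nbs_result
#' @export
glance.nbs_result <- function(x, ...) {
  tibble::tibble(design = x$design, n_perm = x$n_perm,
                 exhaustive = x$exhaustive, edge_alpha = x$edge_alpha,
                 n_components = nrow(x$components),
                 min_p = if (nrow(x$components)) min(x$components$p) else NA_real_)
}

#' Tidy a cross-validation evaluation: per-fold predictions
#'
#' @param x a `cv_evaluation`.
#' @param ... unused.
#' @export
tidy.cv_evaluation <- function(x, ...) x$predictions

#' @rdname tidy.cv_evaluation
#' @export
glance.cv_evaluation <- function(x, ...) {
  if (x$task == "classification") {
    tibble::tibble(task = x$task, auc = x$auc, n_folds = length(x$fold_info))
  } else {
    tibble::tibble(task = x$task, rmse = x$rmse, cor = x$cor,
                   rmse_excluded = x$rmse_excluded %||% NA_real_,
                   n_folds = length(x$fold_info))
  }
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
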
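# RNG bookkeeping: functions that take a `seed` restore the caller's RNG state
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}

new_perm_result <- function(statistic, null, n_perm, exhaustive,
                            design, stat_name) {
  p <- (sum(abs(null) > abs(statistic)) + 1) / (n_perm + 1)
  structure(list(statistic = statistic, null = null, p = p,
                 exhaustive = exhaustive, n_perm = n_perm,
                 design = design, stat = stat_name),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("<perm_result> %s %s: stat = %.4g, p = %.4g (%s, %d permutations)\n",
              x$design, x$stat, x$statistic, x$p,
              if (x$exhaustive) "exhaustive" else "random", x$n_perm))
  invisible(x)
}

#' Number of possible permutations for a design
#'
#' Within-subjects sign flips give `2^n`; between-subjects label shuffles give
#' `choose(n1 + n2, n1)`; correlation (order shuffles) gives `n!`.
#'
#' @param design `"within"`, `"between"` or `"correlation"`.
#' @param n subject count (within / correlation) or `c(n1, n2)` (between).
#' @export
count_permutations <- function(design = c("within", "between", "correlation"), n) {
  design <- match.arg(design)
  switch(design,
         within = 2^n,
         between = choose(sum(n), n[1]),
         correlation = factorial(n))
}

t_one_sample <- function(d) {
  s <- stats::sd(d)
  if (s == 0) return(NA_real_)
  mean(d) / (s / sqrt(length(d)))
}

t_welch <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  if (va + vb == 0) return(NA_real_)
  (mean(a) - mean(b)) / sqrt(va + vb)
}

#' Permutation test for scalar features
#'
#' Within-subjects design: the signs of the per-subject condition differences
#' are flipped (all `2^n` flips when that count does not exceed `max_perm`,
#' otherwise `max_perm` random flips) with the one-sample t statistic.
#' Between-subjects design: condition labels are shuffled (exhaustive over the
#' `choose(n1+n2, n1)` assignments when feasible) with the standard
#' error-weighted mean difference (Welch t). The two-sided p-value is
#' add-one-corrected: `p = (#{|t_perm| > |t_obs|} + 1) / (n_perm + 1)`, so the
#' minimum attainable p is `1/(n_perm + 1)` — e.g. 1/17 = 0.059 for n = 4
#' within, 1/257 = 0.004 for n = 8 within, 1/71 = 0.014 for 4-vs-4 between.
#'
#' @param x per-subject values: condition differences (within) or group A
#'   (between).
#' @param y second condition (within, optional: then differences are `x - y`)
#'   or group B (between).
#' @param design `"within"` or `"between"`.
#' @param max_perm permutation budget (default 2000).
#' @param seed integer seed for the random mode.
#' @return A `perm_result` (see [tidy.perm_result()]).
#' @export
perm_test_scalar <- function(x, y = NULL,
                             design = c("within", "between"),
                             max_perm = 2000, seed = NULL) {
  design <- match.arg(design)
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  if (design == "within") {
    d <- if (is.null(y)) x else x - y
    n <- length(d)
    if (n < 2) stop("need at least 2 subjects")
    obs <- t_one_sample(d)
    if (is.na(obs)) {
      warning("zero-variance differences: degenerate statistic, p = 1")
      return(new_perm_result(0, numeric(0), n_perm = 0, exhaustive = TRUE,
                             design, "t_paired"))
    }
    total <- 2^n
    if (total <= max_perm) {
      signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
      null <- apply(signs, 1L, function(s) t_one_sample(s * d))
      new_perm_result(obs, null, n_perm = total, exhaustive = TRUE,
                      design, "t_paired")
    } else {
      null <- replicate(max_perm, t_one_sample(sample(c(1, -1), n, replace = TRUE) * d))
      new_perm_result(obs, null, n_perm = max_perm, exhaustive = FALSE,
                      design, "t_paired")
    }
  } else {
    if (is.null(y)) stop("between design needs both groups")
    if (length(x) < 2 || length(y) < 2) stop("need at least 2 subjects per group")
    pooled <- c(x, y)
    n1 <- length(x); n <- length(pooled)
    obs <- t_welch(x, y)
    if (is.na(obs)) {
      warning("zero-variance groups: degenerate statistic, p = 1")
      return(new_perm_result(0, numeric(0), n_perm = 0, exhaustive = TRUE,
                             design, "t_welch"))
    }
    total <- choose(n, n1)
    if (total <= max_perm) {
      combos <- utils::combn(n, n1)
      null <- apply(combos, 2L, function(i) t_welch(pooled[i], pooled[-i]))
      new_perm_result(obs, null, n_perm = total, exhaustive = TRUE,
                      design, "t_welch")
    } else {
      null <- replicate(max_perm, {
        i <- sample.int(n, n1)
        t_welch(pooled[i], pooled[-i])
      })
      new_perm_result(obs, null, n_perm = max_perm, exhaustive = FALSE,
                      design, "t_welch")
    }
  }
}

spearman_rho <- function(x, y) stats::cor(rank(x), rank(y))

#' Spearman permutation correlation
#'
#' The outcome vector is shuffled (all `n!` orders when that count does not
#' exceed `max_perm`, otherwise random shuffles) with the Spearman correlation
#' coefficient (average ranks for ties) as the statistic, and the same
#' add-one two-sided p-value as [perm_test_scalar()].
#'
#' @param x per-subject feature values.
#' @param y per-subject outcome scores (shuffled under the null).
#' @param max_perm permutation budget.
#' @param seed integer seed for the random mode.
#' @return A `perm_result`.
#' @export
perm_corr <- function(x, y, max_perm = 2000, seed = NULL) {
  n <- length(x)
  if (n < 3) stop("need at least 3 subjects")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  obs <- spearman_rho(x, y)
  total <- factorial(n)
  rx <- rank(x)
  if (total <= max_perm) {
    perms <- permutations_of(n)
    null <- vapply(perms, function(p) stats::cor(rx, rank(y[p])), numeric(1))
    new_perm_result(obs, null, n_perm = total, exhaustive = TRUE,
                    "correlation", "spearman")
  } else {
    null <- replicate(max_perm, stats::cor(rx, rank(y[sample.int(n)])))
    new_perm_result(obs, null, n_perm = max_perm, exhaustive = FALSE,
                    "correlation", "spearman")
  }
}
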
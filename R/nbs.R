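# ---- edge-wise nonparametric tests, vectorized over edges -------------------
# D: subjects x edges matrix of paired differences. Signed-rank W+ per edge
# under a sign-flip vector f (+1 keep, -1 flip), with zeros dropped and
# midranks for tied |d|.
signed_rank_setup <- function(D) {
  n_edges <- ncol(D)
  ranks <- matrix(0, nrow(D), n_edges)
  n_eff <- integer(n_edges)
  tied <- logical(n_edges)
  for (e in seq_len(n_edges)) {
    d <- D[, e]
    nz <- d != 0
    r <- rank(abs(d[nz]))
    ranks[nz, e] <- r
    n_eff[e] <- sum(nz)
    tied[e] <- anyDuplicated(r) > 0
  }
  list(ranks = ranks, n_eff = n_eff, tied = tied)
}

signed_rank_p <- function(D, setup, flips = NULL) {
  # two-sided p per edge for (optionally sign-flipped) differences
  if (!is.null(flips)) D <- D * flips
  Wpos <- colSums(setup$ranks * (D > 0))
  n <- setup$n_eff
  p <- numeric(ncol(D))
  exact <- !setup$tied & n > 0
  if (any(exact)) {
    w <- Wpos[exact]; ne <- n[exact]
    lower <- stats::psignrank(w, ne)
    upper <- 1 - stats::psignrank(w - 1, ne)
    p[exact] <- pmin(1, 2 * pmin(lower, upper))
  }
  if (any(!exact)) {
    idx <- which(!exact)
    for (e in idx) {
      ne <- n[e]
      if (ne == 0) { p[e] <- 1; next }
      r <- setup$ranks[, e]
      mu <- sum(r) / 2
      sig2 <- sum(r^2) / 4
      z <- (Wpos[e] - mu) / sqrt(sig2)
      p[e] <- 2 * stats::pnorm(-abs(z))
    }
  }
  list(p = p, direction = sign(colSums(sign(D) * (D != 0))),
       median = apply(D, 2L, stats::median))
}

rank_sum_setup <- function(X, Y) {
  # X: nA x edges, Y: nB x edges; pooled midranks per edge
  P <- rbind(X, Y)
  n <- nrow(P)
  ranks <- apply(P, 2L, rank)
  tied <- apply(ranks, 2L, function(r) anyDuplicated(r) > 0)
  list(ranks = ranks, n = n, nA = nrow(X), tied = tied)
}

rank_sum_p <- function(setup, idxA) {
  nA <- length(idxA); nB <- setup$n - nA
  W <- colSums(setup$ranks[idxA, , drop = FALSE])
  U <- W - nA * (nA + 1) / 2
  p <- numeric(ncol(setup$ranks))
  exact <- !setup$tied
  if (any(exact)) {
    u <- U[exact]
    lower <- stats::pwilcox(u, nA, nB)
    upper <- 1 - stats::pwilcox(u - 1, nA, nB)
    p[exact] <- pmin(1, 2 * pmin(lower, upper))
  }
  if (any(!exact)) {
    idx <- which(!exact)
    for (e in idx) {
      r <- setup$ranks[, e]
      mu <- nA * (setup$n + 1) / 2
      # tie-corrected variance of the rank sum
      sig2 <- nA * nB / (setup$n * (setup$n - 1)) *
        (sum(r^2) - setup$n * (setup$n + 1)^2 / 4)
      z <- (W[e] - mu) / sqrt(sig2)
      p[e] <- 2 * stats::pnorm(-abs(z))
    }
  }
  p
}

spearman_edge <- function(RX, y) {
  # RX: standardized column ranks of x per edge (n x edges); y: outcomes
  n <- nrow(RX)
  ry <- rank(y)
  ry <- (ry - mean(ry)) / stats::sd(ry)
  rho <- as.numeric(crossprod(RX, ry)) / (n - 1)
  tval <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-12))
  list(rho = rho, p = 2 * stats::pt(-abs(tval), df = n - 2))
}

# ---- connected components (union-find) -------------------------------------
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

edge_components <- function(edges, n_nodes) {
  # edges: 2-col integer matrix; returns component id per edge
  edges <- matrix(as.integer(edges), ncol = 2)
  parent <- seq_len(n_nodes)
  for (k in seq_len(nrow(edges))) {
    ra <- uf_find(parent, edges[k, 1])
    rb <- uf_find(parent, edges[k, 2])
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_len(nrow(edges)),
                  function(k) uf_find(parent, edges[k, 1]), integer(1))
  match(roots, unique(roots))
}

largest_component_sizes <- function(edge_idx, p, signs, edges, n_nodes, alpha) {
  # largest positive and largest negative component size for one realization
  out <- c(pos = 0, neg = 0)
  for (sgn in c(1, -1)) {
    sel <- which(p < alpha & signs == sgn)
    if (!length(sel)) next
    comp <- edge_components(edges[sel, , drop = FALSE], n_nodes)
    sz <- max(tabulate(comp))
    out[if (sgn == 1) "pos" else "neg"] <- sz
  }
  out
}

#' Network-based statistic (NBS) permutation test
#'
#' Family-wise inference over a channels x channels connectivity network.
#' Edge-wise p-value and sign maps come from the exact-distribution Wilcoxon
#' signed-rank test (within design, on paired differences), the Wilcoxon
#' rank-sum test (between design) or the Spearman correlation (correlation
#' design). Significant edges (p below `edge_alpha`) are split by sign, their
#' connected components extracted, and each observed component's size (edge
#' count) is referred to the permutation null distribution of the largest
#' same-sign component size; the component p-value is
#' `p = (2 * sum(|S_null| > |s_obs|) + 1) / (N + 1)`.
#'
#' @param conns_a list of `connectivity_matrix` (or 3-D array subjects x
#'   channels x channels): condition A (e.g., T1), or the only stack for the
#'   correlation design.
#' @param conns_b condition B (e.g., T0); paired with `conns_a` for the within
#'   design. `NULL` for correlation.
#' @param design `"within"`, `"between"` or `"correlation"`.
#' @param y outcome scores (correlation design only).
#' @param edge_alpha edge-level threshold (default 0.05).
#' @param n_perm permutation budget (default 2000); all possible permutations
#'   are enumerated when fewer than that.
#' @param seed integer seed.
#' @return An `nbs_result`: tibble `components` (id, sign, size, p and a
#'   nested edge tibble), plus the null distributions and the edge-wise maps.
#' @export
nbs_test <- function(conns_a, conns_b = NULL,
                     design = c("within", "between", "correlation"),
                     y = NULL, edge_alpha = 0.05, n_perm = 2000, seed = NULL) {
  design <- match.arg(design)
  A <- conn_stack(conns_a)
  labels <- attr(A, "labels")
  n_nodes <- dim(A)[2]
  edges <- which(upper.tri(diag(n_nodes)), arr.ind = TRUE)
  edges <- cbind(edges[, 1], edges[, 2])
  EA <- t(apply(A, 1L, function(m) m[edges]))
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
  }

  if (design == "within") {
    B <- conn_stack(conns_b)
    if (!identical(dim(A), dim(B))) stop("paired stacks must match in shape")
    EB <- t(apply(B, 1L, function(m) m[edges]))
    D <- EA - EB
    n <- nrow(D)
    setup <- signed_rank_setup(D)
    obs <- signed_rank_p(D, setup)
    obs_sign <- ifelse(obs$median > 0, 1, -1)
    total <- 2^n
    exhaustive <- total <= n_perm
    flips_list <- if (exhaustive) {
      g <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
      lapply(seq_len(nrow(g)), function(i) g[i, ])
    } else {
      replicate(n_perm, sample(c(1, -1), n, replace = TRUE), simplify = FALSE)
    }
    null <- t(vapply(flips_list, function(f) {
      pr <- signed_rank_p(D, setup, flips = f)
      sg <- ifelse(pr$median > 0, 1, -1)
      largest_component_sizes(NULL, pr$p, sg, edges, n_nodes, edge_alpha)
    }, numeric(2)))
    n_used <- length(flips_list)
  } else if (design == "between") {
    B <- conn_stack(conns_b)
    EB <- t(apply(B, 1L, function(m) m[edges]))
    setup <- rank_sum_setup(EA, EB)
    nA <- nrow(EA); nTot <- setup$n
    p_obs <- rank_sum_p(setup, seq_len(nA))
    medA <- apply(EA, 2L, stats::median); medB <- apply(EB, 2L, stats::median)
    obs <- list(p = p_obs)
    obs_sign <- ifelse(medA > medB, 1, -1)
    pooled <- rbind(EA, EB)
    total <- choose(nTot, nA)
    exhaustive <- total <= n_perm
    idx_list <- if (exhaustive) {
      cb <- utils::combn(nTot, nA)
      lapply(seq_len(ncol(cb)), function(i) cb[, i])
    } else {
      replicate(n_perm, sample.int(nTot, nA), simplify = FALSE)
    }
    null <- t(vapply(idx_list, function(ia) {
      p <- rank_sum_p(setup, ia)
      mA <- apply(pooled[ia, , drop = FALSE], 2L, stats::median)
      mB <- apply(pooled[-ia, , drop = FALSE], 2L, stats::median)
      sg <- ifelse(mA > mB, 1, -1)
      largest_component_sizes(NULL, p, sg, edges, n_nodes, edge_alpha)
    }, numeric(2)))
    n_used <- length(idx_list)
  } else {
    if (is.null(y)) stop("correlation design needs outcome scores `y`")
    n <- nrow(EA)
    if (length(y) != n) stop("`y` must have one score per subject")
    RX <- apply(EA, 2L, rank)
    RX <- sweep(RX, 2L, colMeans(RX))
    sds <- sqrt(colSums(RX^2) / (n - 1))
    RX <- sweep(RX, 2L, pmax(sds, 1e-12), `/`)
    obs_se <- spearman_edge(RX, y)
    obs <- list(p = obs_se$p)
    obs_sign <- ifelse(obs_se$rho > 0, 1, -1)
    total <- factorial(n)
    exhaustive <- total <= n_perm
    perms <- if (exhaustive) permutations_of(n)
             else replicate(n_perm, sample.int(n), simplify = FALSE)
    null <- t(vapply(perms, function(pm) {
      se <- spearman_edge(RX, y[pm])
      sg <- ifelse(se$rho > 0, 1, -1)
      largest_component_sizes(NULL, se$p, sg, edges, n_nodes, edge_alpha)
    }, numeric(2)))
    n_used <- length(perms)
  }

  comps <- list()
  for (sgn in c(1, -1)) {
    sel <- which(obs$p < edge_alpha & obs_sign == sgn)
    if (!length(sel)) next
    comp_id <- edge_components(edges[sel, , drop = FALSE], n_nodes)
    for (cid in unique(comp_id)) {
      eidx <- sel[comp_id == cid]
      s_obs <- sgn * length(eidx)
      s_null <- null[, if (sgn == 1) "pos" else "neg"]
      p_comp <- (2 * sum(abs(s_null) > abs(s_obs)) + 1) / (n_used + 1)
      comps[[length(comps) + 1L]] <- tibble::tibble(
        sign = sgn, size = s_obs, p = p_comp,
        edges = list(tibble::tibble(
          from = labels[edges[eidx, 1]],
          to = labels[edges[eidx, 2]])))
    }
  }
  components <- if (length(comps)) {
    dplyr::bind_rows(comps) |>
      dplyr::arrange(.data$p, dplyr::desc(abs(.data$size))) |>
      dplyr::mutate(id = dplyr::row_number(), .before = 1)
  } else {
    tibble::tibble(id = integer(), sign = numeric(), size = numeric(),
                   p = numeric(), edges = list())
  }
  structure(list(components = components,
                 null_pos = null[, "pos"], null_neg = null[, "neg"],
                 edge_p = obs$p, edge_sign = obs_sign, edges = edges,
                 labels = labels, n_perm = n_used, exhaustive = exhaustive,
                 edge_alpha = edge_alpha, design = design),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("<nbs_result> %s design, %d permutations (%s), %d component%s\n",
              x$design, x$n_perm, if (x$exhaustive) "exhaustive" else "random",
              nrow(x$components), if (nrow(x$components) == 1) "" else "s"))
  if (nrow(x$components)) print(x$components[, c("id", "sign", "size", "p")])
  invisible(x)
}

conn_stack <- function(conns) {
  if (is.array(conns) && length(dim(conns)) == 3) {
    labels <- dimnames(conns)[[2]] %||% paste0("CH", seq_len(dim(conns)[2]))
    out <- conns
  } else {
    stopifnot(is.list(conns), length(conns) >= 1)
    labels <- conns[[1]]$labels
    n <- length(labels)
    out <- array(0, dim = c(length(conns), n, n))
    for (i in seq_along(conns)) {
      if (!identical(conns[[i]]$labels, labels))
        stop("connectivity matrices must share channel order")
      out[i, , ] <- conns[[i]]$values
    }
  }
  attr(out, "labels") <- labels
  out
}
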
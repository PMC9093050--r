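test_that("exhaustive sign-flip enumeration reproduces the analytic floors", {
  # maximal within-subject effect: every difference has the same sign
  r4 <- perm_test_scalar(c(1, 2, 3, 4), design = "within")
  expect_true(r4$exhaustive)
  expect_equal(r4$n_perm, 16)
  expect_equal(r4$p, 1 / 17)
  expect_equal(round(r4$p, 3), 0.059)

  r8 <- perm_test_scalar(seq(0.5, 4, by = 0.5), design = "within")
  expect_equal(r8$n_perm, 256)
  expect_equal(r8$p, 1 / 257)
  expect_equal(round(r8$p, 3), 0.004)

  rb <- perm_test_scalar(c(1, 2, 3, 4), c(11, 12, 13, 14), design = "between")
  expect_equal(rb$n_perm, 70)
  expect_equal(rb$p, 1 / 71)
  expect_equal(round(rb$p, 3), 0.014)
})

test_that("permutation counts follow the three designs", {
  expect_equal(count_permutations("within", 4), 16)
  expect_equal(count_permutations("within", 8), 256)
  expect_equal(count_permutations("between", c(4, 4)), 70)
  expect_equal(count_permutations("correlation", 3), 6)
})

test_that("random mode agrees with exhaustive at the attainable floor", {
  # with a maximal effect no permuted |t| exceeds the observed one in either
  # mode, so both sit exactly at the add-one floor 1/(n_perm + 1)
  ex <- perm_test_scalar(c(1, 2, 3, 4), design = "within", max_perm = 2000)
  rnd <- perm_test_scalar(c(1, 2, 3, 4), design = "within", max_perm = 15,
                          seed = 9)
  expect_equal(ex$p, 1 / (ex$n_perm + 1))
  expect_equal(rnd$p, 1 / (rnd$n_perm + 1))
  expect_false(rnd$exhaustive)
})

test_that("degenerate zero-variance input yields p = 1 with a warning", {
  expect_warning(r <- perm_test_scalar(rep(2, 5), design = "within"),
                 "degenerate")
  expect_equal(r$p, 1)
})

test_that("Spearman permutation correlation is exact for tiny n and floors", {
  # n = 3 exhaustive: 6 orderings, hand enumeration
  x <- c(1, 2, 3); y <- c(2, 1, 3)
  r <- perm_corr(x, y)
  expect_true(r$exhaustive)
  expect_equal(r$n_perm, 6)
  rho_all <- apply(rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                         c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)), 1,
                   function(p) cor(rank(x), rank(y[p])))
  obs <- cor(rank(x), rank(y))
  expect_equal(r$p, (sum(abs(rho_all) > abs(obs)) + 1) / 7)

  # perfectly monotone n = 8: observed rho = 1, random mode at its floor
  r8 <- perm_corr(1:8, (1:8)^3, seed = 10)
  expect_equal(r8$statistic, 1)
  expect_equal(r8$p, 1 / 2001)
  expect_error(perm_corr(c(1, 1, 1), 1:3), "constant")
  expect_error(perm_corr(1:2, 1:2), "at least 3")
})

test_that("edge-wise Wilcoxon stages match the exact stats oracle at n = 8", {
  set.seed(24)
  # signed rank, paired differences without ties
  D <- matrix(rnorm(8 * 20), 8, 20)
  setup <- zolpiscope:::signed_rank_setup(D)
  p_mine <- zolpiscope:::signed_rank_p(D, setup)$p
  p_ref <- apply(D, 2L, function(d) wilcox.test(d, exact = TRUE)$p.value)
  expect_equal(p_mine, p_ref, tolerance = 1e-12)

  # rank sum, 4 vs 4
  X <- matrix(rnorm(4 * 20), 4, 20); Y <- matrix(rnorm(4 * 20), 4, 20)
  su <- zolpiscope:::rank_sum_setup(X, Y)
  p2 <- zolpiscope:::rank_sum_p(su, 1:4)
  p2_ref <- vapply(seq_len(20), function(e)
    wilcox.test(X[, e], Y[, e], exact = TRUE)$p.value, numeric(1))
  expect_equal(p2, p2_ref, tolerance = 1e-12)
})

test_that("connected components are extracted correctly from edge sets", {
  edges <- rbind(c(1, 2), c(2, 3), c(4, 5))
  comp <- zolpiscope:::edge_components(edges, 5)
  sizes <- sort(tabulate(comp), decreasing = TRUE)
  expect_equal(sizes, c(2, 1))
  # cross-check against igraph on a random graph
  set.seed(25)
  e2 <- unique(t(replicate(30, sort(sample.int(12, 2)))))
  comp2 <- zolpiscope:::edge_components(e2, 12)
  g <- igraph::graph_from_edgelist(e2, directed = FALSE)
  memb <- igraph::components(g)$membership
  # edges in the same union-find component must share an igraph component
  expect_equal(length(unique(comp2)),
               length(unique(memb[e2[, 1]])))
  same_mine <- outer(comp2, comp2, "==")
  same_ig <- outer(memb[e2[, 1]], memb[e2[, 1]], "==")
  expect_equal(same_mine, same_ig)
})

test_that("NBS recovers a planted component and honors the p floor", {
  set.seed(26)
  n <- 8; nn <- 10
  planted <- cbind(1:6, 2:7)
  A <- array(0, c(n, nn, nn)); B <- array(0, c(n, nn, nn))
  for (s in seq_len(n)) {
    base <- matrix(runif(nn * nn, 0.2, 0.4), nn)
    base <- (base + t(base)) / 2; diag(base) <- 1
    a <- base
    for (k in seq_len(nrow(planted))) {
      i <- planted[k, 1]; j <- planted[k, 2]
      a[i, j] <- a[j, i] <- a[i, j] - 0.15
    }
    A[s, , ] <- a; B[s, , ] <- base
  }
  res <- nbs_test(A, B, design = "within", n_perm = 500, seed = 11)
  expect_true(res$exhaustive)       # 2^8 = 256 <= 500
  top <- res$components[1, ]
  expect_equal(top$sign, -1)
  expect_equal(abs(top$size), 6)
  expect_lt(top$p, 0.05)
  got <- res$components$edges[[1]]
  expect_setequal(paste(got$from, got$to),
                  paste0("CH", planted[, 1], " CH", planted[, 2]))
  # strongest possible component against an exhaustive null: the printed
  # formula's floor 1/(N + 1)
  expect_equal(top$p, 1 / 257)
})

test_that("NBS returns an empty component table when nothing is significant", {
  set.seed(27)
  n <- 3; nn <- 6   # n too small for any signed-rank edge to reach 0.05
  A <- array(runif(n * nn * nn), c(n, nn, nn))
  B <- array(runif(n * nn * nn), c(n, nn, nn))
  for (s in 1:n) {
    A[s, , ] <- (A[s, , ] + t(A[s, , ])) / 2; diag(A[s, , ]) <- 1
    B[s, , ] <- (B[s, , ] + t(B[s, , ])) / 2; diag(B[s, , ]) <- 1
  }
  res <- nbs_test(A, B, design = "within", n_perm = 100, seed = 12)
  expect_equal(nrow(res$components), 0)
})

test_that("NBS supports between and correlation designs", {
  set.seed(28)
  nn <- 8
  mk <- function(shift) {
    m <- matrix(runif(nn * nn, 0.3, 0.5), nn)
    m <- (m + t(m)) / 2
    m[1, 2] <- m[2, 1] <- m[1, 2] + shift
    m[2, 3] <- m[3, 2] <- m[2, 3] + shift
    diag(m) <- 1
    m
  }
  A <- array(0, c(5, nn, nn)); B <- array(0, c(5, nn, nn))
  for (s in 1:5) { A[s, , ] <- mk(0.4); B[s, , ] <- mk(0) }
  rb <- nbs_test(A, B, design = "between", n_perm = 300, seed = 13)
  expect_true(nrow(rb$components) >= 1)
  expect_equal(rb$components$sign[1], 1)

  y <- 1:8
  Ac <- array(0, c(8, nn, nn))
  for (s in 1:8) {
    m <- matrix(runif(nn * nn, 0.3, 0.5), nn); m <- (m + t(m)) / 2
    m[1, 2] <- m[2, 1] <- 0.3 + 0.05 * s   # strictly increasing with y
    diag(m) <- 1
    Ac[s, , ] <- m
  }
  rc <- nbs_test(Ac, design = "correlation", y = y, n_perm = 300, seed = 14)
  expect_true(nrow(rc$components) >= 1)
  expect_true(any(vapply(rc$components$edges, function(e)
    any(e$from == "CH1" & e$to == "CH2"), logical(1))))
})
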
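# Spherical-spline machinery shared by channel interpolation and the
# surface-Laplacian (CSD) transform. Electrode positions live on the unit
# sphere; g() and h() are truncated Legendre series (Perrin-style splines).

legendre_table <- function(x, n_terms) {
  # rows: P_1(x) .. P_{n_terms}(x) for each element of x
  out <- matrix(0, nrow = n_terms, ncol = length(x))
  p_prev <- rep(1, length(x))       # P_0
  p_cur <- x                        # P_1
  out[1, ] <- p_cur
  if (n_terms >= 2) {
    for (n in 1:(n_terms - 1)) {
      p_next <- ((2 * n + 1) * x * p_cur - n * p_prev) / (n + 1)
      out[n + 1, ] <- p_next
      p_prev <- p_cur
      p_cur <- p_next
    }
  }
  out
}

# g (order m) and h (order m-1) kernels evaluated at cos(angle) values
spline_g <- function(cosang, m = 4, n_terms = 50) {
  n <- seq_len(n_terms)
  w <- (2 * n + 1) / (n * (n + 1))^m
  P <- legendre_table(cosang, n_terms)
  as.numeric(crossprod(P, w)) / (4 * pi)
}

spline_h <- function(cosang, m = 4, n_terms = 50) {
  n <- seq_len(n_terms)
  w <- (2 * n + 1) / (n * (n + 1))^(m - 1)
  P <- legendre_table(cosang, n_terms)
  as.numeric(crossprod(P, w)) / (4 * pi)
}

cos_angle_matrix <- function(pos_a, pos_b) {
  x <- tcrossprod(pos_a, pos_b)
  pmin(pmax(x, -1), 1)
}

#' Replace bad channels by spherical-spline interpolation
#'
#' Bad channels are reconstructed from the good channels with a spherical
#' spline of order m = 4 (50 Legendre terms, ridge regularization 1e-5); all
#' other channels pass through untouched.
#'
#' @param rec an [eeg_recording()].
#' @param bad character vector of bad channel labels (subset of `rec$labels`).
#' @param montage an [eeg_montage()] covering the recording's channels.
#' @param lambda ridge regularization added to the spline system.
#' @return The recording with bad channels replaced.
#' @export
interpolate_channels <- function(rec, bad, montage, lambda = 1e-5) {
  if (length(bad) == 0) return(rec)
  if (!all(bad %in% rec$labels)) stop("unknown bad labels: ",
                                      paste(setdiff(bad, rec$labels), collapse = ", "))
  good <- setdiff(rec$labels, bad)
  if (length(good) < 4) stop("need at least 4 good channels")
  pos <- montage$positions[rec$labels, , drop = FALSE]
  pg <- pos[good, , drop = FALSE]
  pb <- pos[bad, , drop = FALSE]
  ng <- length(good)
  G <- matrix(spline_g(as.vector(cos_angle_matrix(pg, pg))), ng, ng)
  Gb <- matrix(spline_g(as.vector(cos_angle_matrix(pb, pg))), length(bad), ng)
  A <- rbind(cbind(G + diag(lambda, ng), rep(1, ng)), c(rep(1, ng), 0))
  rhs <- rbind(rec$data[good, , drop = FALSE], 0)
  sol <- solve(A, rhs)
  coefs <- sol[seq_len(ng), , drop = FALSE]
  c0 <- sol[ng + 1, ]
  interp <- Gb %*% coefs + matrix(c0, nrow = length(bad), ncol = ncol(rec$data), byrow = TRUE)
  rec$data[bad, ] <- interp
  rec
}

#' Surface-Laplacian (current source density) transform
#'
#' Spherical-spline Laplacian with spline order m = 4, 50 Legendre terms and
#' regularization 1e-5 on a unit-radius head, used to attenuate volume
#' conduction before phase-based connectivity. A spatially uniform signal maps
#' to (numerically) zero; the operator is linear.
#'
#' @param rec a common-average-referenced [eeg_recording()].
#' @param montage an [eeg_montage()] covering the recording's channels.
#' @param lambda ridge regularization.
#' @return The CSD-transformed recording with `reference = "laplacian"`.
#' @export
surface_laplacian <- function(rec, montage, lambda = 1e-5) {
  if (!all(rec$labels %in% rownames(montage$positions)))
    stop("montage does not cover recording channels")
  pos <- montage$positions[rec$labels, , drop = FALSE]
  n <- nrow(pos)
  ca <- cos_angle_matrix(pos, pos)
  G <- matrix(spline_g(as.vector(ca)), n, n)
  H <- matrix(spline_h(as.vector(ca)), n, n)
  Gs <- G + diag(lambda, n)
  Gi <- solve(Gs)
  tc <- rowSums(Gi)
  sgi <- sum(tc)
  Cp <- Gi %*% rec$data
  c0 <- colSums(Cp) / sgi
  C <- Cp - outer(tc, c0)
  rec$data <- H %*% C
  rownames(rec$data) <- rec$labels
  rec$reference <- "laplacian"
  rec
}
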
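# Shared fixtures: random landmark configurations, random similarity
# transforms, and a Rodrigues rotation used by the optimizer oracle.

rand_landmarks <- function(seed = NULL, spread = 50) {
  if (!is.null(seed)) set.seed(seed)
  pts <- matrix(rnorm(54, sd = spread), 18, 3)
  rownames(pts) <- landmark_codes()
  pts
}

rand_targets <- function() {
  c(P01 = runif(1, 0.95, 1.25), P02 = runif(1, 1.7, 2.2),
    P03 = runif(1, 0.95, 1.2), P04 = runif(1, 0.88, 1.05),
    P05 = runif(1, 4.2, 6.0), P06 = runif(1, 1.6, 2.1))
}

rand_similarity <- function(pts) {
  R <- random_rotation()
  s <- runif(1, 0.5, 2)
  tr <- runif(3, -200, 200)
  sweep(s * pts %*% R, 2, tr, `+`)
}

rotvec_to_mat <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  k <- v / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# black-box numerical minimization of the similarity-alignment residual,
# independent of the SVD solution path: rotations are searched numerically
# from many random starts; for a fixed rotation the optimal scale and
# translation follow from elementary least squares
oracle_align_residual <- function(X, Y, n_starts = 20) {
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  ssx <- sum(Xc^2)
  f <- function(v) {
    R <- rotvec_to_mat(v)
    s <- sum(Xc * (Yc %*% t(R))) / ssx   # d/ds ||s Xc R - Yc||^2 = 0
    if (s <= 0) return(sqrt(sum(Yc^2) / nrow(X)))
    sqrt(sum((s * Xc %*% R - Yc)^2) / nrow(X))
  }
  best <- Inf
  for (i in seq_len(n_starts)) {
    o <- optim(runif(3, -pi, pi), f, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-15))
    if (o$value < best) best <- o$value
  }
  best
}

cal_table <- normative_proportion_targets()
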
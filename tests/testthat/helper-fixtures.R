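# shared fixtures and independent oracles (kept deliberately separate from
# the package implementations they check)

# random proper rotation + translation
rand_rigid <- function(max_trans = 30) {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- stats::runif(1, 0, pi)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  sv <- svd(R)
  rigid_transform(sv$u %*% t(sv$v), stats::runif(3, -max_trans, max_trans))
}

# smooth open 3D test curve with n points
smooth_curve <- function(n, phase = 0, roles = "sliding") {
  t <- seq(0, 2, length.out = n) + phase
  landmark_curve(cbind(10 * t, 8 * sin(t), 3 * cos(1.3 * t)), roles = roles)
}

# rigidly transform every landmark of a configuration (test-side helper)
transform_cfg <- function(cfg, tf) {
  repoint <- function(crv, pts) structure(pts, roles = attr(crv, "roles"),
                                          closed = attr(crv, "closed"),
                                          class = class(crv))
  cfg$mtbl <- repoint(cfg$mtbl, apply_transform(tf, unclass(cfg$mtbl)))
  cfg$mgbl <- repoint(cfg$mgbl, apply_transform(tf, unclass(cfg$mgbl)))
  if (!is.null(cfg$superimposition))
    cfg$superimposition <- apply_transform(tf, cfg$superimposition)
  cfg
}

# ORACLE: rigid registration residual minimized by grid + quasi-Newton
# refinement over Euler angles (independent of the SVD solution)
oracle_rigid_residual <- function(source, target) {
  euler_R <- function(a) {
    cz <- cos(a[1]); sz <- sin(a[1]); cy <- cos(a[2]); sy <- sin(a[2])
    cx <- cos(a[3]); sx <- sin(a[3])
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -cx * 0 - sx, cx), 3, 3)
    Rx[2, 3] <- -sx; Rx[3, 2] <- sx; Rx[2, 2] <- cx; Rx[3, 3] <- cx
    Rz %*% Ry %*% Rx
  }
  fn <- function(a) {
    R <- euler_R(a)
    tr <- colMeans(target) - as.vector(R %*% colMeans(source))
    sum((sweep(source %*% t(R), 2, tr, `+`) - target)^2)
  }
  starts <- as.matrix(expand.grid(a1 = c(0, pi / 2, pi, 3 * pi / 2),
                                  a2 = c(-pi / 3, 0, pi / 3),
                                  a3 = c(-pi / 2, 0, pi / 2)))
  best <- Inf
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(starts[i, ], fn, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}

# ORACLE: type-7 quantile by hand (linear interpolation of order statistics)
oracle_quantile7 <- function(x, p) {
  x <- sort(x); n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# ORACLE: full bordered TPS system assembled independently; returns the
# bending energy of target relative to reference
oracle_tps_energy <- function(reference, target) {
  m <- nrow(reference)
  K <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m))
    K[i, j] <- sqrt(sum((reference[i, ] - reference[j, ])^2))
  P <- cbind(rep(1, m), reference)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  B <- -solve(L)[1:m, 1:m]
  sum(sapply(1:3, function(c) drop(t(target[, c]) %*% B %*% target[, c])))
}

# ORACLE: exhaustive nearest point on a polyline (per-segment closed form)
oracle_polyline_dist <- function(q, poly) {
  best <- Inf
  for (s in seq_len(nrow(poly) - 1)) {
    a <- poly[s, ]; b <- poly[s + 1, ]
    ab <- b - a
    t <- sum((q - a) * ab) / sum(ab^2)
    t <- min(max(t, 0), 1)
    best <- min(best, sqrt(sum((a + t * ab - q)^2)))
  }
  best
}

# ORACLE: conditional Gaussian posterior mean from the explicit full joint
# covariance Sigma = Q Q' (+ sigma2 I on the observed block)
oracle_conditional_mean <- function(model, observed, sigma2) {
  Q <- model$basis %*% diag(sqrt(model$eigenvalues), length(model$eigenvalues))
  Sigma <- tcrossprod(Q)
  o <- model$observed_rows
  Soo <- Sigma[o, o] + diag(sigma2, length(o))
  model$mean + Sigma[, o] %*% solve(Soo, observed - model$mean[o])
}

# tiny generic population for toy shape models: n subjects, random smooth
# geometry with shared low-rank structure
toy_population <- function(n, n_mt = 5, n_mg = 3, seed = 1) {
  set.seed(seed)
  base_mt <- cbind(seq_len(n_mt), sin(seq_len(n_mt)), cos(seq_len(n_mt)))
  base_mg <- cbind(seq_len(n_mg) + 0.5, cos(seq_len(n_mg)), 1)
  cfgs <- lapply(seq_len(n), function(i) {
    arch_configuration(paste0("t", i), "maxilla",
      mtbl = landmark_curve(base_mt + matrix(rnorm(n_mt * 3, sd = 0.3), n_mt, 3),
                            roles = "sliding"),
      mgbl = landmark_curve(base_mg + matrix(rnorm(n_mg * 3, sd = 0.3), n_mg, 3)))
  })
  population_sample(cfgs)
}

# default fast synthetic world used across tests
quiet_params <- function(...) synthetic_params(n_mt = 40, n_mg = 15,
                                               n_papillae = 5, ...)
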
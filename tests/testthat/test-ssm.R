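aligned_pop <- function(n, seed = 1, ...) {
  generalized_procrustes(generate_population(n, quiet_params(seed = seed, ...)))$population
}

test_that("model structure honours the PCA invariants", {
  pop <- aligned_pop(8, seed = 3)
  m <- ssm_fit(pop)
  k <- length(m$eigenvalues)
  expect_lte(k, 7)
  expect_equal(crossprod(m$basis), diag(k), tolerance = 1e-8)
  expect_true(all(diff(m$eigenvalues) <= 0) && all(m$eigenvalues >= 0))
  expect_equal(sum(m$eigenvalues), m$total_variance, tolerance = 1e-6 * m$total_variance)
  expect_identical(sort(c(m$observed_rows, m$latent_rows)),
                   seq_along(m$mean))
  expect_error(ssm_fit(pop[1:2]), "at least")
})

test_that("degenerate and low-rank training sets behave as stated", {
  base <- generate_subject(quiet_params(landmark_noise_sd = 0,
                                        pose_rot_deg = 0, pose_trans_mm = 0), 4)
  cfgs <- lapply(1:5, function(i) { base$subject_id <- paste0("I", i); base })
  m <- ssm_fit(population_sample(cfgs))
  expect_identical(length(m$eigenvalues), 0L)
  expect_equal(matrix(m$mean, ncol = 3, byrow = TRUE),
               rbind(unclass(base$mtbl), unclass(base$mgbl)),
               tolerance = 1e-12, ignore_attr = TRUE)

  m4 <- ssm_fit(aligned_pop(4, seed = 5))
  expect_lte(length(m4$eigenvalues), 3)
})

test_that("a known 2-factor linear model is recovered", {
  # generator: mean + beta1 f1 + beta2 f2 + tiny noise
  set.seed(17)
  n_pts <- 30
  mean_pts <- unclass(smooth_curve(n_pts))
  f1 <- matrix(rnorm(n_pts * 3), n_pts, 3); f1 <- f1 / sqrt(sum(f1^2))
  f2 <- matrix(rnorm(n_pts * 3), n_pts, 3); f2 <- f2 / sqrt(sum(f2^2))
  cfgs <- lapply(1:30, function(i) {
    b <- rnorm(2, sd = c(3, 2))
    pts <- mean_pts + b[1] * f1 + b[2] * f2 +
      matrix(rnorm(n_pts * 3, sd = 1e-3), n_pts, 3)
    arch_configuration(paste0("f", i), "maxilla",
      mtbl = landmark_curve(pts[1:20, ]),
      mgbl = landmark_curve(pts[21:30, ]))
  })
  m <- ssm_fit(population_sample(cfgs))
  expect_gt(sum(m$eigenvalues[1:2]) / m$total_variance, 0.99)
  # principal angles between recovered and generating 2D subspaces < 2 deg
  G <- qr.Q(qr(cbind(as.vector(t(f1)), as.vector(t(f2)))))
  s <- svd(crossprod(G, m$basis[, 1:2]))$d
  angles <- acos(pmin(pmax(s, -1), 1)) * 180 / pi
  expect_lt(max(angles), 2)
})

test_that("instance/project round trips hold on the model span", {
  pop <- aligned_pop(8, seed = 7)
  m <- ssm_fit(pop)
  k <- length(m$eigenvalues)
  expect_equal(model_instance(m, numeric(k)), m$mean)
  expect_equal(model_project(m, m$mean), numeric(k))
  for (j in c(1, k)) {
    e <- numeric(k); e[j] <- 1
    expect_equal(model_project(m, model_instance(m, e)), e, tolerance = 1e-9)
  }
  # out-of-span shape: projection equals the least-squares oracle
  set.seed(1)
  shape <- m$mean + rnorm(length(m$mean))
  a <- model_project(m, shape)
  Q <- m$basis %*% diag(sqrt(m$eigenvalues), k)
  a_ls <- solve(crossprod(Q), crossprod(Q, shape - m$mean))
  expect_equal(a, as.vector(a_ls), tolerance = 1e-8)
})

test_that("posterior mean matches the full-covariance conditional oracle", {
  set.seed(23)
  for (rep in 1:6) {
    n_mt <- sample(5:14, 1); n_mg <- sample(3:6, 1)
    k_target <- sample(2:5, 1)
    pop <- toy_population(k_target + 1, n_mt, n_mg, seed = 100 + rep)
    m <- ssm_fit(generalized_procrustes(pop)$population)
    sigma2 <- 10^runif(1, -6, -1)
    obs <- m$mean[m$observed_rows] + rnorm(length(m$observed_rows), sd = 0.5)
    post <- posterior_predict(m, obs, sigma2 = sigma2)
    oracle <- oracle_conditional_mean(m, obs, sigma2)
    expect_lt(max(abs(post$full_shape - oracle)), 1e-8)
  }
})

test_that("posterior limits and monotonicity in sigma2", {
  pop <- aligned_pop(10, seed = 9)
  m <- ssm_fit(pop)
  # observed = mean: prediction is the mean
  post <- posterior_predict(m, m$mean[m$observed_rows])
  expect_equal(post$full_shape, m$mean, tolerance = 1e-10)
  expect_equal(post$coefficients, numeric(length(m$eigenvalues)),
               tolerance = 1e-10)
  obs <- as.vector(t(unclass(pop[[2]]$mtbl)))
  # huge sigma2: prediction collapses to the mean
  post_inf <- posterior_predict(m, obs, sigma2 = 1e12)
  expect_equal(post_inf$full_shape, m$mean, tolerance = 1e-6)
  # deviation from the mean is non-increasing in sigma2
  dev <- vapply(10^seq(-8, 8, by = 2), function(s2)
    sqrt(sum((posterior_predict(m, obs, sigma2 = s2)$full_shape - m$mean)^2)),
    numeric(1))
  expect_true(all(diff(dev) <= 1e-9))
  # training shape is recovered entirely as sigma2 -> 0
  x <- c(as.vector(t(unclass(pop[[2]]$mtbl))), as.vector(t(unclass(pop[[2]]$mgbl))))
  post0 <- posterior_predict(m, x[m$observed_rows], sigma2 = 1e-10)
  expect_lt(sqrt(sum((post0$full_shape - x)^2)), 1e-6 * sqrt(sum(x^2)))
  expect_error(posterior_predict(m, obs, sigma2 = 0), "positive")
  expect_error(posterior_predict(m, obs[-1]), "length")
})

test_that("sampling is seeded and matches the model covariance", {
  pop <- aligned_pop(12, seed = 13)
  m <- ssm_fit(pop)
  expect_identical(sample_shape(m, 5), sample_shape(m, 5))
  expect_false(identical(sample_shape(m, 5), sample_shape(m, 6)))
  # z = 0 path through model_instance is the mean
  expect_equal(model_instance(m, numeric(length(m$eigenvalues))), m$mean)
  # Monte-Carlo: leading eigenvalue of the sample covariance within 5%
  sims <- t(simulate(m, nsim = 10000, seed = 42))
  ev1 <- svd(sweep(sims, 2, colMeans(sims)), nu = 0, nv = 0)$d[1]^2 / 9999
  expect_lt(abs(ev1 - m$eigenvalues[1]) / m$eigenvalues[1], 0.05)
})

test_that("model container round-trips losslessly and rejects damage", {
  pop <- aligned_pop(6, seed = 15)
  m <- ssm_fit(pop)
  path <- tempfile(fileext = ".ssm.json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(m2$mean, m$mean, tolerance = 1e-12)
  expect_equal(m2$basis, m$basis, tolerance = 1e-12)
  expect_equal(m2$eigenvalues, m$eigenvalues, tolerance = 1e-12)
  expect_identical(m2$observed_rows, m$observed_rows)
  expect_identical(m2$jaw, m$jaw)
  expect_identical(m2$n_training, m$n_training)
  expect_true(is.double(m2$eigenvalues))
  # truncated file is a format error
  txt <- readLines(path)
  bad <- tempfile(fileext = ".ssm.json")
  writeLines(substr(paste(txt, collapse = ""), 1, 200), bad)
  expect_error(load_model(bad), "readable|format|missing")
})
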
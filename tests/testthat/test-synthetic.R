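test_that("generation is deterministic and structurally consistent", {
  p <- quiet_params(seed = 31)
  a <- generate_subject(p, 123)
  b <- generate_subject(p, 123)
  expect_identical(unclass(a$mtbl), unclass(b$mtbl))
  expect_identical(unclass(a$mgbl), unclass(b$mgbl))
  expect_false(identical(unclass(a$mtbl),
                         unclass(generate_subject(p, 124)$mtbl)))

  pop1 <- generate_population(5, p)
  pop2 <- generate_population(5, p)
  for (i in 1:5)
    expect_identical(unclass(pop1[[i]]$mtbl), unclass(pop2[[i]]$mtbl))
  expect_equal(unname(pop1$counts),
               c(p$n_mt + 2 * p$n_papillae, p$n_mg))
  roles <- attr(pop1[[1]]$mtbl, "roles")
  expect_equal(sum(roles == "fixed"), 2 * p$n_papillae)
  expect_equal(sum(roles == "sliding"), p$n_mt)
  expect_true(all(attr(pop1[[1]]$mgbl, "roles") == "sliding"))
})

test_that("parameter validation rejects invalid worlds", {
  expect_error(synthetic_params(rho = 1.2), "rho")
  expect_error(synthetic_params(landmark_noise_sd = -1), "nonnegative")
  expect_error(synthetic_params(n_mt = 5), "n_mt")
  expect_identical(synthetic_params(preset = "clinical")$n_mt, 560L)
  expect_identical(synthetic_params(preset = "clinical")$n_mg, 150L)
  expect_identical(synthetic_params()$n_mt, 140L)
})

test_that("mean gingival width matches the stated parameter", {
  p <- quiet_params(seed = 33)
  pop <- generate_population(200, p)
  # per-subject mean of the generated width field (the generator's own
  # record of the MT -> MG apical offset)
  widths <- vapply(pop$configurations, function(cfg)
    mean(attr(cfg, "gingival_width")), numeric(1))
  se <- sd(widths) / sqrt(length(widths))
  expect_lt(abs(mean(widths) - p$gingival_width_mean), 3 * se)
  # and the realized geometry carries that offset: MG points sit a few mm
  # apical of the MT polyline
  d <- apply(unclass(pop[[1]]$mgbl), 1, oracle_polyline_dist,
             poly = unclass(pop[[1]]$mtbl))
  expect_gt(mean(d), 1)
  expect_lt(mean(d), 10)
})

test_that("rho = 1 noiseless subjects are exact linear functions of beta", {
  p <- quiet_params(rho = 1, unpredictable_sd = 0, landmark_noise_sd = 0,
                    pose_rot_deg = 0, pose_trans_mm = 0, seed = 35)
  pop <- generate_population(20, p)
  X <- t(vapply(pop$configurations, function(cfg)
    c(t(unclass(cfg$mtbl)), t(unclass(cfg$mgbl))),
    numeric(3 * sum(pop$counts))))
  B <- t(vapply(pop$configurations, function(cfg) attr(cfg, "latent"),
                numeric(p$latent_dim)))
  # residuals of the affine regression of coordinates on beta are ~ 0
  fit <- lm.fit(cbind(1, B), X)
  expect_lt(max(abs(fit$residuals)), 1e-9)
})

test_that("MT-to-MG covariation increases with rho", {
  cors <- vapply(c(0, 0.5, 1), function(r) {
    p <- quiet_params(rho = r, landmark_noise_sd = 0, pose_rot_deg = 0,
                      pose_trans_mm = 0, seed = 37)
    pop <- generate_population(100, p)
    B <- t(vapply(pop$configurations, function(cfg) attr(cfg, "latent"),
                  numeric(p$latent_dim)))
    offs <- vapply(pop$configurations, function(cfg)
      mean(apply(unclass(cfg$mgbl), 1, oracle_polyline_dist,
                 poly = unclass(cfg$mtbl))), numeric(1))
    max(abs(cor(B, offs)))
  }, numeric(1))
  expect_true(all(diff(cors) > 0))
})

test_that("generated MT-BL sliding polylines are simple", {
  p <- quiet_params(seed = 39)
  cfg <- generate_subject(p, 55)
  S <- attr(cfg$mtbl, "roles") == "sliding"
  pts <- unclass(cfg$mtbl)[S, ]
  n <- nrow(pts)
  segs_a <- pts[-n, , drop = FALSE]
  segs_b <- pts[-1, , drop = FALSE]
  # non-adjacent segments never come closer than a small clearance
  min_gap <- Inf
  for (i in seq_len(n - 3)) {
    for (j in (i + 2):(n - 1)) {
      d <- min(sqrt(sum((segs_a[i, ] - segs_a[j, ])^2)),
               sqrt(sum((segs_a[i, ] - segs_b[j, ])^2)),
               sqrt(sum((segs_b[i, ] - segs_a[j, ])^2)),
               sqrt(sum((segs_b[i, ] - segs_b[j, ])^2)))
      min_gap <- min(min_gap, d)
    }
  }
  expect_gt(min_gap, 0.05)
})
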
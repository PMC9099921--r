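test_that("reconstruction from the mean MT-BL returns the mean MG-BL", {
  pop <- generalized_procrustes(generate_population(8, quiet_params(seed = 2)))$population
  m <- ssm_fit(pop)
  mean_mt <- m$template$mtbl
  mean_mt[, ] <- matrix(m$mean[m$observed_rows], ncol = 3, byrow = TRUE)
  pred <- reconstruct_mgbl(m, mean_mt)
  expect_equal(unclass(pred$mgbl),
               matrix(m$mean[m$latent_rows], ncol = 3, byrow = TRUE),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("a training member's MG-BL is recovered in-span", {
  pop <- generate_population(10, quiet_params(seed = 3))
  m <- ssm_fit(generalized_procrustes(pop)$population)
  pred <- reconstruct_mgbl(m, pop[[4]]$mtbl, sigma2 = 1e-8)
  expect_lt(max(sqrt(rowSums((unclass(pred$mgbl) - unclass(pop[[4]]$mgbl))^2))),
            1e-3)
})

test_that("prediction is equivariant under rigid motions of the query", {
  pop <- generate_population(8, quiet_params(seed = 4))
  m <- ssm_fit(generalized_procrustes(pop)$population)
  q <- pop[[2]]$mtbl
  set.seed(77)
  tf <- rand_rigid()
  pred0 <- reconstruct_mgbl(m, q)
  q2 <- q; q2[, ] <- apply_transform(tf, unclass(q))
  pred2 <- reconstruct_mgbl(m, q2)
  expect_lt(max(abs(unclass(pred2$mgbl) -
                      apply_transform(tf, unclass(pred0$mgbl)))), 1e-6)
  expect_error(reconstruct_mgbl(m, pop[[2]]$mgbl), "expects")
})

test_that("pointwise errors match exhaustive brute-force scans", {
  a <- landmark_curve(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  expect_equal(pointwise_error(a, a), c(0, 0, 0))
  single <- rbind(c(0, 0, 0))
  pred <- landmark_curve(rbind(c(0, 1, 0), c(1, 1, 0), c(2, 1, 0)))
  expect_equal(pointwise_error(single, pred, "nearest_vertex"), 1)
  expect_equal(pointwise_error(single, pred, "nearest_on_polyline"), 1)

  set.seed(8)
  actual <- matrix(rnorm(300, sd = 6), 100, 3)
  predicted <- smooth_curve(150)
  dv <- pointwise_error(actual, predicted, "nearest_vertex")
  dp <- pointwise_error(actual, predicted, "nearest_on_polyline")
  pv <- unclass(predicted)
  dv_oracle <- apply(actual, 1, function(q)
    sqrt(min(colSums((t(pv) - q)^2))))
  dp_oracle <- apply(actual, 1, oracle_polyline_dist, poly = pv)
  expect_equal(dv, dv_oracle, tolerance = 1e-12)
  expect_equal(dp, dp_oracle, tolerance = 1e-12)
  expect_true(all(dp <= dv + 1e-12))
})

test_that("error summaries follow the type-7 percentile convention", {
  s <- summarize_errors(c(1, 2, 3))
  expect_equal(s$median, 2)
  s <- summarize_errors(0:10)
  expect_equal(s$p10, 1.0)
  expect_equal(s$p90, 9.0)
  expect_equal(s$median, 5.0)
  set.seed(31)
  x <- runif(1000)
  s <- summarize_errors(x)
  expect_equal(s$p10, oracle_quantile7(x, 0.1), tolerance = 1e-14)
  expect_equal(s$median, oracle_quantile7(x, 0.5), tolerance = 1e-14)
  expect_equal(s$p90, oracle_quantile7(x, 0.9), tolerance = 1e-14)
  expect_error(summarize_errors(numeric(0)), "no distances")
  expect_error(summarize_errors(c(1, -2)), "nonnegative")
})

test_that("LOOCV on identical shapes is exact and statistics are coherent", {
  base <- generate_subject(quiet_params(landmark_noise_sd = 0,
                                        pose_rot_deg = 0, pose_trans_mm = 0), 11)
  set.seed(19)
  cfgs <- lapply(1:6, function(i) {
    cfg <- transform_cfg(base, rand_rigid())
    cfg$subject_id <- paste0("I", i)
    cfg
  })
  rep0 <- loocv(population_sample(cfgs), sliding = FALSE)
  expect_lt(rep0$pooled$median, 1e-6)

  pop <- generate_population(8, quiet_params(seed = 12))
  rep1 <- loocv(pop, sliding = FALSE)
  med <- vapply(rep1$per_subject, `[[`, numeric(1), "median")
  expect_gte(rep1$pooled$median, min(med))
  expect_lte(rep1$pooled$median, max(med))
  expect_equal(rep1$pooled$n_points,
               sum(vapply(rep1$per_subject, `[[`, numeric(1), "n_points")))
  means <- vapply(rep1$per_subject, `[[`, numeric(1), "mean")
  expect_identical(rep1$best_subject_id, names(which.min(means)))
  expect_identical(rep1$worst_subject_id, names(which.max(means)))
})

test_that("the held-out MG-BL never leaks into its own prediction", {
  pop <- generate_population(8, quiet_params(seed = 14))
  i <- 3
  train <- pop[-i]
  fit_fold <- function(train_pop) {
    sr <- relax_population(train_pop, sliding_options(outer_iterations = 2))
    ssm_fit(generalized_procrustes(sr$population)$population)
  }
  m <- fit_fold(train)
  pred_clean <- reconstruct_mgbl(m, pop[[i]]$mtbl)
  # poison the held-out subject's MG-BL with NaN: the fold's training data
  # and the prediction must be structurally unaffected
  poisoned <- pop[[i]]
  poisoned$mgbl[, ] <- NaN
  cfgs <- pop$configurations; cfgs[[i]] <- poisoned
  pop2 <- structure(list(configurations = cfgs, jaw = pop$jaw,
                         counts = pop$counts, params = pop$params),
                    class = "population_sample")
  m2 <- fit_fold(pop2[-i])
  pred_poisoned <- reconstruct_mgbl(m2, pop2[[i]]$mtbl)
  expect_identical(unclass(pred_clean$mgbl), unclass(pred_poisoned$mgbl))
})

test_that("CSV error reports are complete and well-formed", {
  pop <- generate_population(6, quiet_params(seed = 16))
  rep1 <- loocv(pop, sliding = FALSE)
  path <- tempfile(fileext = ".csv")
  write_error_report(rep1, path)
  tab <- read.csv(path)
  expect_identical(names(tab), c("subject_id", "jaw", "point_index",
                                 "statistic", "distance_mm"))
  d <- tab[tab$statistic == "distance", ]
  expect_identical(nrow(d), rep1$pooled$n_points)
  pooled_med <- tab$distance_mm[tab$subject_id == "POOLED" &
                                  tab$statistic == "median"]
  expect_equal(pooled_med, rep1$pooled$median)
})

test_that("4-landmark superimposition recovers a cross-modality pose", {
  cfg <- generate_subject(quiet_params(), 21)
  set.seed(5)
  tf <- rand_rigid()
  cfg2 <- transform_cfg(cfg, tf)
  est <- superimpose_configurations(cfg, cfg2)
  expect_lt(max(abs(apply_transform(est, cfg$superimposition) -
                      cfg2$superimposition)), 1e-9)
})
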
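jittered_pop <- function(n, seed, jitter = 0.02) {
  generate_population(n, quiet_params(landmark_noise_sd = 0,
                                      param_jitter_sd = jitter, seed = seed))
}

test_that("sliding a configuration against itself is a no-op", {
  cfg <- generate_subject(quiet_params(landmark_noise_sd = 0), 5)
  out <- slide_once(cfg, cfg)
  expect_equal(unclass(out$mtbl), unclass(cfg$mtbl), tolerance = 1e-9)
  expect_equal(unclass(out$mgbl), unclass(cfg$mgbl), tolerance = 1e-9)
  expect_equal(attr(out, "bending_energy"), 0, tolerance = 1e-7)
})

test_that("all-fixed configurations never move", {
  cfg <- generate_subject(quiet_params(), 8)
  ref <- generate_subject(quiet_params(), 9)
  freeze <- function(crv) landmark_curve(unclass(crv), roles = "fixed")
  cfg$mtbl <- freeze(cfg$mtbl); cfg$mgbl <- freeze(cfg$mgbl)
  out <- slide_once(cfg, ref)
  expect_identical(unclass(out$mtbl), unclass(cfg$mtbl))
  expect_identical(unclass(out$mgbl), unclass(cfg$mgbl))
})

test_that("sliding recovers a re-parameterized curve's spacing", {
  # same geometric curve, landmarks digitized with uneven spacing; sliding
  # against the evenly spaced reference must shed most of the bending energy
  n <- 40
  t_even <- seq(0, 2, length.out = n)
  warp <- t_even + 0.08 * sin(3 * t_even + 1)
  warp <- 2 * (warp - warp[1]) / (warp[n] - warp[1])
  curve_at <- function(t) cbind(10 * t, 8 * sin(t), 3 * cos(1.3 * t))
  ref <- arch_configuration("ref", "maxilla",
    mtbl = landmark_curve(curve_at(t_even)),
    mgbl = landmark_curve(curve_at(t_even)[1:10, ] + 5))
  cfg <- arch_configuration("warped", "maxilla",
    mtbl = landmark_curve(curve_at(warp)),
    mgbl = landmark_curve(curve_at(t_even)[1:10, ] + 5))
  kern <- list(mtbl = tps_kernel(ref$mtbl), mgbl = tps_kernel(ref$mgbl))
  e0 <- bending_energy(kern$mtbl, cfg$mtbl)
  out <- slide_once(cfg, ref, kernels = kern,
                    options = sliding_options(inner_iterations = 10))
  e1 <- bending_energy(kern$mtbl, out$mtbl)
  expect_lt(e1, 0.1 * e0)
  # slid landmarks remain on the original polyline
  d <- apply(unclass(out$mtbl), 1, oracle_polyline_dist,
             poly = unclass(cfg$mtbl))
  expect_lt(max(d), 1e-6)
})

test_that("population relaxation honours all sliding contracts", {
  pop <- jittered_pop(8, seed = 21)
  sr <- relax_population(pop, sliding_options(outer_iterations = 3))
  # energy trace non-increasing per configuration
  expect_true(all(t(apply(sr$energy_trace, 1, diff)) <= 1e-7))
  for (i in seq_along(pop)) {
    for (crv in c("mtbl", "mgbl")) {
      orig <- pop[[i]][[crv]]; new <- sr$population[[i]][[crv]]
      S <- attr(orig, "roles") == "sliding"
      # slid landmarks lie on their own original polyline
      d <- apply(unclass(new)[S, , drop = FALSE], 1, oracle_polyline_dist,
                 poly = unclass(orig))
      expect_lt(max(d), 1e-6)
      # fixed landmarks bit-identical
      if (any(!S))
        expect_identical(unclass(new)[!S, ], unclass(orig)[!S, ])
    }
  }
})

test_that("relaxation is deterministic and trivial for identical shapes", {
  pop <- jittered_pop(6, seed = 22)
  sr1 <- relax_population(pop)
  sr2 <- relax_population(pop)
  for (i in seq_along(pop)) {
    expect_identical(unclass(sr1$population[[i]]$mtbl),
                     unclass(sr2$population[[i]]$mtbl))
    expect_identical(unclass(sr1$population[[i]]$mgbl),
                     unclass(sr2$population[[i]]$mgbl))
  }

  # identical configurations (no jitter, no noise, same pose): nothing to do
  base <- generate_subject(quiet_params(landmark_noise_sd = 0,
                                        pose_rot_deg = 0, pose_trans_mm = 0), 7)
  cfgs <- lapply(1:5, function(i) { base$subject_id <- paste0("I", i); base })
  sr <- relax_population(population_sample(cfgs))
  expect_lt(max(abs(sr$energy_trace)), 1e-12)
  for (i in 1:5)
    expect_equal(unclass(sr$population[[i]]$mtbl), unclass(base$mtbl),
                 tolerance = 1e-9)
})

test_that("mean bending energy decreases across outer iterations", {
  pop <- jittered_pop(10, seed = 23)
  sr <- relax_population(pop, sliding_options(outer_iterations = 3,
                                              energy_tol = 0))
  means <- colMeans(sr$energy_trace)
  expect_true(all(diff(means) < 0))
})
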
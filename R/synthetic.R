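#' Parameters for the synthetic dental-arch generator
#'
#' Describes a population of jaw configurations: a scalloped MT-BL
#' (gingival margin) along a parabolic dental arch with fixed papilla-tip
#' anchor landmarks, and an MG-BL offset apically by the attached-gingiva
#' width.  Subject-level variation comes from `latent_dim` shape factors
#' (arch width, depth, asymmetry, scallop amplitude, then higher
#' harmonics); `rho` dials how much of the MG-BL variation those factors
#' explain (rho = 1: the MG-BL is an exact linear function of the factors;
#' rho = 0: statistically independent of the MT-BL).
#'
#' @param jaw `"maxilla"` or `"mandible"` (they differ in default arch
#'   dimensions and apical direction only).
#' @param preset `"reduced"` (140 MT-BL / 50 MG-BL semilandmarks, fast) or
#'   `"clinical"` (560 / 150, the counts used for full-size annotations).
#' @param n_mt,n_mg semilandmark counts (override the preset).
#' @param n_papillae interdental papillae, two fixed anchors each (buccal +
#'   oral); 13 for a 14-tooth arch.
#' @param arch_width,arch_depth population-mean arch dimensions in mm
#'   (defaults 60/50 maxilla, 55/45 mandible).
#' @param scallop_amplitude vertical scallop of the gingival margin, mm.
#' @param gingival_width_mean mean MT-BL to MG-BL apical offset, mm.
#' @param latent_dim number of subject shape factors.
#' @param latent_sd per-factor SD in mm (recycled to `latent_dim`).
#' @param rho predictability in `[0, 1]`: fraction dialing the MG-BL
#'   variance explained by the MT-BL factors.
#' @param unpredictable_sd SD (mm) of smooth MG-BL width variation
#'   independent of the MT-BL (low-order harmonics).
#' @param landmark_noise_sd iid digitization noise SD per coordinate, mm.
#' @param pose_rot_deg,pose_trans_mm maximum random rigid pose: rotation
#'   angle (degrees) and per-axis translation (mm).
#' @param param_jitter_sd SD of smooth jitter of the curve parameterization
#'   (emulates inconsistent digitization spacing; what sliding removes).
#' @param seed master seed for [generate_population()].
#' @return A list of class `synthetic_params`.
#' @export
synthetic_params <- function(jaw = c("maxilla", "mandible"),
                             preset = c("reduced", "clinical"),
                             n_mt = NULL, n_mg = NULL, n_papillae = 13L,
                             arch_width = NULL, arch_depth = NULL,
                             scallop_amplitude = 1.5,
                             gingival_width_mean = 4.0,
                             latent_dim = 4L, latent_sd = c(3, 3, 2, 1),
                             rho = 0.7, unpredictable_sd = 1.0,
                             landmark_noise_sd = 0.3,
                             pose_rot_deg = 20, pose_trans_mm = 10,
                             param_jitter_sd = 0, seed = 1L) {
  jaw <- match.arg(jaw)
  preset <- match.arg(preset)
  if (is.null(n_mt)) n_mt <- if (preset == "clinical") 560L else 140L
  if (is.null(n_mg)) n_mg <- if (preset == "clinical") 150L else 50L
  if (is.null(arch_width)) arch_width <- if (jaw == "maxilla") 60 else 55
  if (is.null(arch_depth)) arch_depth <- if (jaw == "maxilla") 50 else 45
  n_mt <- as.integer(n_mt); n_mg <- as.integer(n_mg)
  n_papillae <- as.integer(n_papillae); latent_dim <- as.integer(latent_dim)
  if (n_mt < 10L || n_mg < 10L || n_papillae < 0L)
    stop_input("need n_mt >= 10, n_mg >= 10, n_papillae >= 0")
  if (rho < 0 || rho > 1) stop_input("rho must be in [0, 1]")
  latent_sd <- rep_len(as.numeric(latent_sd), latent_dim)
  sds <- c(latent_sd, unpredictable_sd, landmark_noise_sd, param_jitter_sd)
  if (any(sds < 0)) stop_input("all SDs must be nonnegative")
  if (latent_dim < 1L) stop_input("latent_dim must be >= 1")
  structure(list(jaw = jaw, n_mt = n_mt, n_mg = n_mg,
                 n_papillae = n_papillae, n_teeth = n_papillae + 1L,
                 arch_width = arch_width, arch_depth = arch_depth,
                 scallop_amplitude = scallop_amplitude,
                 gingival_width_mean = gingival_width_mean,
                 latent_dim = latent_dim, latent_sd = latent_sd,
                 rho = rho, unpredictable_sd = unpredictable_sd,
                 landmark_noise_sd = landmark_noise_sd,
                 pose_rot_deg = pose_rot_deg, pose_trans_mm = pose_trans_mm,
                 param_jitter_sd = param_jitter_sd, seed = as.integer(seed)),
            class = "synthetic_params")
}

# apical direction sign: maxilla gingiva extends upward (+z)
apical_sign <- function(jaw) if (jaw == "maxilla") 1 else -1

# parabolic arch centerline at parameter u in [-1, 1]
arch_base_xy <- function(u, params) {
  cbind(params$arch_width / 2 * u, params$arch_depth * (1 - u^2))
}

# tooth-lobe coordinate: papilla tips at integer values 1..n_papillae
tooth_s <- function(u, params) (u + 1) / 2 * params$n_teeth

# scallop height (>= 0, peaks at papillae), occlusal direction
scallop_profile <- function(u, params) 0.5 * (1 + cos(2 * pi * tooth_s(u, params)))

# linear deformation modes: latent_dim displacement fields evaluated at u;
# returns length(u) x 3 matrix for factor j.  on_mt toggles the scallop mode
# (the MG-BL carries no scallop).
mode_field <- function(j, u, params, on_mt) {
  z <- numeric(length(u))
  switch(as.character(min(j, 5L)),
    "1" = cbind(u / 2, z, z),                       # arch width
    "2" = cbind(z, 1 - u^2, z),                     # arch depth
    "3" = cbind(z, 0.4 * u, z),                     # anteroposterior asymmetry
    "4" = cbind(z, z, if (on_mt)                    # scallop amplitude
            -apical_sign(params$jaw) * scallop_profile(u, params) else z),
    cbind(0.3 * cos(j * pi * u), z, z))             # higher harmonics
}

sum_modes <- function(beta, u, params, on_mt) {
  out <- matrix(0, length(u), 3)
  for (j in seq_along(beta))
    out <- out + beta[j] * mode_field(j, u, params, on_mt)
  out
}

# base (beta = 0) MT-BL geometry on the canonical parameter grid, anchors
# included — the landmark set the GPA registration uses
mt_base_geometry <- function(params) {
  asg <- apical_sign(params$jaw)
  u <- -1 + (2 * seq_len(params$n_mt) - 1) / params$n_mt
  pts <- cbind(arch_base_xy(u, params),
               -asg * params$scallop_amplitude * scallop_profile(u, params))
  if (params$n_papillae > 0L) {
    u_pap <- 2 * seq_len(params$n_papillae) / params$n_teeth - 1
    bpap <- cbind(arch_base_xy(u_pap, params),
                  -asg * params$scallop_amplitude * scallop_profile(u_pap, params))
    opap <- bpap
    opap[, 1:2] <- opap[, 1:2] - 8 * outward_normal_xy(u_pap, params)
    u <- c(u, u_pap, u_pap)
    pts <- rbind(pts, bpap, opap)
  }
  list(u = u, pts = pts)
}

# The latent factors must encode SHAPE, not pose: project each mode field,
# restricted to the registration landmarks (MT-BL + anchors), against the
# span of infinitesimal translations and rotations of the mean MT-BL, and
# record the fitted rigid component so it can be subtracted everywhere.
# Otherwise Procrustes alignment becomes factor-dependent and leaks the
# factors into the aligned MG-BL even at rho = 0.
rigid_mode_corrections <- function(params) {
  geo <- mt_base_geometry(params)
  c0 <- colMeans(geo$pts)
  pc <- sweep(geo$pts, 2, c0)
  n <- nrow(pc)
  zero <- numeric(n); one <- rep(1, n)
  # columns: translations x/y/z, then infinitesimal rotations about x/y/z
  fields <- list(cbind(one, zero, zero), cbind(zero, one, zero),
                 cbind(zero, zero, one),
                 cbind(zero, -pc[, 3], pc[, 2]),
                 cbind(pc[, 3], zero, -pc[, 1]),
                 cbind(-pc[, 2], pc[, 1], zero))
  Bm <- vapply(fields, as.vector, numeric(3L * n))
  coef <- vapply(seq_len(params$latent_dim), function(j) {
    y <- as.vector(mode_field(j, geo$u, params, on_mt = TRUE))
    qr.solve(Bm, y)
  }, numeric(6))
  list(centroid = c0, coef = coef)   # coef: 6 x latent_dim
}

# rigid field induced by factors beta at base positions p (n x 3)
rigid_field_at <- function(beta, base_pts, corr) {
  g <- as.vector(corr$coef %*% beta)   # combined (t, omega)
  pc <- sweep(base_pts, 2, corr$centroid)
  cbind(g[1] - g[6] * pc[, 2] + g[5] * pc[, 3],
        g[2] + g[6] * pc[, 1] - g[4] * pc[, 3],
        g[3] - g[5] * pc[, 1] + g[4] * pc[, 2])
}

# mode displacement with the rigid (pose) component removed
shape_modes <- function(beta, u, base_pts, params, on_mt, corr) {
  sum_modes(beta, u, params, on_mt) - rigid_field_at(beta, base_pts, corr)
}

# smooth loadings of the latent factors on the gingival width (mm per mm)
width_loading <- function(u, params) {
  L <- cbind(rep(0.15, length(u)), -0.1 * cos(pi * u), 0.12 * u,
             rep(0.05, length(u)))
  j <- params$latent_dim
  if (j < 4L) L[, seq_len(j), drop = FALSE]
  else if (j == 4L) L
  else cbind(L, vapply(5:j, function(h) 0.03 * cos(h * u), numeric(length(u))))
}

# outward in-plane normal of the arch (away from the arch center)
outward_normal_xy <- function(u, params) {
  tx <- params$arch_width / 2
  ty <- -2 * params$arch_depth * u
  n <- cbind(-ty, tx) / sqrt(tx^2 + ty^2)
  center <- c(0, params$arch_depth / 3)
  p <- arch_base_xy(u, params)
  flip <- rowSums((p - matrix(center, length(u), 2, byrow = TRUE)) * n) < 0
  n[flip, ] <- -n[flip, , drop = FALSE]
  n
}

# smooth monotone jitter of curve parameters (digitization inconsistency)
jitter_params <- function(u, sd) {
  if (sd == 0) return(u)
  amp <- abs(stats::rnorm(1, sd = sd))
  freq <- sample(1:3, 1)
  phase <- stats::runif(1, 0, 2 * pi)
  # keep the map strictly monotone: |d jitter / d u| <= 0.45 < 1
  amp <- min(amp, 0.45 / (pi * freq))
  v <- u + amp * sin(pi * freq * u + phase)
  # rescale back onto the original span (endpoints preserved, order kept)
  min(u) + (v - v[1]) * diff(range(u)) / (v[length(v)] - v[1])
}

random_pose <- function(params) {
  if (params$pose_rot_deg == 0 && params$pose_trans_mm == 0)
    return(rigid_transform())
  ax <- stats::rnorm(3); ax <- ax / vnorm(ax)
  ang <- stats::runif(1, 0, params$pose_rot_deg) * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  # re-orthonormalize round-off so the rigid_transform validator accepts it
  svR <- svd(R)
  R <- svR$u %*% t(svR$v)
  tr <- stats::runif(3, -params$pose_trans_mm, params$pose_trans_mm)
  rigid_transform(R, tr)
}

#' Generate one synthetic subject
#'
#' Draws latent shape factors, builds the MT-BL (scalloped margin with
#' papilla anchors) and the MG-BL (apically offset curve whose covariation
#' with the MT-BL is controlled by `rho`), adds iid landmark noise, and
#' applies a random rigid pose.  Deterministic given `subject_seed`.
#'
#' @param params a [synthetic_params] object.
#' @param subject_seed integer seed for this subject.
#' @param subject_id identifier; defaults to `"subj<seed>"`.
#' @return An [arch_configuration] with attribute `latent` (the factor
#'   vector beta).
#' @export
generate_subject <- function(params, subject_seed,
                             subject_id = paste0("subj", subject_seed)) {
  if (!inherits(params, "synthetic_params"))
    stop_input("params must be a synthetic_params object")
  with_preserved_seed(subject_seed, {
    beta <- stats::rnorm(params$latent_dim, sd = params$latent_sd)
    asg <- apical_sign(params$jaw)
    corr <- rigid_mode_corrections(params)

    # --- MT-BL: scalloped margin (sliding) + papilla anchors (fixed) ---
    # cell-midpoint grid: never coincides with the papilla anchor positions
    u_mt <- jitter_params(-1 + (2 * seq_len(params$n_mt) - 1) / params$n_mt,
                          params$param_jitter_sd)
    base_sl <- cbind(arch_base_xy(u_mt, params),
                     -asg * params$scallop_amplitude * scallop_profile(u_mt, params))
    mt_sl <- base_sl + shape_modes(beta, u_mt, base_sl, params, TRUE, corr)
    if (params$n_papillae > 0L) {
      u_pap <- 2 * seq_len(params$n_papillae) / params$n_teeth - 1
      base_pap <- cbind(arch_base_xy(u_pap, params),
                        -asg * params$scallop_amplitude *
                          scallop_profile(u_pap, params))
      buccal <- base_pap + shape_modes(beta, u_pap, base_pap, params, TRUE, corr)
      base_oral <- base_pap
      base_oral[, 1:2] <- base_oral[, 1:2] -
        8 * outward_normal_xy(u_pap, params)   # lingual side
      oral <- base_oral + shape_modes(beta, u_pap, base_oral, params, TRUE, corr)
      # interleave: sliding points in u order with (buccal, oral) anchors
      # inserted at each papilla position
      all_u <- c(u_mt, u_pap, u_pap + 1e-9)
      all_pts <- rbind(mt_sl, buccal, oral)
      all_roles <- c(rep("sliding", params$n_mt),
                     rep("fixed", 2L * params$n_papillae))
      ord <- order(all_u)
      mt_pts <- all_pts[ord, , drop = FALSE]
      mt_roles <- all_roles[ord]
    } else {
      mt_pts <- mt_sl
      mt_roles <- rep("sliding", params$n_mt)
    }

    # --- MG-BL: population-mean arch + rho-scaled subject modes, offset
    # apically by the attached-gingiva width ---
    u_mg <- jitter_params(seq(-0.95, 0.95, length.out = params$n_mg),
                          params$param_jitter_sd)
    eta_coef <- stats::rnorm(4, sd = params$unpredictable_sd / 2)
    eta <- as.vector(cbind(1, cos(pi * u_mg), cos(2 * pi * u_mg),
                           cos(3 * pi * u_mg)) %*% eta_coef)
    w <- params$gingival_width_mean +
      params$rho * as.vector(width_loading(u_mg, params) %*% beta) +
      sqrt(1 - params$rho^2) * eta
    n_out <- outward_normal_xy(u_mg, params)
    adir <- cbind(0.3 * n_out, rep(asg, params$n_mg))
    adir <- adir / row_norms(adir)
    base_mg <- cbind(arch_base_xy(u_mg, params), 0) +
      params$gingival_width_mean * adir
    mg_pts <- cbind(arch_base_xy(u_mg, params), 0) +
      params$rho * shape_modes(beta, u_mg, base_mg, params, FALSE, corr) +
      w * adir

    # --- superimposition landmarks, noise, pose ---
    u_sup <- c(-1, -1/3, 1/3, 1)
    base_sup <- cbind(arch_base_xy(u_sup, params), -asg * 5)
    sup <- base_sup + shape_modes(beta, u_sup, base_sup, params, FALSE, corr)
    if (params$landmark_noise_sd > 0) {
      mt_pts <- mt_pts + stats::rnorm(length(mt_pts),
                                      sd = params$landmark_noise_sd)
      mg_pts <- mg_pts + stats::rnorm(length(mg_pts),
                                      sd = params$landmark_noise_sd)
    }
    pose <- random_pose(params)
    cfg <- arch_configuration(
      subject_id, params$jaw,
      mtbl = landmark_curve(apply_transform(pose, mt_pts), roles = mt_roles),
      mgbl = landmark_curve(apply_transform(pose, mg_pts)),
      superimposition = apply_transform(pose, sup))
    attr(cfg, "latent") <- beta
    attr(cfg, "gingival_width") <- w
    cfg
  })
}

#' Generate a synthetic population
#'
#' `n` subjects with independent subject seeds derived deterministically
#' from `params$seed`; the parameter record is attached to the returned
#' sample for provenance.
#'
#' @param n number of subjects, >= 2.
#' @param params a [synthetic_params] object.
#' @return A [population_sample].
#' @export
generate_population <- function(n, params = synthetic_params()) {
  n <- as.integer(n)
  if (n < 2L) stop_input("a population needs n >= 2 subjects")
  seeds <- with_preserved_seed(params$seed,
                               sample.int(.Machine$integer.max, n))
  configs <- lapply(seq_len(n), function(i)
    generate_subject(params, seeds[i],
                     subject_id = sprintf("S%03d", i)))
  population_sample(configs, params = params)
}
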
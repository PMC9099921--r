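#' Options for sliding-semilandmark relaxation
#'
#' @param outer_iterations number of reference updates (GPA + consensus +
#'   slide passes).
#' @param inner_iterations slide/project passes per reference.
#' @param reference_policy `"fixed_reference"` (default): slide against the
#'   first GPA consensus, held fixed across outer iterations so bending
#'   energies remain comparable and the energy trace is non-increasing by
#'   construction; `"sample_mean"`: refresh the consensus (and hence the TPS
#'   kernel) each outer iteration — energies under different kernels are not
#'   comparable, so the trace may then rise when the reference moves.
#' @param projection back-projection rule keeping slid landmarks on the
#'   observed curve (only `"nearest_point_on_polyline"` is implemented).
#' @param step_clamp maximum slide distance per pass in mm; `NULL` (default)
#'   clamps each landmark to the mean length of its adjacent curve segments,
#'   which prevents overshoot past neighbouring landmarks.
#' @param energy_tol relative energy improvement below which outer iterations
#'   stop early.
#' @return A list of class `sliding_options`.
#' @export
sliding_options <- function(outer_iterations = 3L, inner_iterations = 1L,
                            reference_policy = c("fixed_reference", "sample_mean"),
                            projection = "nearest_point_on_polyline",
                            step_clamp = NULL, energy_tol = 1e-6) {
  reference_policy <- match.arg(reference_policy)
  projection <- match.arg(projection)
  outer_iterations <- as.integer(outer_iterations)
  inner_iterations <- as.integer(inner_iterations)
  if (outer_iterations < 1L || inner_iterations < 1L)
    stop_input("iteration counts must be >= 1")
  if (!is.null(step_clamp) && (!is.numeric(step_clamp) || step_clamp <= 0))
    stop_input("step_clamp must be positive")
  structure(list(outer_iterations = outer_iterations,
                 inner_iterations = inner_iterations,
                 reference_policy = reference_policy,
                 projection = projection, step_clamp = step_clamp,
                 energy_tol = energy_tol),
            class = "sliding_options")
}

# per-point clamp: half the smaller adjacent segment of the CURRENT polyline,
# so no pass can push a landmark past its neighbours (prevents crowding)
default_clamp <- function(pts) {
  m <- nrow(pts)
  seg <- row_norms(pts[-1, , drop = FALSE] - pts[-m, , drop = FALSE])
  prev_len <- c(seg[1], seg)
  next_len <- c(seg, seg[m - 1L])
  0.5 * pmin(prev_len, next_len)
}

# Slide one curve's semilandmarks along their tangents to reduce TPS bending
# energy vs the kernel reference, then re-project onto the original polyline.
# Backtracks on the displacement scale so the returned energy never exceeds
# the input energy (within round-off).
slide_curve <- function(curve, kernel, options, original_curve) {
  pts <- curve_points(curve)
  roles <- curve_roles(curve)
  S <- which(roles == "sliding")
  if (length(S) == 0L) return(curve)
  B <- kernel$bending_matrix
  if (nrow(B) != nrow(pts))
    stop_input("kernel reference does not match curve length")
  u <- tangents_impl(pts, attr(curve, "closed"), strict = FALSE)
  # quadratic model of the energy in tangential displacements w:
  #   E(w) = E(0) + 2 b'w + w'A w  with A_ij = B_ij (u_i . u_j)
  A <- B * tcrossprod(u)
  b <- -rowSums(u * (B %*% pts))
  w_full <- tryCatch(solve(A[S, S, drop = FALSE], b[S]),
                     error = function(e) NULL)
  if (is.null(w_full)) {
    ridge <- 1e-8 * mean(abs(diag(A)[S]))
    w_full <- tryCatch(
      solve(A[S, S, drop = FALSE] + diag(ridge, length(S)), b[S]),
      error = function(e) NULL)
    if (is.null(w_full)) {
      warning("singular sliding system; landmarks left in place")
      return(curve)
    }
  }
  clamp <- if (is.null(options$step_clamp)) default_clamp(pts)[S]
           else rep(options$step_clamp, length(S))
  e0 <- bending_energy(kernel, pts)
  best <- curve
  for (scale in c(1, 0.5, 0.25, 0.125, 0.0625)) {
    w <- pmin(pmax(w_full * scale, -clamp), clamp)
    cand <- pts
    cand[S, ] <- cand[S, ] + w * u[S, , drop = FALSE]
    cand[S, ] <- project_to_polyline(cand[S, , drop = FALSE], original_curve)
    if (bending_energy(kernel, cand) <= e0 + 1e-9) {
      best <- set_curve_points(curve, cand)
      break
    }
  }
  best
}

#' Slide one configuration against a reference
#'
#' One pass of tangential sliding for every sliding semilandmark of the
#' MT-BL and MG-BL, each against its own TPS kernel built on the reference
#' curve, followed by back-projection onto the configuration's original
#' observed polyline.  Fixed landmarks (papilla anchors) never move.  The
#' configuration and reference must already be in a common (aligned) frame.
#'
#' @param config,reference [arch_configuration] objects in correspondence.
#' @param kernels optional list with elements `mtbl` and `mgbl`
#'   ([tps_kernel] objects on the reference curves); built on the fly when
#'   `NULL`.
#' @param options a [sliding_options] object.
#' @param original configuration whose curves define the original observed
#'   polylines for back-projection (defaults to `config` itself).
#' @return The slid [arch_configuration], with attribute `bending_energy`
#'   (total MT-BL + MG-BL energy vs the reference, never above the input's).
#' @export
slide_once <- function(config, reference, kernels = NULL,
                       options = sliding_options(), original = config) {
  if (is.null(kernels))
    kernels <- list(mtbl = tps_kernel(reference$mtbl),
                    mgbl = tps_kernel(reference$mgbl))
  for (pass in seq_len(options$inner_iterations)) {
    config$mtbl <- slide_curve(config$mtbl, kernels$mtbl, options, original$mtbl)
    config$mgbl <- slide_curve(config$mgbl, kernels$mgbl, options, original$mgbl)
  }
  attr(config, "bending_energy") <-
    bending_energy(kernels$mtbl, config$mtbl) +
    bending_energy(kernels$mgbl, config$mgbl)
  config
}

#' Relax a population's sliding semilandmarks
#'
#' Alternates generalized Procrustes alignment, consensus (reference)
#' update, and per-configuration tangential sliding with back-projection,
#' for `options$outer_iterations` rounds.  Sliding removes arbitrary
#' digitization spacing along the borderline curves by minimizing TPS
#' bending energy relative to the reference; landmarks always remain on
#' their own originally observed polyline, and fixed anchor landmarks are
#' returned bit-identical.  The relaxed population is reported in each
#' subject's original coordinate frame (alignment is internal), so the only
#' change is a re-parameterization of sliding points along their curves.
#'
#' @param pop a [population_sample].
#' @param options a [sliding_options] object.
#' @param fit_indices landmark indices used for the interleaved GPA
#'   (default: MT-BL block).
#' @return A list of class `sliding_result`: `population` (relaxed, original
#'   frames), `aligned_population`, `consensus` (final reference),
#'   `energy_trace` (n x iterations matrix, bending energy vs the current
#'   reference after each outer iteration), `iterations`.
#' @export
relax_population <- function(pop, options = sliding_options(),
                             fit_indices = NULL) {
  if (!inherits(pop, "population_sample"))
    stop_input("pop must be a population_sample")
  n <- length(pop)
  current <- pop
  acc <- replicate(n, rigid_transform(), simplify = FALSE)
  energy_trace <- matrix(NA_real_, n, 0)
  reference <- NULL
  last_mean <- Inf
  iters <- 0L
  for (it in seq_len(options$outer_iterations)) {
    gp <- generalized_procrustes(current, fit_indices = fit_indices)
    current <- gp$population
    for (i in seq_len(n)) acc[[i]] <- compose_transform(gp$transforms[[i]], acc[[i]])
    if (is.null(reference) || options$reference_policy == "sample_mean")
      reference <- gp$consensus
    kernels <- list(mtbl = tps_kernel(reference$mtbl),
                    mgbl = tps_kernel(reference$mgbl))
    configs <- current$configurations
    energies <- numeric(n)
    for (i in seq_len(n)) {
      orig_aligned <- transform_config(pop$configurations[[i]], acc[[i]])
      configs[[i]] <- slide_once(configs[[i]], reference, kernels, options,
                                 original = orig_aligned)
      energies[i] <- attr(configs[[i]], "bending_energy")
      attr(configs[[i]], "bending_energy") <- NULL
    }
    current <- population_sample(configs, params = pop$params)
    energy_trace <- cbind(energy_trace, energies)
    iters <- it
    if (is.finite(last_mean) &&
        (last_mean - mean(energies)) < options$energy_tol * max(last_mean, 1e-12))
      break
    last_mean <- mean(energies)
  }
  colnames(energy_trace) <- paste0("iter", seq_len(ncol(energy_trace)))
  # map the relaxed sliding positions back into each subject's original frame
  out_configs <- pop$configurations
  for (i in seq_len(n)) {
    back <- transform_config(current$configurations[[i]], invert_transform(acc[[i]]))
    for (crv in c("mtbl", "mgbl")) {
      S <- which(curve_roles(out_configs[[i]][[crv]]) == "sliding")
      pts <- curve_points(out_configs[[i]][[crv]])
      moved <- curve_points(back[[crv]])[S, , drop = FALSE]
      pts[S, ] <- project_to_polyline(moved, out_configs[[i]][[crv]])
      out_configs[[i]][[crv]] <- set_curve_points(out_configs[[i]][[crv]], pts)
    }
  }
  structure(list(population = population_sample(out_configs, params = pop$params),
                 aligned_population = current, consensus = reference,
                 energy_trace = energy_trace, iterations = iters),
            class = "sliding_result")
}

#' @export
print.sliding_result <- function(x, ...) {
  cat(sprintf("sliding_result: %d configurations, %d outer iterations, mean energy %.4g\n",
              length(x$population), x$iterations,
              mean(x$energy_trace[, ncol(x$energy_trace)])))
  invisible(x)
}
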
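#' Generalized Procrustes analysis restricted to a landmark subset
#'
#' Iteratively superimposes a population of configurations using only the
#' `fit_indices` landmarks (by default the whole MT-BL block, semilandmarks
#' plus papilla anchors) to estimate each rigid motion, then applies that
#' motion to ALL landmarks, so the MG-BL "rides along" without ever
#' influencing the registration.  Each iteration: (a) center every
#' configuration so the centroid of its fit subset is at the origin, (b)
#' rigid-fit each fit subset to the current consensus fit subset, (c)
#' recompute the consensus as the landmark-wise mean.  Stops when the RMS
#' change of the consensus fit coordinates drops below `tol`.
#'
#' Only rotation and position are removed; size is preserved (errors stay in
#' mm).  Set `scale = TRUE` for a similarity GPA.
#'
#' @param pop a [population_sample].
#' @param fit_indices landmark (row) indices used for registration; default
#'   all MT-BL landmarks.
#' @param tol convergence tolerance on the RMS consensus change (mm).
#' @param max_iter maximum number of iterations.
#' @param scale estimate per-configuration scale factors as well?
#' @return A list of class `procrustes_fit` with elements
#'   `population` (aligned [population_sample]), `consensus` (mean
#'   [arch_configuration]), `transforms` (per-subject [rigid_transform]
#'   original -> aligned), `objective_trace` (sum of squared fit-subset
#'   deviations from the consensus per iteration), `iterations`, and
#'   `converged`.
#' @export
generalized_procrustes <- function(pop, fit_indices = NULL, tol = 1e-8,
                                   max_iter = 100L, scale = FALSE) {
  if (!inherits(pop, "population_sample"))
    stop_input("pop must be a population_sample")
  if (is.null(fit_indices)) fit_indices <- mtbl_indices(pop)
  fit_indices <- as.integer(fit_indices)
  n_pts <- sum(pop$counts)
  if (length(fit_indices) == 0L || any(fit_indices < 1L | fit_indices > n_pts))
    stop_input("fit_indices must be a nonempty subset of landmark indices")
  n <- length(pop)
  pts <- lapply(pop$configurations, config_points)
  transforms <- vector("list", n)
  # (a) initial centering on the fit-subset centroid
  for (i in seq_len(n)) {
    ctr <- colMeans(pts[[i]][fit_indices, , drop = FALSE])
    transforms[[i]] <- rigid_transform(diag(3), -ctr)
    pts[[i]] <- sweep(pts[[i]], 2, ctr)
  }
  mean_pts <- function() Reduce(`+`, pts) / n
  consensus <- mean_pts()
  objective <- function(cons) {
    sum(vapply(pts, function(p)
      sum((p[fit_indices, ] - cons[fit_indices, ])^2), numeric(1)))
  }
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    for (i in seq_len(n)) {
      tf <- rigid_fit(pts[[i]][fit_indices, , drop = FALSE],
                      consensus[fit_indices, , drop = FALSE], scale = scale)
      pts[[i]] <- apply_transform(tf, pts[[i]])
      transforms[[i]] <- compose_transform(tf, transforms[[i]])
    }
    new_consensus <- mean_pts()
    trace[iter] <- objective(new_consensus)
    delta <- sqrt(mean((new_consensus[fit_indices, ] -
                          consensus[fit_indices, ])^2))
    consensus <- new_consensus
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged)
    warning(sprintf("GPA did not converge in %d iterations (last RMS delta %.3g)",
                    iter, delta))
  # canonicalize the consensus orientation so the alignment is invariant to
  # the inputs' arbitrary poses: principal axes of the fit subset, signs
  # fixed by odd moments of the canonical coordinates
  canon <- canonical_frame(consensus[fit_indices, , drop = FALSE])
  for (i in seq_len(n)) {
    pts[[i]] <- apply_transform(canon, pts[[i]])
    transforms[[i]] <- compose_transform(canon, transforms[[i]])
  }
  consensus <- apply_transform(canon, consensus)
  configs <- pop$configurations
  for (i in seq_len(n)) configs[[i]] <- set_config_points(configs[[i]], pts[[i]])
  cons_cfg <- set_config_points(configs[[1]], consensus)
  cons_cfg$subject_id <- "consensus"
  cons_cfg$superimposition <- NULL
  structure(list(population = population_sample(configs, params = pop$params),
                 consensus = cons_cfg, transforms = transforms,
                 objective_trace = trace, iterations = iter,
                 converged = converged),
            class = "procrustes_fit")
}

# Deterministic canonical pose for a point set with shared correspondence:
# rotate onto the principal axes, sign of each axis fixed by the coordinate
# skewness (falling back to a first-half vs second-half index contrast when
# the skewness is degenerate), then enforce a proper rotation.
canonical_frame <- function(P) {
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  V <- svd(crossprod(Pc))$u
  n <- nrow(Pc)
  half <- seq_len(floor(n / 2))
  crit <- numeric(3)
  for (k in 1:3) {
    ck <- as.vector(Pc %*% V[, k])
    s <- sum(ck^3)
    scale3 <- (sum(ck^2) / n)^1.5 * n
    crit[k] <- if (abs(s) > 1e-6 * scale3) s
               else sum(ck[half]) - sum(ck[(n - length(half) + 1L):n])
    if (crit[k] < 0) { V[, k] <- -V[, k]; crit[k] <- -crit[k] }
  }
  if (det(V) < 0) {
    j <- which.min(abs(crit))
    V[, j] <- -V[, j]
  }
  R <- t(V)
  rigid_transform(R, -as.vector(R %*% ctr))
}

#' @export
print.procrustes_fit <- function(x, ...) {
  cat(sprintf("procrustes_fit: %d configurations aligned in %d iterations (%s)\n",
              length(x$population), x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
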
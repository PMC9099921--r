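#' Fit a PCA statistical shape model
#'
#' Vectorizes each aligned configuration (x1 y1 z1 x2 ..., MT-BL block before
#' MG-BL block), computes the sample mean and the eigendecomposition of the
#' sample covariance (divisor n - 1) via SVD of the centered data matrix,
#' and stores unit-norm principal directions with their variances.  The
#' MT-BL coordinate rows form the observed block, the MG-BL rows the latent
#' block used for posterior reconstruction.
#'
#' @param pop an aligned [population_sample] (post-GPA, optionally
#'   post-sliding), n >= 3.
#' @param variance_to_retain fraction of total variance to keep; the
#'   smallest k components whose cumulative eigenvalue fraction reaches it.
#'   Default 1.0 keeps all nonzero components (k <= n - 1).
#' @param sigma2 default observation noise variance in mm^2 used by
#'   [posterior_predict()] and [reconstruct_mgbl()] when not overridden.
#' @return An object of class `arch_ssm`: list with `mean` (3m vector, mm),
#'   `basis` (3m x k, orthonormal columns), `eigenvalues` (k variances,
#'   mm^2, descending), `observed_rows`, `latent_rows`, `jaw`, `n_training`,
#'   `counts`, `template` (a training configuration used to rebuild curves),
#'   `sigma2`.
#' @seealso [posterior_predict()], [reconstruct_mgbl()], [loocv()]
#' @export
ssm_fit <- function(pop, variance_to_retain = 1.0, sigma2 = 1e-4) {
  if (!inherits(pop, "population_sample"))
    stop_input("pop must be a population_sample")
  n <- length(pop)
  if (n < 3L) stop_input("shape model needs at least 3 configurations")
  if (variance_to_retain <= 0 || variance_to_retain > 1)
    stop_input("variance_to_retain must be in (0, 1]")
  X <- t(vapply(pop$configurations, config_vector,
                numeric(3 * sum(pop$counts))))
  mean_v <- colMeans(X)
  Xc <- sweep(X, 2, mean_v)
  sv <- svd(Xc, nu = 0)
  ev <- sv$d^2 / (n - 1)
  total_var <- sum(ev)
  nonzero <- ev > max(ev[1], 1) * 1e-12 * n
  k_max <- min(sum(nonzero), n - 1L)
  if (k_max == 0L) {
    basis <- matrix(0, ncol(X), 0)
    ev <- numeric(0)
  } else {
    cum <- cumsum(ev[seq_len(k_max)]) / total_var
    k <- which(cum >= variance_to_retain - 1e-12)[1]
    if (is.na(k)) k <- k_max
    basis <- sv$v[, seq_len(k), drop = FALSE]
    ev <- ev[seq_len(k)]
  }
  n_mt <- pop$counts[["n_mt"]]
  template <- pop$configurations[[1]]
  template$superimposition <- NULL
  structure(list(mean = mean_v, basis = basis, eigenvalues = ev,
                 observed_rows = seq_len(3L * n_mt),
                 latent_rows = (3L * n_mt + 1L):length(mean_v),
                 jaw = pop$jaw, n_training = n, counts = pop$counts,
                 total_variance = total_var, template = template,
                 sigma2 = sigma2),
            class = "arch_ssm")
}

#' @export
print.arch_ssm <- function(x, ...) {
  cat(sprintf("arch_ssm (%s): %d training shapes, %d MT-BL + %d MG-BL landmarks, %d components\n",
              x$jaw, x$n_training, x$counts[["n_mt"]], x$counts[["n_mg"]],
              length(x$eigenvalues)))
  invisible(x)
}

#' @export
summary.arch_ssm <- function(object, ...) {
  ev <- object$eigenvalues
  tab <- data.frame(component = seq_along(ev), variance_mm2 = ev,
                    proportion = if (length(ev)) ev / object$total_variance else numeric(0),
                    cumulative = if (length(ev)) cumsum(ev) / object$total_variance else numeric(0))
  out <- list(model = object, components = tab)
  class(out) <- "summary.arch_ssm"
  out
}

#' @export
print.summary.arch_ssm <- function(x, ...) {
  print(x$model)
  if (nrow(x$components)) {
    cat("Leading components:\n")
    print(utils::head(x$components, 10), row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
coef.arch_ssm <- function(object, ...) object$eigenvalues

# scaled basis Q = basis diag(sqrt(eigenvalues)); coefficients are in SD units
scaled_basis <- function(model) {
  if (length(model$eigenvalues) == 0L)
    return(matrix(0, length(model$mean), 0))
  model$basis %*% diag(sqrt(model$eigenvalues), length(model$eigenvalues))
}

#' Synthesize and project model shapes
#'
#' `model_instance()` evaluates mean + sum_j alpha_j sqrt(lambda_j) b_j for
#' standard-deviation-scaled coefficients alpha; `model_project()` inverts it
#' on the model span: diag(1/sqrt(lambda)) B' (shape - mean).
#'
#' @param model an [ssm_fit()] model.
#' @param coefficients k-vector of SD-scaled coefficients.
#' @return `model_instance()`: 3m shape vector; `model_project()`: k-vector.
#' @export
model_instance <- function(model, coefficients) {
  if (length(coefficients) != length(model$eigenvalues))
    stop_input("coefficients must have one entry per model component")
  as.vector(model$mean + scaled_basis(model) %*% coefficients)
}

#' @rdname model_instance
#' @param shape 3m shape vector (model frame).
#' @export
model_project <- function(model, shape) {
  if (length(shape) != length(model$mean))
    stop_input("shape must have length 3m")
  if (length(model$eigenvalues) == 0L) return(numeric(0))
  as.vector(crossprod(model$basis, shape - model$mean) / sqrt(model$eigenvalues))
}

#' Posterior-mean prediction from an observed landmark subset
#'
#' Under the Gaussian shape model x = mean + Q alpha, alpha ~ N(0, I), with
#' iid observation noise N(0, sigma2 I) on the observed rows, the posterior
#' mean of the coefficients given the observed coordinates is
#' alpha* = (Qo' Qo + sigma2 I)^-1 Qo' (observed - mean_o), where Qo is the
#' observed-row block of Q = basis diag(sqrt(lambda)).  The full predicted
#' shape is mean + Q alpha* — the exact conditional expectation of the
#' latent (MG-BL) block given the observed (MT-BL) block.
#'
#' @param model an [ssm_fit()] model.
#' @param observed numeric vector of coordinates for `model$observed_rows`
#'   (model frame).
#' @param sigma2 observation noise variance in mm^2 (> 0); defaults to the
#'   model's `sigma2`.
#' @return A list of class `ssm_posterior`: `full_shape` (3m vector),
#'   `coefficients` (alpha*), `sigma2`.
#' @export
posterior_predict <- function(model, observed, sigma2 = model$sigma2) {
  if (!inherits(model, "arch_ssm")) stop_input("model must be an arch_ssm")
  if (!is.numeric(sigma2) || length(sigma2) != 1L || sigma2 <= 0)
    stop_input("sigma2 must be a positive scalar")
  observed <- as.numeric(observed)
  if (length(observed) != length(model$observed_rows))
    stop_input("observed must match the model's observed block length")
  Q <- scaled_basis(model)
  k <- ncol(Q)
  if (k == 0L) {
    alpha <- numeric(0)
    full <- model$mean
  } else {
    Qo <- Q[model$observed_rows, , drop = FALSE]
    rhs <- crossprod(Qo, observed - model$mean[model$observed_rows])
    alpha <- as.vector(solve(crossprod(Qo) + diag(sigma2, k), rhs))
    full <- as.vector(model$mean + Q %*% alpha)
  }
  structure(list(full_shape = full, coefficients = alpha, sigma2 = sigma2),
            class = "ssm_posterior")
}

#' Draw random shapes from the model
#'
#' Samples mean + Q z with z ~ N(0, I_k) from a seeded generator.
#'
#' @param model an [ssm_fit()] model with k >= 1 components.
#' @param seed integer seed; the caller's RNG state is preserved.
#' @return 3m shape vector.
#' @export
sample_shape <- function(model, seed) {
  if (length(model$eigenvalues) < 1L)
    stop_input("model has no components to sample from")
  z <- with_preserved_seed(seed, stats::rnorm(length(model$eigenvalues)))
  model_instance(model, z)
}

#' @export
simulate.arch_ssm <- function(object, nsim = 1, seed = NULL, ...) {
  z <- with_preserved_seed(seed,
    matrix(stats::rnorm(nsim * length(object$eigenvalues)),
           nrow = length(object$eigenvalues)))
  out <- apply(z, 2, function(zi) model_instance(object, zi))
  matrix(out, ncol = nsim)
}

# rebuild landmark_curve objects from a shape vector using the model template
shape_to_config <- function(model, shape, subject_id = "model") {
  cfg <- model$template
  cfg$subject_id <- subject_id
  set_config_points(cfg, vector_to_points(shape))
}

#' Save and load shape models
#'
#' The container is a single JSON file of named numeric arrays plus a
#' metadata record (jaw, counts, training size, format version), written at
#' full floating-point precision so the round trip is lossless.
#'
#' @param model an [ssm_fit()] model.
#' @param path file path (conventionally `.ssm.json`).
#' @return `load_model()` returns the restored `arch_ssm`.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "arch_ssm")) stop_input("model must be an arch_ssm")
  tpl <- model$template
  payload <- list(
    format = "archssm-model", version = 1L,
    jaw = model$jaw, n_training = model$n_training,
    counts = as.list(model$counts),
    sigma2 = model$sigma2, total_variance = model$total_variance,
    mean = model$mean, eigenvalues = model$eigenvalues,
    basis = as.vector(model$basis), basis_ncol = ncol(model$basis),
    observed_rows = model$observed_rows, latent_rows = model$latent_rows,
    template = list(subject_id = tpl$subject_id,
                    mtbl_roles = curve_roles(tpl$mtbl),
                    mtbl_closed = attr(tpl$mtbl, "closed"),
                    mgbl_roles = curve_roles(tpl$mgbl),
                    mgbl_closed = attr(tpl$mgbl, "closed")))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_input("model file not found: ", path)
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e)
                        stop_input("not a readable model file: ",
                                   conditionMessage(e)))
  if (!identical(payload$format, "archssm-model"))
    stop_input("not an archssm model file")
  if (!identical(as.integer(payload$version), 1L))
    stop_input("unsupported model format version: ", payload$version)
  need <- c("mean", "eigenvalues", "basis", "basis_ncol", "observed_rows",
            "latent_rows", "jaw", "counts", "n_training", "template")
  missing <- setdiff(need, names(payload))
  if (length(missing))
    stop_input("model file missing fields: ", paste(missing, collapse = ", "))
  mean_v <- as.numeric(payload$mean)
  pts <- vector_to_points(mean_v)
  n_mt <- as.integer(payload$counts$n_mt)
  tpl <- arch_configuration(
    payload$template$subject_id, payload$jaw,
    mtbl = landmark_curve(pts[seq_len(n_mt), , drop = FALSE],
                          roles = payload$template$mtbl_roles,
                          closed = isTRUE(payload$template$mtbl_closed)),
    mgbl = landmark_curve(pts[(n_mt + 1L):nrow(pts), , drop = FALSE],
                          roles = payload$template$mgbl_roles,
                          closed = isTRUE(payload$template$mgbl_closed)))
  structure(list(
    mean = mean_v,
    basis = matrix(as.numeric(payload$basis), ncol = payload$basis_ncol),
    eigenvalues = as.numeric(payload$eigenvalues),
    observed_rows = as.integer(payload$observed_rows),
    latent_rows = as.integer(payload$latent_rows),
    jaw = payload$jaw, n_training = as.integer(payload$n_training),
    counts = c(n_mt = n_mt, n_mg = as.integer(payload$counts$n_mg)),
    total_variance = as.numeric(payload$total_variance),
    template = tpl, sigma2 = as.numeric(payload$sigma2)),
    class = "arch_ssm")
}
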
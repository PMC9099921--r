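#' Reconstruct the mucogingival borderline from a gingival margin
#'
#' Rigid-fits the query MT-BL onto the model's mean MT-BL (registration uses
#' the MT-BL only — the "known structure"), computes the posterior-mean full
#' shape given the aligned MT-BL coordinates, and maps the predicted MG-BL
#' back into the query's original coordinate frame.  The query's own MT-BL
#' is returned untouched.
#'
#' @param model an [ssm_fit()] model.
#' @param query_mtbl [landmark_curve] with the model's MT-BL landmark count.
#' @param sigma2 observation noise variance (mm^2); default the model's.
#' @return A list of class `mgbl_prediction`: `mgbl` (predicted
#'   [landmark_curve] in the query frame), `posterior` ([posterior_predict()]
#'   result in the model frame), `alignment` (query -> model
#'   [rigid_transform]).
#' @export
reconstruct_mgbl <- function(model, query_mtbl, sigma2 = model$sigma2) {
  if (!inherits(model, "arch_ssm")) stop_input("model must be an arch_ssm")
  if (!inherits(query_mtbl, "landmark_curve"))
    stop_input("query_mtbl must be a landmark_curve")
  n_mt <- model$counts[["n_mt"]]
  if (nrow(query_mtbl) != n_mt)
    stop_input("query MT-BL has ", nrow(query_mtbl),
               " landmarks; the model expects ", n_mt)
  q <- curve_points(query_mtbl)
  mean_mt <- vector_to_points(model$mean[model$observed_rows])
  alignment <- rigid_fit(q, mean_mt)
  q_aligned <- apply_transform(alignment, q)
  post <- posterior_predict(model, as.vector(t(q_aligned)), sigma2 = sigma2)
  mg_model <- vector_to_points(post$full_shape[model$latent_rows])
  mg_query <- apply_transform(invert_transform(alignment), mg_model)
  mgbl <- set_curve_points(model$template$mgbl, mg_query)
  structure(list(mgbl = mgbl, posterior = post, alignment = alignment),
            class = "mgbl_prediction")
}

#' @export
print.mgbl_prediction <- function(x, ...) {
  cat(sprintf("mgbl_prediction: %d predicted MG-BL landmarks (sigma2 = %g mm^2)\n",
              nrow(x$mgbl), x$posterior$sigma2))
  invisible(x)
}

#' @export
#' @rdname reconstruct_mgbl
#' @param object an `arch_ssm` model (for the `predict` method).
#' @param ... unused.
predict.arch_ssm <- function(object, query_mtbl, sigma2 = object$sigma2, ...) {
  reconstruct_mgbl(object, query_mtbl, sigma2 = sigma2)
}

#' Point-wise distances between an actual and a predicted curve
#'
#' For each point of the actual curve, the distance to its closest
#' counterpart on the predicted curve — either the nearest predicted vertex
#' (`"nearest_vertex"`) or the nearest point on the predicted polyline
#' (`"nearest_on_polyline"`, always point-wise less than or equal).  The
#' measure is asymmetric: distances run from the actual to the predicted
#' curve.
#'
#' @param actual,predicted [landmark_curve] objects (or m x 3 matrices).
#' @param mode distance mode; see above.
#' @return Nonnegative numeric vector, one distance (mm) per actual point.
#' @export
pointwise_error <- function(actual, predicted,
                            mode = c("nearest_vertex", "nearest_on_polyline")) {
  mode <- match.arg(mode)
  a <- if (inherits(actual, "landmark_curve")) curve_points(actual)
       else as_points3(actual, "actual")
  if (nrow(a) == 0L) stop_input("actual curve is empty")
  if (mode == "nearest_vertex") {
    p <- if (inherits(predicted, "landmark_curve")) curve_points(predicted)
         else as_points3(predicted, "predicted")
    if (nrow(p) == 0L) stop_input("predicted curve is empty")
    # min over predicted vertices of the euclidean distance, per actual point
    d2 <- outer(rowSums(a^2), rep(1, nrow(p))) +
      outer(rep(1, nrow(a)), rowSums(p^2)) - 2 * tcrossprod(a, p)
    sqrt(pmax(apply(d2, 1, min), 0))
  } else {
    dist_to_polyline(a, predicted)
  }
}

#' Pooled error statistics
#'
#' Median, 10th and 90th percentile (linear interpolation between order
#' statistics, the type-7 convention), and the mean (used only for ranking
#' best/worst cases, since the error distribution is non-Gaussian).
#'
#' @param distances nonempty vector of nonnegative distances (mm).
#' @return A list of class `error_summary`: `n_points`, `median`, `p10`,
#'   `p90`, `mean`.
#' @export
summarize_errors <- function(distances) {
  distances <- as.numeric(distances)
  if (length(distances) == 0L) stop_input("no distances to summarize")
  if (any(!is.finite(distances)) || any(distances < 0))
    stop_input("distances must be finite and nonnegative")
  q <- stats::quantile(distances, c(0.1, 0.5, 0.9), type = 7, names = FALSE)
  structure(list(n_points = length(distances), median = q[2],
                 p10 = q[1], p90 = q[3], mean = mean(distances)),
            class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("error_summary: median %.3f mm (P10 %.3f - P90 %.3f), mean %.3f, n = %d\n",
              x$median, x$p10, x$p90, x$mean, x$n_points))
  invisible(x)
}

#' Leave-one-out cross-validation of MG-BL reconstruction
#'
#' For each subject: rebuild the whole pipeline on the remaining n - 1
#' configurations (optional sliding relaxation, MT-BL-restricted GPA, PCA
#' model), reconstruct the held-out subject's MG-BL from its MT-BL alone,
#' and measure point-wise distances against the held-out true MG-BL in the
#' subject's own coordinate frame.  The held-out MG-BL never influences the
#' training consensus, sliding reference, or principal components.  Pooled
#' statistics concatenate every per-point distance before computing
#' median/P10/P90.
#'
#' @param pop a [population_sample] with n >= 4 subjects.
#' @param sliding `TRUE` for default [sliding_options()], `FALSE` to skip
#'   relaxation, or a `sliding_options` object.
#' @param sigma2 observation noise variance for the posterior (mm^2).
#' @param variance_to_retain passed to [ssm_fit()].
#' @param mode error mode, see [pointwise_error()].
#' @param predictor `"posterior"` for the SSM prediction, `"mean"` for the
#'   baseline that predicts the training-mean MG-BL for every subject
#'   (alignment still via the query MT-BL).
#' @return A list of class `loocv_report`: `per_subject` (named list of
#'   [summarize_errors()] results), `distances` (named list of per-point
#'   vectors), `pooled` (`error_summary`), `best_subject_id`,
#'   `worst_subject_id` (argmin/argmax of the per-subject mean), `jaw`,
#'   `failed` (ids of folds that errored, normally empty).
#' @export
loocv <- function(pop, sliding = TRUE, sigma2 = 1e-4,
                  variance_to_retain = 1.0,
                  mode = c("nearest_vertex", "nearest_on_polyline"),
                  predictor = c("posterior", "mean")) {
  mode <- match.arg(mode)
  predictor <- match.arg(predictor)
  if (!inherits(pop, "population_sample"))
    stop_input("pop must be a population_sample")
  n <- length(pop)
  if (n < 4L) stop_input("LOOCV needs at least 4 subjects")
  slide_opts <- if (isTRUE(sliding)) sliding_options()
                else if (inherits(sliding, "sliding_options")) sliding
                else NULL
  ids <- vapply(pop$configurations, `[[`, character(1), "subject_id")
  per_subject <- distances <- stats::setNames(vector("list", n), ids)
  failed <- character(0)
  for (i in seq_len(n)) {
    res <- tryCatch({
      train <- pop[-i]
      if (!is.null(slide_opts))
        train <- relax_population(train, slide_opts)$population
      gp <- generalized_procrustes(train)
      model <- ssm_fit(gp$population, variance_to_retain = variance_to_retain,
                       sigma2 = sigma2)
      pred <- reconstruct_mgbl(model, pop[[i]]$mtbl,
                               sigma2 = if (predictor == "mean") 1e12 else sigma2)
      if (predictor == "mean") {
        # pure prior-mean baseline: zero coefficients exactly
        mg_model <- vector_to_points(model$mean[model$latent_rows])
        mg_query <- apply_transform(invert_transform(pred$alignment), mg_model)
        pred$mgbl <- set_curve_points(pred$mgbl, mg_query)
      }
      pointwise_error(pop[[i]]$mgbl, pred$mgbl, mode = mode)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("LOOCV fold for subject '%s' failed: %s",
                      ids[i], conditionMessage(res)))
      failed <- c(failed, ids[i])
    } else {
      distances[[i]] <- res
      per_subject[[i]] <- summarize_errors(res)
    }
  }
  ok <- !vapply(distances, is.null, logical(1))
  if (!any(ok)) stop_input("every LOOCV fold failed")
  means <- vapply(per_subject[ok], `[[`, numeric(1), "mean")
  structure(list(per_subject = per_subject[ok], distances = distances[ok],
                 pooled = summarize_errors(unlist(distances[ok])),
                 best_subject_id = names(which.min(means)),
                 worst_subject_id = names(which.max(means)),
                 jaw = pop$jaw, mode = mode, sigma2 = sigma2,
                 predictor = predictor, failed = failed),
            class = "loocv_report")
}

#' @export
print.loocv_report <- function(x, ...) {
  cat(sprintf("loocv_report (%s, %s, %s): %d subjects, %d pooled distances\n",
              x$jaw, x$mode, x$predictor, length(x$per_subject),
              x$pooled$n_points))
  cat(sprintf("  pooled median %.3f mm (P10 %.3f - P90 %.3f)\n",
              x$pooled$median, x$pooled$p10, x$pooled$p90))
  cat(sprintf("  best '%s', worst '%s' by per-subject mean\n",
              x$best_subject_id, x$worst_subject_id))
  if (length(x$failed))
    cat(sprintf("  INCOMPLETE: %d failed folds (%s)\n", length(x$failed),
                paste(x$failed, collapse = ", ")))
  invisible(x)
}

#' @export
plot.loocv_report <- function(x, ...) {
  graphics::boxplot(x$distances, las = 2, ylab = "error (mm)",
                    main = sprintf("LOOCV MG-BL reconstruction error (%s)", x$jaw),
                    ...)
  graphics::abline(h = x$pooled$median, lty = 2)
  invisible(x)
}

#' Write a per-point LOOCV error report as CSV
#'
#' One row per (subject, point) distance; summary rows (per-subject and
#' pooled) carry `point_index = NA` and the statistic name in `statistic`.
#'
#' @param report a [loocv()] report.
#' @param path output CSV path.
#' @return The path, invisibly.  Columns: subject_id, jaw, point_index,
#'   statistic, distance_mm.
#' @export
write_error_report <- function(report, path) {
  if (!inherits(report, "loocv_report"))
    stop_input("report must be a loocv_report")
  rows <- lapply(names(report$distances), function(id) {
    d <- report$distances[[id]]
    s <- report$per_subject[[id]]
    rbind(data.frame(subject_id = id, jaw = report$jaw,
                     point_index = seq_along(d), statistic = "distance",
                     distance_mm = d),
          data.frame(subject_id = id, jaw = report$jaw, point_index = NA,
                     statistic = c("median", "p10", "p90", "mean"),
                     distance_mm = c(s$median, s$p10, s$p90, s$mean)))
  })
  pooled <- data.frame(subject_id = "POOLED", jaw = report$jaw,
                       point_index = NA,
                       statistic = c("median", "p10", "p90", "mean"),
                       distance_mm = c(report$pooled$median, report$pooled$p10,
                                       report$pooled$p90, report$pooled$mean))
  utils::write.csv(rbind(do.call(rbind, rows), pooled), path,
                   row.names = FALSE)
  invisible(path)
}

#' Rigid superimposition from anatomical landmarks
#'
#' Utility for cross-modality use: fits the rigid motion mapping one
#' configuration's 4 anatomical superimposition landmarks onto another's
#' (e.g. digitized plaster cast onto intra-oral scan).
#'
#' @param from,to [arch_configuration] objects carrying superimposition
#'   landmarks.
#' @return A [rigid_transform] mapping `from` coordinates into `to`'s frame.
#' @export
superimpose_configurations <- function(from, to) {
  if (is.null(from$superimposition) || is.null(to$superimposition))
    stop_input("both configurations need superimposition landmarks")
  rigid_fit(from$superimposition, to$superimposition)
}
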
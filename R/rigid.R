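#' Rigid transforms and least-squares rigid registration
#'
#' `rigid_transform()` packages a proper rotation and a translation;
#' `rigid_fit()` solves the orthogonal Procrustes problem without scaling
#' (the Kabsch solution): the proper rigid motion minimizing
#' \eqn{\sum_i \|R s_i + t - t_i\|^2}.  Scaling is deliberately excluded so
#' that downstream errors stay in physical mm; an optional similarity fit is
#' available via `scale = TRUE`.
#'
#' @param rotation 3 x 3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric vector (mm).
#' @return `rigid_transform()` returns an object of class `rigid_transform`
#'   with fields `rotation`, `translation` and `scale`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  storage.mode(rotation) <- "double"
  if (!identical(dim(rotation), c(3L, 3L)))
    stop_input("rotation must be a 3 x 3 matrix")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop_input("rotation must be orthonormal")
  if (det(rotation) < 0)
    stop_input("rotation must be proper (det = +1), not a reflection")
  translation <- as.numeric(translation)
  if (length(translation) != 3L || !all(is.finite(translation)))
    stop_input("translation must be a finite length-3 vector")
  structure(list(rotation = rotation, translation = translation, scale = 1),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(pmax((sum(diag(x$rotation)) - 1) / 2, -1), 1)) * 180 / pi
  cat(sprintf("rigid_transform: rotation %.2f deg, translation (%.3f, %.3f, %.3f) mm",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  if (x$scale != 1) cat(sprintf(", scale %.4f", x$scale))
  cat("\n")
  invisible(x)
}

#' @rdname rigid_transform
#' @param source,target m x 3 matrices of corresponding points, m >= 3.
#' @param scale if `TRUE`, additionally estimate a global scale factor
#'   (similarity fit).  Default `FALSE`: rigid only.
#' @return `rigid_fit()` returns a `rigid_transform` mapping `source` onto
#'   `target` in the least-squares sense.
#' @examples
#' src <- matrix(rnorm(30), 10, 3)
#' tf <- rigid_transform(diag(3)[, c(2, 3, 1)], c(1, 2, 3))
#' fit <- rigid_fit(src, apply_transform(tf, src))
#' max(abs(fit$rotation - tf$rotation))
#' @export
rigid_fit <- function(source, target, scale = FALSE) {
  s <- as_points3(source, "source")
  t <- as_points3(target, "target")
  if (nrow(s) != nrow(t))
    stop_input("source and target must have the same number of points")
  if (nrow(s) < 3L) stop_input("rigid_fit needs at least 3 point pairs")
  cs <- colMeans(s); ct <- colMeans(t)
  s0 <- sweep(s, 2, cs); t0 <- sweep(t, 2, ct)
  H <- crossprod(s0, t0)   # 3x3 cross-covariance
  sv <- svd(H)
  if (sv$d[2] <= 1e-12 * max(sv$d[1], 1))
    stop_input("degenerate source: points are (nearly) collinear")
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  # force a proper rotation by flipping the smallest singular direction
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  k <- 1
  if (isTRUE(scale)) {
    k <- sum(sv$d * c(1, 1, d)) / sum(s0^2)
    if (!is.finite(k) || k <= 0) stop_input("degenerate source for scale estimation")
  }
  out <- rigid_transform(R, ct - k * as.vector(R %*% cs))
  out$scale <- k
  out
}

#' Apply or invert a rigid transform
#'
#' @param transform a [rigid_transform].
#' @param points m x 3 matrix.
#' @return `apply_transform()` returns the transformed m x 3 matrix
#'   (`scale * R p + t` per point); `invert_transform()` the inverse
#'   transform.
#' @export
apply_transform <- function(transform, points) {
  if (!inherits(transform, "rigid_transform"))
    stop_input("transform must be a rigid_transform")
  p <- as_points3(points, "points")
  sweep(transform$scale * (p %*% t(transform$rotation)), 2,
        transform$translation, `+`)
}

#' @rdname apply_transform
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  out <- rigid_transform(Rt, -as.vector(Rt %*% transform$translation) /
                           transform$scale)
  out$scale <- 1 / transform$scale
  out
}

# t2 after t1 (composition t2 o t1)
compose_transform <- function(t2, t1) {
  out <- rigid_transform(t2$rotation %*% t1$rotation,
                         as.vector(t2$scale * t2$rotation %*% t1$translation) +
                           t2$translation)
  out$scale <- t1$scale * t2$scale
  out
}

# residual sum of squares of a fitted transform
fit_residual <- function(transform, source, target) {
  sum((apply_transform(transform, source) - as_points3(target))^2)
}
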
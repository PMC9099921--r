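#' Thin-plate-spline bending energy
#'
#' `tps_kernel()` assembles the 3D thin-plate-spline system on a reference
#' point set with the radial kernel U(r) = r and returns the bending-energy
#' quadratic form: the upper-left m x m block of the inverted bordered
#' matrix \eqn{L = [[K, P], [P', 0]]} with \eqn{P = [1 | x | y | z]}.  In 3D
#' that block is negative semidefinite for U(r) = r (the biharmonic Green's
#' function is -r up to constants), so the block is negated to make the
#' energy nonnegative.  The form annihilates affine functions of the
#' reference coordinates, hence bending energy is invariant under affine
#' maps of the target.
#'
#' `bending_energy()` evaluates \eqn{\sum_{c \in x,y,z} y_c' B y_c} for a
#' target configuration in point-wise correspondence with the reference.
#'
#' @param reference m x 3 matrix (or [landmark_curve]) of reference points,
#'   m >= 5, no duplicates.
#' @return `tps_kernel()`: an object of class `tps_kernel` with fields
#'   `reference` and `bending_matrix` (symmetric PSD, mm^-2).
#' @examples
#' ref <- cbind(seq(0, 2, length.out = 8), sin(seq(0, 3, length.out = 8)), 0.1)
#' k <- tps_kernel(ref)
#' bending_energy(k, ref)                     # 0: self-energy
#' bending_energy(k, ref %*% diag(c(2, 1, 1)))  # ~0: affine map
#' @export
tps_kernel <- function(reference) {
  ref <- if (inherits(reference, "landmark_curve")) curve_points(reference)
         else as_points3(reference, "reference")
  m <- nrow(ref)
  if (m < 5L) stop_input("tps_kernel needs at least 5 reference points")
  K <- as.matrix(stats::dist(ref))   # U(r) = r
  if (any(K[upper.tri(K)] == 0))
    stop_input("duplicate reference points make the TPS system singular")
  P <- cbind(1, ref)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  Li <- tryCatch(solve(L), error = function(e)
    stop_input("singular TPS system: ", conditionMessage(e)))
  B <- -Li[seq_len(m), seq_len(m)]
  B <- (B + t(B)) / 2   # symmetrize round-off
  structure(list(reference = ref, bending_matrix = B), class = "tps_kernel")
}

#' @export
print.tps_kernel <- function(x, ...) {
  cat(sprintf("tps_kernel on %d reference points\n", nrow(x$reference)))
  invisible(x)
}

#' @rdname tps_kernel
#' @param kernel a `tps_kernel`.
#' @param target m x 3 matrix (or [landmark_curve]) in correspondence with
#'   the kernel's reference.
#' @return `bending_energy()`: a nonnegative scalar (mm^2-scaled energy).
#' @export
bending_energy <- function(kernel, target) {
  if (!inherits(kernel, "tps_kernel")) stop_input("kernel must be a tps_kernel")
  y <- if (inherits(target, "landmark_curve")) curve_points(target)
       else as_points3(target, "target")
  if (nrow(y) != nrow(kernel$reference))
    stop_input("target must match the kernel reference length")
  sum(vapply(1:3, function(c) as.numeric(crossprod(y[, c],
      kernel$bending_matrix %*% y[, c])), numeric(1)))
}
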
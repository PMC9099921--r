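#' Landmark curves
#'
#' A `landmark_curve` is an ordered 3D polyline of annotated landmarks in mm.
#' Each point carries a role: `"sliding"` for semilandmarks that may be
#' relaxed along the curve, or `"fixed"` for anatomically homologous anchor
#' points (e.g. interdental papilla tips) that must never move.
#'
#' @param points m x 3 numeric matrix of coordinates (mm), m >= 3.
#' @param roles character vector of length m with values `"sliding"` or
#'   `"fixed"`; a single value is recycled.  Default all sliding.
#' @param closed logical; does the last point connect back to the first?
#' @return An object of class `landmark_curve`: the points matrix with
#'   attributes `roles` and `closed`.
#' @examples
#' crv <- landmark_curve(cbind(0:4, 0, 0))
#' curve_tangents(crv)[1, ]
#' @export
landmark_curve <- function(points, roles = "sliding", closed = FALSE) {
  points <- as_points3(points, "curve points")
  m <- nrow(points)
  if (m < 3L) stop_input("a landmark curve needs at least 3 points")
  roles <- as.character(roles)
  if (length(roles) == 1L) roles <- rep(roles, m)
  if (length(roles) != m) stop_input("roles must have one entry per point")
  if (!all(roles %in% c("sliding", "fixed")))
    stop_input("roles must be 'sliding' or 'fixed'")
  seg <- points[-1, , drop = FALSE] - points[-m, , drop = FALSE]
  if (any(row_norms(seg) == 0))
    stop_input("consecutive curve points must be distinct")
  if (isTRUE(closed) && vnorm(points[m, ] - points[1, ]) == 0)
    stop_input("closed curve: first and last points must be distinct")
  structure(points, roles = roles, closed = isTRUE(closed),
            class = c("landmark_curve", "matrix", "array"))
}

#' @export
print.landmark_curve <- function(x, ...) {
  r <- attr(x, "roles")
  cat(sprintf("landmark_curve: %d points (%d sliding, %d fixed), %s\n",
              nrow(x), sum(r == "sliding"), sum(r == "fixed"),
              if (attr(x, "closed")) "closed" else "open"))
  invisible(x)
}

curve_points <- function(curve) {
  p <- unclass(curve)
  attributes(p) <- list(dim = dim(p))
  p
}

curve_roles <- function(curve) attr(curve, "roles")

# replace coordinates, keep roles/closed
set_curve_points <- function(curve, points) {
  stopifnot(nrow(points) == nrow(curve))
  structure(as_points3(points), roles = attr(curve, "roles"),
            closed = attr(curve, "closed"),
            class = c("landmark_curve", "matrix", "array"))
}

#' Unit tangent directions along a curve
#'
#' Central differences at interior points, one-sided differences at the
#' endpoints of an open curve, and wrap-around differences for a closed one.
#'
#' @param curve a [landmark_curve].
#' @return m x 3 matrix of unit-norm tangent vectors.
#' @export
curve_tangents <- function(curve) {
  tangents_impl(curve_points(curve), attr(curve, "closed"), strict = TRUE)
}

# strict = FALSE: tolerate coincident neighbours (can happen transiently
# while sliding re-projects points) by falling back to one-sided differences
tangents_impl <- function(p, closed, strict) {
  m <- nrow(p)
  nxt <- if (closed) c(2:m, 1L) else c(2:m, m)
  prv <- if (closed) c(m, 1:(m - 1L)) else c(1L, 1:(m - 1L))
  t_raw <- p[nxt, , drop = FALSE] - p[prv, , drop = FALSE]
  n <- row_norms(t_raw)
  if (any(n == 0)) {
    if (strict) stop_input("degenerate curve: zero-length tangent")
    for (i in which(n == 0)) {
      cand <- rbind(p[nxt[i], ] - p[i, ], p[i, ] - p[prv[i], ])
      cn <- row_norms(cand)
      if (any(cn > 0)) {
        t_raw[i, ] <- cand[which(cn > 0)[1], ]
      } else {
        j <- which(n > 0)
        t_raw[i, ] <- if (length(j)) t_raw[j[which.min(abs(j - i))], ]
                      else c(1, 0, 0)
      }
      n[i] <- vnorm(t_raw[i, ])
    }
  }
  t_raw / n
}

#' Project points onto a polyline
#'
#' Maps each query point to the globally nearest point on any segment of the
#' polyline traced by `polyline`'s points (closing segment included for
#' closed curves).
#'
#' @param points k x 3 matrix of query points.
#' @param polyline a [landmark_curve] (or m x 3 matrix) defining the polyline.
#' @return k x 3 matrix of projected points lying on the polyline.
#' @export
project_to_polyline <- function(points, polyline) {
  q <- as_points3(points, "query points")
  if (nrow(q) == 0L) return(q)
  p <- if (inherits(polyline, "landmark_curve")) curve_points(polyline)
       else as_points3(polyline, "polyline")
  closed <- inherits(polyline, "landmark_curve") && attr(polyline, "closed")
  m <- nrow(p)
  a <- p[-m, , drop = FALSE]
  b <- p[-1, , drop = FALSE]
  if (closed) { a <- rbind(a, p[m, ]); b <- rbind(b, p[1, ]) }
  ab <- b - a
  len2 <- rowSums(ab^2)
  out <- q
  for (i in seq_len(nrow(q))) {
    # parameter of orthogonal projection onto each segment, clamped to [0,1]
    t <- (ab %*% q[i, ] - rowSums(ab * a)) / len2
    t <- pmin(pmax(as.vector(t), 0), 1)
    cand <- a + ab * t
    d2 <- rowSums((cand - matrix(q[i, ], nrow(a), 3, byrow = TRUE))^2)
    out[i, ] <- cand[which.min(d2), ]
  }
  out
}

# distance from each point to the polyline (used in tests/reporting)
dist_to_polyline <- function(points, polyline) {
  proj <- project_to_polyline(points, polyline)
  row_norms(as_points3(points) - proj)
}
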
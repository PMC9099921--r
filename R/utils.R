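# internal helpers

#' @keywords internal
"_PACKAGE"

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_preserved_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_input <- function(...) stop(..., call. = FALSE)

# m x 3 numeric matrix coercion with finiteness check
as_points3 <- function(x, what = "points") {
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop_input(what, " must be an m x 3 matrix")
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop_input(what, " must contain only finite coordinates")
  x
}

vnorm <- function(x) sqrt(sum(x^2))

row_norms <- function(m) sqrt(rowSums(m^2))
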
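#' Subject configurations and population samples
#'
#' An `arch_configuration` holds one subject's jaw annotation: the
#' mucous-tooth borderline (MT-BL, the gingival margin, with fixed papilla
#' anchor landmarks) and the mucogingival borderline (MG-BL), plus optional
#' anatomical superimposition landmarks.
#'
#' @param subject_id character scalar, unique within a population.
#' @param jaw `"maxilla"` or `"mandible"`.
#' @param mtbl,mgbl [landmark_curve] objects for the two borderlines.
#' @param superimposition optional 4 x 3 matrix of labeled anatomical
#'   landmarks used for cross-modality rigid superimposition.
#' @return An object of class `arch_configuration`.
#' @export
arch_configuration <- function(subject_id, jaw = c("maxilla", "mandible"),
                               mtbl, mgbl, superimposition = NULL) {
  jaw <- match.arg(jaw)
  if (!inherits(mtbl, "landmark_curve") || !inherits(mgbl, "landmark_curve"))
    stop_input("mtbl and mgbl must be landmark_curve objects")
  if (!is.null(superimposition)) {
    superimposition <- as_points3(superimposition, "superimposition landmarks")
    if (nrow(superimposition) != 4L)
      stop_input("exactly 4 superimposition landmarks are required")
  }
  structure(list(subject_id = as.character(subject_id), jaw = jaw,
                 mtbl = mtbl, mgbl = mgbl,
                 superimposition = superimposition),
            class = "arch_configuration")
}

#' @export
print.arch_configuration <- function(x, ...) {
  cat(sprintf("arch_configuration '%s' (%s): MT-BL %d points, MG-BL %d points\n",
              x$subject_id, x$jaw, nrow(x$mtbl), nrow(x$mgbl)))
  invisible(x)
}

config_counts <- function(config) {
  c(n_mt = nrow(config$mtbl), n_mg = nrow(config$mgbl))
}

# stacked m_total x 3 coordinate matrix, MT block first
config_points <- function(config) {
  rbind(curve_points(config$mtbl), curve_points(config$mgbl))
}

set_config_points <- function(config, points) {
  n_mt <- nrow(config$mtbl)
  config$mtbl <- set_curve_points(config$mtbl, points[seq_len(n_mt), , drop = FALSE])
  config$mgbl <- set_curve_points(config$mgbl,
                                  points[(n_mt + 1):nrow(points), , drop = FALSE])
  config
}

# 3m vector, x1 y1 z1 x2 y2 z2 ...
config_vector <- function(config) as.vector(t(config_points(config)))

vector_to_points <- function(v) matrix(v, ncol = 3, byrow = TRUE)

# apply a rigid transform to every landmark of a configuration
transform_config <- function(config, transform) {
  config <- set_config_points(config, apply_transform(transform, config_points(config)))
  if (!is.null(config$superimposition))
    config$superimposition <- apply_transform(transform, config$superimposition)
  config
}

#' Bundle configurations into a population sample
#'
#' All members must share the jaw label and identical MT-BL/MG-BL landmark
#' counts (point-wise correspondence is assumed downstream), and subject ids
#' must be unique.
#'
#' @param configurations list of [arch_configuration] objects, n >= 2.
#' @param params optional record of generator parameters (provenance).
#' @return An object of class `population_sample`.
#' @export
population_sample <- function(configurations, params = NULL) {
  if (!is.list(configurations) || length(configurations) < 2L)
    stop_input("a population needs at least 2 configurations")
  ok <- vapply(configurations, inherits, logical(1), "arch_configuration")
  if (!all(ok)) stop_input("all members must be arch_configuration objects")
  jaws <- vapply(configurations, `[[`, character(1), "jaw")
  if (length(unique(jaws)) != 1L)
    stop_input("all members must share the same jaw label")
  ids <- vapply(configurations, `[[`, character(1), "subject_id")
  if (anyDuplicated(ids)) stop_input("subject ids must be unique")
  cts <- vapply(configurations, config_counts, numeric(2))
  if (any(cts[1, ] != cts[1, 1]) || any(cts[2, ] != cts[2, 1]))
    stop_input("all members must share identical MT-BL and MG-BL landmark counts")
  structure(list(configurations = configurations, jaw = jaws[1],
                 counts = c(n_mt = unname(cts[1, 1]), n_mg = unname(cts[2, 1])),
                 params = params),
            class = "population_sample")
}

#' @export
length.population_sample <- function(x) length(x$configurations)

#' @export
`[.population_sample` <- function(x, i) {
  population_sample(x$configurations[i], params = x$params)
}

#' @export
`[[.population_sample` <- function(x, i) x$configurations[[i]]

#' @export
print.population_sample <- function(x, ...) {
  cat(sprintf("population_sample: %d %s configurations, %d MT-BL + %d MG-BL landmarks\n",
              length(x), x$jaw, x$counts["n_mt"], x$counts["n_mg"]))
  invisible(x)
}

# landmark indices (rows of the stacked point matrix) of the MT-BL block
mtbl_indices <- function(pop) seq_len(pop$counts[["n_mt"]])

# coordinate-row indices in the 3m vectorization for a set of landmark indices
coord_rows <- function(landmark_indices) {
  as.vector(t(outer((landmark_indices - 1L) * 3L, 1:3, `+`)))
}
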
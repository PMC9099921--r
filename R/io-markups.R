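#' Slicer markups documents
#'
#' A `markups_document` bundles named landmark curves read from or destined
#' for 3D Slicer markups files.  Internally all coordinates use the RAS
#' (right-anterior-superior) convention in mm; LPS files have x and y
#' negated at the I/O boundary.
#'
#' @param curves named list of [landmark_curve] objects; conventional names
#'   are `"MT-BL"`, `"MG-BL"` and `"ANATOMICAL"` (superimposition points).
#' @param source_path optional provenance string.
#' @return An object of class `markups_document` (coordinates always RAS).
#' @export
markups_document <- function(curves, source_path = NULL) {
  if (!is.list(curves) || is.null(names(curves)) || any(names(curves) == ""))
    stop_input("curves must be a named list")
  ok <- vapply(curves, inherits, logical(1), "landmark_curve")
  if (!all(ok)) stop_input("all curves must be landmark_curve objects")
  structure(list(curves = curves, coordinate_system = "RAS",
                 source_path = source_path),
            class = "markups_document")
}

#' @export
print.markups_document <- function(x, ...) {
  cat(sprintf("markups_document: %d curve(s) [%s], RAS mm\n",
              length(x$curves), paste(names(x$curves), collapse = ", ")))
  invisible(x)
}

lps_flip <- function(points) {
  points[, 1] <- -points[, 1]
  points[, 2] <- -points[, 2]
  points
}

strip_index <- function(labels) sub("-[0-9]+$", "", labels)

#' Read 3D Slicer markups files
#'
#' Supports the legacy fiducial CSV (`.fcsv`) and the modern JSON
#' (`.mrk.json`) dialects.  The declared coordinate system is honoured
#' (LPS inputs are converted to RAS by negating x and y); when no
#' declaration is present the current Slicer default (LPS) is assumed with
#' a warning.  Point order is preserved; the point `description` field
#' carries the sliding/fixed role where present.
#'
#' @param path file path ending in `.fcsv` or `.mrk.json`.
#' @return A [markups_document] (coordinates in RAS mm).
#' @export
read_markups <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  if (grepl("\\.fcsv$", path, ignore.case = TRUE)) read_fcsv(path)
  else if (grepl("\\.mrk\\.json$", path, ignore.case = TRUE)) read_mrk_json(path)
  else stop_input("unknown markups format (expect .fcsv or .mrk.json): ", path)
}

read_fcsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(body) == 0L) stop_input("fcsv file has no points: ", path)
  cs_line <- grep("CoordinateSystem", header, value = TRUE)
  cs <- if (length(cs_line)) {
    val <- trimws(sub(".*=", "", cs_line[1]))
    if (val %in% c("0", "RAS")) "RAS"
    else if (val %in% c("1", "LPS")) "LPS"
    else stop_input("unknown coordinate system declaration: ", val)
  } else {
    warning("no CoordinateSystem declaration; assuming LPS (Slicer default)")
    "LPS"
  }
  fields <- strsplit(body, ",", fixed = TRUE)
  bad <- vapply(fields, length, integer(1)) < 12L
  if (any(bad)) stop_input("malformed fcsv row(s) in ", path)
  xyz <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3)))
  if (any(!is.finite(xyz))) stop_input("non-numeric coordinates in ", path)
  labels <- vapply(fields, `[`, character(1), 12L)
  roles <- vapply(fields, `[`, character(1), 13L)
  if (cs == "LPS") xyz <- lps_flip(xyz)
  assemble_document(xyz, labels, roles, closed = NULL, path)
}

read_mrk_json <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop_input("malformed markups JSON: ",
                                                 conditionMessage(e)))
  if (is.null(doc$markups)) stop_input("no markups array in ", path)
  curves <- list()
  for (mk in doc$markups) {
    cs <- mk$coordinateSystem
    if (is.null(cs)) {
      warning("no coordinateSystem declaration; assuming LPS (Slicer default)")
      cs <- "LPS"
    }
    if (!cs %in% c("RAS", "LPS"))
      stop_input("unknown coordinate system: ", cs)
    cps <- mk$controlPoints
    if (is.null(cps) || length(cps) == 0L) next
    xyz <- t(vapply(cps, function(p) as.numeric(unlist(p$position)), numeric(3)))
    if (cs == "LPS") xyz <- lps_flip(xyz)
    roles <- vapply(cps, function(p)
      if (is.null(p$description)) "" else as.character(p$description),
      character(1))
    roles <- ifelse(roles %in% c("sliding", "fixed"), roles, "sliding")
    nm <- if (!is.null(mk$name)) mk$name else {
      labs <- vapply(cps, function(p)
        if (is.null(p$label)) "curve" else as.character(p$label), character(1))
      unique(strip_index(labs))[1]
    }
    curves[[nm]] <- landmark_curve(xyz, roles = roles,
                                   closed = identical(mk$type, "ClosedCurve"))
  }
  if (length(curves) == 0L) stop_input("no control points found in ", path)
  markups_document(curves, source_path = path)
}

assemble_document <- function(xyz, labels, roles, closed, path) {
  roles <- ifelse(roles %in% c("sliding", "fixed"), roles, "sliding")
  groups <- strip_index(labels)
  curves <- list()
  for (g in unique(groups)) {
    idx <- which(groups == g)
    curves[[g]] <- landmark_curve(xyz[idx, , drop = FALSE],
                                  roles = roles[idx], closed = FALSE)
  }
  markups_document(curves, source_path = path)
}

#' Write a markups document
#'
#' Emits either dialect; files round-trip through [read_markups()] and load
#' in 3D Slicer.  Coordinates are converted from the internal RAS
#' convention to the declared output system.
#'
#' @param doc a [markups_document].
#' @param path output path; extension picks the dialect when
#'   `dialect = "auto"`.
#' @param dialect `"auto"`, `"fcsv"` or `"mrk.json"`.
#' @param coordinate_system `"LPS"` (Slicer default) or `"RAS"`.
#' @return `path`, invisibly.
#' @export
write_markups <- function(doc, path, dialect = c("auto", "fcsv", "mrk.json"),
                          coordinate_system = c("LPS", "RAS")) {
  dialect <- match.arg(dialect)
  coordinate_system <- match.arg(coordinate_system)
  if (!inherits(doc, "markups_document"))
    stop_input("doc must be a markups_document")
  if (any(vapply(doc$curves, nrow, integer(1)) == 0L))
    stop_input("cannot write empty curves")
  if (dialect == "auto")
    dialect <- if (grepl("\\.fcsv$", path, ignore.case = TRUE)) "fcsv"
               else "mrk.json"
  if (dialect == "fcsv") write_fcsv(doc, path, coordinate_system)
  else write_mrk_json(doc, path, coordinate_system)
  invisible(path)
}

fmt_num <- function(x) sprintf("%.17g", x)

write_fcsv <- function(doc, path, cs) {
  rows <- character(0)
  id <- 0L
  for (nm in names(doc$curves)) {
    crv <- doc$curves[[nm]]
    pts <- curve_points(crv)
    if (cs == "LPS") pts <- lps_flip(pts)
    roles <- curve_roles(crv)
    for (i in seq_len(nrow(pts))) {
      id <- id + 1L
      rows <- c(rows, sprintf(
        "vtkMRMLMarkupsFiducialNode_%d,%s,%s,%s,0,0,0,1,1,1,0,%s-%d,%s,",
        id, fmt_num(pts[i, 1]), fmt_num(pts[i, 2]), fmt_num(pts[i, 3]),
        nm, i, roles[i]))
    }
  }
  writeLines(c("# Markups fiducial file version = 4.11",
               sprintf("# CoordinateSystem = %s", cs),
               "# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID",
               rows), path)
}

write_mrk_json <- function(doc, path, cs) {
  markups <- lapply(names(doc$curves), function(nm) {
    crv <- doc$curves[[nm]]
    pts <- curve_points(crv)
    if (cs == "LPS") pts <- lps_flip(pts)
    roles <- curve_roles(crv)
    list(type = if (attr(crv, "closed")) "ClosedCurve" else "Curve",
         name = nm, coordinateSystem = cs,
         controlPoints = lapply(seq_len(nrow(pts)), function(i)
           list(id = as.character(i), label = sprintf("%s-%d", nm, i),
                description = roles[i],
                position = pts[i, ])))
  })
  jsonlite::write_json(
    list("@schema" = "https://raw.githubusercontent.com/slicer/slicer/master/Modules/Loadable/Markups/Resources/Schema/markups-schema-v1.0.3.json#",
         markups = markups),
    path, auto_unbox = TRUE, digits = NA)
}

#' Convert between markups documents and configurations
#'
#' `markups_to_configuration()` maps curves named `"MT-BL"`, `"MG-BL"` and
#' optionally `"ANATOMICAL"` (4 points) onto an [arch_configuration];
#' `configuration_to_markups()` is its inverse.
#'
#' @param doc a [markups_document].
#' @param subject_id,jaw configuration metadata.
#' @return An [arch_configuration] / a [markups_document].
#' @export
markups_to_configuration <- function(doc, subject_id, jaw) {
  if (is.null(doc$curves[["MT-BL"]]) || is.null(doc$curves[["MG-BL"]]))
    stop_input("document must contain curves labeled 'MT-BL' and 'MG-BL'")
  sup <- doc$curves[["ANATOMICAL"]]
  arch_configuration(subject_id, jaw,
                     mtbl = doc$curves[["MT-BL"]],
                     mgbl = doc$curves[["MG-BL"]],
                     superimposition = if (!is.null(sup)) curve_points(sup))
}

#' @rdname markups_to_configuration
#' @param config an [arch_configuration].
#' @export
configuration_to_markups <- function(config) {
  curves <- list("MT-BL" = config$mtbl, "MG-BL" = config$mgbl)
  if (!is.null(config$superimposition))
    curves[["ANATOMICAL"]] <- landmark_curve(config$superimposition,
                                             roles = "fixed")
  markups_document(curves)
}

#' Read and write whole populations
#'
#' One markups file per subject plus a JSON manifest recording jaw, subject
#' ids, file names and (for synthetic populations) the generator
#' parameters and master seed, so any run is reproducible from the manifest
#' alone.
#'
#' @param pop a [population_sample].
#' @param dir directory (created if needed).
#' @param dialect markups dialect, see [write_markups()].
#' @return `write_population()`: `dir` invisibly; `read_population()`: a
#'   [population_sample].
#' @export
write_population <- function(pop, dir, dialect = c("mrk.json", "fcsv")) {
  dialect <- match.arg(dialect)
  if (!inherits(pop, "population_sample"))
    stop_input("pop must be a population_sample")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- vapply(pop$configurations, `[[`, character(1), "subject_id")
  files <- paste0(ids, ".", dialect)
  for (i in seq_along(ids))
    write_markups(configuration_to_markups(pop[[i]]),
                  file.path(dir, files[i]), dialect = dialect)
  params <- pop$params
  manifest <- list(format = "archssm-population", version = 1L,
                   jaw = pop$jaw, subjects = ids, files = files,
                   params = if (!is.null(params)) unclass(params))
  jsonlite::write_json(manifest, file.path(dir, "population.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_population
#' @export
read_population <- function(dir) {
  mf_path <- file.path(dir, "population.json")
  if (!file.exists(mf_path)) stop_input("no population.json manifest in ", dir)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  if (!identical(mf$format, "archssm-population"))
    stop_input("not an archssm population manifest")
  configs <- lapply(seq_along(mf$subjects), function(i)
    markups_to_configuration(read_markups(file.path(dir, mf$files[i])),
                             subject_id = mf$subjects[i], jaw = mf$jaw))
  params <- if (!is.null(mf$params))
    structure(mf$params, class = "synthetic_params")
  population_sample(configs, params = params)
}
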
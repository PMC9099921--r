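#' Read vertices from a PLY file
#'
#' Minimal Polygon File Format reader for the two dialects intra-oral scan
#' exports use: ASCII and binary little-endian.  Returns the vertex
#' coordinates and, when present, per-vertex colors; faces are skipped
#' unless requested.
#'
#' @param path PLY file path.
#' @param faces also return the face index list (0-based indices as stored)?
#' @return A list with `vertices` (m x 3 double matrix), `colors`
#'   (m x 3 integer matrix of 0-255 triples, or `NULL`) and, if requested,
#'   `faces`.
#' @export
read_ply_vertices <- function(path, faces = FALSE) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!identical(trimws(magic), "ply")) stop_input("not a PLY file: ", path)
  fmt <- NULL
  elements <- list()   # list of list(name, count, props = data.frame)
  cur <- NULL
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0L) stop_input("malformed PLY header (no end_header)")
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0L || tok[1] == "comment") next
    if (tok[1] == "format") {
      fmt <- tok[2]
      if (!fmt %in% c("ascii", "binary_little_endian"))
        stop_input("unsupported PLY format: ", fmt)
    } else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]),
                  props = list())
    } else if (tok[1] == "property") {
      if (is.null(cur)) stop_input("property before element in PLY header")
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], type = "list", count_type = tok[3],
               item_type = tok[4])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3], type = tok[2])
      }
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    } else stop_input("unrecognized PLY header line: ", line)
  }
  if (is.null(fmt)) stop_input("PLY header missing format declaration")
  if (is.null(elements$vertex)) stop_input("PLY file has no vertex element")
  data <- if (fmt == "ascii") read_ply_ascii(con, elements)
          else read_ply_binary(con, elements)
  v <- data$vertex
  need <- c("x", "y", "z")
  if (!all(need %in% names(v))) stop_input("vertex element lacks x/y/z")
  vertices <- cbind(x = v$x, y = v$y, z = v$z)
  colors <- if (all(c("red", "green", "blue") %in% names(v)))
    cbind(red = as.integer(v$red), green = as.integer(v$green),
          blue = as.integer(v$blue))
  out <- list(vertices = vertices, colors = colors)
  if (faces) out$faces <- data$face_list
  out
}

ply_type_info <- function(type) {
  switch(type,
    char = , int8 = list(what = integer(), size = 1L, signed = TRUE),
    uchar = , uint8 = list(what = integer(), size = 1L, signed = FALSE),
    short = , int16 = list(what = integer(), size = 2L, signed = TRUE),
    ushort = , uint16 = list(what = integer(), size = 2L, signed = FALSE),
    int = , int32 = list(what = integer(), size = 4L, signed = TRUE),
    uint = , uint32 = list(what = integer(), size = 4L, signed = TRUE),
    float = , float32 = list(what = numeric(), size = 4L, signed = TRUE),
    double = , float64 = list(what = numeric(), size = 8L, signed = TRUE),
    stop_input("unsupported PLY property type: ", type))
}

read_ply_ascii <- function(con, elements) {
  txt <- readLines(con)
  txt <- txt[nzchar(trimws(txt))]
  pos <- 1L
  out <- list()
  for (el in elements) {
    has_list <- any(vapply(el$props, function(p) p$type == "list", logical(1)))
    rows <- txt[pos:(pos + el$count - 1L)]
    pos <- pos + el$count
    if (!has_list) {
      m <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
      cols <- vapply(el$props, `[[`, character(1), "name")
      out[[el$name]] <- stats::setNames(as.data.frame(m), cols)
    } else if (el$name == "face") {
      out$face_list <- lapply(strsplit(trimws(rows), "\\s+"), function(tk)
        as.integer(tk[-1]))
    }
  }
  out
}

read_ply_binary <- function(con, elements) {
  out <- list()
  for (el in elements) {
    scalar <- !any(vapply(el$props, function(p) p$type == "list", logical(1)))
    if (scalar) {
      cols <- lapply(el$props, function(p) vector(mode =
        if (is.integer(ply_type_info(p$type)$what)) "integer" else "numeric",
        length = el$count))
      names(cols) <- vapply(el$props, `[[`, character(1), "name")
      # fixed record: read property-by-property per vertex
      for (i in seq_len(el$count)) {
        for (j in seq_along(el$props)) {
          ti <- ply_type_info(el$props[[j]]$type)
          cols[[j]][i] <- readBin(con, what = ti$what, n = 1, size = ti$size,
                                  endian = "little", signed = ti$signed)
        }
      }
      out[[el$name]] <- as.data.frame(cols)
    } else {
      flist <- vector("list", el$count)
      for (i in seq_len(el$count)) {
        for (p in el$props) {
          if (p$type == "list") {
            ci <- ply_type_info(p$count_type)
            k <- readBin(con, what = ci$what, n = 1, size = ci$size,
                         endian = "little", signed = ci$signed)
            ii <- ply_type_info(p$item_type)
            vals <- readBin(con, what = ii$what, n = k, size = ii$size,
                            endian = "little", signed = ii$signed)
            if (el$name == "face" && p$name %in%
                  c("vertex_indices", "vertex_index"))
              flist[[i]] <- as.integer(vals)
          } else {
            ti <- ply_type_info(p$type)
            readBin(con, what = ti$what, n = 1, size = ti$size,
                    endian = "little", signed = ti$signed)
          }
        }
      }
      if (el$name == "face") out$face_list <- flist
    }
  }
  out
}

#' Snap points onto a mesh
#'
#' Replaces each point by its nearest mesh vertex — a cosmetic step that
#' drapes a predicted borderline onto the digitized cast surface.
#'
#' @param points k x 3 matrix (e.g. predicted MG-BL landmarks).
#' @param mesh_vertices m x 3 matrix of mesh vertex coordinates.
#' @return k x 3 matrix of snapped points with attribute `displacement`
#'   (distance moved per point, mm).
#' @export
snap_to_mesh <- function(points, mesh_vertices) {
  p <- as_points3(points, "points")
  v <- as_points3(mesh_vertices, "mesh vertices")
  if (nrow(v) == 0L) stop_input("mesh has no vertices")
  if (nrow(p) == 0L) {
    attr(p, "displacement") <- numeric(0)
    return(p)
  }
  d2 <- outer(rowSums(p^2), rep(1, nrow(v))) +
    outer(rep(1, nrow(p)), rowSums(v^2)) - 2 * tcrossprod(p, v)
  idx <- apply(d2, 1, which.min)
  out <- v[idx, , drop = FALSE]
  attr(out, "displacement") <- row_norms(out - p)
  out
}
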
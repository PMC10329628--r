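# Plain-text mesh and point-cloud I/O (ASCII STL / OBJ / PLY / XYZ) plus a
# VTK-legacy writer for hex models, for visual inspection in ParaView.

#' Read a triangulated surface mesh (ASCII STL, OBJ or PLY)
#'
#' @param path file path; format chosen from the extension.
#' @param validate check watertightness (default TRUE).
#' @return a \code{surface_mesh}.
#' @export
read_surface_mesh <- function(path, validate = TRUE) {
  ext <- tolower(tools::file_ext(path))
  vf <- switch(ext,
    stl = read_stl_ascii(path),
    obj = read_obj(path),
    ply = read_ply(path),
    stop("unsupported mesh format: ", ext)
  )
  surface_mesh(vf$vertices, vf$faces, validate = validate)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  verts <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                                 function(x) as.numeric(x[1:3])))
  faces <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fl)), "\\s+"),
                                 function(x) as.integer(sub("/.*", "", x[1:3]))))
  list(vertices = verts, faces = faces)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  coords <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                  function(x) as.numeric(x[2:4])))
  if (nrow(coords) %% 3 != 0) stop("malformed STL")
  key <- apply(coords, 1, function(r) paste(signif(r, 12), collapse = "_"))
  uid <- match(key, unique(key))
  verts <- coords[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  end <- match("end_header", trimws(lines))
  if (is.na(end)) stop("not an ASCII PLY file")
  header <- lines[seq_len(end)]
  if (!any(grepl("^format\\s+ascii", header))) stop("only ASCII PLY supported")
  nv <- as.integer(sub(".*vertex\\s+", "", grep("element vertex", header, value = TRUE)[1]))
  nf_line <- grep("element face", header, value = TRUE)
  nf <- if (length(nf_line)) as.integer(sub(".*face\\s+", "", nf_line[1])) else 0L
  body <- lines[(end + 1):length(lines)]
  verts <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                                 function(x) as.numeric(x[1:3])))
  faces <- NULL
  if (nf > 0) {
    faces <- do.call(rbind, lapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"),
                                   function(x) as.integer(x[2:4]) + 1L))
  }
  list(vertices = verts, faces = faces)
}

#' Write a surface mesh or point cloud as ASCII PLY
#'
#' @param x a \code{surface_mesh}, or a numeric matrix (n x 3) of points.
#' @param path output file path.
#' @export
write_ply <- function(x, path) {
  if (inherits(x, "surface_mesh")) {
    v <- x$vertices; f <- x$faces
  } else {
    v <- as.matrix(x); f <- NULL
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", if (is.null(f)) 0L else nrow(f)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(apply(v, 1, paste, collapse = " "), con)
  if (!is.null(f))
    writeLines(paste(3, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}

#' Read a point cloud from PLY or XYZ
#' @param path file path.
#' @return numeric matrix (n x 3) of positions in meters.
#' @export
read_point_cloud <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") return(read_ply(path)$vertices)
  if (ext %in% c("xyz", "txt", "csv")) {
    m <- as.matrix(utils::read.table(path, header = FALSE,
                                     sep = if (ext == "csv") "," else ""))
    return(m[, 1:3, drop = FALSE])
  }
  stop("unsupported point-cloud format: ", ext)
}

#' Write a hexahedral model as a VTK-legacy unstructured grid
#'
#' @param model a \code{hex_model}.
#' @param path output .vtk path.
#' @param displacements optional (n_nodes x 3) displacement field written as
#'   point data.
#' @export
write_vtk_hex <- function(model, path, displacements = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(model$nodes); m <- nrow(model$hexes)
  writeLines(c("# vtk DataFile Version 3.0", "hexahedral model", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(apply(model$nodes, 1, paste, collapse = " "), con)
  writeLines(sprintf("CELLS %d %d", m, m * 9L), con)
  writeLines(apply(model$hexes - 1L, 1, function(r) paste(c(8L, r), collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("12", m), con)  # VTK_HEXAHEDRON
  if (!is.null(displacements)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    writeLines("VECTORS displacement double", con)
    writeLines(apply(displacements, 1, paste, collapse = " "), con)
  }
  invisible(path)
}
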
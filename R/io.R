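#' Read a triangle mesh from STL, PLY or OBJ
#'
#' Supported formats: STL (binary and ASCII, auto-detected), ASCII PLY
#' (xyz + triangular/polygonal faces, polygons fan-triangulated) and OBJ
#' (geometry only; `v`/`f` records, texture/normal indices ignored,
#' polygons fan-triangulated). The loaded mesh is cleaned: duplicate
#' vertices merged within 1e-6 mm, degenerate faces dropped.
#'
#' @param path file path.
#' @param format `"stl"`, `"ply"` or `"obj"`; default inferred from the
#'   file extension.
#' @return A [triangle_mesh()].
#' @export
load_mesh <- function(path, format = tolower(tools::file_ext(path))) {
  if (!file.exists(path)) stop("mesh file not found: ", path, call. = FALSE)
  format <- match.arg(format, c("stl", "ply", "obj"))
  raw <- switch(format,
    stl = read_stl(path),
    ply = read_ply(path),
    obj = read_obj(path)
  )
  if (nrow(raw$vertices) == 0L || nrow(raw$faces) == 0L) {
    stop("mesh file '", path, "' contains no geometry", call. = FALSE)
  }
  mesh <- triangle_mesh(raw$vertices, raw$faces,
                        name = tools::file_path_sans_ext(basename(path)))
  message(sprintf("loaded '%s': %d vertices, %d faces", basename(path),
                  nrow(mesh$vertices), nrow(mesh$faces)))
  mesh
}

#' Write a triangle mesh to STL, PLY or OBJ
#'
#' ASCII variants are written with 9 significant digits, so a save/load
#' round trip preserves coordinates within 1e-6 mm. Binary STL
#' (`format = "stl_binary"`) stores float32 and round-trips to roughly
#' 1e-4 mm at skull-scale coordinates.
#'
#' @param mesh a `triangle_mesh`.
#' @param path output path.
#' @param format `"stl"` (ASCII), `"stl_binary"`, `"ply"` or `"obj"`;
#'   default inferred from the extension (STL defaults to ASCII).
#' @return Invisibly, `path`.
#' @export
save_mesh <- function(mesh, path,
                      format = tolower(tools::file_ext(path))) {
  if (!inherits(mesh, "triangle_mesh")) {
    stop("not a triangle_mesh", call. = FALSE)
  }
  if (nrow(mesh$faces) == 0L) {
    stop("refusing to write a mesh with no faces", call. = FALSE)
  }
  format <- match.arg(format, c("stl", "stl_binary", "ply", "obj"))
  switch(format,
    stl = write_stl_ascii(mesh, path),
    stl_binary = write_stl_binary(mesh, path),
    ply = write_ply(mesh, path),
    obj = write_obj(mesh, path)
  )
  invisible(path)
}

# ---- STL ----

read_stl <- function(path) {
  size <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = min(84, size))
  is_binary <- FALSE
  if (size >= 84) {
    ntri <- readBin(head[81:84], "integer", size = 4, endian = "little")
    if (!is.na(ntri) && ntri >= 0 && size == 84 + 50 * as.numeric(ntri)) {
      is_binary <- TRUE
    }
  }
  if (is_binary) {
    seek(con, 84)
    body <- readBin(con, "raw", n = size - 84)
    ntri <- readBin(head[81:84], "integer", size = 4, endian = "little")
    # each record: 12 floats (48 bytes) + uint16 attribute
    rec <- matrix(body, nrow = 50)
    coords <- readBin(as.vector(rec[1:48, ]), "double", size = 4,
                      n = 12 * ntri, endian = "little")
    cm <- matrix(coords, ncol = 12, byrow = TRUE)
    verts <- rbind(cm[, 4:6, drop = FALSE], cm[, 7:9, drop = FALSE],
                   cm[, 10:12, drop = FALSE])
    ord <- as.vector(t(matrix(seq_len(3 * ntri), ncol = 3)))
    verts <- verts[ord, , drop = FALSE]
  } else {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (length(vl) == 0L || length(vl) %% 3 != 0L) {
      stop("malformed ASCII STL: ", path, call. = FALSE)
    }
    verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                   function(x) as.numeric(x[2:4])))
  }
  n <- nrow(verts)
  list(vertices = verts, faces = matrix(seq_len(n), ncol = 3, byrow = TRUE))
}

write_stl_ascii <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  nrm <- face_normals(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", mesh$name), con)
  fmt <- paste0(" facet normal %.9g %.9g %.9g\n  outer loop\n",
                "   vertex %.9g %.9g %.9g\n   vertex %.9g %.9g %.9g\n",
                "   vertex %.9g %.9g %.9g\n  endloop\n endfacet")
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  writeLines(sprintf(fmt, nrm[, 1], nrm[, 2], nrm[, 3],
                     a[, 1], a[, 2], a[, 3], b[, 1], b[, 2], b[, 3],
                     c[, 1], c[, 2], c[, 3]), con)
  writeLines(sprintf("endsolid %s", mesh$name), con)
}

write_stl_binary <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  nrm <- face_normals(mesh)
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(formatC(mesh$name, width = -80))
  writeBin(header[1:80], con)
  writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
  tri <- cbind(nrm, v[f[, 1], , drop = FALSE], v[f[, 2], , drop = FALSE],
               v[f[, 3], , drop = FALSE])
  for (i in seq_len(nrow(f))) {
    writeBin(as.numeric(tri[i, ]), con, size = 4, endian = "little")
    writeBin(as.raw(c(0, 0)), con)
  }
}

# ---- PLY (ASCII) ----

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || trimws(lines[1]) != "ply") {
    stop("not a PLY file: ", path, call. = FALSE)
  }
  end <- match("end_header", trimws(lines))
  if (is.na(end)) stop("PLY header not terminated: ", path, call. = FALSE)
  header <- trimws(lines[seq_len(end)])
  if (any(grepl("^format\\s+binary", header))) {
    stop("binary PLY is not supported; use ASCII PLY", call. = FALSE)
  }
  elems <- grep("^element\\s", header, value = TRUE)
  counts <- stats::setNames(
    as.integer(vapply(strsplit(elems, "\\s+"), `[`, "", 3)),
    vapply(strsplit(elems, "\\s+"), `[`, "", 2)
  )
  nv <- counts[["vertex"]]
  nf <- counts[["face"]]
  body <- trimws(lines[(end + 1):length(lines)])
  body <- body[nzchar(body)]
  vl <- strsplit(body[seq_len(nv)], "\\s+")
  verts <- do.call(rbind, lapply(vl, function(x) as.numeric(x[1:3])))
  fl <- strsplit(body[nv + seq_len(nf)], "\\s+")
  faces <- do.call(rbind, lapply(fl, function(x) {
    k <- as.integer(x[1])
    idx <- as.integer(x[2:(1 + k)]) + 1L      # PLY is 0-based
    if (k == 3L) matrix(idx, 1, 3)
    else cbind(idx[1], idx[2:(k - 1)], idx[3:k])  # fan
  }))
  list(vertices = verts, faces = faces)
}

write_ply <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("comment %s", mesh$name),
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
             con)
}

# ---- OBJ ----

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                 function(x) as.numeric(x[2:4])))
  faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(x) {
    idx <- as.integer(sub("/.*$", "", x[-1]))   # drop /vt/vn refs
    k <- length(idx)
    if (k < 3L) stop("OBJ face with fewer than 3 vertices", call. = FALSE)
    if (k == 3L) matrix(idx, 1, 3)
    else cbind(idx[1], idx[2:(k - 1)], idx[3:k])
  }))
  list(vertices = verts, faces = faces)
}

write_obj <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("o %s", mesh$name), con)
  writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
}

# ---- Contours ----

#' Read and write surface contours
#'
#' Two on-disk forms: a CSV with header `x,y,z` plus a JSON sidecar
#' (`<stem>.json`) holding `{closed, name, line_width_mm}`, or a single
#' `.json` file holding points and metadata together. Consecutive duplicate
#' points are removed on load.
#'
#' @param path `.csv` or `.json` path.
#' @return A [surface_contour()].
#' @export
load_contour <- function(path) {
  if (!file.exists(path)) {
    stop("contour file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::fromJSON(path)
    pts <- matrix(unlist(obj$points), ncol = 3, byrow = is.list(obj$points))
    if (!is.list(obj$points)) pts <- as.matrix(obj$points)
    surface_contour(pts, closed = isTRUE(obj$closed),
                    name = if (!is.null(obj$name)) obj$name else "contour",
                    line_width_mm = if (!is.null(obj$line_width_mm))
                      obj$line_width_mm else NA_real_)
  } else {
    df <- utils::read.csv(path)
    if (!all(c("x", "y", "z") %in% names(df))) {
      stop("contour CSV needs columns x,y,z: ", path, call. = FALSE)
    }
    sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
    meta <- if (file.exists(sidecar)) jsonlite::fromJSON(sidecar) else list()
    surface_contour(
      as.matrix(df[, c("x", "y", "z")]),
      closed = isTRUE(meta$closed),
      name = if (!is.null(meta$name)) meta$name
             else tools::file_path_sans_ext(basename(path)),
      line_width_mm = if (!is.null(meta$line_width_mm)) meta$line_width_mm
                      else NA_real_
    )
  }
}

#' @rdname load_contour
#' @param contour a `surface_contour`.
#' @export
save_contour <- function(contour, path) {
  ext <- tolower(tools::file_ext(path))
  meta <- list(closed = contour$closed, name = contour$name,
               line_width_mm = contour$line_width_mm)
  if (is.na(meta$line_width_mm)) meta$line_width_mm <- NULL
  if (ext == "json") {
    jsonlite::write_json(c(list(points = contour$points), meta), path,
                         auto_unbox = TRUE, digits = NA)
  } else {
    df <- as.data.frame(contour$points)
    names(df) <- c("x", "y", "z")
    utils::write.csv(df, path, row.names = FALSE)
    jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(path),
                                      ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
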
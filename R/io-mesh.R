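# Mesh file I/O: PLY (ascii / binary little-endian), STL (ascii / binary)
# and OBJ.  PLY export can carry per-vertex RGBA colour taken from a
# material table (alpha encodes 1 - transparency).  STL stores a triangle
# soup, so reading it merges exactly coincident vertices.

mesh_format_of <- function(path, format = "auto") {
  if (format != "auto") return(format)
  switch(tolower(tools::file_ext(path)),
         ply = "ply", stl = "stl", obj = "obj",
         stop("cannot infer mesh format from path: ", path, call. = FALSE))
}

#' Read a triangle mesh (PLY, STL or OBJ)
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"ply"`, `"stl"` or `"obj"`.
#' @return a [triangle_mesh].
#' @export
read_mesh <- function(path, format = "auto") {
  format <- mesh_format_of(path, format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format,
         ply = read_ply(path),
         stl = read_stl(path),
         obj = read_obj(path))
}

#' Write a triangle mesh (PLY, STL or OBJ)
#'
#' @param mesh a [triangle_mesh].
#' @param path output path.
#' @param format `"auto"`, `"ply"`, `"stl"` or `"obj"`.
#' @param materials optional [material_table]; when given, PLY output
#'   carries per-vertex RGBA from the vertex labels (alpha =
#'   `a * (1 - transparency)`).
#' @param binary write the binary dialect (PLY binary_little_endian /
#'   binary STL); ignored for OBJ.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = "auto", materials = NULL,
                       binary = FALSE) {
  format <- mesh_format_of(path, format)
  switch(format,
         ply = write_ply(mesh, path, materials, binary),
         stl = write_stl(mesh, path, binary),
         obj = write_obj(mesh, path))
  invisible(path)
}

vertex_colors_of <- function(mesh, materials) {
  n <- nrow(mesh$vertices)
  cols <- matrix(200L, n, 4)
  for (i in seq_len(nrow(materials))) {
    sel <- mesh$vertex_labels == materials$label[i]
    if (!any(sel)) next
    rgba <- c(materials$r[i], materials$g[i], materials$b[i],
              materials$a[i] * (1 - materials$transparency[i]))
    cols[sel, ] <- matrix(as.integer(round(rgba * 255)), sum(sel), 4,
                          byrow = TRUE)
  }
  cols
}

## ---- PLY -----------------------------------------------------------------

write_ply <- function(mesh, path, materials = NULL, binary = FALSE) {
  n <- nrow(mesh$vertices); m <- nrow(mesh$triangles)
  has_col <- !is.null(materials)
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0"
           else "format ascii 1.0",
           "comment produced by otodrill",
           sprintf("element vertex %d", n),
           "property float x", "property float y", "property float z",
           "property float nx", "property float ny", "property float nz",
           if (has_col) c("property uchar red", "property uchar green",
                          "property uchar blue", "property uchar alpha"),
           sprintf("element face %d", m),
           "property list uchar int vertex_indices",
           "end_header")
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con, sep = "\n")
  cols <- if (has_col) vertex_colors_of(mesh, materials)
  VN <- mesh$vertex_normals %||% vertex_normals_of(mesh)
  if (binary) {
    for (i in seq_len(n)) {
      writeBin(as.numeric(c(mesh$vertices[i, ], VN[i, ])), con, size = 4,
               endian = "little")
      if (has_col) writeBin(as.raw(cols[i, ]), con)
    }
    for (i in seq_len(m)) {
      writeBin(as.raw(3), con)
      writeBin(as.integer(mesh$triangles[i, ] - 1L), con, size = 4,
               endian = "little")
    }
  } else {
    vl <- apply(cbind(mesh$vertices, VN), 1, function(r)
      paste(sprintf("%.9g", r), collapse = " "))
    if (has_col) vl <- paste(vl, apply(cols, 1, paste, collapse = " "))
    writeLines(vl, con, sep = "\n")
    writeLines(paste(3L, mesh$triangles[, 1] - 1L, mesh$triangles[, 2] - 1L,
                     mesh$triangles[, 3] - 1L), con, sep = "\n")
  }
  invisible(path)
}

ply_prop_size <- function(type) {
  switch(type, char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
         short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
         int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
         float = 4L, float32 = 4L, double = 8L, float64 = 8L,
         stop("unsupported PLY property type: ", type, call. = FALSE))
}

ply_read_scalar <- function(con, type) {
  sz <- ply_prop_size(type)
  if (type %in% c("float", "float32", "double", "float64"))
    readBin(con, "double", 1, sz, endian = "little")
  else
    readBin(con, "integer", 1, sz,
            signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")),
            endian = "little")
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  if (readLines(con, n = 1L) != "ply")
    stop("not a PLY file: ", path, call. = FALSE)
  fmt <- NULL; elements <- list(); cur <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("PLY header truncated", call. = FALSE)
    tok <- strsplit(trimws(line), "[ \t]+")[[1]]
    if (tok[1] == "comment") next
    if (tok[1] == "format") { fmt <- tok[2]; next }
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]),
                  props = list())
      next
    }
    if (tok[1] == "property") {
      if (tok[2] == "list")
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], list = TRUE, count_type = tok[3],
               item_type = tok[4])
      else
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3], list = FALSE, type = tok[2])
      next
    }
    if (tok[1] == "end_header") { elements[[cur$name]] <- cur; break }
  }
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", fmt, call. = FALSE)
  read_elem_ascii <- function(elem, lines) {
    vals <- list(); li <- 1L
    for (r in seq_len(elem$count)) {
      tok <- strsplit(trimws(lines[li]), "[ \t]+")[[1]]; li <- li + 1L
      ti <- 1L; row <- list()
      for (p in elem$props) {
        if (p$list) {
          cnt <- as.integer(tok[ti]); ti <- ti + 1L
          row[[p$name]] <- as.numeric(tok[ti:(ti + cnt - 1L)])
          ti <- ti + cnt
        } else {
          row[[p$name]] <- as.numeric(tok[ti]); ti <- ti + 1L
        }
      }
      vals[[r]] <- row
    }
    vals
  }
  read_elem_binary <- function(elem) {
    vals <- vector("list", elem$count)
    for (r in seq_len(elem$count)) {
      row <- list()
      for (p in elem$props) {
        if (p$list) {
          cnt <- ply_read_scalar(con, p$count_type)
          row[[p$name]] <- vapply(seq_len(cnt), function(i)
            ply_read_scalar(con, p$item_type), numeric(1))
        } else row[[p$name]] <- ply_read_scalar(con, p$type)
      }
      vals[[r]] <- row
    }
    vals
  }
  data <- list()
  if (fmt == "ascii") {
    lines <- readLines(con)
    off <- 0L
    for (elem in elements) {
      data[[elem$name]] <- read_elem_ascii(elem,
                                           lines[(off + 1L):length(lines)])
      off <- off + elem$count
    }
  } else {
    for (elem in elements) data[[elem$name]] <- read_elem_binary(elem)
  }
  vrows <- data[["vertex"]]
  V <- t(vapply(vrows, function(r) c(r$x, r$y, r$z), numeric(3)))
  frows <- data[["face"]] %||% list()
  tris <- list()
  for (r in frows) {
    idx <- r$vertex_indices %||% r$vertex_index
    for (i in seq_len(length(idx) - 2L))
      tris[[length(tris) + 1L]] <- idx[c(1L, i + 1L, i + 2L)] + 1L
  }
  TRm <- if (length(tris)) do.call(rbind, tris) else
    matrix(integer(0), ncol = 3)
  triangle_mesh(V, TRm)
}

## ---- STL -----------------------------------------------------------------

write_stl <- function(mesh, path, binary = FALSE) {
  V <- mesh$vertices; TR <- mesh$triangles
  fc <- if (nrow(TR)) face_cross(mesh) else matrix(numeric(0), ncol = 3)
  fn <- fc / pmax(sqrt(rowSums(fc^2)), 1e-300)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con), add = TRUE)
    writeBin(raw(80), con)
    writeBin(nrow(TR), con, size = 4, endian = "little")
    for (i in seq_len(nrow(TR))) {
      writeBin(as.numeric(c(fn[i, ], V[TR[i, 1], ], V[TR[i, 2], ],
                            V[TR[i, 3], ])), con, size = 4,
               endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con), add = TRUE)
    writeLines("solid otodrill", con)
    for (i in seq_len(nrow(TR))) {
      writeLines(c(sprintf("  facet normal %.9g %.9g %.9g",
                           fn[i, 1], fn[i, 2], fn[i, 3]),
                   "    outer loop",
                   sprintf("      vertex %.9g %.9g %.9g",
                           V[TR[i, 1:3], 1], V[TR[i, 1:3], 2],
                           V[TR[i, 1:3], 3]),
                   "    endloop", "  endfacet"), con)
    }
    writeLines("endsolid otodrill", con)
  }
  invisible(path)
}

soup_to_mesh <- function(P) {
  key <- paste(P[, 1], P[, 2], P[, 3])
  uid <- !duplicated(key)
  V <- P[uid, , drop = FALSE]
  idx <- match(key, key[uid])
  triangle_mesh(V, matrix(idx, ncol = 3, byrow = TRUE))
}

read_stl <- function(path) {
  head <- readBin(path, "raw", 512)
  is_ascii <- identical(rawToChar(head[1:5]), "solid") &&
    grepl("facet", rawToChar(head[head != as.raw(0)]), fixed = TRUE)
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^[ \t]*vertex", lines, value = TRUE)
    P <- do.call(rbind, lapply(strsplit(trimws(vl), "[ \t]+"), function(t)
      as.numeric(t[2:4])))
  } else {
    con <- file(path, "rb")
    on.exit(close(con), add = TRUE)
    readBin(con, "raw", 80)
    nt <- readBin(con, "integer", 1, 4, endian = "little")
    P <- matrix(0, nt * 3L, 3)
    for (i in seq_len(nt)) {
      rec <- readBin(con, "double", 12, 4, endian = "little")
      readBin(con, "raw", 2)
      P[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    }
  }
  if (is.null(P) || !nrow(P)) return(empty_mesh())
  soup_to_mesh(P)
}

## ---- OBJ -----------------------------------------------------------------

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines("# produced by otodrill", con)
  V <- mesh$vertices
  VN <- mesh$vertex_normals %||% vertex_normals_of(mesh)
  writeLines(sprintf("v %.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]), con)
  writeLines(sprintf("vn %.9g %.9g %.9g", VN[, 1], VN[, 2], VN[, 3]), con)
  TR <- mesh$triangles
  writeLines(sprintf("f %d//%d %d//%d %d//%d",
                     TR[, 1], TR[, 1], TR[, 2], TR[, 2], TR[, 3], TR[, 3]),
             con)
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v ", lines, value = TRUE)
  V <- do.call(rbind, lapply(strsplit(trimws(vl), "[ \t]+"), function(t)
    as.numeric(t[2:4])))
  fl <- grep("^f ", lines, value = TRUE)
  tris <- list()
  for (f in fl) {
    tok <- strsplit(trimws(f), "[ \t]+")[[1]][-1]
    idx <- as.integer(vapply(strsplit(tok, "/"), `[`, "", 1))
    for (i in seq_len(length(idx) - 2L))
      tris[[length(tris) + 1L]] <- idx[c(1L, i + 1L, i + 2L)]
  }
  if (is.null(V)) return(empty_mesh())
  TRm <- if (length(tris)) do.call(rbind, tris) else
    matrix(integer(0), ncol = 3)
  triangle_mesh(V, TRm)
}
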
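# Volume file I/O: NRRD (raw/gzip encodings), NIfTI-1 (.nii / .nii.gz) and
# raw little-endian payload + JSON sidecar.  NRRD and NIfTI carry a single
# scalar channel, so a labeled volume writes its label grid to a companion
# "<base>-labels.<ext>" file which read_volume picks up automatically; the
# raw+JSON dialect stores both arrays behind one sidecar.  All payloads are
# little-endian; density is float64 and labels int32 so round-trips are
# bit-exact.

volume_format_of <- function(path, format = "auto") {
  if (format != "auto") return(format)
  p <- tolower(path)
  if (grepl("\\.(nrrd|nhdr)$", p)) return("nrrd")
  if (grepl("\\.nii(\\.gz)?$", p)) return("nifti")
  if (grepl("\\.json$", p)) return("rawjson")
  stop("cannot infer volume format from path: ", path, call. = FALSE)
}

labels_companion_path <- function(path) {
  sub("(\\.(nrrd|nhdr)|\\.nii(\\.gz)?)$", "-labels\\1", path,
      ignore.case = TRUE)
}

#' Read a volume file
#'
#' Supports NRRD (raw and gzip encodings), NIfTI-1 (optionally gzipped)
#' and a raw little-endian payload described by a JSON sidecar.  Voxel
#' spacing must be present in the header/sidecar; a companion
#' `<base>-labels.<ext>` file, when present, populates the label grid.
#'
#' @param path file path (for `rawjson`, the `.json` sidecar).
#' @param format `"auto"` (by extension), `"nrrd"`, `"nifti"` or
#'   `"rawjson"`.
#' @return a [labeled_volume].
#' @export
read_volume <- function(path, format = "auto") {
  format <- volume_format_of(path, format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  v <- switch(format,
              nrrd = read_nrrd(path),
              nifti = read_nifti(path),
              rawjson = read_rawjson(path),
              stop("unknown volume format: ", format, call. = FALSE))
  if (format %in% c("nrrd", "nifti")) {
    lp <- labels_companion_path(path)
    if (!identical(lp, path) && file.exists(lp)) {
      lv <- switch(format, nrrd = read_nrrd(lp), nifti = read_nifti(lp))
      if (!identical(as.integer(lv$dims), v$dims))
        stop("label companion dims do not match density volume",
             call. = FALSE)
      v$label <- array(as.integer(round(lv$density)), v$dims)
    }
  }
  validate_volume(v)
  v
}

#' Write a volume file
#'
#' Inverse of [read_volume]; `read_volume(write_volume(v, path))` round
#' trips density, label, spacing and origin bit-identically in every
#' supported dialect.  For NRRD/NIfTI a nonzero label grid is written to a
#' companion `<base>-labels.<ext>` file.
#'
#' @param volume a [labeled_volume].
#' @param path output path (for `rawjson`, the `.json` sidecar path).
#' @param format `"auto"`, `"nrrd"`, `"nifti"` or `"rawjson"`.
#' @param gzip compress the payload (NRRD gzip encoding; ignored for NIfTI
#'   where compression follows the `.gz` extension).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, format = "auto", gzip = FALSE) {
  validate_volume(volume)
  format <- volume_format_of(path, format)
  switch(format,
         nrrd = {
           write_nrrd(volume$density, "double", volume, path, gzip)
           if (any(volume$label != 0L))
             write_nrrd(volume$label, "int", volume,
                        labels_companion_path(path), gzip)
         },
         nifti = {
           write_nifti(volume$density, 64L, volume, path)
           if (any(volume$label != 0L))
             write_nifti(volume$label, 8L, volume,
                         labels_companion_path(path))
         },
         rawjson = write_rawjson(volume, path),
         stop("unknown volume format: ", format, call. = FALSE))
  invisible(path)
}

## ---- NRRD ----------------------------------------------------------------

nrrd_dtypes <- list(
  "double" = list(what = "double", size = 8L),
  "float"  = list(what = "double", size = 4L),
  "int"    = list(what = "integer", size = 4L),
  "int32"  = list(what = "integer", size = 4L),
  "short"  = list(what = "integer", size = 2L),
  "ushort" = list(what = "integer", size = 2L, signed = FALSE),
  "uchar"  = list(what = "integer", size = 1L, signed = FALSE))

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000[0-9]$", magic))
    stop("not an NRRD file: ", path, call. = FALSE)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L)
      stop("NRRD header not terminated by blank line", call. = FALSE)
    if (line == "") break
    if (startsWith(line, "#")) next
    m <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(m) == 3L) fields[[tolower(m[2])]] <- m[3]
  }
  need <- function(k) {
    if (is.null(fields[[k]]))
      stop("NRRD header missing required field: ", k, call. = FALSE)
    fields[[k]]
  }
  ndim <- as.integer(need("dimension"))
  if (ndim != 3L) stop("only 3D NRRD volumes supported", call. = FALSE)
  sizes <- as.integer(strsplit(trimws(need("sizes")), "[ \t]+")[[1]])
  type <- trimws(need("type"))
  dt <- nrrd_dtypes[[type]]
  if (is.null(dt)) stop("unsupported NRRD type: ", type, call. = FALSE)
  spacing <- NULL
  if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    dirs <- lapply(vecs, function(s)
      as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]]))
    spacing <- vapply(dirs, function(d) sqrt(sum(d^2)), numeric(1))
  } else if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(trimws(fields[["spacings"]]), "[ \t]+")[[1]])
  }
  if (is.null(spacing) || length(spacing) != 3L || any(!is.finite(spacing)) ||
      any(spacing <= 0))
    stop("NRRD header has missing or non-positive spacing", call. = FALSE)
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "",
                                       fields[["space origin"]]), ",")[[1]])
  endian <- tolower(fields[["endian"]] %||% "little")
  enc <- tolower(trimws(need("encoding")))
  n <- prod(sizes)
  if (enc == "raw") {
    data <- readBin(con, dt$what, n = n, size = dt$size,
                    signed = dt$signed %||% TRUE, endian = endian)
  } else if (enc %in% c("gzip", "gz")) {
    comp <- readBin(con, "raw", n = file.size(path))
    bytes <- memDecompress(comp, type = "gzip")
    data <- readBin(bytes, dt$what, n = n, size = dt$size,
                    signed = dt$signed %||% TRUE, endian = endian)
  } else {
    stop("unsupported NRRD encoding: ", enc, call. = FALSE)
  }
  if (length(data) != n)
    stop("NRRD payload size does not match header sizes", call. = FALSE)
  labeled_volume(array(as.numeric(data), sizes), spacing = spacing,
                 origin = origin)
}

write_nrrd <- function(data, type, geom, path, gzip = FALSE) {
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  hdr <- c("NRRD0004",
           sprintf("type: %s", type),
           "dimension: 3",
           "space dimension: 3",
           sprintf("sizes: %d %d %d", geom$dims[1], geom$dims[2],
                   geom$dims[3]),
           sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
                   geom$spacing[1], geom$spacing[2], geom$spacing[3]),
           sprintf("space origin: (%.17g,%.17g,%.17g)",
                   geom$origin[1], geom$origin[2], geom$origin[3]),
           "endian: little",
           sprintf("encoding: %s", if (gzip) "gzip" else "raw"),
           "")
  writeLines(hdr, con, sep = "\n")
  size <- if (type == "double") 8L else 4L
  if (gzip) {
    raw <- writeBin(if (type == "double") as.numeric(data)
                    else as.integer(data),
                    raw(), size = size, endian = "little")
    writeBin(memCompress(raw, type = "gzip"), con)
  } else {
    writeBin(if (type == "double") as.numeric(data) else as.integer(data),
             con, size = size, endian = "little")
  }
  invisible(path)
}

## ---- NIfTI-1 -------------------------------------------------------------

nifti_con <- function(path, mode) {
  if (grepl("\\.gz$", tolower(path))) gzfile(path, mode) else file(path, mode)
}

read_nifti <- function(path) {
  con <- nifti_con(path, "rb")
  on.exit(close(con), add = TRUE)
  sizeof_hdr <- readBin(con, "integer", 1, 4, endian = "little")
  if (sizeof_hdr != 348L)
    stop("not a little-endian NIfTI-1 file: ", path, call. = FALSE)
  readBin(con, "raw", 36)                         # data_type..dim_info
  dim <- readBin(con, "integer", 8, 2, endian = "little")
  readBin(con, "raw", 14)                         # intent_p*, intent_code
  datatype <- readBin(con, "integer", 1, 2, endian = "little")
  readBin(con, "integer", 1, 2, endian = "little")  # bitpix
  readBin(con, "integer", 1, 2, endian = "little")  # slice_start
  pixdim <- readBin(con, "double", 8, 4, endian = "little")
  vox_offset <- readBin(con, "double", 1, 4, endian = "little")
  scl_slope <- readBin(con, "double", 1, 4, endian = "little")
  scl_inter <- readBin(con, "double", 1, 4, endian = "little")
  readBin(con, "raw", 32)                         # slice_end..glmin
  readBin(con, "raw", 104)                        # descrip, aux_file
  qform_code <- readBin(con, "integer", 1, 2, endian = "little")
  sform_code <- readBin(con, "integer", 1, 2, endian = "little")
  quat <- readBin(con, "double", 6, 4, endian = "little")
  srow <- matrix(readBin(con, "double", 12, 4, endian = "little"),
                 nrow = 3, byrow = TRUE)
  readBin(con, "raw", 20)                         # intent_name, magic
  if (dim[1] != 3L) stop("only 3D NIfTI volumes supported", call. = FALSE)
  sizes <- dim[2:4]
  spacing <- pixdim[2:4]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("NIfTI header has missing or non-positive pixdim spacing",
         call. = FALSE)
  origin <- c(0, 0, 0)
  if (sform_code > 0L) origin <- srow[, 4]
  else if (qform_code > 0L) origin <- quat[4:6]
  skip <- round(vox_offset) - 348L
  if (skip > 0L) readBin(con, "raw", skip)
  n <- prod(sizes)
  data <- switch(as.character(datatype),
                 "2"  = readBin(con, "integer", n, 1, signed = FALSE),
                 "4"  = readBin(con, "integer", n, 2, endian = "little"),
                 "8"  = readBin(con, "integer", n, 4, endian = "little"),
                 "16" = readBin(con, "double", n, 4, endian = "little"),
                 "64" = readBin(con, "double", n, 8, endian = "little"),
                 stop("unsupported NIfTI datatype: ", datatype,
                      call. = FALSE))
  if (length(data) != n)
    stop("NIfTI payload size does not match header dim", call. = FALSE)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  labeled_volume(array(as.numeric(data), sizes), spacing = spacing,
                 origin = origin)
}

write_nifti <- function(data, datatype, geom, path) {
  con <- nifti_con(path, "wb")
  on.exit(close(con), add = TRUE)
  wB <- function(x, size) writeBin(x, con, size = size, endian = "little")
  zraw <- function(n) writeBin(raw(n), con)
  wB(348L, 4)                                   # sizeof_hdr
  zraw(36)                                      # data_type..dim_info
  wB(as.integer(c(3, geom$dims, 1, 1, 1, 1)), 2)  # dim
  zraw(12); wB(0L, 2)                           # intent_p*, intent_code
  wB(as.integer(datatype), 2)
  wB(if (datatype == 64L) 64L else 32L, 2)      # bitpix
  wB(0L, 2)                                     # slice_start
  writeBin(as.numeric(c(1, geom$spacing, 0, 0, 0, 0)), con, size = 4,
           endian = "little")                   # pixdim (qfac = 1)
  writeBin(c(352, 1, 0), con, size = 4, endian = "little")  # vox_offset, scl
  zraw(3 * 2 + 2)                               # slice_end/code, xyzt_units
  writeBin(numeric(4), con, size = 4, endian = "little")  # cal/slice_dur/toff
  zraw(8)                                       # glmax, glmin
  zraw(104)                                     # descrip, aux_file
  wB(0L, 2); wB(1L, 2)                          # qform_code, sform_code
  writeBin(numeric(6), con, size = 4, endian = "little")  # quatern/qoffset
  srow <- rbind(c(geom$spacing[1], 0, 0, geom$origin[1]),
                c(0, geom$spacing[2], 0, geom$origin[2]),
                c(0, 0, geom$spacing[3], geom$origin[3]))
  writeBin(as.numeric(t(srow)), con, size = 4, endian = "little")
  zraw(16)                                      # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con) # magic
  zraw(4)                                       # extension flag
  if (datatype == 64L) wB(as.numeric(data), 8) else wB(as.integer(data), 4)
  invisible(path)
}

## ---- raw + JSON sidecar --------------------------------------------------

read_rawjson <- function(path) {
  side <- jsonlite::fromJSON(path)
  dims <- as.integer(side$dims)
  spacing <- as.numeric(side$spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("sidecar has missing or non-positive spacing", call. = FALSE)
  dir <- dirname(path)
  n <- prod(dims)
  dfile <- file.path(dir, side$density_file)
  density <- readBin(dfile, "double", n, 8, endian = "little")
  if (length(density) != n)
    stop("raw density payload does not match sidecar dims", call. = FALSE)
  label <- NULL
  if (!is.null(side$label_file)) {
    label <- readBin(file.path(dir, side$label_file), "integer", n, 4,
                     endian = "little")
    if (length(label) != n)
      stop("raw label payload does not match sidecar dims", call. = FALSE)
    label <- array(label, dims)
  }
  labeled_volume(array(density, dims), label = label, spacing = spacing,
                 origin = as.numeric(side$origin))
}

write_rawjson <- function(volume, path) {
  base <- sub("\\.json$", "", basename(path))
  dir <- dirname(path)
  dfile <- paste0(base, ".density.raw")
  writeBin(as.numeric(volume$density), file.path(dir, dfile), size = 8,
           endian = "little")
  side <- list(dims = volume$dims, spacing = volume$spacing,
               origin = volume$origin, dtype = "float64",
               density_file = dfile)
  if (any(volume$label != 0L)) {
    lfile <- paste0(base, ".labels.raw")
    writeBin(as.integer(volume$label), file.path(dir, lfile), size = 4,
             endian = "little")
    side$label_file <- lfile
  }
  jsonlite::write_json(side, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}
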
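#' Material (tissue-property) table
#'
#' Per-label rendering and interaction properties of the tissue components
#' in a labeled volume: display colour/transparency, contact stiffness for
#' haptic force rendering, whether the material may be drilled, a
#' removal-ease multiplier, a removal resistance, and a render flag.
#' Label 0 is reserved for void space and must not appear in the table.
#'
#' @param df data.frame with columns `label` (unique positive integers),
#'   `name`, `r`, `g`, `b`, `a` (RGBA in `[0, 1]`), `transparency`
#'   (`[0, 1]`), `stiffness` (N/mm, > 0), `drillable` (logical), `ease`
#'   (> 0), `resistance` (exposure units, >= 0; 0 means instantaneous
#'   removal) and `render` (logical).  Missing optional columns get
#'   defaults (`a` 1, `transparency` 0, `ease` 1, `resistance` 0,
#'   `render` TRUE).
#' @return a `material_table` object (validated data.frame).
#' @export
material_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("label", "name", "r", "g", "b", "stiffness", "drillable")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("material table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(df$a)) df$a <- 1
  if (is.null(df$transparency)) df$transparency <- 0
  if (is.null(df$ease)) df$ease <- 1
  if (is.null(df$resistance)) df$resistance <- 0
  if (is.null(df$render)) df$render <- TRUE
  df$label <- as.integer(df$label)
  df$drillable <- as.logical(df$drillable)
  df$render <- as.logical(df$render)
  class(df) <- c("material_table", "data.frame")
  validate_materials(df)
  df
}

#' Validate a material table
#'
#' @param m a `material_table`.
#' @return `m`, invisibly; stops on violated invariants (duplicate or
#'   reserved labels, non-positive stiffness/ease, out-of-range colour).
#' @export
validate_materials <- function(m) {
  stopifnot(inherits(m, "material_table"))
  if (anyDuplicated(m$label))
    stop("material labels must be unique", call. = FALSE)
  if (any(m$label == 0L))
    stop("label 0 is reserved for void and may not appear", call. = FALSE)
  if (any(m$label < 0L)) stop("labels must be positive", call. = FALSE)
  cols <- as.matrix(m[, c("r", "g", "b", "a", "transparency")])
  if (any(cols < 0 | cols > 1))
    stop("colour/transparency components must lie in [0, 1]", call. = FALSE)
  if (any(m$stiffness <= 0))
    stop("stiffness must be strictly positive", call. = FALSE)
  if (any(m$ease <= 0))
    stop("ease must be strictly positive", call. = FALSE)
  if (any(m$resistance < 0))
    stop("resistance must be non-negative", call. = FALSE)
  invisible(m)
}

material_row <- function(m, label) {
  i <- match(as.integer(label), m$label)
  if (is.na(i))
    stop("label ", label, " not present in material table", call. = FALSE)
  m[i, , drop = FALSE]
}

#' Modify the removal ease of one material
#'
#' With nonzero resistance `R`, a continuously exposed voxel is removed at
#' `t = R / (rate * ease)`, so doubling ease halves time-to-removal.
#' Setting ease on an undrillable material is accepted; removal stays
#' blocked by `drillable = FALSE`.
#'
#' @param m a `material_table`.
#' @param label label id present in the table.
#' @param ease new ease multiplier, strictly positive.
#' @return the updated `material_table`.
#' @export
set_ease <- function(m, label, ease) {
  if (!is.numeric(ease) || length(ease) != 1L || !is.finite(ease) ||
      ease <= 0)
    stop("`ease` must be a single positive number", call. = FALSE)
  i <- match(as.integer(label), m$label)
  if (is.na(i)) stop("label ", label, " not in table", call. = FALSE)
  m$ease[i] <- ease
  m
}

#' Read / write a material table as JSON
#'
#' The on-disk schema is an object keyed by label id, each entry holding
#' `name`, `color` (RGBA array), `transparency`, `stiffness`, `drillable`,
#' `ease`, `resistance`, `render`.  Validated on load.
#'
#' @param path file path.
#' @return `read_materials` returns a `material_table`.
#' @export
read_materials <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rows <- lapply(names(obj), function(k) {
    e <- obj[[k]]
    data.frame(label = as.integer(k), name = e$name,
               r = e$color[[1]], g = e$color[[2]], b = e$color[[3]],
               a = if (length(e$color) >= 4) e$color[[4]] else 1,
               transparency = e$transparency %||% 0,
               stiffness = e$stiffness,
               drillable = isTRUE(e$drillable),
               ease = e$ease %||% 1,
               resistance = e$resistance %||% 0,
               render = !isFALSE(e$render),
               stringsAsFactors = FALSE)
  })
  material_table(do.call(rbind, rows))
}

#' @rdname read_materials
#' @param m a `material_table` to serialize.
#' @export
write_materials <- function(m, path) {
  validate_materials(m)
  obj <- lapply(seq_len(nrow(m)), function(i) {
    list(name = m$name[i],
         color = c(m$r[i], m$g[i], m$b[i], m$a[i]),
         transparency = m$transparency[i],
         stiffness = m$stiffness[i],
         drillable = m$drillable[i],
         ease = m$ease[i],
         resistance = m$resistance[i],
         render = m$render[i])
  })
  names(obj) <- as.character(m$label)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

materials_hash <- function(m) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  write_materials(m, tf)
  unname(tools::md5sum(tf))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default material table for phantom models
#'
#' Labels: 1 cortical bone, 2 trabecular bone, 3 vessel (carotid/sigmoid
#' analogue), 4 nerve, 5 dural plate, 6 ossicle.  Bone is drillable;
#' soft-tissue structures default to undrillable so they behave as
#' protected anatomy.
#'
#' @return a `material_table`.
#' @export
default_materials <- function() {
  material_table(data.frame(
    label = 1:6,
    name = c("cortical bone", "trabecular bone", "vessel", "nerve",
             "dural plate", "ossicle"),
    r = c(0.93, 0.85, 0.85, 0.95, 0.60, 0.98),
    g = c(0.89, 0.78, 0.10, 0.85, 0.60, 0.75),
    b = c(0.76, 0.62, 0.10, 0.30, 0.75, 0.80),
    a = 1,
    transparency = c(0, 0, 0, 0, 0.3, 0),
    stiffness = c(0.8, 0.5, 0.3, 0.3, 0.4, 0.7),
    drillable = c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE),
    ease = 1,
    resistance = 0,
    render = TRUE,
    stringsAsFactors = FALSE))
}
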
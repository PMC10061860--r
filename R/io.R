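#' Read a labeled plant point cloud
#'
#' Reads PLY (ASCII or binary little-endian) or a plain whitespace-separated
#' table with columns `x y z [r g b] [label]`. Coordinates are taken to be in
#' meters with z vertical. Part labels are taken from an explicit per-vertex
#' scalar property named `label` when present; otherwise they are inferred
#' from pure annotation colors (red `(255,0,0)` = main stem, green
#' `(0,255,0)` = branch, blue `(0,0,255)` = boll, anything else unlabeled).
#'
#' @param path path to the file.
#' @param format `"ply"`, `"xyz"`, or `"auto"` (sniff the PLY magic bytes).
#' @return A [plant_cloud()] with point order preserved from the file.
#' @export
#' @examples
#' f <- tempfile(fileext = ".ply")
#' pc <- plant_cloud(cbind(0, 0, 0:2 / 2), labels = c(0L, 1L, 2L))
#' write_cloud(pc, f)
#' read_cloud(f)
read_cloud <- function(path, format = c("auto", "ply", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    magic <- readBin(path, "raw", n = 4L)
    format <- if (length(magic) >= 3 && rawToChar(magic[1:3]) == "ply") "ply" else "xyz"
  }
  if (format == "ply") read_ply(path) else read_xyz(path)
}

#' Write a labeled plant point cloud
#'
#' Writes PLY or a plain `x y z [r g b] [label]` table. When labels are
#' present, both a per-vertex integer `label` property and the convention
#' colors (red/green/blue for main stem/branch/boll, gray for unlabeled) are
#' emitted, so files remain readable by viewers that only understand colors.
#'
#' @param cloud a [plant_cloud()].
#' @param path output file path.
#' @param format `"ply"` or `"xyz"`; default from the file extension.
#' @param binary write binary little-endian PLY instead of ASCII.
#' @return The path, invisibly.
#' @export
write_cloud <- function(cloud, path, format = c("auto", "ply", "xyz"),
                        binary = FALSE) {
  stopifnot(inherits(cloud, "plant_cloud"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "xyz"
  if (format == "ply") write_ply(cloud, path, binary = binary)
  else write_xyz(cloud, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# PLY

PLY_TYPES <- list(
  char = list(size = 1L, what = "integer", signed = TRUE),
  int8 = list(size = 1L, what = "integer", signed = TRUE),
  uchar = list(size = 1L, what = "integer", signed = FALSE),
  uint8 = list(size = 1L, what = "integer", signed = FALSE),
  short = list(size = 2L, what = "integer", signed = TRUE),
  int16 = list(size = 2L, what = "integer", signed = TRUE),
  ushort = list(size = 2L, what = "integer", signed = FALSE),
  uint16 = list(size = 2L, what = "integer", signed = FALSE),
  int = list(size = 4L, what = "integer", signed = TRUE),
  int32 = list(size = 4L, what = "integer", signed = TRUE),
  uint = list(size = 4L, what = "integer", signed = TRUE),
  uint32 = list(size = 4L, what = "integer", signed = TRUE),
  float = list(size = 4L, what = "double", signed = TRUE),
  float32 = list(size = 4L, what = "double", signed = TRUE),
  double = list(size = 8L, what = "double", signed = TRUE),
  float64 = list(size = 8L, what = "double", signed = TRUE)
)

read_ply <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  # locate end of header at byte level (binary bodies contain NUL bytes)
  m <- grepRaw("end_header", raw, fixed = TRUE)
  if (length(m) == 0) stop("malformed PLY: no end_header")
  m <- m[1]
  data_offset <- m + 9L  # last byte of "end_header"
  if (data_offset < length(raw) && raw[data_offset + 1L] == as.raw(13L))
    data_offset <- data_offset + 1L
  if (data_offset < length(raw) && raw[data_offset + 1L] == as.raw(10L))
    data_offset <- data_offset + 1L
  header <- strsplit(rawToChar(raw[seq_len(m - 1L)]), "\r?\n")[[1]]
  if (length(header) == 0 || header[1] != "ply") stop("not a PLY file")

  fmt_line <- grep("^format ", header, value = TRUE)
  if (length(fmt_line) != 1) stop("malformed PLY: missing format line")
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", fmt)

  # parse elements/properties; only the vertex element is used and it must
  # come first among elements
  elem_idx <- grep("^element ", header)
  if (length(elem_idx) == 0) stop("malformed PLY: no element")
  first_elem <- strsplit(trimws(header[elem_idx[1]]), "\\s+")[[1]]
  if (first_elem[2] != "vertex")
    stop("unsupported PLY layout: first element must be vertex")
  n <- as.integer(first_elem[3])
  prop_end <- if (length(elem_idx) > 1) elem_idx[2] - 1L else length(header)
  prop_lines <- grep("^property ", header[seq(elem_idx[1], prop_end)], value = TRUE)
  props <- lapply(strsplit(trimws(prop_lines), "\\s+"), function(tok) {
    if (tok[2] == "list") stop("list properties are not supported on vertices")
    list(type = tok[2], name = tok[3])
  })
  pnames <- vapply(props, `[[`, "", "name")
  if (!all(c("x", "y", "z") %in% pnames))
    stop("PLY vertex element lacks x/y/z coordinates")

  if (fmt == "ascii") {
    txt <- rawToChar(raw[(data_offset + 1L):length(raw)])
    vals <- scan(text = txt, what = numeric(), n = n * length(props), quiet = TRUE)
    if (length(vals) < n * length(props)) stop("truncated PLY data")
    dat <- matrix(vals, nrow = n, byrow = TRUE)
  } else {
    sizes <- vapply(props, function(p) PLY_TYPES[[p$type]]$size, 1L)
    if (any(vapply(props, function(p) is.null(PLY_TYPES[[p$type]]), TRUE)))
      stop("unsupported PLY property type")
    rec <- sum(sizes)
    if (length(raw) < data_offset + as.double(rec) * n) stop("truncated PLY data")
    offs <- cumsum(c(0L, sizes[-length(sizes)]))
    dat <- matrix(0, n, length(props))
    base <- data_offset + rep((0:(n - 1L)) * rec, each = 1L)
    for (j in seq_along(props)) {
      ty <- PLY_TYPES[[props[[j]]$type]]
      pos <- outer(seq_len(ty$size), base + offs[j], `+`)
      bytes <- raw[as.vector(pos)]
      dat[, j] <- readBin(bytes, ty$what, n = n, size = ty$size,
                          signed = if (ty$size >= 4) TRUE else ty$signed,
                          endian = "little")
    }
  }
  colnames(dat) <- pnames
  coords <- dat[, c("x", "y", "z"), drop = FALSE]
  colors <- NULL
  if (all(c("red", "green", "blue") %in% pnames))
    colors <- dat[, c("red", "green", "blue"), drop = FALSE]
  labels <- NULL
  if ("label" %in% pnames) {
    labels <- as.integer(round(dat[, "label"]))
  } else if (!is.null(colors)) {
    inferred <- colors_to_labels(round(colors))
    if (any(inferred != -1L)) labels <- inferred
  }
  plant_cloud(coords, colors = if (!is.null(colors)) round(colors), labels = labels)
}

write_ply <- function(cloud, path, binary = FALSE) {
  n <- n_points(cloud)
  has_lab <- !is.null(cloud$labels)
  colors <- if (has_lab) labels_to_colors(cloud$labels) else cloud$colors
  has_col <- !is.null(colors)

  header <- c(
    "ply",
    sprintf("format %s 1.0", if (binary) "binary_little_endian" else "ascii"),
    "comment written by cottontraits",
    sprintf("element vertex %d", n),
    "property double x", "property double y", "property double z"
  )
  if (has_col) header <- c(header,
    "property uchar red", "property uchar green", "property uchar blue")
  if (has_lab) header <- c(header, "property int label")
  header <- c(header, "end_header")

  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (binary) {
    rec <- 24L + (if (has_col) 3L else 0L) + (if (has_lab) 4L else 0L)
    out <- matrix(as.raw(0), rec, n)
    cbytes <- writeBin(as.vector(t(cloud$coords)), raw(), size = 8, endian = "little")
    out[1:24, ] <- matrix(cbytes, 24L, n)
    off <- 24L
    if (has_col) {
      out[off + (1:3), ] <- matrix(as.raw(t(colors)), 3L, n)
      off <- off + 3L
    }
    if (has_lab)
      out[off + (1:4), ] <- matrix(writeBin(cloud$labels, raw(), size = 4,
                                            endian = "little"), 4L, n)
    writeBin(as.vector(out), con)
  } else {
    lines <- sprintf("%.10g %.10g %.10g",
                     cloud$coords[, 1], cloud$coords[, 2], cloud$coords[, 3])
    if (has_col)
      lines <- paste(lines, colors[, 1], colors[, 2], colors[, 3])
    if (has_lab)
      lines <- paste(lines, cloud$labels)
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# plain x y z [r g b] [label] table

read_xyz <- function(path) {
  dat <- tryCatch(as.matrix(read.table(path)),
                  error = function(e) stop("cannot read table: ", conditionMessage(e)))
  if (!is.numeric(dat)) stop("table contains non-numeric fields")
  nc <- ncol(dat)
  if (nc == 3)
    return(plant_cloud(dat))
  if (nc == 4)
    return(plant_cloud(dat[, 1:3, drop = FALSE], labels = as.integer(dat[, 4])))
  if (nc %in% c(6, 7)) {
    colors <- round(dat[, 4:6, drop = FALSE])
    labels <- if (nc == 7) as.integer(dat[, 7]) else {
      inferred <- colors_to_labels(colors)
      if (any(inferred != -1L)) inferred else NULL
    }
    return(plant_cloud(dat[, 1:3, drop = FALSE], colors = colors, labels = labels))
  }
  stop("expected 3, 4, 6 or 7 columns, got ", nc)
}

write_xyz <- function(cloud, path) {
  has_lab <- !is.null(cloud$labels)
  colors <- if (has_lab) labels_to_colors(cloud$labels) else cloud$colors
  lines <- sprintf("%.10g %.10g %.10g",
                   cloud$coords[, 1], cloud$coords[, 2], cloud$coords[, 3])
  if (!is.null(colors))
    lines <- paste(lines, colors[, 1], colors[, 2], colors[, 3])
  if (has_lab)
    lines <- paste(lines, cloud$labels)
  writeLines(lines, path)
  invisible(path)
}
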
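#' Construct a point cloud
#'
#' A `point_cloud` is the package's in-memory container for a dense 3D point
#' cloud: an `n x 3` coordinate matrix in millimetres, an optional `n x 3`
#' 8-bit RGB matrix, and an optional per-point character label (used by the
#' synthetic generators to retain ground truth such as `"top"`, `"lateral"`,
#' `"bed"`, `"plant"`, `"background"`).
#'
#' @param xyz numeric matrix (or data frame) with columns x, y, z in mm.
#' @param rgb optional integer matrix with columns r, g, b in 0..255.
#' @param label optional character vector, one entry per point.
#' @return An object of class `point_cloud`.
#' @export
#' @examples
#' pc <- point_cloud(cbind(x = 0:2, y = 0, z = c(0, 5, 10)))
#' npoints(pc)
point_cloud <- function(xyz, rgb = NULL, label = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L)
    stop("`xyz` must have exactly three columns (x, y, z)", call. = FALSE)
  storage.mode(xyz) <- "double"
  if (!all(is.finite(xyz)))
    stop("point coordinates must be finite", call. = FALSE)
  colnames(xyz) <- c("x", "y", "z")
  n <- nrow(xyz)
  if (!is.null(rgb)) {
    rgb <- as.matrix(rgb)
    if (nrow(rgb) != n || ncol(rgb) != 3L)
      stop("`rgb` must be an n x 3 matrix matching the points", call. = FALSE)
    if (any(rgb < 0 | rgb > 255))
      stop("color channels must lie in [0, 255]", call. = FALSE)
    storage.mode(rgb) <- "double"
    colnames(rgb) <- c("r", "g", "b")
  }
  if (!is.null(label)) {
    label <- as.character(label)
    if (length(label) != n)
      stop("`label` must have one entry per point", call. = FALSE)
  }
  structure(list(xyz = xyz, rgb = rgb, label = label),
            class = "point_cloud")
}

#' Number of points in a cloud
#' @param cloud a [point_cloud()].
#' @return Integer point count.
#' @export
npoints <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  nrow(cloud$xyz)
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud: %d points%s%s>\n", npoints(x),
              if (!is.null(x$rgb)) ", RGB" else "",
              if (!is.null(x$label)) ", labeled" else ""))
  if (npoints(x) > 0) {
    rng <- apply(x$xyz, 2, range)
    cat(sprintf("  x: [%.1f, %.1f]  y: [%.1f, %.1f]  z: [%.1f, %.1f] mm\n",
                rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  }
  invisible(x)
}

#' @export
as.data.frame.point_cloud <- function(x, ...) {
  df <- as.data.frame(x$xyz)
  if (!is.null(x$rgb)) df <- cbind(df, as.data.frame(x$rgb))
  if (!is.null(x$label)) df$label <- x$label
  df
}

#' Has the cloud per-point color?
#' @param cloud a [point_cloud()].
#' @return `TRUE` if RGB is present.
#' @export
has_color <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  !is.null(cloud$rgb)
}

# subset a cloud by a logical or integer index, keeping rgb/label aligned
subset_cloud <- function(cloud, idx) {
  point_cloud(cloud$xyz[idx, , drop = FALSE],
              rgb = if (!is.null(cloud$rgb)) cloud$rgb[idx, , drop = FALSE],
              label = if (!is.null(cloud$label)) cloud$label[idx])
}

#' Read a PLY point cloud
#'
#' Reads `ascii 1.0` and `binary_little_endian 1.0` PLY files containing a
#' `vertex` element with `x`, `y`, `z` (float or double) properties and
#' optionally `red`, `green`, `blue` (uchar).  Coordinates are interpreted as
#' millimetres.  Other elements and properties are skipped.
#'
#' @param path path to a `.ply` file.
#' @return A [point_cloud()].
#' @export
read_ply <- function(path) {
  if (!file.exists(path))
    stop(sprintf("PLY file not found: %s", path), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))

  # --- header -------------------------------------------------------------
  read_hline <- function() {
    chars <- character()
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || ch == "\n") break
      if (ch != "\r") chars <- c(chars, ch)
    }
    paste(chars, collapse = "")
  }
  if (read_hline() != "ply")
    stop(sprintf("not a PLY file (missing magic): %s", path), call. = FALSE)
  format <- NULL
  elements <- list()   # name -> list(count, props = data.frame(type, name))
  cur <- NULL
  repeat {
    line <- read_hline()
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0L) next
    if (tok[1] == "comment") next
    if (tok[1] == "format") {
      format <- tok[2]
    } else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]),
                  types = character(), props = character())
    } else if (tok[1] == "property") {
      if (tok[2] == "list")
        stop("list properties are not supported", call. = FALSE)
      cur$types <- c(cur$types, tok[2])
      cur$props <- c(cur$props, tok[3])
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    }
  }
  if (!format %in% c("ascii", "binary_little_endian"))
    stop(sprintf("unsupported PLY format '%s'", format), call. = FALSE)
  if (is.null(elements$vertex))
    stop("PLY file has no 'vertex' element", call. = FALSE)
  vert <- elements$vertex
  for (p in c("x", "y", "z"))
    if (!p %in% vert$props)
      stop(sprintf("PLY vertex element lacks required property '%s'", p),
           call. = FALSE)

  type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                 short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                 int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                 float = 4L, float32 = 4L, double = 8L, float64 = 8L)

  read_element_binary <- function(el) {
    sizes <- unname(type_size[el$types])
    if (anyNA(sizes)) stop("unknown PLY property type", call. = FALSE)
    row_bytes <- sum(sizes)
    raw <- readBin(con, "raw", n = row_bytes * el$count)
    out <- matrix(NA_real_, nrow = el$count, ncol = length(el$props),
                  dimnames = list(NULL, el$props))
    offset <- 0L
    mat <- matrix(raw, nrow = row_bytes, ncol = el$count)
    for (j in seq_along(el$props)) {
      bytes <- mat[(offset + 1L):(offset + sizes[j]), , drop = FALSE]
      tp <- el$types[j]
      vals <- if (tp %in% c("float", "float32", "double", "float64")) {
        readBin(as.vector(bytes), "double", n = el$count,
                size = sizes[j], endian = "little")
      } else {
        signed <- tp %in% c("char", "int8", "short", "int16", "int", "int32")
        readBin(as.vector(bytes), "integer", n = el$count, size = sizes[j],
                signed = signed || sizes[j] == 4L, endian = "little")
      }
      out[, j] <- vals
      offset <- offset + sizes[j]
    }
    out
  }

  if (format == "ascii") {
    txt <- readLines(con, warn = FALSE)
    txt <- txt[nzchar(trimws(txt))]
    need <- vert$count
    if (length(txt) < need)
      stop("PLY vertex data truncated", call. = FALSE)
    fields <- strsplit(trimws(txt[seq_len(need)]), "\\s+")
    vmat <- matrix(as.numeric(unlist(fields)), nrow = need, byrow = TRUE)
    colnames(vmat) <- vert$props
  } else {
    # skip any element preceding vertex, then read vertex rows
    for (el in elements) {
      if (el$name == "vertex") { vmat <- read_element_binary(el); break }
      sizes <- unname(type_size[el$types])
      invisible(readBin(con, "raw", n = sum(sizes) * el$count))
    }
  }

  xyz <- vmat[, c("x", "y", "z"), drop = FALSE]
  rgb <- NULL
  if (all(c("red", "green", "blue") %in% vert$props))
    rgb <- vmat[, c("red", "green", "blue"), drop = FALSE]
  point_cloud(xyz, rgb = rgb)
}

#' Write a PLY point cloud
#'
#' Writes a [point_cloud()] as `ascii` or `binary_little_endian` PLY with
#' `float` coordinates and, when present, `uchar` red/green/blue channels.
#' Labels are not stored in the PLY (use the sidecar CSV written by
#' [simulate_scene()] for ground truth).
#'
#' @param cloud a [point_cloud()].
#' @param path output path.
#' @param binary write binary little-endian instead of ASCII.
#' @return `path`, invisibly.
#' @export
write_ply <- function(cloud, path, binary = FALSE) {
  stopifnot(inherits(cloud, "point_cloud"))
  n <- npoints(cloud)
  with_rgb <- has_color(cloud)
  hdr <- c(
    "ply",
    sprintf("format %s 1.0",
            if (binary) "binary_little_endian" else "ascii"),
    "comment generated by phenopou",
    sprintf("element vertex %d", n),
    "property float x", "property float y", "property float z",
    if (with_rgb) c("property uchar red", "property uchar green",
                    "property uchar blue"),
    "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (binary) {
    xyz <- cloud$xyz
    rgb <- if (with_rgb) round(cloud$rgb)
    for (i in seq_len(n)) {
      writeBin(as.numeric(xyz[i, ]), con, size = 4L, endian = "little")
      if (with_rgb)
        writeBin(as.raw(rgb[i, ]), con)
    }
  } else {
    xyz <- format(cloud$xyz, trim = TRUE, scientific = FALSE, digits = 9)
    rows <- paste(xyz[, 1], xyz[, 2], xyz[, 3])
    if (with_rgb) {
      rgb <- round(cloud$rgb)
      rows <- paste(rows, rgb[, 1], rgb[, 2], rgb[, 3])
    }
    writeLines(rows, con, sep = "\n")
  }
  invisible(path)
}
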
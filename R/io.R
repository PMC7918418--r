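#' Read a point cloud from PLY, XYZ/CSV or OBJ
#'
#' Format is chosen by file extension (`.ply`, `.obj`, anything else is
#' treated as whitespace- or comma-separated XYZ). PLY supports ASCII and
#' binary little-endian vertex elements; only the x/y/z properties are used.
#'
#' @param path input file.
#' @return a `point_cloud`.
#' @export
read_point_cloud <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  pts <- switch(ext,
                ply = read_ply_vertices(path),
                obj = read_obj_vertices(path),
                read_xyz_table(path))
  point_cloud(pts, provenance = basename(path))
}

read_xyz_table <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else ""
  has_header <- !grepl("^\\s*[-+0-9.eE]", first)
  df <- utils::read.table(path, sep = sep, header = has_header,
                          comment.char = "#")
  num <- vapply(df, is.numeric, logical(1))
  as.matrix(df[, which(num)[1:3]])
}

read_obj_vertices <- function(path) {
  lines <- readLines(path)
  v <- lines[startsWith(lines, "v ")]
  if (!length(v)) stop("no vertex lines in OBJ file: ", path)
  m <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", v)), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  m
}

read_ply_vertices <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  header <- character(0)
  repeat {
    ln <- readLines(con, n = 1)
    if (!length(ln)) stop("unterminated PLY header")
    header <- c(header, ln)
    if (trimws(ln) == "end_header") break
  }
  fmt <- sub("^format\\s+", "", grep("^format", header, value = TRUE)[1])
  fmt <- strsplit(trimws(fmt), "\\s+")[[1]][1]
  # parse element/property declarations in order
  elems <- list(); cur <- NULL
  for (ln in header) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elems[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]),
                  props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      cur$props[[length(cur$props) + 1L]] <-
        list(type = tok[2], list_types = tok[2:(length(tok) - 1)],
             name = tok[length(tok)])
    }
  }
  if (!is.null(cur)) elems[[cur$name]] <- cur
  vt <- elems[["vertex"]]
  if (is.null(vt)) stop("PLY file has no vertex element")
  pnames <- vapply(vt$props, `[[`, "", "name")
  if (fmt == "ascii") {
    vals <- scan(con, what = double(),
                 n = vt$count * length(vt$props), quiet = TRUE)
    m <- matrix(vals, ncol = length(vt$props), byrow = TRUE)
    return(m[, match(c("x", "y", "z"), pnames), drop = FALSE])
  }
  if (fmt != "binary_little_endian")
    stop("unsupported PLY format: ", fmt)
  sizes <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
             short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
             int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
             float = 4L, float32 = 4L, double = 8L, float64 = 8L)
  types <- vapply(vt$props, `[[`, "", "type")
  if (any(types == "list")) stop("list properties in vertex element unsupported")
  stride <- sum(sizes[types])
  raw <- readBin(con, "raw", n = vt$count * stride)
  offs <- cumsum(c(0L, sizes[types]))[seq_along(types)]
  read_prop <- function(k) {
    sz <- sizes[[types[k]]]
    sel <- as.vector(outer(seq_len(sz), (seq_len(vt$count) - 1L) * stride +
                             offs[k], `+`))
    what <- if (types[k] %in% c("float", "float32", "double", "float64"))
      "double" else "integer"
    readBin(raw[sel], what, n = vt$count, size = sz, endian = "little",
            signed = !(types[k] %in% c("uchar", "uint8", "ushort", "uint16")))
  }
  cbind(read_prop(match("x", pnames)),
        read_prop(match("y", pnames)),
        read_prop(match("z", pnames)))
}

#' Write a point cloud as ASCII PLY
#'
#' @param cloud a `point_cloud`, `slpc` or n x 3 matrix.
#' @param path output file.
#' @export
write_ply <- function(cloud, path) {
  P <- cloud_points(cloud)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(P)),
               "property float x", "property float y", "property float z",
               "end_header"), con)
  utils::write.table(format(P, digits = 9, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a point set to be fitted as CSV
#'
#' Columns: `slice_index`, `point_index`, `x`, `y`, `z`.
#'
#' @param psf a `psf` object (see [build_ordered_psf()]).
#' @param path output file.
#' @export
write_psf_csv <- function(psf, path) {
  rows <- do.call(rbind, lapply(seq_along(psf$columns), function(j) {
    m <- psf$columns[[j]]
    data.frame(slice_index = psf$slice_indices[j] %||% (j - 1L),
               point_index = seq_len(nrow(m)) - 1L,
               x = m[, 1], y = m[, 2], z = m[, 3])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read a point set to be fitted from CSV written by [write_psf_csv()]
#'
#' @param path CSV file path.
#' @return a `psf` object.
#' @export
read_psf_csv <- function(path) {
  df <- utils::read.csv(path)
  idx <- unique(df$slice_index)
  cols <- lapply(idx, function(j)
    as.matrix(df[df$slice_index == j, c("x", "y", "z")]))
  new_psf(cols, slice_indices = idx)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
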
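#' Construct a point cloud tibble
#'
#' A point cloud is an ordinary tibble with numeric columns `x`, `y`, `z`
#' (metres, z-up), so it composes with dplyr verbs; extra per-point columns
#' (e.g. intensity) are carried along untouched. The `source_id` attribute
#' records where the cloud came from.
#'
#' @param points A data frame or matrix with (at least) x, y, z coordinates
#'   in metres. A 3+ column matrix is taken as x, y, z in column order.
#' @param source_id Identifier for the tree/scan this cloud belongs to.
#' @return A tibble of class `point_cloud`.
#' @export
point_cloud <- function(points, source_id = "cloud") {
  if (is.matrix(points)) {
    if (ncol(points) < 3) stop_bad_arg("point matrix needs >= 3 columns, got %d", ncol(points))
    points <- tibble::tibble(x = points[, 1], y = points[, 2], z = points[, 3])
  }
  points <- tibble::as_tibble(points)
  miss <- setdiff(c("x", "y", "z"), names(points))
  if (length(miss) > 0)
    stop_bad_arg("point cloud is missing coordinate column(s): %s", paste(miss, collapse = ", "))
  for (cc in c("x", "y", "z")) {
    if (!is.numeric(points[[cc]]))
      stop_bad_arg("coordinate column '%s' is not numeric", cc)
    if (any(!is.finite(points[[cc]])))
      stop_bad_arg("coordinate column '%s' contains non-finite values", cc)
  }
  attr(points, "source_id") <- source_id
  class(points) <- unique(c("point_cloud", class(points)))
  points
}

#' @rdname point_cloud
#' @param x Object to test.
#' @export
is_point_cloud <- function(x) {
  is.data.frame(x) && all(c("x", "y", "z") %in% names(x))
}

cloud_source <- function(cloud) attr(cloud, "source_id") %||% "cloud"

check_cloud <- function(cloud, min_points = 1L, what = "operation") {
  if (!is_point_cloud(cloud))
    stop_bad_arg("expected a point cloud (data frame with x, y, z columns)")
  if (nrow(cloud) == 0) stop_bad_arg("empty cloud", class = "tlscarbon_empty_cloud")
  if (nrow(cloud) < min_points)
    stop_bad_arg("%s needs >= %d points, cloud has %d", what, min_points, nrow(cloud),
                 class = "tlscarbon_insufficient_points")
  invisible(cloud)
}

#' Read a point cloud from PLY, XYZ or LAS
#'
#' PLY is supported in ASCII and binary little-endian form (vertex element
#' with float or double coordinates; extra scalar vertex properties are kept
#' as columns). XYZ is whitespace-delimited text with x y z in the first
#' three columns. LAS (1.2-1.4, point record formats 0-3, coordinates only)
#' is read from the header's scale/offset and raw integer triplets.
#'
#' @param path Path to the file.
#' @param format One of `"auto"`, `"ply"`, `"xyz"`, `"las"`. `"auto"` picks
#'   by file extension.
#' @return A [point_cloud()] tibble; point order is preserved.
#' @export
read_cloud <- function(path, format = c("auto", "ply", "xyz", "las")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_bad_arg("file does not exist: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, ply = "ply", xyz = "xyz", txt = "xyz", las = "las",
                     stop_bad_arg("cannot infer point-cloud format from extension '.%s'", ext))
  }
  cloud <- switch(format,
                  ply = read_ply(path),
                  xyz = read_xyz(path),
                  las = read_las(path))
  if (nrow(cloud) == 0)
    stop_bad_arg("empty cloud: %s contains no points", path, class = "tlscarbon_empty_cloud")
  point_cloud(cloud, source_id = tools::file_path_sans_ext(basename(path)))
}

#' Write a point cloud to PLY or XYZ
#'
#' @param cloud A [point_cloud()] (any data frame with x, y, z).
#' @param path Output path.
#' @param format `"ply"` or `"xyz"`.
#' @param binary For PLY: write binary little-endian (float32 coordinates)
#'   when `TRUE`, ASCII at full precision when `FALSE`.
#' @return `path`, invisibly.
#' @export
write_cloud <- function(cloud, path, format = c("ply", "xyz"), binary = TRUE) {
  format <- match.arg(format)
  check_cloud(cloud)
  if (format == "xyz") {
    lines <- sprintf("%.9g %.9g %.9g", cloud$x, cloud$y, cloud$z)
    writeLines(lines, path)
    return(invisible(path))
  }
  n <- nrow(cloud)
  fmt <- if (binary) "binary_little_endian" else "ascii"
  header <- c("ply", sprintf("format %s 1.0", fmt),
              "comment written by tlscarbon",
              sprintf("element vertex %d", n),
              if (binary) c("property float x", "property float y", "property float z")
              else c("property double x", "property double y", "property double z"),
              "end_header")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (binary) {
    m <- rbind(cloud$x, cloud$y, cloud$z)
    writeBin(as.numeric(m), con, size = 4, endian = "little")
  } else {
    writeLines(sprintf("%.17g %.17g %.17g", cloud$x, cloud$y, cloud$z), con, sep = "\n")
  }
  invisible(path)
}

ply_prop_size <- function(type) {
  switch(type,
         char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
         short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
         int = 4L, uint = 4L, int32 = 4L, uint32 = 4L, float = 4L, float32 = 4L,
         double = 8L, float64 = 8L,
         stop_bad_arg("unsupported PLY property type '%s'", type))
}

read_ply <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (length(magic) == 0 || trimws(magic) != "ply")
    stop_bad_arg("parse error in %s line 1: not a PLY file (missing 'ply' magic)", path)
  fmt <- NULL
  elements <- list() # list of list(name, count, props = tibble(name, type))
  lineno <- 1L
  repeat {
    line <- readLines(con, n = 1)
    lineno <- lineno + 1L
    if (length(line) == 0)
      stop_bad_arg("parse error in %s line %d: header ended before 'end_header'", path, lineno)
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0 || tok[1] == "comment" || tok[1] == "obj_info") next
    if (tok[1] == "end_header") break
    if (tok[1] == "format") {
      fmt <- tok[2]
      if (!fmt %in% c("ascii", "binary_little_endian"))
        stop_bad_arg("parse error in %s line %d: unsupported PLY format '%s'", path, lineno, fmt)
    } else if (tok[1] == "element") {
      elements[[length(elements) + 1]] <-
        list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (length(elements) == 0)
        stop_bad_arg("parse error in %s line %d: property before any element", path, lineno)
      i <- length(elements)
      if (tok[2] == "list") {
        elements[[i]]$props[[length(elements[[i]]$props) + 1]] <-
          list(name = tok[5], type = "list", count_type = tok[3], item_type = tok[4])
      } else {
        elements[[i]]$props[[length(elements[[i]]$props) + 1]] <-
          list(name = tok[3], type = tok[2])
      }
    }
  }
  if (is.null(fmt)) stop_bad_arg("parse error in %s: header has no 'format' line", path)
  vi <- which(vapply(elements, function(e) e$name == "vertex", logical(1)))
  if (length(vi) != 1)
    stop_bad_arg("parse error in %s: PLY file has no 'vertex' element", path)

  read_element_ascii <- function(el, want) {
    nprop <- length(el$props)
    if (any(vapply(el$props, function(p) p$type == "list", logical(1)))) {
      # consume el$count lines without interpreting them
      readLines(con, n = el$count)
      return(NULL)
    }
    lines <- readLines(con, n = el$count)
    if (length(lines) < el$count)
      stop_bad_arg("parse error in %s: element '%s' expects %d rows, file has %d",
                   path, el$name, el$count, length(lines))
    if (!want) return(NULL)
    toks <- strsplit(trimws(lines), "\\s+")
    bad <- which(vapply(toks, length, integer(1)) < nprop)
    if (length(bad) > 0)
      stop_bad_arg("parse error in %s: vertex row %d has fewer than %d values", path, bad[1], nprop)
    vals <- suppressWarnings(
      vapply(toks, function(t) as.numeric(t[seq_len(nprop)]), numeric(nprop)))
    vals <- if (nprop == 1) matrix(vals, nrow = 1) else vals
    bad <- which(apply(vals, 2, function(v) any(is.na(v))))
    if (length(bad) > 0)
      stop_bad_arg("parse error in %s: non-numeric value in vertex row %d", path, bad[1])
    out <- as.data.frame(t(vals))
    names(out) <- vapply(el$props, `[[`, character(1), "name")
    out
  }
  read_element_binary <- function(el, want) {
    if (any(vapply(el$props, function(p) p$type == "list", logical(1)))) {
      # binary list elements have data-dependent record sizes; they are only
      # tolerated after the vertex element (the loop stops once vertex is read)
      stop_bad_arg("parse error in %s: binary list-property element '%s' precedes 'vertex'",
                   path, el$name)
    }
    sizes <- vapply(el$props, function(p) ply_prop_size(p$type), integer(1))
    rec <- sum(sizes)
    raw <- readBin(con, "raw", n = rec * el$count)
    if (length(raw) < rec * el$count)
      stop_bad_arg("parse error in %s at byte offset %d: expected %d bytes for element '%s', got %d",
                   path, seek(con), rec * el$count, el$name, length(raw))
    if (!want) return(NULL)
    offs <- cumsum(c(0L, sizes))
    out <- list()
    base <- rec * (seq_len(el$count) - 1L)
    for (j in seq_along(el$props)) {
      p <- el$props[[j]]
      idx <- rep(base, each = sizes[j]) + offs[j] + seq_len(sizes[j])
      bytes <- raw[idx]
      out[[p$name]] <- switch(p$type,
        float = , float32 = readBin(bytes, "numeric", n = el$count, size = 4, endian = "little"),
        double = , float64 = readBin(bytes, "numeric", n = el$count, size = 8, endian = "little"),
        char = , int8 = readBin(bytes, "integer", n = el$count, size = 1, signed = TRUE, endian = "little"),
        uchar = , uint8 = readBin(bytes, "integer", n = el$count, size = 1, signed = FALSE, endian = "little"),
        short = , int16 = readBin(bytes, "integer", n = el$count, size = 2, signed = TRUE, endian = "little"),
        ushort = , uint16 = readBin(bytes, "integer", n = el$count, size = 2, signed = FALSE, endian = "little"),
        readBin(bytes, "integer", n = el$count, size = 4, endian = "little"))
    }
    as.data.frame(out)
  }

  vert <- NULL
  for (k in seq_along(elements)) {
    el <- elements[[k]]
    want <- (k == vi)
    got <- if (fmt == "ascii") read_element_ascii(el, want) else read_element_binary(el, want)
    if (want) vert <- got
    if (!is.null(vert) && fmt == "binary_little_endian") break
  }
  miss <- setdiff(c("x", "y", "z"), names(vert))
  if (length(miss) > 0)
    stop_bad_arg("parse error in %s: vertex element lacks propert%s %s", path,
                 if (length(miss) > 1) "ies" else "y", paste(miss, collapse = ", "))
  tibble::as_tibble(vert)
}

read_xyz <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    stop_bad_arg("empty cloud: %s has no data lines", path, class = "tlscarbon_empty_cloud")
  toks <- strsplit(trimws(lines), "[,;[:space:]]+")
  nt <- vapply(toks, length, integer(1))
  bad <- which(nt < 3)
  if (length(bad) > 0)
    stop_bad_arg("parse error in %s line %d: expected at least 3 columns, got %d",
                 path, bad[1], nt[bad[1]])
  xyz <- suppressWarnings(vapply(toks, function(t) as.numeric(t[1:3]), numeric(3)))
  bad <- which(apply(xyz, 2, function(v) any(is.na(v))))
  if (length(bad) > 0)
    stop_bad_arg("parse error in %s line %d: non-numeric coordinate token", path, bad[1])
  tibble::tibble(x = xyz[1, ], y = xyz[2, ], z = xyz[3, ])
}

read_las <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, open = "rb")
  on.exit(close(con))
  raw <- readBin(con, "raw", n = sz)
  if (length(raw) < 227 || rawToChar(raw[1:4]) != "LASF")
    stop_bad_arg("parse error in %s at byte offset 0: not a LAS file (missing LASF signature)", path)
  u8  <- function(off) as.integer(raw[off + 1])
  u16 <- function(off) readBin(raw[off + 1:2], "integer", size = 2, signed = FALSE, endian = "little")
  u32 <- function(off) sum(as.numeric(as.integer(raw[off + 1:4])) * 256^(0:3))
  dbl <- function(off) readBin(raw[off + 1:8], "numeric", size = 8, endian = "little")
  ver <- c(u8(24), u8(25))
  pt_offset <- u32(96)
  pt_format <- u8(104)
  pt_len <- u16(105)
  npts <- u32(107)
  if (npts == 0 && ver[1] == 1 && ver[2] >= 4 && length(raw) >= 255) {
    npts <- sum(as.numeric(as.integer(raw[247 + 1:8])) * 256^(0:7))
  }
  if (pt_format > 3)
    stop_bad_arg("parse error in %s: LAS point format %d unsupported (formats 0-3 only)",
                 path, pt_format)
  scale <- c(dbl(131), dbl(139), dbl(147))
  offst <- c(dbl(155), dbl(163), dbl(171))
  need <- pt_offset + npts * pt_len
  if (length(raw) < need)
    stop_bad_arg("parse error in %s at byte offset %d: truncated point data (need %d bytes)",
                 path, length(raw), need)
  if (npts == 0) return(tibble::tibble(x = numeric(0), y = numeric(0), z = numeric(0)))
  base <- pt_offset + pt_len * (seq_len(npts) - 1)
  get_i32 <- function(field_off) {
    idx <- rep(base + field_off, each = 4) + rep(1:4, npts)
    readBin(raw[idx], "integer", n = npts, size = 4, endian = "little")
  }
  tibble::tibble(x = get_i32(0) * scale[1] + offst[1],
                 y = get_i32(4) * scale[2] + offst[2],
                 z = get_i32(8) * scale[3] + offst[3])
}

#' Read a tree metadata table
#'
#' Expects a CSV with header columns `site`, `tree_id`, `planting_year`,
#' `scan_year`; computes `age = scan_year - planting_year` and rejects rows
#' whose scan year is not after the planting year.
#'
#' @param path Path to a UTF-8 CSV file.
#' @return A tibble with one row per tree and an added `age` column (years).
#' @export
read_tree_table <- function(path) {
  if (!file.exists(path)) stop_bad_arg("file does not exist: %s", path)
  if (file.info(path)$size == 0)
    stop_bad_arg("schema error in %s: file is empty", path)
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  tree_records(tab, source = path)
}

#' @rdname read_tree_table
#' @param records A data frame with the same required columns (for in-memory
#'   tables, e.g. from [generate_site()]).
#' @param source Label used in error messages.
#' @export
tree_records <- function(records, source = "tree table") {
  required <- c("site", "tree_id", "planting_year", "scan_year")
  miss <- setdiff(required, names(records))
  if (length(miss) > 0)
    stop_bad_arg("schema error in %s: missing column(s) %s", source, paste(miss, collapse = ", "))
  if (nrow(records) == 0)
    stop_bad_arg("schema error in %s: no data rows", source)
  records <- tibble::as_tibble(records)
  for (cc in c("planting_year", "scan_year")) {
    if (!is.numeric(records[[cc]]))
      stop_bad_arg("schema error in %s: column '%s' is not numeric", source, cc)
  }
  bad <- which(records$scan_year <= records$planting_year)
  if (length(bad) > 0)
    stop_bad_arg("invalid tree record row(s) %s in %s: scan_year must be after planting_year",
                 paste(bad, collapse = ", "), source)
  dplyr::mutate(records, age = .data$scan_year - .data$planting_year)
}
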
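#' Read a PCD point-cloud file
#'
#' Supports PCD VERSION 0.7 headers with `ascii` and `binary` (little-endian)
#' data sections. Fields `x`, `y`, `z` are required; any further fields (e.g.
#' `intensity`, `label`) are skipped. `binary_compressed` files are rejected:
#' the LZF codec is out of scope.
#'
#' @param path path to a `.pcd` file.
#' @return A `pointcloud` tibble, one row per stored point, order preserved.
#' @export
read_pcd <- function(path) {
  if (!file.exists(path)) stop("read_pcd: no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)

  hdr <- list()
  n_header_lines <- 0
  repeat {
    line <- readLines(con, n = 1, warn = FALSE)
    if (length(line) == 0) stop("read_pcd: truncated header in ", path)
    n_header_lines <- n_header_lines + 1
    if (n_header_lines > 100) stop("read_pcd: header not terminated by DATA line")
    if (grepl("^\\s*#", line) || !nzchar(trimws(line))) next
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    key <- toupper(tok[1])
    hdr[[key]] <- tok[-1]
    if (key == "DATA") break
  }

  for (req in c("FIELDS", "SIZE", "TYPE", "COUNT", "POINTS", "DATA")) {
    if (is.null(hdr[[req]])) {
      stop("read_pcd: malformed header, missing ", req, " line")
    }
  }
  fields <- hdr$FIELDS
  sizes <- as.integer(hdr$SIZE)
  types <- toupper(hdr$TYPE)
  counts <- as.integer(hdr$COUNT)
  if (length(sizes) != length(fields) || length(types) != length(fields) ||
      length(counts) != length(fields)) {
    stop("read_pcd: FIELDS/SIZE/TYPE/COUNT length mismatch in header")
  }
  if (!all(c("x", "y", "z") %in% fields)) {
    stop("read_pcd: header FIELDS line lacks x y z (got: ",
         paste(fields, collapse = " "), ")")
  }
  n_pts <- as.integer(hdr$POINTS[1])
  dialect <- tolower(hdr$DATA[1])

  if (n_pts == 0) return(pointcloud())

  if (dialect == "ascii") {
    raw_lines <- readLines(con, warn = FALSE)
    raw_lines <- raw_lines[nzchar(trimws(raw_lines))]
    if (length(raw_lines) < n_pts) {
      stop("read_pcd: expected ", n_pts, " data lines, found ", length(raw_lines))
    }
    raw_lines <- raw_lines[seq_len(n_pts)]
    n_vals <- sum(counts)
    vals <- scan(text = raw_lines, what = double(), quiet = TRUE)
    if (length(vals) != n_pts * n_vals) {
      stop("read_pcd: data section field-count mismatch (line values != header)")
    }
    m <- matrix(vals, nrow = n_pts, ncol = n_vals, byrow = TRUE)
    # column offset of each field start within a record
    offs <- cumsum(c(0, counts))[seq_along(fields)] + 1
    ix <- offs[match("x", fields)]
    iy <- offs[match("y", fields)]
    iz <- offs[match("z", fields)]
    return(pointcloud(x = m[, ix], y = m[, iy], z = m[, iz]))
  }

  if (dialect == "binary") {
    rec_size <- sum(sizes * counts)
    blob <- readBin(con, "raw", n = rec_size * n_pts)
    if (length(blob) < rec_size * n_pts) {
      stop("read_pcd: binary data section truncated")
    }
    byte_offs <- cumsum(c(0, sizes * counts))[seq_along(fields)]
    get_field <- function(name) {
      i <- match(name, fields)
      off <- byte_offs[i]
      sz <- sizes[i]
      what <- switch(types[i], F = "double", I = "integer", U = "integer",
                     stop("read_pcd: unknown TYPE ", types[i]))
      idx <- as.vector(outer(seq_len(sz), (seq_len(n_pts) - 1) * rec_size + off, "+"))
      readBin(blob[idx], what = what, n = n_pts, size = sz,
              endian = "little", signed = !(types[i] == "U" && sz < 4))
    }
    return(pointcloud(x = get_field("x"), y = get_field("y"), z = get_field("z")))
  }

  if (dialect == "binary_compressed") {
    stop("read_pcd: binary_compressed PCD is not supported (LZF codec out of scope)")
  }
  stop("read_pcd: unknown DATA dialect '", dialect, "'")
}

#' Write a point cloud to a PCD file
#'
#' Emits a PCD VERSION 0.7 file with fields `x y z` stored as float32 (the
#' conventional on-disk width). The ascii dialect prints 9 significant digits
#' so ascii round-trips preserve coordinates well below the millimetre.
#'
#' @param cloud a point cloud tibble.
#' @param path output path.
#' @param dialect `"ascii"` or `"binary"` (little-endian).
#' @return `path`, invisibly.
#' @export
write_pcd <- function(cloud, path, dialect = c("ascii", "binary")) {
  cloud <- as_pointcloud(cloud)
  dialect <- match.arg(dialect)
  n <- nrow(cloud)
  hdr <- c(
    "# .PCD v0.7 - Point Cloud Data file format",
    "VERSION 0.7",
    "FIELDS x y z",
    "SIZE 4 4 4",
    "TYPE F F F",
    "COUNT 1 1 1",
    sprintf("WIDTH %d", n),
    "HEIGHT 1",
    "VIEWPOINT 0 0 0 1 0 0 0",
    sprintf("POINTS %d", n),
    sprintf("DATA %s", dialect)
  )
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  if (n == 0) return(invisible(path))
  if (dialect == "ascii") {
    writeLines(sprintf("%.9g %.9g %.9g", cloud$x, cloud$y, cloud$z), con)
  } else {
    interleaved <- as.vector(t(cloud_matrix(cloud)))
    writeBin(interleaved, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Write per-plant measurement records to CSV
#'
#' @param records tibble of per-plant results with columns `plant_id`,
#'   `x_seed`, `y_seed`, `diameter_m`, `height_m`, `status`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plant_csv <- function(records, path) {
  cols <- c("plant_id", "x_seed", "y_seed", "diameter_m", "height_m", "status")
  miss <- setdiff(cols, names(records))
  if (length(miss) > 0) stop("write_plant_csv: missing column(s): ",
                             paste(miss, collapse = ", "))
  utils::write.csv(as.data.frame(records)[, cols], path, row.names = FALSE)
  invisible(path)
}
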
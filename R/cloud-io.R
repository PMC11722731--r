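# Point-cloud container and readers/writers.
#
# A point cloud is a plain tibble with numeric columns x, y, z (meters,
# right-handed, Z up, local frame — no CRS handling) and an optional integer
# `label` column: -1 = noise/unassigned, >= 0 = tree id (dense from 0),
# -2 = ground, <= -3 = distractor classes (signs, poles, boxes).

#' Coerce and validate a point-cloud tibble
#'
#' @param x data frame (or matrix with 3-4 columns) holding x, y, z in
#'   meters and optionally an integer `label` column.
#' @param source optional provenance string, stored as an attribute.
#' @return a tibble with columns `x`, `y`, `z` (double) and, when present,
#'   `label` (integer).
#' @export
as_point_cloud <- function(x, source = NULL) {
  if (is.matrix(x)) {
    x <- as.data.frame(x)
    names(x) <- c("x", "y", "z", "label")[seq_len(ncol(x))]
  }
  if (!all(c("x", "y", "z") %in% names(x))) {
    abort("a point cloud needs columns x, y, z")
  }
  xs <- as.double(x$x); ys <- as.double(x$y); zs <- as.double(x$z)
  out <- tibble::tibble(x = xs, y = ys, z = zs)
  if (!is.null(x[["label"]])) out$label <- as.integer(x$label)
  if (nrow(out) > 0 && !all(is.finite(out$x) & is.finite(out$y) & is.finite(out$z))) {
    abort("point cloud coordinates must be finite")
  }
  if (!is.null(source)) attr(out, "source") <- source
  out
}

sidecar_path <- function(path) paste0(sub("\\.[A-Za-z0-9]+$", "", path), ".labels.csv")

guess_fmt <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("xyz", "txt", "asc")) "xyz"
  else if (ext == "ply") "ply"
  else if (ext %in% c("las", "laz")) "las"
  else abort(paste0("cannot infer point-cloud format from extension '.", ext, "'"))
}

#' Read a point cloud from disk
#'
#' Supported dialects: ASCII XYZ (whitespace-separated `x y z [label]`
#' columns, `#` comments), ASCII PLY (vertex properties x, y, z and an
#' optional integer `label`), and LAS 1.2 point format 0 (labels carried in
#' the point_source_id field). For any format, a `<stem>.labels.csv` sidecar
#' with columns `point_index,tree_id` (0-based indices) is picked up
#' automatically when the file itself carries no labels.
#'
#' @param path file path.
#' @param fmt one of `"auto"`, `"xyz"`, `"ply"`, `"las"`.
#' @return point-cloud tibble (see [as_point_cloud()]).
#' @export
read_cloud <- function(path, fmt = c("auto", "xyz", "ply", "las")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (fmt == "auto") fmt <- guess_fmt(path)
  cloud <- switch(fmt,
    xyz = read_xyz(path),
    ply = read_ply(path),
    las = read_las(path)
  )
  sc <- sidecar_path(path)
  if (is.null(cloud[["label"]]) && file.exists(sc)) {
    lab <- utils::read.csv(sc)
    if (!all(c("point_index", "tree_id") %in% names(lab))) {
      abort(paste0("label sidecar ", sc, " lacks point_index,tree_id columns"))
    }
    labels <- rep(-1L, nrow(cloud))
    labels[lab$point_index + 1L] <- as.integer(lab$tree_id)
    cloud$label <- labels
  }
  attr(cloud, "source") <- path
  cloud
}

#' Write a point cloud to disk
#'
#' Labels are written inline for `xyz` (4th column) and `ply` (an int
#' property) and in the point_source_id field for `las`; setting
#' `sidecar = TRUE` additionally writes a `<stem>.labels.csv` companion.
#'
#' @param cloud point-cloud tibble.
#' @param path destination path.
#' @param fmt `"auto"` (from extension), `"xyz"`, `"ply"` or `"las"`.
#' @param sidecar also write the label sidecar CSV.
#' @return `path`, invisibly.
#' @export
write_cloud <- function(cloud, path, fmt = c("auto", "xyz", "ply", "las"),
                        sidecar = FALSE) {
  fmt <- match.arg(fmt)
  cloud <- as_point_cloud(cloud)
  if (fmt == "auto") fmt <- guess_fmt(path)
  switch(fmt,
    xyz = write_xyz(cloud, path),
    ply = write_ply(cloud, path),
    las = write_las(cloud, path)
  )
  if (sidecar && !is.null(cloud[["label"]])) {
    utils::write.csv(
      data.frame(point_index = seq_len(nrow(cloud)) - 1L, tree_id = cloud$label),
      sidecar_path(path), row.names = FALSE, quote = FALSE
    )
  }
  invisible(path)
}

# ---- XYZ ----------------------------------------------------------------

read_xyz <- function(path) {
  dat <- tryCatch(
    utils::read.table(path, comment.char = "#", header = FALSE,
                      colClasses = "numeric"),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) {
        return(data.frame())
      }
      abort(paste0("malformed XYZ file ", path, ": ", conditionMessage(e)))
    }
  )
  if (nrow(dat) == 0 || ncol(dat) == 0) {
    return(as_point_cloud(tibble::tibble(x = double(), y = double(), z = double())))
  }
  if (ncol(dat) < 3) abort(paste0("XYZ file ", path, " has fewer than 3 columns"))
  cloud <- tibble::tibble(x = dat[[1]], y = dat[[2]], z = dat[[3]])
  if (ncol(dat) >= 4) cloud$label <- as.integer(dat[[4]])
  as_point_cloud(cloud)
}

write_xyz <- function(cloud, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(cloud) == 0) return(invisible(path))
  if (!is.null(cloud[["label"]])) {
    writeLines(sprintf("%.7f %.7f %.7f %d", cloud$x, cloud$y, cloud$z, cloud$label), con)
  } else {
    writeLines(sprintf("%.7f %.7f %.7f", cloud$x, cloud$y, cloud$z), con)
  }
  invisible(path)
}

# ---- PLY (ascii) --------------------------------------------------------

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || lines[1] != "ply") {
    abort(paste0("malformed PLY file ", path, ": missing 'ply' magic on line 1"))
  }
  end <- match("end_header", lines)
  if (is.na(end)) abort(paste0("malformed PLY file ", path, ": no end_header"))
  header <- lines[seq_len(end)]
  if (!any(grepl("^format ascii", header))) {
    abort(paste0("unsupported PLY encoding in ", path, " (ascii only)"))
  }
  vline <- grep("^element vertex ", header, value = TRUE)
  if (length(vline) != 1) abort(paste0("malformed PLY file ", path, ": need one vertex element"))
  n <- as.integer(sub("^element vertex ", "", vline))
  props <- sub("^property +\\S+ +", "", grep("^property ", header, value = TRUE))
  body <- lines[seq(end + 1, length.out = n)]
  if (n == 0) {
    cloud <- tibble::tibble(x = double(), y = double(), z = double())
    if ("label" %in% props) cloud$label <- integer()
    return(as_point_cloud(cloud))
  }
  dat <- utils::read.table(text = body, header = FALSE)
  if (ncol(dat) != length(props)) {
    abort(paste0("malformed PLY file ", path, ": vertex rows do not match header"))
  }
  names(dat) <- props
  if (!all(c("x", "y", "z") %in% props)) {
    abort(paste0("PLY file ", path, " lacks x/y/z vertex properties"))
  }
  as_point_cloud(dat[, intersect(c("x", "y", "z", "label"), props)])
}

write_ply <- function(cloud, path) {
  has_lab <- !is.null(cloud[["label"]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0", "comment written by streetseg",
    paste("element vertex", nrow(cloud)),
    "property double x", "property double y", "property double z",
    if (has_lab) "property int label",
    "end_header"
  ), con)
  if (nrow(cloud) > 0) {
    if (has_lab) {
      writeLines(sprintf("%.7f %.7f %.7f %d", cloud$x, cloud$y, cloud$z, cloud$label), con)
    } else {
      writeLines(sprintf("%.7f %.7f %.7f", cloud$x, cloud$y, cloud$z), con)
    }
  }
  invisible(path)
}

# ---- LAS 1.2, point format 0 -------------------------------------------
# Coordinates are stored as int32 at a 1e-7 m scale with per-file offsets,
# so local street scenes (extent << 200 m) round-trip below 1e-6 m. Labels
# ride in point_source_id, read back as signed 16-bit so the negative
# noise/ground/distractor classes survive; header file-source-id = 1 marks
# that labels are present.

LAS_SCALE <- 1e-7

write_las <- function(cloud, path) {
  n <- nrow(cloud)
  off <- if (n > 0) c(min(cloud$x), min(cloud$y), min(cloud$z)) else c(0, 0, 0)
  con <- file(path, "wb")
  on.exit(close(con))
  has_lab <- !is.null(cloud[["label"]])

  writeChar("LASF", con, 4, eos = NULL)
  writeBin(as.integer(if (has_lab) 1L else 0L), con, size = 2, endian = "little") # file source id
  writeBin(0L, con, size = 2, endian = "little")                  # global encoding
  writeBin(raw(16), con)                                          # GUID
  writeBin(as.raw(c(1, 2)), con)                                  # version 1.2
  writeChar(formatC("streetseg", width = 32, flag = "-"), con, 32, eos = NULL)
  writeChar(formatC("streetseg", width = 32, flag = "-"), con, 32, eos = NULL)
  writeBin(c(1L, 2026L), con, size = 2, endian = "little")        # day, year
  writeBin(227L, con, size = 2, endian = "little")                # header size
  writeBin(227L, con, size = 4, endian = "little")                # offset to data
  writeBin(0L, con, size = 4, endian = "little")                  # n VLRs
  writeBin(as.raw(0), con)                                        # point format 0
  writeBin(20L, con, size = 2, endian = "little")                 # record length
  writeBin(n, con, size = 4, endian = "little")                   # n points
  writeBin(c(n, 0L, 0L, 0L, 0L), con, size = 4, endian = "little")# by return
  writeBin(rep(LAS_SCALE, 3), con, size = 8, endian = "little")   # scales
  writeBin(off, con, size = 8, endian = "little")                 # offsets
  rng <- if (n > 0) {
    c(max(cloud$x), min(cloud$x), max(cloud$y), min(cloud$y),
      max(cloud$z), min(cloud$z))
  } else rep(0, 6)
  writeBin(rng, con, size = 8, endian = "little")

  if (n > 0) {
    xi <- as.integer(round((cloud$x - off[1]) / LAS_SCALE))
    yi <- as.integer(round((cloud$y - off[2]) / LAS_SCALE))
    zi <- as.integer(round((cloud$z - off[3]) / LAS_SCALE))
    lab <- if (has_lab) cloud$label else rep(0L, n)
    rec <- matrix(as.raw(0), nrow = 20, ncol = n)
    rec[1:4, ]   <- matrix(writeBin(xi, raw(), size = 4, endian = "little"), nrow = 4)
    rec[5:8, ]   <- matrix(writeBin(yi, raw(), size = 4, endian = "little"), nrow = 4)
    rec[9:12, ]  <- matrix(writeBin(zi, raw(), size = 4, endian = "little"), nrow = 4)
    rec[15, ]    <- as.raw(9)  # return 1 of 1
    rec[19:20, ] <- matrix(writeBin(lab, raw(), size = 2, endian = "little"), nrow = 2)
    writeBin(as.vector(rec), con)
  }
  invisible(path)
}

read_las <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- readChar(con, 4, useBytes = TRUE)
  if (!identical(sig, "LASF")) abort(paste0("malformed LAS file ", path, ": bad signature"))
  file_src <- readBin(con, integer(), size = 2, endian = "little", signed = FALSE)
  readBin(con, integer(), size = 2, endian = "little")  # global encoding
  readBin(con, raw(), 16)
  ver <- readBin(con, raw(), 2)
  readChar(con, 64, useBytes = TRUE)                    # sys id + software
  readBin(con, integer(), 2, size = 2, endian = "little")
  readBin(con, integer(), size = 2, endian = "little", signed = FALSE) # header size
  data_off <- readBin(con, integer(), size = 4, endian = "little")
  readBin(con, integer(), size = 4, endian = "little")  # n VLRs
  fmt_id <- as.integer(readBin(con, raw(), 1))
  rec_len <- readBin(con, integer(), size = 2, endian = "little", signed = FALSE)
  n <- readBin(con, integer(), size = 4, endian = "little")
  readBin(con, integer(), 5, size = 4, endian = "little")
  scale <- readBin(con, numeric(), 3, size = 8, endian = "little")
  off <- readBin(con, numeric(), 3, size = 8, endian = "little")
  readBin(con, numeric(), 6, size = 8, endian = "little")
  if (fmt_id != 0) abort(paste0("unsupported LAS point format ", fmt_id, " (only 0)"))

  seek(con, data_off)
  raw_all <- readBin(con, raw(), n * rec_len)
  if (length(raw_all) < n * rec_len) {
    abort(paste0("malformed LAS file ", path, ": truncated point records"))
  }
  if (n == 0) {
    return(as_point_cloud(tibble::tibble(x = double(), y = double(), z = double())))
  }
  recs <- matrix(raw_all, nrow = rec_len)
  int_at <- function(rows) {  # 4 consecutive raw rows -> int32 vector
    readBin(as.vector(recs[rows, , drop = FALSE]), integer(), n,
            size = 4, endian = "little")
  }
  xi <- int_at(1:4); yi <- int_at(5:8); zi <- int_at(9:12)
  lab <- readBin(as.vector(recs[19:20, , drop = FALSE]), integer(), n,
                 size = 2, endian = "little", signed = TRUE)
  cloud <- tibble::tibble(
    x = xi * scale[1] + off[1],
    y = yi * scale[2] + off[2],
    z = zi * scale[3] + off[3]
  )
  if (file_src == 1L) cloud$label <- as.integer(lab)
  as_point_cloud(cloud)
}

# ---- ground -------------------------------------------------------------

#' Remove ground points with a grid-minimum filter
#'
#' Keeps points whose height above the minimum z of their grid cell exceeds
#' `height_margin`. This is deliberately simple plumbing for scenes whose
#' ground has not yet been stripped (a cloth-simulation filter or similar is
#' the usual upstream choice); pre-filtered clouds pass through unchanged
#' apart from margin effects near each cell's lowest points.
#'
#' @param cloud point-cloud tibble.
#' @param cell grid cell size in meters (> 0).
#' @param height_margin height above the cell minimum below which points are
#'   discarded, meters.
#' @return the filtered point cloud (a subset of the input rows).
#' @export
remove_ground <- function(cloud, cell = 1, height_margin = 0.3) {
  stopifnot(cell > 0, height_margin >= 0)
  cloud <- as_point_cloud(cloud)
  if (nrow(cloud) == 0) return(cloud)
  cell_id <- paste(floor(cloud$x / cell), floor(cloud$y / cell))
  cell_min <- tapply(cloud$z, cell_id, min)
  keep <- cloud$z > cell_min[cell_id] + height_margin
  cloud[keep, , drop = FALSE]
}
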
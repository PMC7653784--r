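#' Read a micrograph from MRC, PNG or TIFF
#'
#' MRC2014 modes 0 (int8), 1 (int16), 2 (float32) and 6 (uint16) are
#' supported; the header pixel size (cell length / grid size) is attached as
#' the `pixel_size` attribute when present.  PNG and TIFF images are read
#' through the \pkg{png} and \pkg{tiff} packages; multi-channel images are
#' averaged to one grayscale channel.
#'
#' @param path File path.
#' @param format `"auto"` (by extension and magic bytes), `"mrc"`, `"png"`
#'   or `"tiff"`.
#' @return A numeric matrix (rows = y, top-left origin) with attributes
#'   `pixel_size` (Angstrom per pixel or `NA`) and `source_path`.
#' @export
read_micrograph <- function(path, format = c("auto", "mrc", "png", "tiff")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mrc = , mrcs = , map = "mrc",
                     png = "png", tif = , tiff = "tiff",
                     stop("cannot guess micrograph format from extension '",
                          ext, "'", call. = FALSE))
  }
  m <- switch(format,
    mrc = read_mrc(path),
    png = {
      a <- png::readPNG(path)
      if (length(dim(a)) == 3) a <- apply(a, c(1, 2), mean)
      attr(a, "pixel_size") <- NA_real_
      a
    },
    tiff = {
      a <- tiff::readTIFF(path)
      if (length(dim(a)) == 3) a <- apply(a, c(1, 2), mean)
      attr(a, "pixel_size") <- NA_real_
      a
    })
  attr(m, "source_path") <- path
  m
}

#' Write a micrograph to MRC (mode 2), PNG or TIFF
#'
#' @param m Numeric matrix.
#' @param path Output path; format chosen by extension unless given.
#' @param format `"auto"`, `"mrc"`, `"png"` or `"tiff"`.
#' @param pixel_size Angstrom per pixel, written into the MRC header.
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(m, path, format = c("auto", "mrc", "png", "tiff"),
                             pixel_size = attr(m, "pixel_size") %||% NA_real_) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mrc = , mrcs = , map = "mrc",
                     png = "png", tif = , tiff = "tiff",
                     stop("cannot guess output format from extension '",
                          ext, "'", call. = FALSE))
  }
  switch(format,
    mrc = write_mrc(m, path, pixel_size),
    png = {
      r <- range(m)
      v <- if (diff(r) > 0) (m - r[1]) / diff(r) else m * 0
      png::writePNG(v, path)
    },
    tiff = {
      r <- range(m)
      v <- if (diff(r) > 0) (m - r[1]) / diff(r) else m * 0
      tiff::writeTIFF(v, path, bits.per.sample = 16)
    })
  invisible(path)
}

# -- MRC2014 ------------------------------------------------------------
# 1024-byte header, little endian.  Word 1-3 nx ny nz, word 4 mode,
# words 8-10 mx my mz, words 11-13 cell lengths, word 24 nsymbt.

read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- hdr[1]; ny <- hdr[2]; nz <- hdr[3]; mode <- hdr[4]
  mxyz <- hdr[8:10]
  cell <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  seek(con, 23 * 4)
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (nx < 1 || ny < 1 || nz < 1)
    stop("MRC header field nx/ny/nz invalid (", nx, ", ", ny, ", ", nz, ")",
         call. = FALSE)
  n <- nx * ny
  seek(con, 1024 + nsymbt)
  data <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = n, size = 1, signed = TRUE),
    "1" = readBin(con, "integer", n = n, size = 2, signed = TRUE,
                  endian = "little"),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    "6" = readBin(con, "integer", n = n, size = 2, signed = FALSE,
                  endian = "little"),
    stop("MRC header field mode = ", mode,
         " unsupported (need 0, 1, 2 or 6)", call. = FALSE))
  if (length(data) < n)
    stop("MRC file truncated: expected ", n, " pixels, read ", length(data),
         call. = FALSE)
  # MRC stores rows fastest along x; row 1 of the file is the first y line.
  m <- matrix(as.numeric(data), nrow = ny, ncol = nx, byrow = TRUE)
  attr(m, "pixel_size") <- if (mxyz[1] > 0 && cell[1] > 0)
    cell[1] / mxyz[1] else NA_real_
  m
}

write_mrc <- function(m, path, pixel_size = NA_real_) {
  con <- file(path, "wb")
  on.exit(close(con))
  ny <- nrow(m); nx <- ncol(m)
  ps <- if (is.na(pixel_size)) 1 else pixel_size
  writeBin(as.integer(c(nx, ny, 1L, 2L, 0L, 0L, 0L, nx, ny, 1L)), con,
           size = 4, endian = "little")
  writeBin(as.numeric(c(nx * ps, ny * ps, ps, 90, 90, 90)), con,
           size = 4, endian = "little")
  writeBin(as.integer(c(1L, 2L, 3L)), con, size = 4, endian = "little")
  writeBin(as.numeric(c(min(m), max(m), mean(m))), con, size = 4,
           endian = "little")
  writeBin(as.integer(c(0L, 0L)), con, size = 4, endian = "little") # ispg, nsymbt
  writeBin(raw(100), con)                                           # extra
  writeBin(as.numeric(c(0, 0, 0)), con, size = 4, endian = "little") # origin
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)                  # machst
  writeBin(as.numeric(stats::sd(m)), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")                    # nlabl
  writeBin(raw(800), con)
  writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
  invisible(path)
}

# -- Coordinate formats -------------------------------------------------

#' Write particle boxes in the EMAN .box dialect
#'
#' The .box format uses a lower-left origin, so the internal top-left `y`
#' is flipped using the image height: `y_box = H - (y + h)`.
#'
#' @param picks Tibble with columns `x`, `y`, `w`, `h` (internal top-left
#'   convention).
#' @param path Output path.
#' @param image_height Height of the source micrograph in pixels; required
#'   for the origin flip.
#' @return `path`, invisibly.
#' @export
write_box <- function(picks, path, image_height) {
  if (missing(image_height) || is.null(image_height) || is.na(image_height))
    stop("image_height is required to flip y to the .box lower-left origin",
         call. = FALSE)
  lines <- sprintf("%d\t%d\t%d\t%d", as.integer(picks$x),
                   as.integer(image_height - (picks$y + picks$h)),
                   as.integer(picks$w), as.integer(picks$h))
  writeLines(lines, path)
  invisible(path)
}

#' Read an EMAN .box file back into the internal convention
#'
#' @param path File path.
#' @param image_height Image height in pixels used for the origin flip.
#' @return Tibble with columns `x`, `y`, `w`, `h`.
#' @export
read_box <- function(path, image_height) {
  txt <- readLines(path)
  txt <- txt[nzchar(trimws(txt))]
  if (!length(txt))
    return(tibble::tibble(x = integer(), y = integer(),
                          w = integer(), h = integer()))
  f <- do.call(rbind, lapply(strsplit(txt, "\\s+"), as.integer))
  tibble::tibble(x = f[, 1], y = image_height - (f[, 2] + f[, 4]),
                 w = f[, 3], h = f[, 4])
}

#' Write a RELION coordinate STAR file
#'
#' Emits a `data_` loop with `rlnCoordinateX`, `rlnCoordinateY` (box
#' centers, 0-based pixels) and `rlnAutopickFigureOfMerit`.
#'
#' @param picks Tibble with `x`, `y`, `w`, `h` and optionally `score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_star <- function(picks, path) {
  header <- c("", "data_", "", "loop_",
              "_rlnCoordinateX #1", "_rlnCoordinateY #2",
              "_rlnAutopickFigureOfMerit #3")
  score <- if ("score" %in% names(picks)) picks$score else
    rep(1, nrow(picks))
  rows <- sprintf("%.6f %.6f %.6f", picks$x + picks$w / 2,
                  picks$y + picks$h / 2, score)
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a RELION coordinate STAR file
#'
#' @param path File path.
#' @param w,h Box width and height used to convert centers back to
#'   top-left corners.
#' @return Tibble with `x`, `y`, `w`, `h`, `score`.
#' @export
read_star <- function(path, w, h) {
  txt <- readLines(path)
  cols <- grep("^_rln", txt, value = TRUE)
  names_ <- sub("^_([A-Za-z]+) .*$", "\\1", cols)
  body <- txt[-(1:max(grep("^_rln", txt)))]
  body <- body[nzchar(trimws(body))]
  if (!length(body))
    return(tibble::tibble(x = double(), y = double(), w = double(),
                          h = double(), score = double()))
  f <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  colnames(f) <- names_
  tibble::tibble(x = f[, "rlnCoordinateX"] - w / 2,
                 y = f[, "rlnCoordinateY"] - h / 2, w = w, h = h,
                 score = if ("rlnAutopickFigureOfMerit" %in% names_)
                   f[, "rlnAutopickFigureOfMerit"] else 1)
}

#' Write / read ground-truth coordinates as TSV
#'
#' Columns: `x_center`, `y_center`, `width`, `height`, `label`.
#'
#' @param truth Tibble with `cx`, `cy`, `w`, `h`, `label`.
#' @param path File path.
#' @return `path` (write) or a tibble (read).
#' @export
write_truth <- function(truth, path) {
  df <- data.frame(x_center = truth$cx, y_center = truth$cy,
                   width = truth$w, height = truth$h, label = truth$label)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  tibble::tibble(cx = df$x_center, cy = df$y_center, w = df$width,
                 h = df$height, label = df$label,
                 x = df$x_center - df$width / 2,
                 y = df$y_center - df$height / 2)
}

# -- Config -------------------------------------------------------------

config_defaults <- function() {
  list(window = 227, scale_step = 0.125, stride = NA_real_,
       learning_rate = 1e-4, k = 2, score_threshold = 0.5,
       closeness_tol = 0.2, iou_threshold = 0.3, min_area = 20,
       border_margin = 1, jaccard_min = 0.8, area_frac = 0.7,
       overlap_factor = 1.5, seed = 1,
       classes = c("top_view", "side_view", "irregular",
                   "background", "negative"))
}

#' Load a plain-text key=value pipeline configuration
#'
#' Unknown keys raise an error listing the valid keys; omitted keys take
#' documented defaults (sliding window 227 px, scaling step 0.125,
#' learning rate 1e-4, ...).  `classes` is comma-separated.
#'
#' @param path Path to a text file of `key = value` lines (`#` comments
#'   allowed); may be empty.
#' @return A named list of validated settings.
#' @export
load_config <- function(path) {
  cfg <- config_defaults()
  txt <- if (file.exists(path)) readLines(path) else
    stop("config file not found: ", path, call. = FALSE)
  txt <- sub("#.*$", "", txt)
  txt <- trimws(txt)
  txt <- txt[nzchar(txt)]
  for (line in txt) {
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      stop("malformed config line: '", line, "'", call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(cfg))
      stop("unknown config key '", key, "'; valid keys: ",
           paste(names(cfg), collapse = ", "), call. = FALSE)
    cfg[[key]] <- if (key == "classes")
      trimws(strsplit(val, ",")[[1]]) else as.numeric(val)
  }
  num_pos <- c("window", "scale_step", "learning_rate", "k")
  for (key in num_pos)
    if (!is.na(cfg[[key]]) && cfg[[key]] <= 0)
      stop("config key '", key, "' must be positive, got ", cfg[[key]],
           call. = FALSE)
  if (!is.na(cfg$stride) && cfg$stride <= 0)
    stop("config key 'stride' must be positive, got ", cfg$stride,
         call. = FALSE)
  cfg
}
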
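# Frame-sequence containers and file I/O: multi-page TIFF, PNG frame
# directories, a documented raw stream format, results CSV, JSON configs.

#' Construct a frame sequence
#'
#' A lazy, index-addressable container for a time series of frames sharing
#' dimensions and bit depth. Frames are fetched on demand so an N-frame
#' sequence never needs to reside in memory at once.
#'
#' @param n_frames number of frames.
#' @param get_frame function(i) returning frame i as an integer matrix
#'   (rows = y).
#' @param config an [imaging_config()] or `NULL`.
#' @param source free-text source descriptor.
#' @return A `frame_sequence` object.
#' @export
frame_sequence <- function(n_frames, get_frame, config = NULL,
                           source = "memory") {
  stopifnot(is.function(get_frame), n_frames >= 0)
  structure(list(n_frames = as.integer(n_frames), get_frame = get_frame,
                 config = config, source = source),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("frame_sequence: %d frames from %s\n", x$n_frames, x$source))
  invisible(x)
}

#' Number of frames in a sequence
#' @param frames a `frame_sequence`.
#' @export
n_frames <- function(frames) frames$n_frames

#' Fetch one frame by index
#' @param frames a `frame_sequence`.
#' @param i frame index (1-based acquisition order).
#' @return Integer matrix (rows = y, cols = x).
#' @export
get_frame <- function(frames, i) {
  stopifnot(i >= 1, i <= frames$n_frames)
  frames$get_frame(i)
}

#' Wrap in-memory frames as a sequence
#' @param mats list of integer matrices with identical dimensions.
#' @param config optional [imaging_config()].
#' @export
frames_in_memory <- function(mats, config = NULL) {
  if (length(mats) > 1) {
    d <- vapply(mats, dim, integer(2))
    if (any(d[1, ] != d[1, 1]) || any(d[2, ] != d[2, 1])) {
      stop("format error: frames have mixed dimensions")
    }
  }
  frame_sequence(length(mats), function(i) mats[[i]], config, "memory")
}

.raw_magic <- "VDCS"

#' Write frames to the raw stream format
#'
#' Little-endian container: 4-byte magic `"VDCS"`, one version byte, four
#' 32-bit integers (width, height, bit depth, frame count), one 64-bit float
#' (frame rate in Hz), then the frames in acquisition order, row-major
#' (y rows), 1 byte/px at 8-bit or 2 bytes/px at 16-bit.
#'
#' @param frames a `frame_sequence` or list of integer matrices.
#' @param path output path.
#' @param frame_rate_hz frame rate stored in the header.
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @export
write_raw_stream <- function(frames, path, frame_rate_hz = 1000,
                             bit_depth = 8L) {
  if (is.list(frames) && !inherits(frames, "frame_sequence")) {
    frames <- frames_in_memory(frames)
  }
  stopifnot(bit_depth %in% c(8L, 16L))
  n <- n_frames(frames)
  f1 <- if (n > 0) get_frame(frames, 1) else matrix(0L, 0, 0)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(.raw_magic), con)
  writeBin(as.raw(1L), con)
  writeBin(as.integer(c(ncol(f1), nrow(f1), bit_depth, n)), con,
           size = 4, endian = "little")
  writeBin(as.double(frame_rate_hz), con, size = 8, endian = "little")
  maxval <- 2^bit_depth - 1
  for (i in seq_len(n)) {
    m <- get_frame(frames, i)
    if (min(m) < 0 || max(m) > maxval) {
      stop(sprintf("frame %d has values outside [0, %d] for %d-bit storage",
                   i, maxval, bit_depth))
    }
    v <- as.integer(t(m))
    if (bit_depth == 16L) v[v > 32767L] <- v[v > 32767L] - 65536L
    writeBin(v, con, size = bit_depth / 8, endian = "little")
  }
  invisible(path)
}

.open_raw <- function(path, config) {
  con <- file(path, "rb")
  magic <- rawToChar(readBin(con, "raw", 4))
  if (!identical(magic, .raw_magic)) { close(con); stop("format error: not a raw vdcyto stream") }
  readBin(con, "raw", 1)  # version
  hdr <- readBin(con, "integer", 4, size = 4, endian = "little")
  rate <- readBin(con, "double", 1, size = 8, endian = "little")
  close(con)
  W <- hdr[1]; H <- hdr[2]; bits <- hdr[3]; count <- hdr[4]
  if (!bits %in% c(8L, 16L)) stop("format error: unsupported bit depth ", bits)
  .validate_dims(W, H, config)
  bytes <- bits / 8
  offset0 <- 4 + 1 + 16 + 8
  frame_bytes <- W * H * bytes
  frame_sequence(count, function(i) {
    con <- file(path, "rb"); on.exit(close(con))
    seek(con, offset0 + (i - 1) * frame_bytes)
    v <- readBin(con, "integer", W * H, size = bytes, signed = FALSE,
                 endian = "little")
    matrix(as.integer(v), nrow = H, byrow = TRUE)
  }, config, sprintf("raw:%s (%g fps)", path, rate))
}

.validate_dims <- function(W, H, config) {
  if (!is.null(config) &&
      (W != config$roi_width_px || H != config$roi_height_px)) {
    stop(sprintf("format error: frame dimensions %d x %d do not match config ROI %d x %d",
                 W, H, config$roi_width_px, config$roi_height_px))
  }
}

.open_tiff <- function(path, config) {
  meta <- tiff::readTIFF(path, all = TRUE, payload = FALSE)
  count <- if (is.data.frame(meta)) nrow(meta) else length(meta)
  first <- tiff::readTIFF(path, all = 1, info = TRUE)[[1]]
  bits <- attr(first, "bits.per.sample")
  if (is.null(bits)) bits <- 8L
  if (!bits %in% c(8L, 16L)) stop("format error: unsupported bit depth ", bits)
  scale <- 2^bits - 1
  if (length(dim(first)) > 2) stop("format error: expected grayscale TIFF")
  .validate_dims(ncol(first), nrow(first), config)
  dims <- dim(first)
  frame_sequence(count, function(i) {
    m <- tiff::readTIFF(path, all = i)[[1]]
    if (!identical(dim(m), dims)) stop("format error: frames have mixed dimensions")
    matrix(as.integer(round(m * scale)), nrow = nrow(m))
  }, config, sprintf("tiff:%s", path))
}

.open_png_dir <- function(path, config) {
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop("format error: no PNG frames in ", path)
  first <- png::readPNG(files[1])
  if (length(dim(first)) > 2) stop("format error: expected grayscale PNG frames")
  .validate_dims(ncol(first), nrow(first), config)
  dims <- dim(first)
  frame_sequence(length(files), function(i) {
    m <- png::readPNG(files[i])
    if (length(dim(m)) > 2 || !identical(dim(m), dims)) {
      stop("format error: frames have mixed dimensions")
    }
    matrix(as.integer(round(m * 255)), nrow = nrow(m))
  }, config, sprintf("pngdir:%s", path))
}

#' Open a frame sequence from disk
#'
#' Supported containers: multi-page grayscale TIFF, a directory of
#' lexicographically ordered single-frame PNGs, or the package's raw stream
#' format ([write_raw_stream()]). Frames are yielded in acquisition order and
#' read lazily; dimensions are validated against `config` when supplied.
#'
#' @param path file or directory path.
#' @param config optional [imaging_config()] for validation and calibration.
#' @return A [frame_sequence()].
#' @export
open_sequence <- function(path, config = NULL) {
  if (dir.exists(path)) return(.open_png_dir(path, config))
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) return(.open_tiff(path, config))
  .open_raw(path, config)
}

#' Write frames as a multi-page grayscale TIFF
#'
#' @param frames `frame_sequence` or list of integer matrices.
#' @param path output path.
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @export
write_frames_tiff <- function(frames, path, bit_depth = 8L) {
  if (is.list(frames) && !inherits(frames, "frame_sequence")) {
    frames <- frames_in_memory(frames)
  }
  stopifnot(bit_depth %in% c(8L, 16L))
  scale <- 2^bit_depth - 1
  mats <- lapply(seq_len(n_frames(frames)), function(i) {
    get_frame(frames, i) / scale
  })
  tiff::writeTIFF(mats, path, bits.per.sample = bit_depth)
  invisible(path)
}

# --- results tables ----------------------------------------------------------

.results_header <- "#vdcyto_results_v1"

.results_columns <- c(frame_index = "integer", channel_id = "integer",
                      centroid_x_um = "numeric", centroid_y_um = "numeric",
                      area_um2 = "numeric", perimeter_um = "numeric",
                      deformability = "numeric", brightness = "numeric",
                      aspect_ratio = "numeric", area_ratio = "numeric",
                      accepted = "logical", reject_reason = "character")

#' Create an empty results table
#' @return Zero-row data frame with the fixed per-cell column schema.
#' @export
empty_results_table <- function() {
  out <- lapply(.results_columns, function(cl) vector(cl, 0))
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  class(out) <- c("results_table", "data.frame")
  out
}

#' Write a per-cell results table to CSV
#'
#' Comma-separated, `.` decimal, UTF-8, mandatory header row; the first line
#' stamps the schema version. Numeric columns are written with 12 significant
#' digits so values round-trip beyond 9 significant digits.
#'
#' @param table results table (from [process_sequence()] or [read_results()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  miss <- setdiff(names(.results_columns), names(table))
  if (length(miss)) stop("results table is missing columns: ",
                         paste(miss, collapse = ", "))
  tbl <- table[names(.results_columns)]
  fmt <- tbl
  for (nm in names(.results_columns)) {
    if (.results_columns[[nm]] == "numeric") {
      fmt[[nm]] <- sprintf("%.12g", tbl[[nm]])
      fmt[[nm]][is.na(tbl[[nm]])] <- "NA"
    }
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.results_header, con)
  utils::write.table(fmt, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-cell results table from CSV
#' @param path CSV written by [write_results()].
#' @return A `results_table` data frame.
#' @export
read_results <- function(path) {
  first <- readLines(path, n = 1)
  if (!identical(first, .results_header)) {
    stop(sprintf("results schema mismatch: expected '%s', found '%s'",
                 .results_header, first))
  }
  out <- utils::read.csv(path, skip = 1, stringsAsFactors = FALSE,
                         colClasses = unname(.results_columns),
                         na.strings = "NA")
  out$reject_reason[is.na(out$reject_reason)] <- ""
  class(out) <- c("results_table", "data.frame")
  out
}

#' Write / read an imaging or detection configuration as JSON
#' @param config an [imaging_config()] or [detection_config()].
#' @param path JSON path.
#' @export
write_config <- function(config, path) {
  obj <- c(list(class = class(config)[1]), unclass(config))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- obj$class
  obj$class <- NULL
  class(obj) <- cls
  obj
}
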
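# File formats: MRC micrographs (modes 0/1/2), PNG/TIFF fallbacks,
# EMAN2-style .box coordinate files, and the trained-model container.
#
# Internal coordinates are 0-based with the origin at the top-left corner and
# y running downward; the EMAN2 bottom-left-origin convention is converted at
# the box-file boundary, nowhere else.

MRC_HEADER_BYTES <- 1024L

#' Read a micrograph image
#'
#' Reads MRC 2-D images (modes 0 = int8, 1 = int16, 2 = float32,
#' little-endian; the first section of a stack) and falls back to PNG or TIFF
#' (including 16-bit) by file extension. Pixel size metadata, when present in
#' the MRC header, is attached as attribute `pixel_size`.
#'
#' @param path Path to a `.mrc`/`.mrcs`/`.map`, `.png`, or `.tif`/`.tiff`
#'   file.
#' @return Numeric matrix of intensities, rows = y (downward), cols = x.
#' @export
read_micrograph <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("mrc", "mrcs", "map")) return(read_mrc(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("reading PNG requires the png package", call. = FALSE)
    }
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    return(img)
  }
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the tiff package", call. = FALSE)
    }
    img <- tiff::readTIFF(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    return(img)
  }
  stop("unrecognized micrograph format: .", ext, call. = FALSE)
}

#' @rdname read_micrograph
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  fsize <- file.size(path)
  if (fsize < MRC_HEADER_BYTES) {
    stop("corrupt MRC header: file has only ", fsize, " bytes, need ",
         MRC_HEADER_BYTES, call. = FALSE)
  }
  ints <- readBin(con, "integer", n = 10L, size = 4L, endian = "little")
  nx <- ints[1L]; ny <- ints[2L]; nz <- ints[3L]; mode <- ints[4L]
  if (nx < 1L || ny < 1L || nz < 1L || is.na(nx) || is.na(ny)) {
    stop("corrupt MRC header: bad dimensions at byte offset 0", call. = FALSE)
  }
  cella <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  seek(con, 23L * 4L)
  nsymbt_raw <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  nsymbt <- if (is.na(nsymbt_raw) || nsymbt_raw < 0L) 0L else nsymbt_raw
  bytes_per <- switch(as.character(mode), "0" = 1L, "1" = 2L, "2" = 4L,
                      stop("unsupported MRC mode ", mode,
                           " at byte offset 12", call. = FALSE))
  need <- MRC_HEADER_BYTES + nsymbt + as.numeric(nx) * ny * bytes_per
  if (fsize < need) {
    stop("truncated MRC file: need ", need, " bytes, found ", fsize,
         " (data starts at byte offset ", MRC_HEADER_BYTES + nsymbt, ")",
         call. = FALSE)
  }
  seek(con, MRC_HEADER_BYTES + nsymbt)
  n <- nx * ny
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = n, size = 1L, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                             endian = "little")),
    "2" = readBin(con, "numeric", n = n, size = 4L, endian = "little"))
  if (length(vals) != n) {
    stop("truncated MRC data section in ", path, call. = FALSE)
  }
  m <- t(matrix(vals, nrow = nx, ncol = ny))  # MRC stores x fastest
  if (ints[8L] > 0L && cella[1L] > 0) {
    attr(m, "pixel_size") <- cella[1L] / ints[8L]
  }
  m
}

#' Write a micrograph as MRC mode 2
#'
#' @param micrograph Numeric matrix (rows = y, cols = x).
#' @param path Output path.
#' @param pixel_size Pixel size in Angstrom recorded in the header.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(micrograph, path, pixel_size = 1) {
  assert_grid(micrograph, "micrograph")
  nx <- ncol(micrograph); ny <- nrow(micrograph)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(c(nx, ny, 1L, 2L))               # dims, mode 2 (float32)
  wi(c(0L, 0L, 0L))                   # nstart
  wi(c(nx, ny, 1L))                   # sampling
  wf(c(nx * pixel_size, ny * pixel_size, pixel_size))  # cell in Angstrom
  wf(c(90, 90, 90))
  wi(c(1L, 2L, 3L))                   # column/row/section axes
  wf(c(min(micrograph), max(micrograph), mean(micrograph)))
  wi(c(1L, 0L))                       # ispg, nsymbt
  wi(rep(0L, 25L))                    # extra
  wf(c(0, 0, 0))                      # origin
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(micrograph))
  wi(0L)                              # nlabl
  writeBin(raw(800L), con)            # labels
  wf(as.vector(t(micrograph)))        # x fastest
  invisible(path)
}

#' Write particle coordinates as an EMAN2-style box file
#'
#' One tab-separated line per particle: `x y w h`, where `(x, y)` is the box
#' corner in the EMAN2 convention (origin at the image bottom-left, y
#' upward). The y-axis flip from the internal top-left convention is
#' `y_file = image_height - box_side - y_internal`. Particles are written in
#' descending score order.
#'
#' @param candidates Candidate tibble with `x`, `y` (internal convention) and
#'   optionally `score`.
#' @param box_side Box side in pixels.
#' @param path Output path.
#' @param image_height Micrograph height in pixels (needed for the y flip).
#' @return The number of particles written.
#' @export
write_box_file <- function(candidates, box_side, path, image_height) {
  stopifnot(is.data.frame(candidates))
  box_side <- as.integer(box_side)
  image_height <- as.integer(image_height)
  if (nrow(candidates) > 0L && "score" %in% names(candidates)) {
    candidates <- candidates[order(-candidates$score), , drop = FALSE]
  }
  lines <- if (nrow(candidates) == 0L) character(0) else {
    sprintf("%d\t%d\t%d\t%d", as.integer(candidates$x),
            image_height - box_side - as.integer(candidates$y),
            box_side, box_side)
  }
  writeLines(lines, path)
  length(lines)
}

#' Read an EMAN2-style box file back to internal coordinates
#'
#' @param path Box file path.
#' @param image_height Micrograph height in pixels.
#' @return Tibble with internal 0-based top-left `x`, `y` and the box sides
#'   `box_w`, `box_h`.
#' @export
read_box_file <- function(path, image_height) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble(x = integer(0), y = integer(0), box_w = integer(0),
                  box_h = integer(0)))
  }
  parts <- do.call(rbind, lapply(strsplit(lines, "[\t ]+"), function(p) {
    if (length(p) < 4L) stop("malformed box-file line: ", paste(p, collapse = " "),
                             call. = FALSE)
    as.integer(p[1:4])
  }))
  tibble(x = parts[, 1L],
         y = as.integer(image_height) - parts[, 4L] - parts[, 2L],
         box_w = parts[, 3L], box_h = parts[, 4L])
}

MODEL_FORMAT <- "cryopick_model"
MODEL_VERSION <- 1L

#' Save or load a trained network
#'
#' The container embeds the configuration with the weights (plus a format
#' and version field) so a schedule can never be paired with mismatched
#' parameters.
#'
#' @param state A `cnn_state` or `cnn_fit`.
#' @param path File path.
#' @return `save_network` returns `path` invisibly; `load_network` returns
#'   the `cnn_state`.
#' @export
save_network <- function(state, path) {
  state <- as_cnn_state(state)
  saveRDS(list(format = MODEL_FORMAT, version = MODEL_VERSION,
               config = state$config, params = state$params,
               rng_seed = state$rng_seed),
          path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  obj <- readRDS(path)
  if (!identical(obj$format, MODEL_FORMAT)) {
    stop("not a saved picking model: ", path, call. = FALSE)
  }
  if (!identical(obj$version, MODEL_VERSION)) {
    stop("unsupported model container version ", obj$version, call. = FALSE)
  }
  structure(list(config = obj$config, params = obj$params,
                 rng_seed = obj$rng_seed),
            class = "cnn_state")
}
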
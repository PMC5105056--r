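#' Read a height map from file
#'
#' Supported formats: Gwyddion Simple Field (`gsf`, heights and pixel sizes
#' stored in metres, converted to nm), single-channel TIFF with a JSON sidecar
#' (`<path>.json` holding pixel sizes and the height range used for integer
#' quantization), and plain CSV matrices (heights already in nm; pixel size
#' from an explicit argument or a JSON sidecar).
#'
#' Non-finite pixels are rejected by default; `fill = TRUE` replaces them by
#' their line median via [fill_nonfinite()].
#'
#' @param path Input file path.
#' @param format One of `"gsf"`, `"tiff"`, `"csv"`; default guesses from the
#'   file extension.
#' @param pixel_size Pixel size in nm (scalar or `c(x, y)`); required for CSV
#'   files without a sidecar, ignored for formats that store it.
#' @param fill Replace non-finite pixels by their line median instead of
#'   failing.
#' @return A [heightmap].
#' @seealso [write_heightmap()]
#' @export
read_heightmap <- function(path, format = c("auto", "gsf", "tiff", "csv"),
                           pixel_size = NULL, fill = FALSE) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!file.exists(path)) stop("file not found: ", path)
  hm <- switch(format,
    gsf  = read_gsf(path),
    tiff = read_tiff_hm(path),
    csv  = read_csv_hm(path, pixel_size))
  if (fill) hm$heights <- fill_nonfinite(hm$heights)
  if (!all(is.finite(hm$heights)))
    stop("non-finite heights in ", path,
         "; pass fill = TRUE to repair by line median")
  heightmap(hm$heights, hm$pixel_size, hm$meta)
}

#' Write a height map to file
#'
#' GSF stores 32-bit floats in metres (quantization at float precision, about
#' 1e-7 relative); CSV stores full-precision nm values; TIFF stores 16-bit
#' integers scaled over the height range, with the documented quantization
#' step `range / 65535` and a JSON sidecar recording pixel sizes and range.
#'
#' @param map A [heightmap].
#' @param path Output file path.
#' @param format One of `"gsf"`, `"tiff"`, `"csv"`; default guesses from the
#'   file extension.
#' @return Invisibly, `path`.
#' @export
write_heightmap <- function(map, path, format = c("auto", "gsf", "tiff", "csv")) {
  stopifnot_heightmap(map)
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  switch(format,
    gsf  = write_gsf(map, path),
    tiff = write_tiff_hm(map, path),
    csv  = write_csv_hm(map, path))
  invisible(path)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    gsf = "gsf", tif = "tiff", tiff = "tiff", csv = "csv",
    stop("cannot guess height-map format from extension '", ext,
         "'; pass format = explicitly"))
}

sidecar_path <- function(path) paste0(path, ".json")

## ---- GSF (Gwyddion Simple Field 1.0) ----

read_gsf <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  magic <- "Gwyddion Simple Field 1.0\n"
  nm_magic <- nchar(magic)
  if (length(raw) < nm_magic ||
      rawToChar(raw[seq_len(nm_magic)]) != magic)
    stop("not a GSF file (magic line missing): ", path)
  nul <- which(raw == as.raw(0L))[1L]
  if (is.na(nul)) stop("malformed GSF header (no NUL padding): ", path)
  header_len <- nul - 1L
  header <- strsplit(rawToChar(raw[seq_len(header_len)]), "\n",
                     fixed = TRUE)[[1L]][-1L]
  kv <- list()
  for (line in header[nzchar(header)]) {
    parts <- regmatches(line, regexpr(" = ", line, fixed = TRUE),
                        invert = TRUE)[[1L]]
    if (length(parts) != 2L)
      stop("malformed GSF header line '", line, "' in ", path)
    kv[[parts[[1L]]]] <- parts[[2L]]
  }
  need <- function(key, as = as.numeric) {
    if (is.null(kv[[key]]))
      stop("GSF header missing required field '", key, "' in ", path)
    as(kv[[key]])
  }
  xres <- need("XRes", as.integer)
  yres <- need("YRes", as.integer)
  xreal <- if (is.null(kv$XReal)) 1 else as.numeric(kv$XReal)
  yreal <- if (is.null(kv$YReal)) 1 else as.numeric(kv$YReal)
  data_off <- 4L * (header_len %/% 4L) + 4L
  n <- xres * yres
  if (length(raw) < data_off + 4L * n)
    stop("GSF data truncated (expected ", n, " float32 values) in ", path)
  vals <- readBin(raw[(data_off + 1L):length(raw)], "double",
                  n = n, size = 4L, endian = "little")
  heights <- matrix(vals, nrow = yres, ncol = xres, byrow = TRUE)
  list(heights = heights * 1e9,          # metres -> nm
       pixel_size = c(xreal / xres, yreal / yres) * 1e9,
       meta = kv[setdiff(names(kv), c("XRes", "YRes", "XReal", "YReal"))])
}

write_gsf <- function(map, path) {
  h <- map$heights
  header <- sprintf(
    "Gwyddion Simple Field 1.0\nXRes = %d\nYRes = %d\nXReal = %.17g\nYReal = %.17g\nXYUnits = m\nZUnits = m\nTitle = %s\n",
    ncol(h), nrow(h),
    ncol(h) * map$pixel_size_x * 1e-9,
    nrow(h) * map$pixel_size_y * 1e-9,
    if (!is.null(map$meta$Title)) map$meta$Title else "tipshape export")
  hraw <- charToRaw(header)
  pad <- 4L * (length(hraw) %/% 4L) + 4L - length(hraw)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hraw, con)
  writeBin(raw(pad), con)
  writeBin(as.numeric(t(h)) * 1e-9, con, size = 4L, endian = "little")
}

## ---- CSV matrix + JSON sidecar ----

read_csv_hm <- function(path, pixel_size) {
  heights <- as.matrix(utils::read.csv(path, header = FALSE))
  if (!is.numeric(heights))
    stop("CSV height map is not numeric: ", path)
  dimnames(heights) <- NULL
  meta <- list()
  if (is.null(pixel_size)) {
    sc <- sidecar_path(path)
    if (!file.exists(sc))
      stop("CSV height map needs a pixel size: pass pixel_size = ",
           "or provide a sidecar ", sc)
    side <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (is.null(side$pixel_size_x_nm))
      stop("sidecar ", sc, " missing field 'pixel_size_x_nm'")
    pixel_size <- c(side$pixel_size_x_nm,
                    side$pixel_size_y_nm %||% side$pixel_size_x_nm)
    meta <- side[setdiff(names(side),
                         c("pixel_size_x_nm", "pixel_size_y_nm"))]
  }
  list(heights = heights, pixel_size = pixel_size, meta = meta)
}

write_csv_hm <- function(map, path) {
  utils::write.table(map$heights, path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(pixel_size_x_nm = map$pixel_size_x,
         pixel_size_y_nm = map$pixel_size_y, unit = "nm"),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
}

## ---- TIFF (16-bit, range-scaled) + JSON sidecar ----

read_tiff_hm <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("TIFF height map requires sidecar ", sc,
         " (pixel sizes and height range)")
  side <- jsonlite::read_json(sc, simplifyVector = TRUE)
  for (f in c("pixel_size_x_nm", "pixel_size_y_nm", "z_min_nm", "z_max_nm"))
    if (is.null(side[[f]])) stop("sidecar ", sc, " missing field '", f, "'")
  img <- tiff::readTIFF(path)
  if (length(dim(img)) != 2L)
    stop("expected a single-channel TIFF: ", path)
  heights <- side$z_min_nm + img * (side$z_max_nm - side$z_min_nm)
  list(heights = heights,
       pixel_size = c(side$pixel_size_x_nm, side$pixel_size_y_nm),
       meta = side[setdiff(names(side),
                           c("pixel_size_x_nm", "pixel_size_y_nm",
                             "z_min_nm", "z_max_nm"))])
}

write_tiff_hm <- function(map, path) {
  h <- map$heights
  zmin <- min(h); zmax <- max(h)
  scaled <- if (zmax > zmin) (h - zmin) / (zmax - zmin) else h * 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(pixel_size_x_nm = map$pixel_size_x,
         pixel_size_y_nm = map$pixel_size_y, unit = "nm",
         z_min_nm = zmin, z_max_nm = zmax, bits = 16L,
         quantization_step_nm = (zmax - zmin) / 65535),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
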
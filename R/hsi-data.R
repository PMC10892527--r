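# ENVI cube / label raster I/O and scene assembly.
#
# Coordinate convention throughout: 0-based (line, sample) indices,
# line-major; ENVI "lines" = H (array rows), "samples" = W (array columns).

.enviTypes <- data.frame(
  code = c(1L, 2L, 3L, 4L, 5L, 12L),
  what = c("integer", "integer", "integer", "double", "double", "integer"),
  size = c(1L, 2L, 4L, 4L, 8L, 2L),
  signed = c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE))

.headerPath <- function(path) {
  if (grepl("\\.hdr$", path)) return(path)
  hdr <- paste0(path, ".hdr")
  if (file.exists(hdr)) return(hdr)
  alt <- sub("\\.[^.]+$", ".hdr", path)
  if (alt != path && file.exists(alt)) return(alt)
  hdr
}

.dataPath <- function(path) {
  if (!grepl("\\.hdr$", path)) return(path)
  sub("\\.hdr$", "", path)
}

# Parse an ENVI header into a named list; values inside { } may span lines.
.parseENVIHeader <- function(hdrFile) {
  txt <- readLines(hdrFile, warn = FALSE)
  if (length(txt) == 0L || !grepl("^ENVI", txt[1L]))
    stopf("'%s' is not an ENVI header (missing ENVI magic)", hdrFile)
  body <- paste(txt[-1L], collapse = "\n")
  out <- list()
  pos <- 1L
  pat <- "(?m)^\\s*([a-zA-Z][a-zA-Z0-9 _()]*?)\\s*=\\s*"
  m <- gregexpr(pat, body, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(out)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    keyRaw <- substr(body, starts[i], starts[i] + lens[i] - 1L)
    key <- tolower(trimws(sub("=\\s*$", "", keyRaw)))
    valStart <- starts[i] + lens[i]
    valEnd <- if (i < length(starts)) starts[i + 1L] - 1L else nchar(body)
    val <- substr(body, valStart, valEnd)
    if (grepl("^\\s*\\{", val)) {
      val <- sub("^\\s*\\{", "", val)
      val <- sub("\\}[\\s\\S]*$", "", val, perl = TRUE)
    }
    out[[key]] <- trimws(gsub("\n", " ", val))
  }
  out
}

#' Read a hyperspectral cube from an ENVI header/data pair
#'
#' Accepts all three ENVI interleaves (BSQ, BIL, BIP) and integer or
#' floating-point data types; values are returned as doubles.
#'
#' @param path the data file (with `<path>.hdr` alongside) or the `.hdr`
#'   itself.
#' @return A [HyperspectralCube-class].
#' @seealso [writeENVICube()]
#' @export
readENVICube <- function(path) {
  hdrFile <- .headerPath(path)
  if (!file.exists(hdrFile)) stopf("ENVI header '%s' not found", hdrFile)
  hdr <- .parseENVIHeader(hdrFile)
  for (k in c("lines", "samples", "bands"))
    if (is.null(hdr[[k]])) stopf("ENVI header missing required field '%s'", k)
  H <- as.integer(hdr$lines); W <- as.integer(hdr$samples); C <- as.integer(hdr$bands)
  dtype <- as.integer(hdr[["data type"]] %||% "4")
  ti <- match(dtype, .enviTypes$code)
  if (is.na(ti)) stopf("unsupported ENVI data type %d", dtype)
  interleave <- tolower(hdr$interleave %||% "bsq")
  endian <- if ((hdr[["byte order"]] %||% "0") == "1") "big" else "little"
  wl <- if (!is.null(hdr$wavelength)) {
    as.double(strsplit(hdr$wavelength, ",")[[1L]])
  } else as.double(seq_len(C))
  if (length(wl) != C)
    stopf("header lists %d wavelengths for %d bands", length(wl), C)

  dataFile <- .dataPath(path)
  if (!file.exists(dataFile)) stopf("ENVI data file '%s' not found", dataFile)
  n <- H * W * C
  v <- readBin(dataFile, what = .enviTypes$what[ti], n = n + 1L,
               size = .enviTypes$size[ti], signed = .enviTypes$signed[ti],
               endian = endian)
  if (length(v) < n)
    stopf("ENVI data truncated: %d values for a declared %dx%dx%d cube",
          length(v), H, W, C)
  v <- as.double(v[seq_len(n)])
  arr <- switch(interleave,
    bsq = aperm(array(v, c(W, H, C)), c(2L, 1L, 3L)),
    bil = aperm(array(v, c(W, C, H)), c(3L, 1L, 2L)),
    bip = aperm(array(v, c(C, W, H)), c(3L, 2L, 1L)),
    stopf("unknown interleave '%s'", interleave))
  hyperspectralCube(arr, wl, meta = list(source = dataFile, interleave = interleave))
}

#' Write a hyperspectral cube as an ENVI header/data pair
#'
#' @param cube a [HyperspectralCube-class].
#' @param path output data file; `<path>.hdr` is written alongside.
#' @param interleave `"bsq"` (default), `"bil"` or `"bip"`.
#' @param dataType ENVI data-type code; the default 5 (64-bit float) makes
#'   the round trip bit-exact.
#' @return `path`, invisibly.
#' @export
writeENVICube <- function(cube, path, interleave = c("bsq", "bil", "bip"),
                          dataType = 5L) {
  stopifnot(is(cube, "HyperspectralCube"))
  interleave <- match.arg(interleave)
  ti <- match(as.integer(dataType), .enviTypes$code)
  if (is.na(ti)) stopf("unsupported ENVI data type %d", dataType)
  d <- dim(cube@values)
  v <- switch(interleave,
    bsq = as.vector(aperm(cube@values, c(2L, 1L, 3L))),
    bil = as.vector(aperm(cube@values, c(2L, 3L, 1L))),
    bip = as.vector(aperm(cube@values, c(3L, 2L, 1L))))
  hdr <- c(
    "ENVI",
    "description = {grassRNet hyperspectral cube}",
    sprintf("samples = %d", d[2L]),
    sprintf("lines = %d", d[1L]),
    sprintf("bands = %d", d[3L]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", .enviTypes$code[ti]),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    "wavelength = {",
    paste(" ", paste(sprintf("%.17g", cube@wavelengths), collapse = ", ")),
    "}")
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(path, "wb")
  on.exit(close(con))
  if (.enviTypes$what[ti] == "integer") v <- as.integer(round(v))
  writeBin(v, con, size = .enviTypes$size[ti], endian = "little")
  invisible(path)
}

#' Read / write a label raster
#'
#' Label maps travel as a single-band integer ENVI raster plus a YAML class
#' table sidecar (`<path>.classes.yml` holding id, name, color), or as an
#' RGB PNG keyed by the class-table colours.
#'
#' @param path data path as in [readENVICube()].
#' @return A [LabelMap-class].
#' @export
readENVILabels <- function(path) {
  cube <- readENVICube(path)
  if (dim(cube@values)[3L] != 1L) stopf("label raster must be single-band")
  codes <- matrix(as.integer(cube@values[, , 1L]), nrow = dim(cube@values)[1L])
  side <- paste0(.dataPath(path), ".classes.yml")
  ct <- NULL
  if (file.exists(side)) {
    y <- yaml::read_yaml(side)
    ct <- data.frame(id = vapply(y, function(e) as.integer(e$id), 0L),
                     name = vapply(y, function(e) as.character(e$name), ""),
                     color = vapply(y, function(e) as.character(e$color), ""),
                     stringsAsFactors = FALSE)
  }
  labelMap(codes, ct)
}

#' @rdname readENVILabels
#' @param labels a [LabelMap-class].
#' @export
writeENVILabels <- function(labels, path) {
  stopifnot(is(labels, "LabelMap"))
  arr <- array(as.double(labels@codes), c(dim(labels@codes), 1L))
  writeENVICube(hyperspectralCube(arr, 1), path, dataType = 3L)
  ct <- labels@classTable
  y <- lapply(seq_len(nrow(ct)), function(i)
    list(id = ct$id[i], name = ct$name[i], color = ct$color[i]))
  yaml::write_yaml(y, paste0(path, ".classes.yml"))
  invisible(path)
}

#' @rdname readENVILabels
#' @export
writeLabelPNG <- function(labels, path) {
  stopifnot(is(labels, "LabelMap"))
  ct <- labels@classTable
  pal <- c("#000000", ct$color)            # index 1 = unlabeled (black)
  rgb <- grDevices::col2rgb(pal) / 255
  idx <- match(labels@codes, c(0L, ct$id))
  img <- array(0, c(nrow(labels@codes), ncol(labels@codes), 3L))
  for (ch in 1:3) img[, , ch] <- matrix(rgb[ch, idx], nrow = nrow(labels@codes))
  png::writePNG(img, path)
  invisible(path)
}

#' @rdname readENVILabels
#' @param classTable class table used to map PNG colours back to ids.
#' @export
readLabelPNG <- function(path, classTable) {
  img <- png::readPNG(path)
  rgb <- grDevices::col2rgb(c("#000000", classTable$color)) / 255
  key <- round(img[, , 1] * 1e4) * 1e8 + round(img[, , 2] * 1e4) * 1e4 +
    round(img[, , 3] * 1e4)
  palKey <- round(rgb[1, ] * 1e4) * 1e8 + round(rgb[2, ] * 1e4) * 1e4 +
    round(rgb[3, ] * 1e4)
  idx <- match(key, palKey)
  if (any(is.na(idx))) stopf("PNG contains colours not present in the class table")
  labelMap(matrix(c(0L, classTable$id)[idx], nrow = nrow(key)), classTable)
}

#' Centre-crop a cube (and aligned labels)
#'
#' The crop window is centred; when the margin is odd the extra pixel is
#' dropped from the bottom/right (ties break toward the top-left).
#'
#' @param cube a [HyperspectralCube-class].
#' @param h,w target lines and samples, `h <= H`, `w <= W`.
#' @param labels optional aligned [LabelMap-class], cropped with the same
#'   window.
#' @return the cropped cube, or `list(cube, labels)` when labels are given.
#' @export
centerCrop <- function(cube, h, w, labels = NULL) {
  stopifnot(is(cube, "HyperspectralCube"))
  d <- dim(cube@values)
  if (h > d[1L] || w > d[2L])
    stopf("crop %dx%d exceeds cube extent %dx%d", h, w, d[1L], d[2L])
  r0 <- (d[1L] - h) %/% 2L
  c0 <- (d[2L] - w) %/% 2L
  rows <- seq.int(r0 + 1L, r0 + h)
  cols <- seq.int(c0 + 1L, c0 + w)
  out <- hyperspectralCube(cube@values[rows, cols, , drop = FALSE],
                           cube@wavelengths, cube@meta)
  if (is.null(labels)) return(out)
  stopifnot(is(labels, "LabelMap"))
  if (!all(dim(labels@codes) == d[1:2]))
    stopf("label raster %dx%d does not match cube %dx%d",
          nrow(labels@codes), ncol(labels@codes), d[1L], d[2L])
  list(cube = out,
       labels = labelMap(labels@codes[rows, cols, drop = FALSE], labels@classTable))
}

#' Stitch quadrat tiles into one scene
#'
#' Places tiles row-major on a `rows x cols` grid: tile `i` of the list goes
#' to block row `(i-1) %/% cols`, block column `(i-1) %% cols`. All tiles
#' must agree in shape and wavelengths. Six 150x150x256 quadrat crops on a
#' 3x2 grid yield the 450x300x256 study scene.
#'
#' @param cubes list of [HyperspectralCube-class] tiles.
#' @param rows,cols grid shape with `rows * cols == length(cubes)`.
#' @param labels optional list of aligned [LabelMap-class] tiles.
#' @return stitched cube, or `list(cube, labels)`.
#' @export
stitchQuadrats <- function(cubes, rows, cols, labels = NULL) {
  if (rows * cols != length(cubes))
    stopf("%d tiles do not fill a %dx%d grid", length(cubes), rows, cols)
  d0 <- dim(cubes[[1L]]@values)
  wl0 <- cubes[[1L]]@wavelengths
  for (tile in cubes) {
    if (!all(dim(tile@values) == d0))
      stopf("tile shape %s does not match %s",
            paste(dim(tile@values), collapse = "x"), paste(d0, collapse = "x"))
    if (length(tile@wavelengths) != length(wl0) ||
        any(tile@wavelengths != wl0))
      stopf("tile band/wavelength mismatch")
  }
  out <- array(0, c(rows * d0[1L], cols * d0[2L], d0[3L]))
  outLab <- if (!is.null(labels)) matrix(0L, rows * d0[1L], cols * d0[2L])
  for (i in seq_along(cubes)) {
    bi <- (i - 1L) %/% cols
    bj <- (i - 1L) %% cols
    rIdx <- bi * d0[1L] + seq_len(d0[1L])
    cIdx <- bj * d0[2L] + seq_len(d0[2L])
    out[rIdx, cIdx, ] <- cubes[[i]]@values
    if (!is.null(labels)) outLab[rIdx, cIdx] <- labels[[i]]@codes
  }
  cube <- hyperspectralCube(out, wl0, cubes[[1L]]@meta)
  if (is.null(labels)) return(cube)
  list(cube = cube, labels = labelMap(outLab, labels[[1L]]@classTable))
}

#' Mean spectrum over a region of interest
#'
#' Per-band arithmetic mean over the selected pixels — how reference
#' reflectance curves are extracted from ~300 pure ROI pixels per class.
#'
#' @param cube a [HyperspectralCube-class].
#' @param mask logical `H x W` matrix, or a 2-column matrix of 0-based
#'   (line, sample) indices.
#' @return A [Spectrum-class].
#' @export
roiMeanSpectrum <- function(cube, mask) {
  stopifnot(is(cube, "HyperspectralCube"))
  d <- dim(cube@values)
  if (is.logical(mask)) {
    if (!all(dim(mask) == d[1:2])) stopf("mask must match the cube's H x W")
    lin <- which(mask)
  } else {
    mask <- as.matrix(mask)
    if (ncol(mask) != 2L) stopf("index mask must have 2 columns")
    lin <- (mask[, 1L] + 1L) + d[1L] * mask[, 2L]
  }
  if (length(lin) == 0L) stopf("empty ROI mask")
  flat <- matrix(cube@values, d[1L] * d[2L], d[3L])
  Spectrum(colMeans(flat[lin, , drop = FALSE]), cube@wavelengths)
}
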
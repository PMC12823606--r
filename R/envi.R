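#' Read a hypercube from an ENVI raster
#'
#' Reads the de facto hyperspectral interchange format: a plain-text `.hdr`
#' header next to a flat binary payload. Supported payloads are 32-bit
#' (data type 4) or 64-bit (data type 5) IEEE floats in band-sequential
#' (BSQ) interleave, the layout `write_envi()` produces. The wavelength list
#' in the header becomes the cube's grid.
#'
#' @param header_path path to the `.hdr` file; the payload is the same path
#'   without the `.hdr` extension.
#' @return A [hypercube].
#' @seealso [write_envi()]
#' @export
read_envi <- function(header_path) {
  if (!file.exists(header_path)) stop("ENVI header not found: ", header_path)
  data_path <- sub("\\.hdr$", "", header_path)
  if (identical(data_path, header_path) || !file.exists(data_path))
    stop("ENVI payload not found for header: ", header_path)
  h <- parse_envi_header(header_path)
  for (key in c("samples", "lines", "bands", "data type", "interleave"))
    if (is.null(h[[key]])) stop("ENVI header missing required field: ", key)
  samples <- as.integer(h[["samples"]])
  lines <- as.integer(h[["lines"]])
  bands <- as.integer(h[["bands"]])
  dtype <- as.integer(h[["data type"]])
  if (!dtype %in% c(4L, 5L)) stop("unsupported ENVI data type: ", dtype)
  if (tolower(h[["interleave"]]) != "bsq")
    stop("unsupported ENVI interleave: ", h[["interleave"]])
  byte_order <- if (is.null(h[["byte order"]])) 0L else as.integer(h[["byte order"]])
  endian <- if (byte_order == 0L) "little" else "big"
  size <- if (dtype == 4L) 4L else 8L
  n <- as.double(samples) * lines * bands
  payload_bytes <- file.info(data_path)$size
  if (payload_bytes != n * size)
    stop(sprintf("ENVI payload size mismatch: header declares %d x %d x %d (%.0f bytes), file has %.0f",
                 lines, samples, bands, n * size, payload_bytes))
  con <- file(data_path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = n, size = size, endian = endian)
  # BSQ: sample fastest, then line, then band; internal order (line, sample, band)
  cube_data <- aperm(array(vals, dim = c(samples, lines, bands)), c(2L, 1L, 3L))
  wl <- h[["wavelength"]]
  if (is.null(wl)) stop("ENVI header missing wavelength list")
  wl <- as.numeric(strsplit(gsub("[{}]", "", wl), ",")[[1]])
  if (length(wl) != bands)
    stop("ENVI wavelength list length does not match band count")
  hypercube(cube_data, wl, meta = list(source = data_path))
}

parse_envi_header <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (length(txt) == 0L || !grepl("^ENVI", txt[1L]))
    stop("not an ENVI header (missing ENVI magic line): ", path)
  # re-join { ... } blocks that span lines
  joined <- character(0)
  buf <- ""
  open <- FALSE
  for (line in txt[-1L]) {
    if (open) {
      buf <- paste(buf, line)
      if (grepl("\\}", line)) { joined <- c(joined, buf); open <- FALSE }
    } else if (grepl("\\{", line) && !grepl("\\}", line)) {
      buf <- line; open <- TRUE
    } else joined <- c(joined, line)
  }
  joined <- joined[grepl("=", joined)]
  keys <- tolower(trimws(sub("=.*$", "", joined)))
  vals <- trimws(sub("^[^=]*=", "", joined))
  stats::setNames(as.list(vals), keys)
}

#' Write a hypercube as an ENVI raster
#'
#' Writes a band-sequential little-endian float payload at `path` and a text
#' header at `path.hdr` carrying the shape, data type and wavelength list.
#' Writing then reading reproduces the payload bit-exactly; with the default
#' 32-bit storage, values of a double-precision cube are rounded to float32
#' on the first write (the second round trip is the identity).
#'
#' @param cube a [hypercube].
#' @param path payload destination; header goes to `paste0(path, ".hdr")`.
#' @param data_type 4 (float32, default) or 5 (float64).
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path, data_type = 4L) {
  stopifnot(inherits(cube, "hypercube"))
  if (!data_type %in% c(4L, 5L)) stop("data_type must be 4 (float32) or 5 (float64)")
  d <- dim(cube$data)
  size <- if (data_type == 4L) 4L else 8L
  hdr <- c(
    "ENVI",
    "description = {lymphspec hyperspectral cube}",
    paste0("samples = ", d[2L]),
    paste0("lines = ", d[1L]),
    paste0("bands = ", d[3L]),
    "header offset = 0",
    "file type = ENVI Standard",
    paste0("data type = ", data_type),
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = Nanometers",
    paste0("wavelength = {", paste(format(cube$wavelengths, trim = TRUE),
                                   collapse = ", "), "}")
  )
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(aperm(cube$data, c(2L, 1L, 3L))), con,
           size = size, endian = "little")
  invisible(path)
}
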
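#' Voltage image-stack container
#'
#' A `voltage_stack` holds a fluorescence movie `F[x, y, t]` together with its
#' sampling interval, pixel pitch and region-of-interest mask. After
#' [precondition_stack()] the per-pixel time series of masked-in pixels lie in
#' \eqn{[0, 1]} and masked-out pixels are exactly zero at all frames.
#'
#' @param data numeric 3-D array with dimensions `(nx, ny, nt)` (x fastest).
#' @param dt_ms frame interval in ms (default 1, i.e. 1 kHz).
#' @param pitch_mm pixel edge length in mm (default 0.7).
#' @param mask logical `nx x ny` matrix, `TRUE` = tissue. Default all `TRUE`.
#' @param meta free-form provenance list.
#' @return an object of class `voltage_stack`.
#' @export
voltage_stack <- function(data, dt_ms = 1, pitch_mm = 0.7, mask = NULL,
                          meta = list()) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (dt_ms <= 0) stop("dt_ms must be > 0")
  if (pitch_mm <= 0) stop("pitch_mm must be > 0")
  nx <- dim(data)[1L]; ny <- dim(data)[2L]
  if (is.null(mask)) mask <- matrix(TRUE, nx, ny)
  mask <- matrix(as.logical(mask), nx, ny)
  structure(list(data = data, dt_ms = dt_ms, pitch_mm = pitch_mm,
                 mask = mask, meta = meta),
            class = "voltage_stack")
}

#' @export
print.voltage_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voltage_stack> %d x %d px, %d frames (dt %.3g ms, pitch %.3g mm), %d/%d masked-in\n",
              d[1L], d[2L], d[3L], x$dt_ms, x$pitch_mm, sum(x$mask), d[1L] * d[2L]))
  invisible(x)
}

# stack data as a T x P matrix (time down the rows, pixels x-fastest).
stack_as_matrix <- function(stack) {
  d <- dim(stack$data)
  m <- aperm(stack$data, c(3L, 1L, 2L))
  dim(m) <- c(d[3L], d[1L] * d[2L])
  m
}

# inverse of stack_as_matrix
matrix_as_stack_data <- function(m, nx, ny) {
  nt <- nrow(m)
  dim(m) <- c(nt, nx, ny)
  aperm(m, c(2L, 3L, 1L))
}

#' Number of frames, spatial dimensions and time axis of a stack
#' @param stack a [voltage_stack()].
#' @return `stack_dims`: integer vector `(nx, ny, nt)`; `stack_times`: numeric
#'   vector of frame times in ms.
#' @export
stack_dims <- function(stack) dim(stack$data)

#' @rdname stack_dims
#' @export
stack_times <- function(stack) (seq_len(dim(stack$data)[3L]) - 1) * stack$dt_ms

#' Scalar per-pixel map with an "unassigned" sentinel
#'
#' Thin wrapper around a numeric `nx x ny` matrix; `NA` is the sentinel for
#' pixels that carry no value (masked out, no event, no resolvable time).
#'
#' @param values numeric matrix (or `NULL` for an empty map).
#' @param nx,ny spatial dimensions, required when `values` is `NULL`.
#' @param units unit string stored as an attribute (default `"ms"`).
#' @param pitch_mm pixel pitch carried along for gradient computations.
#' @return a `scalar_map` (numeric matrix subclass).
#' @export
scalar_map <- function(values = NULL, nx = NULL, ny = NULL, units = "ms",
                       pitch_mm = NA_real_) {
  if (is.null(values)) {
    stopifnot(!is.null(nx), !is.null(ny))
    values <- matrix(NA_real_, nx, ny)
  }
  structure(as.matrix(values), units = units, pitch_mm = pitch_mm,
            class = c("scalar_map", "matrix", "array"))
}

#' @export
print.scalar_map <- function(x, ...) {
  cat(sprintf("<scalar_map> %d x %d px (%s), %d defined, range [%s, %s]\n",
              nrow(x), ncol(x), attr(x, "units") %||% "?", sum(!is.na(x)),
              format(suppressWarnings(min(x, na.rm = TRUE))),
              format(suppressWarnings(max(x, na.rm = TRUE)))))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Raw-binary + JSON sidecar dialect.
## Binary file: little-endian float32 or uint16, x fastest, then y, then t.
## Sidecar: JSON object {nx, ny, nt, dt_ms, pitch_mm, dtype}.
## ---------------------------------------------------------------------------

#' Read / write an image stack in the raw-binary + JSON sidecar dialect
#'
#' The binary payload is little-endian `float32` or `uint16`, x fastest, then
#' y, then t; the JSON sidecar records `nx, ny, nt, dt_ms, pitch_mm, dtype`.
#'
#' @param path path to the binary payload; the sidecar is `paste0(path, ".json")`
#'   unless given explicitly.
#' @param sidecar optional explicit sidecar path.
#' @return [read_raw_stack()] returns a [voltage_stack()];
#'   [write_raw_stack()] returns `path` invisibly.
#' @export
read_raw_stack <- function(path, sidecar = NULL) {
  sidecar <- sidecar %||% paste0(path, ".json")
  if (!file.exists(path)) stop("stack file not found: ", path)
  if (!file.exists(sidecar)) stop("sidecar not found: ", sidecar)
  sc <- jsonlite::fromJSON(sidecar)
  for (f in c("nx", "ny", "nt", "dt_ms", "pitch_mm", "dtype"))
    if (is.null(sc[[f]])) stop("sidecar missing field: ", f)
  n <- sc$nx * sc$ny * sc$nt
  con <- file(path, "rb"); on.exit(close(con))
  raw <- switch(sc$dtype,
    float32 = readBin(con, "numeric", n = n, size = 4L, endian = "little"),
    uint16  = readBin(con, "integer", n = n, size = 2L, signed = FALSE,
                      endian = "little"),
    stop("unsupported dtype: ", sc$dtype))
  if (length(raw) < n) stop("stack file truncated: expected ", n, " values")
  arr <- array(as.numeric(raw), dim = c(sc$nx, sc$ny, sc$nt))
  voltage_stack(arr, dt_ms = sc$dt_ms, pitch_mm = sc$pitch_mm,
                meta = list(source = path, dtype = sc$dtype))
}

#' @rdname read_raw_stack
#' @param stack a [voltage_stack()] to serialize.
#' @param dtype `"float32"` (default) or `"uint16"`.
#' @export
write_raw_stack <- function(stack, path, dtype = "float32") {
  d <- dim(stack$data)
  sc <- list(nx = d[1L], ny = d[2L], nt = d[3L], dt_ms = stack$dt_ms,
             pitch_mm = stack$pitch_mm, dtype = dtype)
  con <- file(path, "wb")
  v <- as.vector(stack$data)
  if (dtype == "float32") {
    writeBin(v, con, size = 4L, endian = "little")
  } else if (dtype == "uint16") {
    writeBin(as.integer(round(v)), con, size = 2L, endian = "little")
  } else {
    close(con); stop("unsupported dtype: ", dtype)
  }
  close(con)
  jsonlite::write_json(sc, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a region-of-interest mask from a plain-text file
#'
#' Supports headerless CSV (one row per y, nonzero = in) and ASCII PGM ("P2",
#' nonzero = in). Binary image formats are intentionally not supported.
#'
#' @param path file path (`.csv` or `.pgm`).
#' @return logical matrix indexed `[x, y]`.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  if (grepl("\\.pgm$", path, ignore.case = TRUE)) {
    txt <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
    if (txt[1L] != "P2") stop("only ASCII PGM (P2) masks are supported")
    nxy <- as.integer(txt[2:3])
    vals <- as.integer(txt[-(1:4)])
    m <- matrix(vals, nrow = nxy[1L], ncol = nxy[2L]) # column-per-row of file
    return(m != 0L)
  }
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  # CSV rows are y, columns are x; transpose to [x, y]
  t(m != 0)
}

#' Export a scalar map as CSV
#'
#' Writes the map as a `ny`-row, `nx`-column headerless CSV (row = y), with
#' empty cells for the unassigned sentinel.
#' @param map a [scalar_map()].
#' @param path output path.
#' @export
write_map_csv <- function(map, path) {
  utils::write.table(t(unclass(map)), path, sep = ",", na = "",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Render a scalar map as a PNG isochrone image
#'
#' Filled image with isolines every `isoline_ms` (10 ms by default, the
#' conventional isochrone spacing). Silently skips when no PNG device is
#' available (headless build without cairo).
#' @param map a [scalar_map()].
#' @param path output path.
#' @param isoline_ms isoline spacing in map units.
#' @export
write_map_png <- function(map, path, isoline_ms = 10) {
  ok <- tryCatch({
    grDevices::png(path, width = 480, height = 480)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) return(invisible(NULL))
  on.exit(grDevices::dev.off())
  z <- unclass(map)
  graphics::image(seq_len(nrow(z)), seq_len(ncol(z)), z,
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "x", ylab = "y", useRaster = TRUE)
  rng <- range(z, na.rm = TRUE)
  if (diff(rng) > isoline_ms) {
    lv <- seq(ceiling(rng[1L] / isoline_ms) * isoline_ms, rng[2L], by = isoline_ms)
    graphics::contour(seq_len(nrow(z)), seq_len(ncol(z)), z, levels = lv,
                      add = TRUE, drawlabels = FALSE)
  }
  invisible(path)
}
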
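## Material label codes shared by all phantom constructors.
LABEL_AIR <- 0L
LABEL_TISSUE <- 1L
LABEL_BONE <- 2L
LABEL_AGAROSE <- 3L

#' Voxelized complex-refractive-index volume
#'
#' Holds the decrement delta and absorption index beta of the complex
#' refractive index n = 1 - delta + i*beta on a regular voxel grid, plus a
#' material label grid (0 = air, 1 = soft tissue, 2 = bone, 3 = agarose).
#' Axis order is (slice, row, column); the beam travels along the column
#' axis at projection angle 0.
#'
#' @param delta 3D numeric array, refractive decrement per voxel (>= 0)
#' @param beta 3D numeric array, absorption index per voxel (>= 0)
#' @param labels 3D integer array of material labels, same shape
#' @param voxel_size voxel edge length in um
#' @param meta optional list of provenance metadata (e.g. the phantom spec)
#' @return object of class `complex_index_volume`
#' @export
complex_index_volume <- function(delta, beta, labels, voxel_size, meta = list()) {
  stopifnot(is.array(delta), is.array(beta), is.array(labels))
  if (!identical(dim(delta), dim(beta)) || !identical(dim(delta), dim(labels)))
    stop("delta, beta and labels must have identical shapes")
  if (length(dim(delta)) != 3L) stop("volumes must be 3D (slice, row, column)")
  if (!all(is.finite(delta)) || !all(is.finite(beta)))
    stop("delta and beta must be finite everywhere")
  if (any(delta < 0) || any(beta < 0))
    stop("delta and beta must be non-negative")
  stopifnot(is.numeric(voxel_size), length(voxel_size) == 1, voxel_size > 0)
  storage.mode(labels) <- "integer"
  structure(
    list(delta = delta, beta = beta, labels = labels,
         voxel_size = voxel_size, meta = meta),
    class = "complex_index_volume"
  )
}

#' @export
print.complex_index_volume <- function(x, ...) {
  d <- dim(x$delta)
  tab <- table(factor(x$labels, levels = 0:3,
                      labels = c("air", "tissue", "bone", "agarose")))
  cat(sprintf("<complex_index_volume> %d x %d x %d voxels @ %g um\n",
              d[1], d[2], d[3], x$voxel_size))
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Delta-to-beta ratio map of a volume
#'
#' gamma = delta/beta where beta > 0, NA elsewhere.
#' @param volume a `complex_index_volume`
#' @return 3D array of gamma values
#' @export
gamma_map <- function(volume) {
  g <- volume$delta / volume$beta
  g[volume$beta == 0] <- NA_real_
  g
}

## ---- serialization: raw float64 little-endian + JSON sidecar -------------
## The field-standard container here would be multi-page TIFF; no TIFF codec
## is available in the target R environment, so stacks and volumes are
## written as raw little-endian doubles with a JSON sidecar carrying shape
## and geometry metadata.

#' @keywords internal
write_raw_array <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(x), con, size = 8, endian = "little")
  invisible(path)
}

#' @keywords internal
read_raw_array <- function(path, dim) {
  n <- prod(dim)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, what = "double", n = n, size = 8, endian = "little")
  if (length(v) != n) stop("raw array file truncated: ", path)
  array(v, dim = dim)
}

#' Write a complex-index volume to disk
#'
#' Writes `<stem>_delta.raw`, `<stem>_beta.raw`, `<stem>_labels.raw`
#' (little-endian float64) plus `<stem>.json` with shape, voxel size and
#' metadata.
#'
#' @param volume a `complex_index_volume`
#' @param stem path stem (without extension)
#' @return the sidecar path, invisibly
#' @export
write_volume <- function(volume, stem) {
  stopifnot(inherits(volume, "complex_index_volume"))
  write_raw_array(volume$delta, paste0(stem, "_delta.raw"))
  write_raw_array(volume$beta, paste0(stem, "_beta.raw"))
  write_raw_array(as.double(volume$labels), paste0(stem, "_labels.raw"))
  side <- list(shape = dim(volume$delta), voxel_size_um = volume$voxel_size,
               meta = volume$meta)
  path <- paste0(stem, ".json")
  jsonlite::write_json(side, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a complex-index volume written by [write_volume()]
#'
#' @param stem path stem used when writing
#' @return a `complex_index_volume`
#' @export
read_volume <- function(stem) {
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  shp <- as.integer(side$shape)
  delta <- read_raw_array(paste0(stem, "_delta.raw"), shp)
  beta <- read_raw_array(paste0(stem, "_beta.raw"), shp)
  labels <- read_raw_array(paste0(stem, "_labels.raw"), shp)
  storage.mode(labels) <- "integer"
  complex_index_volume(delta, beta, labels, side$voxel_size_um,
                       meta = as.list(side$meta))
}
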
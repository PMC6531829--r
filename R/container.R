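#' @title HDIM HDF5 container
#' @description
#' On-disk layout (format version 1):
#' \preformatted{
#' /format_version            int
#' /counts                    5-D integer dataset (row, col, spectral, pol, time)
#' /axes/wavelength_centers   double, nm
#' /axes/time_bin_edges       double, ns
#' /axes/polarization_labels  string pair
#' /meta/excitation_wavelength  double, nm
#' /meta/g_factor               double
#' /meta/pixel_size             double, um
#' /meta/provenance             JSON string
#' }
#' Counts round-trip bit-exactly (integers); axes within double precision.
#' @name hdim_container
NULL

hdim_format_version <- 1L

#' Write an HDIM stack to an HDF5 container
#'
#' @param stack An `hdim_stack`.
#' @param path Output file path; overwritten if it exists.
#' @return `path`, invisibly.
#' @seealso [read_hdim()], [hdim_container]
#' @export
write_hdim <- function(stack, path) {
  stopifnot(inherits(stack, "hdim_stack"))
  validate_hdim_stack(stack)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5write(hdim_format_version, path, "format_version")
  counts <- stack$counts
  storage.mode(counts) <- "integer"
  rhdf5::h5createDataset(path, "counts", dims = dim(counts),
                         storage.mode = "integer", chunk = dim(counts),
                         level = 4)
  rhdf5::h5write(counts, path, "counts")
  rhdf5::h5createGroup(path, "axes")
  rhdf5::h5write(stack$wavelength_centers, path, "axes/wavelength_centers")
  rhdf5::h5write(stack$time_bin_edges, path, "axes/time_bin_edges")
  rhdf5::h5write(stack$polarization_labels, path, "axes/polarization_labels")
  rhdf5::h5createGroup(path, "meta")
  rhdf5::h5write(stack$excitation_wavelength, path, "meta/excitation_wavelength")
  rhdf5::h5write(stack$g_factor, path, "meta/g_factor")
  rhdf5::h5write(stack$pixel_size, path, "meta/pixel_size")
  rhdf5::h5write(as.character(jsonlite::toJSON(stack$provenance,
                                               auto_unbox = TRUE,
                                               digits = NA, null = "null")),
                 path, "meta/provenance")
  invisible(path)
}

#' Read an HDIM stack from an HDF5 container
#'
#' Validates the format version and the presence of every required dataset;
#' a missing dataset is reported by name.
#'
#' @param path Path to a file written by [write_hdim()].
#' @return An `hdim_stack`.
#' @export
read_hdim <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  present <- rhdf5::h5ls(path)
  names_present <- file.path(gsub("^/$", "", present$group), present$name)
  names_present <- sub("^/", "", names_present)
  required <- c("format_version", "counts", "axes/wavelength_centers",
                "axes/time_bin_edges", "axes/polarization_labels",
                "meta/excitation_wavelength", "meta/g_factor",
                "meta/pixel_size", "meta/provenance")
  missing <- setdiff(required, names_present)
  if (length(missing)) {
    stop("container is missing required dataset(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ver <- as.integer(rhdf5::h5read(path, "format_version"))
  if (!identical(ver, hdim_format_version)) {
    stop(sprintf("container format version %d not supported (expected %d).",
                 ver, hdim_format_version), call. = FALSE)
  }
  prov <- tryCatch(
    jsonlite::fromJSON(as.character(rhdf5::h5read(path, "meta/provenance")),
                       simplifyVector = TRUE),
    error = function(e) list())
  if (is.null(prov)) prov <- list()
  hdim_stack(
    counts = rhdf5::h5read(path, "counts"),
    wavelength_centers = as.numeric(rhdf5::h5read(path, "axes/wavelength_centers")),
    time_bin_edges = as.numeric(rhdf5::h5read(path, "axes/time_bin_edges")),
    excitation_wavelength = as.numeric(rhdf5::h5read(path, "meta/excitation_wavelength")),
    g_factor = as.numeric(rhdf5::h5read(path, "meta/g_factor")),
    pixel_size = as.numeric(rhdf5::h5read(path, "meta/pixel_size")),
    polarization_labels = as.character(rhdf5::h5read(path, "axes/polarization_labels")),
    provenance = as.list(prov)
  )
}

#' Import a multi-page TIFF of count planes
#'
#' Reads raw count planes from a multi-page TIFF plus a sidecar JSON axis
#' descriptor. Page `k` (1-based) holds the spatial plane for spectral bin
#' `s`, polarization `p`, time bin `t` with
#' `k = s + (p - 1) * n_spectral + (t - 1) * n_spectral * n_pol`
#' (spectral fastest, then polarization, then time — the canonical HDSS
#' flattening order).
#'
#' @param tiff_path Multi-page TIFF of integer count planes.
#' @param json_path Sidecar JSON with fields `wavelength_centers`,
#'   `time_bin_edges`, and optionally `polarization_labels`,
#'   `excitation_wavelength`, `g_factor`, `pixel_size`.
#' @return An `hdim_stack`.
#' @export
read_hdim_tiff <- function(tiff_path, json_path) {
  if (!file.exists(tiff_path)) stop("file not found: ", tiff_path, call. = FALSE)
  if (!file.exists(json_path)) stop("sidecar not found: ", json_path, call. = FALSE)
  meta <- jsonlite::fromJSON(json_path, simplifyVector = TRUE)
  for (f in c("wavelength_centers", "time_bin_edges")) {
    if (is.null(meta[[f]])) {
      stop("sidecar JSON is missing required field: ", f, call. = FALSE)
    }
  }
  pages <- tiff::readTIFF(tiff_path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  ns <- length(meta$wavelength_centers)
  npol <- length(meta$polarization_labels %||% c("parallel", "perpendicular"))
  nt <- length(meta$time_bin_edges) - 1L
  if (length(pages) != ns * npol * nt) {
    stop(sprintf("TIFF has %d pages but the axis descriptor implies %d (= %d spectral x %d polarization x %d time).",
                 length(pages), ns * npol * nt, ns, npol, nt), call. = FALSE)
  }
  sh <- dim(pages[[1]])
  counts <- array(0L, dim = c(sh[1], sh[2], ns, npol, nt))
  k <- 1L
  for (t in seq_len(nt)) for (p in seq_len(npol)) for (s in seq_len(ns)) {
    # page order written spectral-fastest; loop nesting inverted accordingly
    counts[, , s, p, t] <- pages[[(t - 1L) * npol * ns + (p - 1L) * ns + s]]
    k <- k + 1L
  }
  hdim_stack(
    counts,
    wavelength_centers = meta$wavelength_centers,
    time_bin_edges = meta$time_bin_edges,
    excitation_wavelength = meta$excitation_wavelength %||% 840,
    g_factor = meta$g_factor %||% 1,
    pixel_size = meta$pixel_size %||% 0.78,
    polarization_labels = meta$polarization_labels %||% c("parallel", "perpendicular"),
    provenance = list(source = tiff_path, sidecar = json_path)
  )
}

#' Export a stack as a multi-page TIFF plus JSON sidecar
#'
#' Inverse of [read_hdim_tiff()]; counts are written as 16- or 32-bit
#' integer planes in the canonical page order.
#'
#' @param stack An `hdim_stack`.
#' @param tiff_path,json_path Output paths.
#' @return `tiff_path`, invisibly.
#' @export
write_hdim_tiff <- function(stack, tiff_path, json_path) {
  d <- dim(stack$counts)
  mx <- max(stack$counts)
  bits <- if (mx < 2^16) 16L else 32L
  pages <- vector("list", prod(d[3:5]))
  k <- 1L
  for (t in seq_len(d[5])) for (p in seq_len(d[4])) for (s in seq_len(d[3])) {
    pages[[k]] <- stack$counts[, , s, p, t] / (2^bits - 1)  # writeTIFF expects [0,1]
    k <- k + 1L
  }
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = bits, reduce = FALSE)
  jsonlite::write_json(
    list(wavelength_centers = stack$wavelength_centers,
         time_bin_edges = stack$time_bin_edges,
         polarization_labels = stack$polarization_labels,
         excitation_wavelength = stack$excitation_wavelength,
         g_factor = stack$g_factor,
         pixel_size = stack$pixel_size),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(tiff_path)
}

#' Export a feature map as 32-bit TIFF with a JSON sidecar
#'
#' Values are min-max scaled into \[0, 1\] and written at 32-bit depth; the
#' sidecar `<path>.json` records `feature_name`, `units`, `value_min`,
#' `value_max` for exact de-scaling, and masked pixels (written as 0) as a
#' run-length-free index list when any exist.
#'
#' @param map A `feature_map`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_feature_map_tiff <- function(map, path) {
  stopifnot(inherits(map, "feature_map"))
  v <- map$values
  vv <- v[map$mask]
  lo <- if (length(vv)) min(vv) else 0
  hi <- if (length(vv)) max(vv) else 1
  scl <- if (hi > lo) hi - lo else 1
  v <- (v - lo) / scl
  v[!map$mask] <- 0
  tiff::writeTIFF(v, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(feature_name = map$feature_name, units = map$units,
         value_min = lo, value_max = hi,
         masked_pixels = which(!map$mask)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a feature map written by [write_feature_map_tiff()]
#'
#' @param path TIFF path (sidecar `<path>.json` must sit beside it).
#' @return A `feature_map`.
#' @export
read_feature_map_tiff <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"), simplifyVector = TRUE)
  v <- tiff::readTIFF(path)
  v <- v * (meta$value_max - meta$value_min) + meta$value_min
  mask <- matrix(TRUE, nrow(v), ncol(v))
  if (length(meta$masked_pixels)) mask[meta$masked_pixels] <- FALSE
  new_feature_map(v, meta$feature_name, meta$units, mask)
}

#' Export a 1-D spectroscopic summary as CSV
#'
#' @param summary A `spectro_summary` (see [emission_spectrum()]).
#' @param path Output CSV path. The header names the abscissa/ordinate units.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(summary, path) {
  stopifnot(inherits(summary, "spectro_summary"))
  utils::write.csv(as.data.frame(summary$data), path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
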
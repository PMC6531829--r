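#' Default wavelength axis
#'
#' Bin centers for a grating spectrograph covering `bandwidth` nm in
#' `n` uniform bins starting at `start` nm.
#'
#' @param n Number of spectral bins.
#' @param start First bin edge, nm.
#' @param bandwidth Total covered bandwidth, nm.
#' @return Numeric vector of `n` bin centers, nm.
#' @export
default_wavelength_centers <- function(n = 16, start = 420, bandwidth = 200) {
  width <- bandwidth / n
  start + width * (seq_len(n) - 0.5)
}

#' Default TCSPC time axis
#'
#' Uniform time-bin edges spanning one laser repetition period.
#'
#' @param n Number of time bins.
#' @param period Repetition period, ns (12.5 ns corresponds to an 80 MHz
#'   Ti:sapphire oscillator).
#' @return Numeric vector of `n + 1` edges, ns.
#' @export
default_time_edges <- function(n = 64, period = 12.5) {
  seq(0, period, length.out = n + 1)
}

#' Construct an HDIM photon-count stack
#'
#' The central container: a 5-D nonnegative photon-count histogram indexed
#' `(row, col, spectral, polarization, time)` with calibrated wavelength and
#' time axes and acquisition metadata. The default detection geometry is
#' 16 spectral bins x 2 polarization states x 64 time bins, i.e. 2048
#' histogram values per pixel (the hyperdimensional spectral signature, HDSS).
#'
#' @param counts 5-D array of nonnegative integers,
#'   dim `(rows, cols, n_spectral, 2, n_time)`.
#' @param wavelength_centers Strictly increasing bin-center wavelengths, nm.
#' @param time_bin_edges Strictly increasing, uniform-width bin edges, ns,
#'   spanning one repetition period (length `n_time + 1`).
#' @param excitation_wavelength Excitation wavelength, nm (metadata).
#' @param g_factor Detection-balance correction G (> 0); applied only in
#'   anisotropy estimation.
#' @param pixel_size Pixel size, micrometres (metadata).
#' @param polarization_labels Ordered pair naming the polarization channels.
#' @param provenance Free-form list recording how the stack was made
#'   (simulation parameters, seed, source file, ...).
#' @return An object of class `hdim_stack`.
#' @export
hdim_stack <- function(counts,
                       wavelength_centers = default_wavelength_centers(dim(counts)[3]),
                       time_bin_edges = default_time_edges(dim(counts)[5]),
                       excitation_wavelength = 840,
                       g_factor = 1,
                       pixel_size = 0.78,
                       polarization_labels = c("parallel", "perpendicular"),
                       provenance = list()) {
  x <- structure(
    list(
      counts = counts,
      wavelength_centers = as.numeric(wavelength_centers),
      time_bin_edges = as.numeric(time_bin_edges),
      excitation_wavelength = as.numeric(excitation_wavelength),
      g_factor = as.numeric(g_factor),
      pixel_size = as.numeric(pixel_size),
      polarization_labels = as.character(polarization_labels),
      provenance = provenance
    ),
    class = "hdim_stack"
  )
  validate_hdim_stack(x)
}

#' Validate an HDIM stack
#'
#' Checks the container invariants: 5-D nonnegative counts, axis lengths
#' matching the count dimensions, strictly increasing wavelength centers,
#' strictly increasing uniform time edges, positive G-factor.
#'
#' @param x An `hdim_stack`.
#' @return `x`, invisibly unchanged, or an error describing the violation.
#' @export
validate_hdim_stack <- function(x) {
  d <- dim(x$counts)
  if (length(d) != 5L) {
    stop("`counts` must be a 5-D array (row, col, spectral, polarization, time); got ",
         length(d), " dimensions.", call. = FALSE)
  }
  if (any(x$counts < 0)) stop("`counts` must be nonnegative.", call. = FALSE)
  if (length(x$wavelength_centers) != d[3]) {
    stop(sprintf("`wavelength_centers` has length %d but there are %d spectral bins.",
                 length(x$wavelength_centers), d[3]), call. = FALSE)
  }
  if (any(diff(x$wavelength_centers) <= 0)) {
    stop("`wavelength_centers` must be strictly increasing.", call. = FALSE)
  }
  if (d[4] != length(x$polarization_labels)) {
    stop("polarization axis length must match `polarization_labels`.", call. = FALSE)
  }
  if (length(x$time_bin_edges) != d[5] + 1L) {
    stop(sprintf("`time_bin_edges` has length %d but %d time bins need %d edges.",
                 length(x$time_bin_edges), d[5], d[5] + 1L), call. = FALSE)
  }
  dt <- diff(x$time_bin_edges)
  if (any(dt <= 0)) stop("`time_bin_edges` must be strictly increasing.", call. = FALSE)
  if (diff(range(dt)) > 1e-9 * mean(dt)) {
    stop("`time_bin_edges` must have uniform width.", call. = FALSE)
  }
  if (!is.finite(x$g_factor) || x$g_factor <= 0) {
    stop("`g_factor` must be a positive number.", call. = FALSE)
  }
  invisible(x)
}

hdim_axis_names <- c("row", "col", "spectral", "polarization", "time")

#' @export
print.hdim_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<hdim_stack> %d x %d pixels, %d spectral x %d polarization x %d time bins (%d values/pixel)\n",
              d[1], d[2], d[3], d[4], d[5], prod(d[3:5])))
  cat(sprintf("  wavelength: %.1f-%.1f nm | time window: %.2f ns | excitation: %.0f nm | G = %.3g\n",
              min(x$wavelength_centers), max(x$wavelength_centers),
              diff(range(x$time_bin_edges)), x$excitation_wavelength, x$g_factor))
  cat(sprintf("  total photons: %s\n", format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
dim.hdim_stack <- function(x) dim(x$counts)

#' Total photon count of a stack
#' @param stack An `hdim_stack`.
#' @return Total number of recorded photons.
#' @export
total_counts <- function(stack) sum(stack$counts)

#' Axis values of a stack
#'
#' @param stack An `hdim_stack`.
#' @return Named list of the five axis coordinate vectors: row/col indices,
#'   wavelength centers (nm), polarization labels, time-bin centers (ns).
#' @export
hdim_axes <- function(stack) {
  d <- dim(stack$counts)
  list(
    row = seq_len(d[1]),
    col = seq_len(d[2]),
    spectral = stack$wavelength_centers,
    polarization = stack$polarization_labels,
    time = time_bin_centers(stack)
  )
}

#' Time-bin centers of a stack
#' @param stack An `hdim_stack`.
#' @return Numeric vector of bin-center times, ns.
#' @export
time_bin_centers <- function(stack) {
  e <- stack$time_bin_edges
  (utils::head(e, -1) + utils::tail(e, -1)) / 2
}

#' Project a stack by summing over axes
#'
#' Collapses (sums photon counts over) the named axes, retaining the rest in
#' canonical order `(row, col, spectral, polarization, time)`. Photon totals
#' are conserved exactly, and collapses commute: any ordering of axis subsets
#' gives the identical result.
#'
#' @param stack An `hdim_stack`.
#' @param collapse_axes Character vector, subset of
#'   `c("row", "col", "spectral", "polarization", "time")`. Empty means
#'   identity.
#' @return An `hdim_projection`: list with `counts` (array over the retained
#'   axes, or a scalar if all were collapsed), `axes` (named list of retained
#'   axis coordinates) and `retained` (axis names).
#' @examples
#' st <- simulate_stack(uniform_scene(4, 4, "FITC", 10),
#'                      geometry = hdim_geometry(4, 4), seed = 1)
#' img <- project(st, c("spectral", "polarization", "time"))
#' sum(img$counts) == total_counts(st)
#' @export
project <- function(stack, collapse_axes = character()) {
  stopifnot(inherits(stack, "hdim_stack"))
  collapse_axes <- as.character(collapse_axes)
  bad <- setdiff(collapse_axes, hdim_axis_names)
  if (length(bad)) {
    stop(sprintf("unknown axis name(s) %s; valid axes are: %s",
                 paste0("'", bad, "'", collapse = ", "),
                 paste(hdim_axis_names, collapse = ", ")), call. = FALSE)
  }
  keep <- which(!(hdim_axis_names %in% collapse_axes))
  axes <- hdim_axes(stack)
  if (length(keep) == 5L) {
    out <- stack$counts
  } else if (length(keep) == 0L) {
    out <- sum(stack$counts)
  } else {
    out <- apply(stack$counts, keep, sum)
    if (length(keep) == 1L) out <- as.vector(out)
  }
  structure(
    list(counts = out,
         axes = axes[keep],
         retained = hdim_axis_names[keep]),
    class = "hdim_projection"
  )
}

#' @export
print.hdim_projection <- function(x, ...) {
  cat(sprintf("<hdim_projection> retained axes: %s | total photons: %s\n",
              if (length(x$retained)) paste(x$retained, collapse = ", ") else "(none)",
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' Tidy a projection into a tibble
#'
#' One row per retained-axis combination with its photon count; axis
#' coordinates become columns named after the axes.
#'
#' @param x An `hdim_projection`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.hdim_projection <- function(x, ...) {
  if (length(x$retained) == 0L) {
    return(tibble::tibble(counts = x$counts))
  }
  grid <- do.call(tidyr::expand_grid, rev(x$axes))
  grid <- grid[, rev(seq_along(x$axes)), drop = FALSE]
  names(grid) <- x$retained
  grid$counts <- as.vector(x$counts)
  tibble::as_tibble(grid)
}

#' Spatially bin a stack
#'
#' Sums `factor x factor` pixel blocks; each output pixel's 2048-value
#' histogram is the sum of the block's histograms. Trailing rows/columns that
#' do not fill a block are dropped (no invented photons; counts over the
#' retained area are conserved exactly).
#'
#' @param stack An `hdim_stack`.
#' @param factor Positive integer binning factor.
#' @return A new `hdim_stack` with spatial dims `floor(dim / factor)`.
#' @export
spatial_bin <- function(stack, factor) {
  stopifnot(inherits(stack, "hdim_stack"))
  if (!(length(factor) == 1L && factor >= 1 && factor == as.integer(factor))) {
    stop("`factor` must be a single integer >= 1.", call. = FALSE)
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(stack)
  d <- dim(stack$counts)
  nr <- (d[1] %/% factor) * factor
  nc <- (d[2] %/% factor) * factor
  if (nr < factor || nc < factor) {
    stop("stack too small for the requested binning factor.", call. = FALSE)
  }
  x <- stack$counts[seq_len(nr), seq_len(nc), , , , drop = FALSE]
  rb <- nr %/% factor
  cb <- nc %/% factor
  rest <- prod(d[3:5])
  # rows: (factor, rb, nc * rest) -> sum over the block sub-index
  dim(x) <- c(factor, rb, nc * rest)
  x <- colSums(x)                       # (rb, nc * rest)
  # cols: (rb, factor, cb, rest) -> sum over dim 2
  dim(x) <- c(rb, factor, cb * rest)
  x <- aperm(x, c(2, 1, 3))
  dim(x) <- c(factor, rb * cb * rest)
  x <- colSums(x)
  dim(x) <- c(rb, cb, d[3], d[4], d[5])
  if (is.integer(stack$counts) && max(x) <= .Machine$integer.max) {
    storage.mode(x) <- "integer"       # keep photon totals integer-exact
  }
  prov <- stack$provenance
  prov$spatial_binning <- c(prov$spatial_binning, factor)
  hdim_stack(x,
             wavelength_centers = stack$wavelength_centers,
             time_bin_edges = stack$time_bin_edges,
             excitation_wavelength = stack$excitation_wavelength,
             g_factor = stack$g_factor,
             pixel_size = stack$pixel_size * factor,
             polarization_labels = stack$polarization_labels,
             provenance = prov)
}

#' Flatten a stack into a pixels-by-HDSS matrix
#'
#' Each row is one pixel's flattened hyperdimensional spectral signature
#' (2048 values under the default geometry), in canonical order: spectral
#' index fastest, then polarization, then time.
#'
#' @param stack An `hdim_stack`.
#' @param normalization `"raw"` (counts) or `"total_count"` (each pixel vector
#'   divided by its photon sum; zero-count pixels become `NA` rows).
#' @return Numeric matrix, `rows*cols` x `n_spectral*n_pol*n_time`; pixels in
#'   column-major spatial order.
#' @export
hdss_matrix <- function(stack, normalization = c("raw", "total_count")) {
  normalization <- match.arg(normalization)
  d <- dim(stack$counts)
  npix <- d[1] * d[2]
  dd <- prod(d[3:5])
  m <- aperm(stack$counts, c(3, 4, 5, 1, 2))
  dim(m) <- c(dd, npix)
  m <- t(m)
  if (normalization == "total_count") {
    tot <- rowSums(m)
    m <- m / tot          # rows with tot == 0 become NaN -> caller masks
    m[tot == 0, ] <- NA_real_
  }
  m
}
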
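#' CIE 1931 color-matching functions (analytic approximation)
#'
#' Multi-lobe Gaussian analytic fit to the CIE 1931 2-degree standard
#' observer (accurate to about 1 %). Used to build the default
#' eye-sensitivity matrix for [true_color()].
#'
#' @param wavelength_nm Wavelengths, nm.
#' @return Matrix with columns `xbar`, `ybar`, `zbar`.
#' @export
cie1931_cmf <- function(wavelength_nm) {
  g <- function(x, mu, s1, s2) {
    s <- ifelse(x < mu, s1, s2)
    exp(-0.5 * ((x - mu) / s)^2)
  }
  x <- 1.056 * g(wavelength_nm, 599.8, 37.9, 31.0) +
       0.362 * g(wavelength_nm, 442.0, 16.0, 26.7) -
       0.065 * g(wavelength_nm, 501.1, 20.4, 26.2)
  y <- 0.821 * g(wavelength_nm, 568.8, 46.9, 40.5) +
       0.286 * g(wavelength_nm, 530.9, 16.3, 31.1)
  z <- 1.217 * g(wavelength_nm, 437.0, 11.8, 36.0) +
       0.681 * g(wavelength_nm, 459.0, 26.0, 13.8)
  cbind(xbar = x, ybar = y, zbar = z)
}

# XYZ -> linear sRGB (D65) primary matrix
xyz_to_srgb <- matrix(c(
   3.2406, -1.5372, -0.4986,
  -0.9689,  1.8758,  0.0415,
   0.0557, -0.2040,  1.0570), nrow = 3, byrow = TRUE,
  dimnames = list(c("R", "G", "B"), c("X", "Y", "Z")))

#' Default eye-sensitivity matrix for a wavelength axis
#'
#' CIE 1931 color-matching functions sampled at the spectral bin centers,
#' composed with the linear sRGB primary transform; negative weights are
#' clipped to zero so photon counts always contribute nonnegatively.
#'
#' @param wavelength_centers Spectral bin centers, nm.
#' @return 3 x n matrix (rows R, G, B).
#' @export
eye_sensitivity_matrix <- function(wavelength_centers) {
  cmf <- cie1931_cmf(wavelength_centers)     # n x 3
  m <- xyz_to_srgb %*% t(cmf)                # 3 x n
  m[m < 0] <- 0
  m
}

new_rgb_image <- function(channels) {
  stopifnot(length(dim(channels)) == 3, dim(channels)[3] == 3)
  channels[channels < 0] <- 0
  channels[channels > 1] <- 1
  structure(list(channels = channels), class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$channels)
  cat(sprintf("<rgb_image> %d x %d px\n", d[1], d[2]))
  invisible(x)
}

#' Render a stack in true color
#'
#' Projects the stack on its spectral axis (summing time and polarization),
#' weights each wavelength bin's photons by an eye-sensitivity matrix, sums
#' into three color channels and normalizes by the image maximum — the scene
#' as it would appear through the eyepieces.
#'
#' @param stack An `hdim_stack`.
#' @param sensitivity_matrix 3 x n_spectral weight matrix; default
#'   [eye_sensitivity_matrix()] at the stack's bin centers.
#' @return An `rgb_image` (values in \[0, 1\]).
#' @export
true_color <- function(stack,
                       sensitivity_matrix = eye_sensitivity_matrix(stack$wavelength_centers)) {
  p <- project(stack, c("polarization", "time"))
  d <- dim(p$counts)
  if (!(is.matrix(sensitivity_matrix) && nrow(sensitivity_matrix) == 3 &&
        ncol(sensitivity_matrix) == d[3])) {
    stop(sprintf("sensitivity matrix must be 3 x %d (channels x spectral bins).",
                 d[3]), call. = FALSE)
  }
  flat <- p$counts
  dim(flat) <- c(d[1] * d[2], d[3])
  rgb <- flat %*% t(sensitivity_matrix)
  mx <- max(rgb)
  if (mx > 0) rgb <- rgb / mx
  new_rgb_image(array(rgb, dim = c(d[1], d[2], 3)))
}

#' Stain stretch parameters
#'
#' Controls the robust component stretch used by the digital stains:
#' each score map is rescaled as
#' `(score - min) / (s * (max* - min))` and clipped to \[0, 1\], where `min`
#' is the image minimum and `max* = median + sd_multiplier * SD` (computed
#' over unmasked pixels, moderating noise-dependent variations).
#'
#' @param s Saturation scale: a number (>= 0), or `"auto"` to pick the
#'   smallest `s >= 1` that places the `saturation_percentile` score at 1
#'   (so at most `100 - saturation_percentile` percent of pixels clip).
#' @param saturation_percentile Percentile that saturates under auto-s.
#' @param sd_multiplier SD multiplier in `max*`.
#' @return A `stain_params` list.
#' @export
stain_params <- function(s = 1, saturation_percentile = 95,
                         sd_multiplier = 3) {
  if (!identical(s, "auto")) stopifnot(is.numeric(s), s >= 0)
  stopifnot(saturation_percentile > 50, saturation_percentile <= 100,
            sd_multiplier > 0)
  structure(list(s = s, saturation_percentile = saturation_percentile,
                 sd_multiplier = sd_multiplier),
            class = "stain_params")
}

#' Robustly stretch a PCA score map to \[0, 1\]
#'
#' See [stain_params()] for the stretch definition. A constant map (where
#' `max*` equals the minimum) returns all zeros with a warning. The stretch
#' is monotone non-decreasing in the input score.
#'
#' @param score_map A `feature_map` of PCA scores.
#' @param params A [stain_params()].
#' @return A `feature_map` with values in \[0, 1\] (masked pixels 0).
#' @export
stretch_component <- function(score_map, params = stain_params()) {
  stopifnot(inherits(score_map, "feature_map"))
  v <- map_values(score_map)
  out <- matrix(0, nrow(score_map$values), ncol(score_map$values))
  if (!length(v)) {
    warning("score map has no unmasked pixels; returning zeros")
    return(new_feature_map(out, paste0(score_map$feature_name, " (stretched)"),
                           "dimensionless", score_map$mask | TRUE))
  }
  lo <- min(v)
  hi <- stats::median(v) + params$sd_multiplier * stats::sd(v)
  if (!is.finite(hi) || hi <= lo) {
    warning("constant score map: stretch is undefined, returning zeros")
    return(new_feature_map(out, paste0(score_map$feature_name, " (stretched)"),
                           "dimensionless", score_map$mask | TRUE))
  }
  s <- params$s
  if (identical(s, "auto")) {
    q <- stats::quantile(v, params$saturation_percentile / 100, names = FALSE)
    s <- max(1, (q - lo) / (hi - lo))
  }
  vals <- score_map$values
  vals[!score_map$mask] <- lo              # masked pixels render as 0
  out <- (vals - lo) / (s * (hi - lo))
  out[out < 0] <- 0
  out[out > 1] <- 1
  new_feature_map(out, paste0(score_map$feature_name, " (stretched)"),
                  "dimensionless", score_map$mask | TRUE)
}

#' Convert CMYK maps to an RGB image
#'
#' Naive device-independent conversion `R = (1-C)(1-K)`, `G = (1-M)(1-K)`,
#' `B = (1-Y)(1-K)`. Inputs outside \[0, 1\] are clipped with a warning.
#'
#' @param c,m,y,k Matrices in \[0, 1\] of equal shape.
#' @return An `rgb_image`.
#' @export
cmyk_to_rgb <- function(c, m, y, k) {
  chans <- list(c = c, m = m, y = y, k = k)
  for (nm in names(chans)) {
    x <- chans[[nm]]
    if (any(x < 0 | x > 1, na.rm = TRUE)) {
      warning("channel '", nm, "' has values outside [0, 1]; clipping")
      x[x < 0] <- 0
      x[x > 1] <- 1
      chans[[nm]] <- x
    }
  }
  d <- dim(chans$c)
  out <- array(0, dim = c(d[1], d[2], 3))
  out[, , 1] <- (1 - chans$c) * (1 - chans$k)
  out[, , 2] <- (1 - chans$m) * (1 - chans$k)
  out[, , 3] <- (1 - chans$y) * (1 - chans$k)
  new_rgb_image(out)
}

#' Digital HE-like and DAB-like stains from PCA score maps
#'
#' `render_he_like()` maps the stretched first three PCA components to the
#' magenta, cyan and black channels of a CMYK composite (yellow left empty),
#' then converts to RGB — a hematoxylin-eosin-like rendering. `render_dab_like()`
#' additionally maps the stretched fourth component to the yellow channel,
#' giving a DAB-like rendering. Both are deterministic functions of their
#' inputs.
#'
#' @param score_maps List of `feature_map`s named `PC1`, `PC2`, `PC3`
#'   (and `PC4` for the DAB-like stain), e.g. from [pca_apply()].
#' @param params A [stain_params()].
#' @return An `rgb_image`.
#' @export
render_he_like <- function(score_maps, params = stain_params()) {
  render_stain(score_maps, params, use_pc4 = FALSE)
}

#' @rdname render_he_like
#' @export
render_dab_like <- function(score_maps, params = stain_params()) {
  render_stain(score_maps, params, use_pc4 = TRUE)
}

render_stain <- function(score_maps, params, use_pc4) {
  need <- paste0("PC", seq_len(if (use_pc4) 4 else 3))
  missing <- setdiff(need, names(score_maps))
  if (length(missing)) {
    stop("missing PCA component map(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  st <- purrr::map(score_maps[need], stretch_component, params = params)
  m <- st$PC1$values
  c <- st$PC2$values
  k <- st$PC3$values
  y <- if (use_pc4) st$PC4$values else matrix(0, nrow(m), ncol(m))
  cmyk_to_rgb(c = c, m = m, y = y, k = k)
}

#' Write an RGB image as 8-bit PNG
#'
#' @param img An `rgb_image`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rgb_png <- function(img, path) {
  stopifnot(inherits(img, "rgb_image"))
  png::writePNG(img$channels, path)
  invisible(path)
}

#' @export
plot.rgb_image <- function(x, ...) {
  d <- dim(x$channels)
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, d[2]), ylim = c(0, d[1]), asp = 1)
  graphics::rasterImage(x$channels, 0, 0, d[2], d[1], interpolate = FALSE)
  invisible(x)
}
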
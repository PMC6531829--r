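#' @title Per-pixel spectroscopic feature maps and 1-D summaries
#' @description
#' These estimators collapse the hyperdimensional spectral signature into the
#' classical observables: emission spectrum, fluorescence decay, steady-state
#' anisotropy, mean (barycenter) lifetime and spectral peak.
#' @name hdim_features
NULL

new_spectro_summary <- function(kind, data, condition_label = "") {
  structure(list(kind = kind, data = data, condition_label = condition_label),
            class = "spectro_summary")
}

#' @export
print.spectro_summary <- function(x, ...) {
  cat(sprintf("<spectro_summary: %s>%s, %d points\n", x$kind,
              if (nzchar(x$condition_label)) paste0(" [", x$condition_label, "]") else "",
              nrow(x$data)))
  invisible(x)
}

#' @export
tidy.spectro_summary <- function(x, ...) tibble::as_tibble(x$data)

#' Emission spectrum of a stack
#'
#' Sums photon counts over space, polarization and time, leaving counts per
#' wavelength bin. A pure projection: the ordinate sums to the stack's total
#' photon count.
#'
#' @param stack An `hdim_stack`.
#' @param condition_label Optional label carried into the summary.
#' @return A `spectro_summary` whose `data` has columns
#'   `wavelength_nm`, `counts`.
#' @export
emission_spectrum <- function(stack, condition_label = "") {
  p <- project(stack, c("row", "col", "polarization", "time"))
  new_spectro_summary(
    "emission_spectrum",
    tibble::tibble(wavelength_nm = p$axes$spectral, counts = p$counts),
    condition_label)
}

#' Fluorescence decay of a stack
#'
#' Sums counts over space, wavelength and polarization, leaving counts per
#' TCSPC time bin.
#'
#' @inheritParams emission_spectrum
#' @return A `spectro_summary` with columns `time_ns`, `counts`.
#' @export
decay_curve <- function(stack, condition_label = "") {
  p <- project(stack, c("row", "col", "spectral", "polarization"))
  new_spectro_summary(
    "decay",
    tibble::tibble(time_ns = p$axes$time, counts = p$counts),
    condition_label)
}

#' Steady-state fluorescence anisotropy
#'
#' \code{r = (Ipar - G*Iperp) / (Ipar + 2*G*Iperp)}. Where the denominator
#' is zero the result is `NA` (masked), never an error. Invariant under joint
#' rescaling of both channels.
#'
#' @param parallel,perpendicular Nonnegative photon counts (vectorized).
#' @param g_factor Detection-balance correction G (> 0).
#' @return Anisotropy values in \[-0.5, 1\]; `NA` where undefined.
#' @examples
#' anisotropy(2, 1) # 0.25
#' @export
anisotropy <- function(parallel, perpendicular, g_factor = 1) {
  stopifnot(g_factor > 0)
  if (any(parallel < 0, na.rm = TRUE) || any(perpendicular < 0, na.rm = TRUE)) {
    stop("counts must be nonnegative.", call. = FALSE)
  }
  den <- parallel + 2 * g_factor * perpendicular
  r <- (parallel - g_factor * perpendicular) / den
  r[den == 0] <- NA_real_
  r
}

new_feature_map <- function(values, feature_name, units, mask) {
  stopifnot(identical(dim(values), dim(mask)))
  values[!mask] <- NA_real_
  structure(list(values = values, feature_name = feature_name, units = units,
                 mask = mask),
            class = "feature_map")
}

#' @export
print.feature_map <- function(x, ...) {
  cat(sprintf("<feature_map: %s [%s]> %d x %d px, %d masked\n",
              x$feature_name, x$units, nrow(x$values), ncol(x$values),
              sum(!x$mask)))
  invisible(x)
}

#' Tidy a feature map into a tibble
#'
#' @param x A `feature_map`.
#' @param ... Unused.
#' @return Tibble with columns `row`, `col`, `value`, `masked`.
#' @export
tidy.feature_map <- function(x, ...) {
  d <- dim(x$values)
  tibble::tibble(
    row = rep(seq_len(d[1]), times = d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    value = as.vector(x$values),
    masked = !as.vector(x$mask)
  )
}

#' Valid (unmasked) values of a feature map
#' @param map A `feature_map`.
#' @return Numeric vector of values on unmasked pixels.
#' @export
map_values <- function(map) map$values[map$mask]

#' Anisotropy spectrum of a stack
#'
#' Collapses space and time, then forms the anisotropy of the two
#' polarization channels per wavelength bin.
#'
#' @inheritParams emission_spectrum
#' @return A `spectro_summary` with columns `wavelength_nm`, `anisotropy`.
#' @export
anisotropy_spectrum <- function(stack, condition_label = "") {
  p <- project(stack, c("row", "col", "time"))
  r <- anisotropy(p$counts[, 1], p$counts[, 2], stack$g_factor)
  new_spectro_summary(
    "anisotropy_spectrum",
    tibble::tibble(wavelength_nm = p$axes$spectral, anisotropy = r),
    condition_label)
}

#' Per-pixel steady-state anisotropy map
#'
#' Collapses spectral and time axes and applies [anisotropy()] per pixel.
#' Pixels with fewer than `min_counts` total photons are masked (anisotropy
#' noise grows as 1/sqrt(N)).
#'
#' @param stack An `hdim_stack`.
#' @param min_counts Masking threshold, photons per pixel.
#' @return A `feature_map` (dimensionless).
#' @export
anisotropy_map <- function(stack, min_counts = 100) {
  p <- project(stack, c("spectral", "time"))
  d2 <- dim(p$counts)[1:2]
  par <- array(p$counts[, , 1, drop = FALSE], d2)
  perp <- array(p$counts[, , 2, drop = FALSE], d2)
  tot <- par + perp
  mask <- tot >= min_counts & (par + 2 * stack$g_factor * perp) > 0
  r <- anisotropy(par, perp, stack$g_factor)
  new_feature_map(r, "steady-state anisotropy", "dimensionless", mask)
}

#' Per-pixel mean (barycenter) fluorescence lifetime map
#'
#' After collapsing the spectral axis, the polarization channels are combined
#' into the total-intensity decay and the mean photon arrival time relative
#' to `t0` is taken:
#' \eqn{\bar\tau = \sum_i (t_i - t_0) c_i / \sum_i c_i} over time-bin centers
#' \eqn{t_i}. By default the channels are combined with the magic-angle
#' weighting `Ipar + 2 G Iperp`, under which the total intensity of a
#' rotating mono-exponential emitter is exactly \eqn{\propto e^{-t/\tau}}
#' (a plain channel sum retains a fast anisotropy-decay component that
#' biases the barycenter early; it is available as
#' `polarization_weight = "sum"`). For a mono-exponential decay observed
#' over a finite window \eqn{[0, T]} the estimator converges to the
#' truncated-exponential mean \eqn{\tau - T/(e^{T/\tau} - 1)}; setting
#' `truncation_correction = TRUE` numerically inverts that relation to
#' report \eqn{\tau} itself.
#'
#' @param stack An `hdim_stack`.
#' @param min_counts Masking threshold, photons per pixel.
#' @param t0 Time origin, ns; defaults to the first bin edge (delta-IRF
#'   assumption).
#' @param truncation_correction Undo the finite-window bias assuming a
#'   mono-exponential decay (off by default).
#' @param polarization_weight `"magic_angle"` (default; `Ipar + 2 G Iperp`)
#'   or `"sum"` (plain channel sum).
#' @return A `feature_map` in ns.
#' @export
mean_lifetime_map <- function(stack, min_counts = 100,
                              t0 = stack$time_bin_edges[1],
                              truncation_correction = FALSE,
                              polarization_weight = c("magic_angle", "sum")) {
  polarization_weight <- match.arg(polarization_weight)
  p <- project(stack, "spectral")
  dd <- dim(p$counts)                    # (row, col, pol, time)
  w_perp <- if (polarization_weight == "magic_angle") 2 * stack$g_factor else 1
  dec <- p$counts[, , 1, , drop = FALSE] + w_perp * p$counts[, , 2, , drop = FALSE]
  d <- dd[c(1, 2, 4)]
  dim(dec) <- d                          # (row, col, time)
  centers <- p$axes$time - t0
  flat <- dec
  dim(flat) <- c(d[1] * d[2], d[3])
  # mask on physically recorded photons, not on the weighted sum
  raw_tot <- rowSums(matrix(p$counts, d[1] * d[2], 2 * d[3]))
  tot <- rowSums(flat)
  tbar <- as.vector(flat %*% centers) / tot
  if (truncation_correction) {
    T_win <- diff(range(stack$time_bin_edges))
    tbar <- vapply(tbar, invert_truncated_mean, numeric(1), T_win = T_win)
  }
  dim(tbar) <- c(d[1], d[2])
  mask <- matrix(raw_tot >= pmax(min_counts, 1) & tot > 0, d[1], d[2])
  new_feature_map(tbar, "mean fluorescence lifetime", "ns", mask)
}

#' Truncated-exponential mean arrival time
#'
#' Closed-form mean of `t ~ Exp(1/tau)` conditioned on `t < T_win`:
#' \eqn{\tau - T/(e^{T/\tau} - 1)}. This is the noise-free expectation of the
#' barycenter lifetime estimator under a delta IRF.
#'
#' @param tau Decay lifetime, ns.
#' @param T_win Observation window, ns.
#' @return Mean arrival time, ns.
#' @export
truncated_exp_mean <- function(tau, T_win) {
  z <- T_win / tau
  tau - T_win / expm1(z)
}

# Solve truncated_exp_mean(tau, T_win) = m for tau.
invert_truncated_mean <- function(m, T_win) {
  if (!is.finite(m) || m <= 0) return(NA_real_)
  if (m >= T_win / 2) return(Inf)  # uniform-histogram limit: tau -> infinity
  stats::uniroot(function(tau) truncated_exp_mean(tau, T_win) - m,
                 lower = m, upper = T_win * 1e3, tol = 1e-10)$root
}

#' Per-pixel spectral peak map
#'
#' Wavelength of the maximum spectral bin after collapsing polarization and
#' time, refined by three-point parabolic interpolation
#' \eqn{\delta = \tfrac12 (c_{-1} - c_{+1}) / (c_{-1} - 2 c_0 + c_{+1})}
#' in bin units. Maxima at the axis edges (or with a degenerate parabola)
#' are returned uninterpolated. A `"centroid"` method (intensity-weighted
#' mean wavelength) is available as an alternative.
#'
#' @param stack An `hdim_stack`.
#' @param min_counts Masking threshold, photons per pixel.
#' @param method `"peak"` (argmax + parabolic refinement, default) or
#'   `"centroid"`.
#' @return A `feature_map` in nm.
#' @export
spectral_peak_map <- function(stack, min_counts = 100,
                              method = c("peak", "centroid")) {
  method <- match.arg(method)
  p <- project(stack, c("polarization", "time"))
  d <- dim(p$counts)
  wl <- p$axes$spectral
  flat <- p$counts
  dim(flat) <- c(d[1] * d[2], d[3])
  tot <- rowSums(flat)
  if (method == "centroid") {
    pk <- as.vector(flat %*% wl) / tot
  } else {
    bin_w <- mean(diff(wl))
    idx <- max.col(flat, ties.method = "first")
    pk <- wl[idx]
    interior <- idx > 1L & idx < d[3]
    ii <- which(interior)
    if (length(ii)) {
      cm1 <- flat[cbind(ii, idx[ii] - 1L)]
      c0  <- flat[cbind(ii, idx[ii])]
      cp1 <- flat[cbind(ii, idx[ii] + 1L)]
      den <- cm1 - 2 * c0 + cp1
      delta <- ifelse(den == 0, 0, 0.5 * (cm1 - cp1) / den)
      pk[ii] <- pk[ii] + delta * bin_w
    }
  }
  dim(pk) <- c(d[1], d[2])
  mask <- matrix(tot >= pmax(min_counts, 1), d[1], d[2])
  new_feature_map(pk, "spectral peak", "nm", mask)
}

#' Pooled feature histograms across conditions
#'
#' Histograms one feature map per condition on a shared grid, the way
#' per-pixel feature variability is displayed for a solution panel: one
#' distribution per condition plus their pooled overlay. All maps must share
#' units; each condition's histogram mass equals its unmasked pixel count.
#'
#' @param maps Named list of `feature_map`s (names = condition labels).
#' @param bins Number of bins (shared grid over the pooled range), or a
#'   numeric vector of breaks.
#' @return Tibble with columns `condition` (the label, or `"pooled"` for the
#'   overlay), `mid` (bin center), `count`.
#' @export
feature_histograms <- function(maps, bins = 64) {
  stopifnot(length(maps) >= 1)
  units <- unique(purrr::map_chr(maps, "units"))
  if (length(units) != 1) {
    stop("feature maps mix units (", paste(units, collapse = ", "),
         "); histograms require a single unit.", call. = FALSE)
  }
  vals <- purrr::map(maps, map_values)
  rng <- range(unlist(vals), finite = TRUE)
  if (length(bins) == 1L) {
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  } else {
    breaks <- bins
  }
  per <- purrr::imap(vals, function(v, nm) {
    h <- graphics::hist(v[v >= breaks[1] & v <= breaks[length(breaks)]],
                        breaks = breaks, plot = FALSE)
    tibble::tibble(condition = nm, mid = h$mids, count = h$counts)
  })
  per <- dplyr::bind_rows(per)
  pooled <- per |>
    dplyr::group_by(.data$mid) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::mutate(condition = "pooled", .before = 1)
  dplyr::bind_rows(per, pooled)
}
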
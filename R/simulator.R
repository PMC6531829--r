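#' Define a fluorophore's photophysical parameters
#'
#' A parameter record for the forward model: Gaussian emission spectrum,
#' mono-exponential decay with Stern-Volmer quenching, single rotational
#' correlation time with Perrin depolarization, and a fundamental anisotropy
#' bounded by the photoselection ceiling.
#'
#' @param name Label.
#' @param emission_peak Emission maximum, nm.
#' @param emission_sigma Gaussian spectral width, nm (> 0).
#' @param lifetime_0 Unquenched lifetime tau0, ns (> 0).
#' @param stern_volmer_K Stern-Volmer constant, per mM (>= 0).
#' @param rot_corr_time_0 Rotational correlation time theta0 in water, ns (> 0).
#' @param fundamental_anisotropy Dimensionless r0 in \[-0.2, 4/7\]; defaults to
#'   the two-photon collinear ceiling 4/7.
#' @param brightness Expected detected photons per unit concentration (uM)
#'   per pixel at unit exposure scale (> 0).
#' @return A `fluorophore` object (named list).
#' @export
fluorophore <- function(name, emission_peak, emission_sigma, lifetime_0,
                        stern_volmer_K = 0, rot_corr_time_0 = 0.2,
                        fundamental_anisotropy = 4 / 7, brightness = 1000) {
  stopifnot(emission_sigma > 0, lifetime_0 > 0, stern_volmer_K >= 0,
            rot_corr_time_0 > 0, brightness > 0,
            fundamental_anisotropy >= -0.2,
            fundamental_anisotropy <= 4 / 7 + 1e-12)
  structure(list(name = name, emission_peak = emission_peak,
                 emission_sigma = emission_sigma, lifetime_0 = lifetime_0,
                 stern_volmer_K = stern_volmer_K,
                 rot_corr_time_0 = rot_corr_time_0,
                 fundamental_anisotropy = fundamental_anisotropy,
                 brightness = brightness),
            class = "fluorophore")
}

#' Default synthetic fluorophore pair
#'
#' Literature-typical stand-ins for fluorescein (FITC) and rhodamine 6G
#' (R6G): these are synthetic parameter sets, not measured constants.
#' Brightnesses are set so the default panel concentrations (10 uM FITC,
#' 1 uM R6G) give similar per-pixel photon yields.
#'
#' @return Named list of two `fluorophore` objects (`FITC`, `R6G`).
#' @export
default_fluorophores <- function() {
  list(
    FITC = fluorophore("FITC", emission_peak = 517, emission_sigma = 30,
                       lifetime_0 = 4.0, stern_volmer_K = 8,
                       rot_corr_time_0 = 0.2, brightness = 1000),
    R6G = fluorophore("R6G", emission_peak = 552, emission_sigma = 20,
                      lifetime_0 = 4.1, stern_volmer_K = 5,
                      rot_corr_time_0 = 0.3, brightness = 10000)
  )
}

#' Define a solution environment
#'
#' @param quencher_mM Collisional quencher concentration (KI analogue), mM.
#' @param viscosity_factor Multiplier on the rotational correlation time
#'   (glycerol analogue), >= 1.
#' @param label Text label.
#' @return An `hdim_environment` object.
#' @export
environment_condition <- function(quencher_mM = 0, viscosity_factor = 1,
                                  label = "") {
  stopifnot(quencher_mM >= 0, viscosity_factor >= 1)
  structure(list(quencher_mM = quencher_mM,
                 viscosity_factor = viscosity_factor, label = label),
            class = "hdim_environment")
}

#' The default 12-solution condition panel
#'
#' Reconstructs the reference experimental design: compositions F (FITC only,
#' 10 uM), R (R6G only, 1 uM) and D (the mixture), each in four environments
#' - `0` (buffer), `G` (glycerol: slowed rotation), `Q` (iodide quencher:
#' shortened lifetime) and `B` (both) - giving the 12 labels
#' F0, FG, FQ, FB, R0, RG, RQ, RB, D0, DG, DQ, DB.
#'
#' @param quencher_mM Quencher concentration used in the Q and B
#'   environments, mM (0.1 mM = 100 uM).
#' @param viscosity_factor Rotational slowdown of the G and B environments
#'   (about the bulk viscosity ratio of 65 % v/v glycerol to water).
#' @param fitc_uM,r6g_uM Concentrations of the two fluorophores, uM.
#' @return A `condition_panel`: tibble with columns `label`, `composition`
#'   (named concentration vectors, uM) and `environment`.
#' @export
default_panel <- function(quencher_mM = 0.1, viscosity_factor = 15,
                          fitc_uM = 10, r6g_uM = 1) {
  comps <- list(
    F = c(FITC = fitc_uM),
    R = c(R6G = r6g_uM),
    D = c(FITC = fitc_uM, R6G = r6g_uM)
  )
  envs <- list(
    `0` = environment_condition(0, 1, "0"),
    G = environment_condition(0, viscosity_factor, "G"),
    Q = environment_condition(quencher_mM, 1, "Q"),
    B = environment_condition(quencher_mM, viscosity_factor, "B")
  )
  rows <- purrr::map(names(comps), function(cn) {
    purrr::map(names(envs), function(en) {
      list(label = paste0(cn, en), composition = comps[[cn]],
           environment = envs[[en]])
    })
  })
  rows <- purrr::flatten(rows)
  panel <- tibble::tibble(
    label = purrr::map_chr(rows, "label"),
    composition = purrr::map(rows, "composition"),
    environment = purrr::map(rows, "environment")
  )
  structure(panel, class = c("condition_panel", class(panel)))
}

#' Uniform spatial scene
#'
#' A homogeneous solution: constant concentration maps (one per fluorophore)
#' and a single environment everywhere.
#'
#' @param rows,cols Spatial shape.
#' @param fluor_names Fluorophore names (must match the fluorophore list used
#'   at simulation time).
#' @param concentrations Concentrations, uM, one per name.
#' @param environment An `hdim_environment`.
#' @return A `scene` object.
#' @export
uniform_scene <- function(rows, cols, fluor_names, concentrations,
                          environment = environment_condition()) {
  maps <- purrr::map(as.numeric(concentrations),
                     ~ matrix(.x, nrow = rows, ncol = cols))
  names(maps) <- fluor_names
  scene(maps, environment)
}

#' Construct a spatial scene
#'
#' @param concentration_maps Named list of nonnegative matrices (uM), one per
#'   fluorophore, all the same shape.
#' @param environment A single `hdim_environment` applied everywhere
#'   (spatially varying environments are composed by simulating sub-scenes).
#' @return A `scene` object.
#' @export
scene <- function(concentration_maps, environment = environment_condition()) {
  stopifnot(length(concentration_maps) >= 1)
  shp <- dim(concentration_maps[[1]])
  for (m in concentration_maps) {
    if (!identical(dim(m), shp)) {
      stop("all concentration maps must share the same shape.", call. = FALSE)
    }
    if (any(m < 0)) stop("concentrations must be nonnegative.", call. = FALSE)
  }
  structure(list(concentration_maps = concentration_maps,
                 environment = environment, shape = shp),
            class = "scene")
}

#' Acquisition geometry descriptor
#'
#' @param rows,cols Image size in pixels.
#' @param n_spectral,n_time Spectral and time bins (default 16 x 64; with the
#'   two polarization channels this is the 2048-value HDSS geometry).
#' @param wavelength_start,bandwidth Spectral axis coverage, nm.
#' @param period TCSPC window = laser repetition period, ns.
#' @return A list describing the detection geometry.
#' @export
hdim_geometry <- function(rows = 64, cols = 64, n_spectral = 16, n_time = 64,
                          wavelength_start = 420, bandwidth = 200,
                          period = 12.5) {
  list(rows = rows, cols = cols, n_spectral = n_spectral, n_time = n_time,
       wavelength_centers = default_wavelength_centers(n_spectral,
                                                       wavelength_start,
                                                       bandwidth),
       wavelength_edges = seq(wavelength_start, wavelength_start + bandwidth,
                              length.out = n_spectral + 1),
       time_bin_edges = default_time_edges(n_time, period))
}

#' Per-fluorophore expected HDSS under an environment
#'
#' The factorized forward model for one fluorophore in one environment:
#' spectral fractions (Gaussian), outer polarized-decay fractions
#' (Stern-Volmer-quenched lifetime, viscosity-scaled rotational correlation
#' time, Perrin/photoselection anisotropy kinetics).
#'
#' @param fl A `fluorophore`.
#' @param env An `hdim_environment`.
#' @param geometry An [hdim_geometry()].
#' @param wrap_around Fold incomplete decays from preceding pulses into the
#'   window (see [polarized_decay()]); default `FALSE`.
#' @return Array `(n_spectral, 2, n_time)` of fractions summing to 1, plus
#'   attributes `tau` and `theta` (the environment-modified values, ns).
#' @export
expected_signature <- function(fl, env, geometry, wrap_around = FALSE) {
  tau <- quenched_lifetime(fl$lifetime_0, fl$stern_volmer_K, env$quencher_mM)
  theta <- fl$rot_corr_time_0 * env$viscosity_factor
  spec <- spectral_fractions(fl$emission_peak, fl$emission_sigma,
                             geometry$wavelength_edges)
  pol <- polarized_decay(fl$fundamental_anisotropy, tau, theta,
                         geometry$time_bin_edges, wrap_around = wrap_around)
  sig <- array(0, dim = c(geometry$n_spectral, 2, geometry$n_time))
  sig[, 1, ] <- outer(spec, pol$parallel)
  sig[, 2, ] <- outer(spec, pol$perpendicular)
  attr(sig, "tau") <- tau
  attr(sig, "theta") <- theta
  sig
}

#' Noise-free expected HDIM stack for a scene
#'
#' Expected counts per pixel and histogram bin:
#' `brightness * concentration * exposure_scale`, distributed over the HDSS
#' by the factorized signature of each fluorophore and summed over
#' fluorophores. This is the Poisson mean used by [simulate_stack()] and the
#' closed-form oracle for the feature estimators.
#'
#' @param scn A `scene`.
#' @param fluorophores Named list of `fluorophore`s covering the scene's maps.
#' @param geometry An [hdim_geometry()] (spatial dims taken from the scene).
#' @param exposure_scale Global brightness multiplier.
#' @param wrap_around Fold incomplete decays into the window; default `FALSE`.
#' @return 5-D array of expected counts (double).
#' @export
expected_stack <- function(scn, fluorophores = default_fluorophores(),
                           geometry = hdim_geometry(), exposure_scale = 1,
                           wrap_around = FALSE) {
  stopifnot(inherits(scn, "scene"))
  rows <- scn$shape[1]; cols <- scn$shape[2]
  lam <- array(0, dim = c(rows, cols, geometry$n_spectral, 2, geometry$n_time))
  for (nm in names(scn$concentration_maps)) {
    fl <- fluorophores[[nm]]
    if (is.null(fl)) stop("no fluorophore definition for map '", nm, "'.",
                          call. = FALSE)
    sig <- expected_signature(fl, scn$environment, geometry, wrap_around)
    amp <- fl$brightness * exposure_scale * scn$concentration_maps[[nm]]
    lam <- lam + outer(amp, sig)
  }
  lam
}

#' Simulate an HDIM stack
#'
#' Draws independent Poisson counts around the expected stack of a scene.
#' The same seed always reproduces the identical stack.
#'
#' @inheritParams expected_stack
#' @param seed Integer seed (required for reproducibility).
#' @param expected Optional precomputed [expected_stack()] array (skips
#'   recomputation when simulating replicates).
#' @return An `hdim_stack` with simulation provenance recorded.
#' @export
simulate_stack <- function(scn, fluorophores = default_fluorophores(),
                           geometry = hdim_geometry(), exposure_scale = 1,
                           seed, expected = NULL, wrap_around = FALSE) {
  if (missing(seed)) stop("`seed` is required for reproducible simulation.",
                          call. = FALSE)
  lam <- expected %||% expected_stack(scn, fluorophores, geometry,
                                      exposure_scale, wrap_around)
  counts <- with_local_seed(seed, {
    array(stats::rpois(length(lam), lam), dim = dim(lam))
  })
  hdim_stack(
    counts,
    wavelength_centers = geometry$wavelength_centers,
    time_bin_edges = geometry$time_bin_edges,
    provenance = list(
      generator = "hyperdim::simulate_stack",
      seed = seed,
      exposure_scale = exposure_scale,
      environment = unclass(scn$environment),
      fluorophores = names(scn$concentration_maps)
    )
  )
}

#' Simulate the full condition panel
#'
#' One uniform-solution stack per panel condition; per-condition seeds are
#' derived deterministically from `seed`.
#'
#' @param panel A [default_panel()]-style `condition_panel`.
#' @param fluorophores Named list of `fluorophore`s.
#' @param geometry An [hdim_geometry()].
#' @param exposure_scale Global brightness multiplier (1 gives about 10^4
#'   photons per pixel with the default fluorophores and concentrations).
#' @param seed Integer seed.
#' @return Named list of `hdim_stack`s, one per condition label.
#' @export
simulate_panel <- function(panel = default_panel(),
                           fluorophores = default_fluorophores(),
                           geometry = hdim_geometry(), exposure_scale = 1,
                           seed, wrap_around = FALSE) {
  if (missing(seed)) stop("`seed` is required.", call. = FALSE)
  out <- purrr::map(seq_len(nrow(panel)), function(i) {
    comp <- panel$composition[[i]]
    scn <- uniform_scene(geometry$rows, geometry$cols,
                         names(comp), comp, panel$environment[[i]])
    simulate_stack(scn, fluorophores, geometry, exposure_scale,
                   seed = (seed + i - 1L) %% .Machine$integer.max,
                   wrap_around = wrap_around)
  })
  names(out) <- panel$label
  out
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}
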
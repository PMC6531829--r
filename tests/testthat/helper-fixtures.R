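# Shared fixtures: tiny geometries, random stacks, independent oracles,
# and a one-shot cache for the expensive end-to-end panel run.

tiny_geometry <- function(rows = 6, cols = 5, n_spectral = 4, n_time = 8) {
  hdim_geometry(rows, cols, n_spectral = n_spectral, n_time = n_time)
}

# A stack of iid Poisson counts with no photophysical structure.
random_stack <- function(seed, rows = 5, cols = 4, n_spectral = 3,
                         n_time = 6, mean_counts = 3) {
  geo <- hdim_geometry(rows, cols, n_spectral = n_spectral, n_time = n_time)
  counts <- withr::with_seed(seed, {
    array(rpois(rows * cols * n_spectral * 2 * n_time, mean_counts),
          dim = c(rows, cols, n_spectral, 2, n_time))
  })
  hdim_stack(counts, wavelength_centers = geo$wavelength_centers,
             time_bin_edges = geo$time_bin_edges)
}

# Independent brute-force covariance PCA: eigendecomposition of cov(X),
# signs aligned by the largest-|loading|-positive rule.
brute_force_pca <- function(X, k) {
  mu <- colMeans(X)
  C <- stats::cov(X)
  e <- eigen(C, symmetric = TRUE)
  V <- e$vectors[, seq_len(k), drop = FALSE]
  sgn <- apply(V, 2, function(v) sign(v[which.max(abs(v))]))
  sgn[sgn == 0] <- 1
  V <- sweep(V, 2, sgn, `*`)
  list(mean = mu, loadings = t(V), values = e$values[seq_len(k)],
       scores = sweep(X, 2, mu) %*% V)
}

# Photon-weighted truth for a panel condition: expected photon share,
# lifetime, rotational correlation time and Perrin anisotropy per component.
condition_truth <- function(composition, env,
                            fluorophores = default_fluorophores()) {
  nm <- names(composition)
  w <- vapply(nm, function(n) fluorophores[[n]]$brightness * composition[[n]],
              numeric(1))
  w <- w / sum(w)
  tau <- vapply(nm, function(n) {
    quenched_lifetime(fluorophores[[n]]$lifetime_0,
                      fluorophores[[n]]$stern_volmer_K, env$quencher_mM)
  }, numeric(1))
  theta <- vapply(nm, function(n) {
    fluorophores[[n]]$rot_corr_time_0 * env$viscosity_factor
  }, numeric(1))
  r0 <- vapply(nm, function(n) fluorophores[[n]]$fundamental_anisotropy,
               numeric(1))
  list(weights = w, tau = tau, theta = theta, r0 = r0,
       # time-integrated (wrapped) anisotropy of the mixture: photon-weighted
       perrin = sum(w * perrin_steady_state(r0, tau, theta)),
       # expected barycenter of the truncated mixture decay
       barycenter = function(T_win) sum(w * truncated_exp_mean(tau, T_win)))
}

# Continuous argmax of the condition's Gaussian-mixture emission density.
condition_peak_truth <- function(composition,
                                 fluorophores = default_fluorophores()) {
  nm <- names(composition)
  w <- vapply(nm, function(n) fluorophores[[n]]$brightness * composition[[n]],
              numeric(1))
  dens <- function(x) {
    sum(vapply(seq_along(nm), function(i) {
      w[i] * stats::dnorm(x, fluorophores[[nm[i]]]$emission_peak,
                          fluorophores[[nm[i]]]$emission_sigma)
    }, numeric(1)))
  }
  stats::optimize(Vectorize(dens), c(440, 620), maximum = TRUE)$maximum
}

# One-shot cache for expensive shared computations within a test run.
.hdim_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .hdim_test_cache)) {
    assign(key, force(expr), envir = .hdim_test_cache)
  }
  get(key, envir = .hdim_test_cache)
}

# The canonical end-to-end panel run used by the separability and
# estimator-recovery suites (64 x 64 px, seed fixed at 1).
full_panel_run <- function() {
  cached("full_panel", reproduce_panel(seed = 1))
}

# Smaller Poisson panel for per-condition estimator medians (32 x 32 px).
poisson_panel <- function(wrap = FALSE) {
  key <- if (wrap) "poisson_panel_wrap" else "poisson_panel"
  cached(key, simulate_panel(geometry = hdim_geometry(32, 32),
                             seed = if (wrap) 2 else 1, wrap_around = wrap))
}

# Closed-form wrapped (full-integral) polarization channel integrals for one
# mono-exponential rotator: par ~ (tau + 2 r0 tc)/3, perp ~ (tau - r0 tc)/3
# with tc = (1/tau + 1/theta)^-1. Independent of the package's decay code.
wrapped_channels <- function(r0, tau, theta) {
  tc <- 1 / (1 / tau + 1 / theta)
  list(par = (tau + 2 * r0 * tc) / 3, perp = (tau - r0 * tc) / 3)
}

# Exact steady-state anisotropy of a brightness-weighted fluorophore mixture
# (each component detected with B_f photons split par/perp by its own
# kinetics). Reduces to the Perrin value for a single fluorophore.
mixture_anisotropy_truth <- function(truth) {
  P <- 0; Q <- 0
  for (i in seq_along(truth$weights)) {
    ch <- wrapped_channels(truth$r0[i], truth$tau[i], truth$theta[i])
    norm <- truth$weights[i] / (ch$par + ch$perp)
    P <- P + norm * ch$par
    Q <- Q + norm * ch$perp
  }
  (P - Q) / (P + 2 * Q)
}
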
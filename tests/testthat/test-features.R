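test_that("1-D summaries are pure, photon-conserving projections", {
  st <- random_stack(seed = 31)
  sp <- emission_spectrum(st, "toy")
  expect_identical(sum(sp$data$counts), total_counts(st))
  expect_identical(sp$data$wavelength_nm, st$wavelength_centers)
  dc <- decay_curve(st)
  expect_identical(sum(dc$data$counts), total_counts(st))
  # a simulated single Gaussian fluorophore peaks in the right bin
  geo <- hdim_geometry(4, 4)
  scn <- uniform_scene(4, 4, "FITC", 10)
  sim <- simulate_stack(scn, geometry = geo, seed = 1)
  spec <- emission_spectrum(sim)$data
  k <- which.max(spec$counts)
  expect_lt(abs(spec$wavelength_nm[k] - 517), 12.5)  # within one bin
  # a noise-free exponential decay is monotone decreasing
  lam <- expected_stack(scn, geometry = geo)
  stf <- hdim_stack(lam, geo$wavelength_centers, geo$time_bin_edges)
  expect_true(all(diff(decay_curve(stf)$data$counts) < 0))
})

test_that("anisotropy follows its defining ratio and masks zero denominators", {
  expect_equal(anisotropy(1, 1), 0)
  expect_equal(anisotropy(1, 0), 1)
  expect_equal(anisotropy(2, 1), 0.25)
  expect_equal(anisotropy(0, 1), -0.5)
  expect_true(is.na(anisotropy(0, 0)))
  # G-factor rebalances the perpendicular channel
  expect_equal(anisotropy(2, 1, g_factor = 2), 0)
  # invariance under joint scaling of both channels
  expect_equal(anisotropy(20, 7), anisotropy(20e6, 7e6))
  expect_error(anisotropy(-1, 1), "nonnegative")
})

test_that("anisotropy maps recover the isotropic and Perrin limits", {
  geo <- tiny_geometry(12, 12)
  iso <- fluorophore("iso", 500, 25, 4, fundamental_anisotropy = 0,
                     brightness = 2000)
  st <- simulate_stack(uniform_scene(12, 12, "iso", 10),
                       fluorophores = list(iso = iso), geometry = geo,
                       seed = 8)
  m <- anisotropy_map(st, min_counts = 100)
  # r ~ 0 within 3 sigma Poisson bound per pixel (sigma ~ 1/sqrt(2N))
  n <- total_counts(st) / (12 * 12)
  expect_true(all(abs(map_values(m)) < 3 / sqrt(n) + 0.01))
  # wrapped noise-free expectation hits the Perrin value to 1e-3
  fl <- fluorophore("slow", 500, 25, 4, rot_corr_time_0 = 2,
                    fundamental_anisotropy = 0.57, brightness = 1000)
  lam <- expected_stack(uniform_scene(2, 2, "slow", 10),
                        fluorophores = list(slow = fl),
                        geometry = geo2 <- tiny_geometry(2, 2),
                        wrap_around = TRUE)
  stf <- hdim_stack(lam * 100, geo2$wavelength_centers, geo2$time_bin_edges)
  r <- map_values(anisotropy_map(stf, min_counts = 1))[1]
  expect_equal(r, perrin_steady_state(0.57, 4, 2), tolerance = 1e-3)
  # truncation (no wrap) biases r high, but only by ~0.01 at theta = 2 ns
  lam_t <- expected_stack(uniform_scene(2, 2, "slow", 10),
                          fluorophores = list(slow = fl), geometry = geo2)
  st_t <- hdim_stack(lam_t * 100, geo2$wavelength_centers,
                     geo2$time_bin_edges)
  r_t <- map_values(anisotropy_map(st_t, min_counts = 1))[1]
  expect_gt(r_t, perrin_steady_state(0.57, 4, 2))
  expect_lt(r_t - perrin_steady_state(0.57, 4, 2), 0.012)
  # mask is exactly the low-count pixel set
  st0 <- random_stack(seed = 33, mean_counts = 1)
  mm <- anisotropy_map(st0, min_counts = 150)
  tots <- project(st0, c("spectral", "time"))$counts
  tot2 <- tots[, , 1] + tots[, , 2]
  expect_identical(unname(mm$mask), unname(tot2 >= 150))
})

test_that("barycenter lifetime matches closed-form delta/uniform/truncated oracles", {
  geo <- tiny_geometry(2, 2, n_time = 10)
  dtc <- diff(geo$time_bin_edges)[1]
  centers <- geo$time_bin_edges[-11] + dtc / 2
  # all counts in one bin -> that bin's center
  counts <- array(0, dim = c(2, 2, 4, 2, 10))
  counts[, , , , 4] <- 5
  st <- hdim_stack(counts, geo$wavelength_centers, geo$time_bin_edges)
  m <- mean_lifetime_map(st, min_counts = 1)
  expect_equal(unique(map_values(m)), centers[4])
  # uniform counts over the window -> T/2
  counts[] <- 1
  stu <- hdim_stack(counts, geo$wavelength_centers, geo$time_bin_edges)
  expect_equal(unique(map_values(mean_lifetime_map(stu, min_counts = 1))),
               12.5 / 2)
  # noise-free tau = 2 ns expectation on 64 bins over 12.5 ns
  geo64 <- hdim_geometry(2, 2)
  fl <- fluorophore("f2", 500, 25, 2, brightness = 1000)
  lam <- expected_stack(uniform_scene(2, 2, "f2", 10),
                        fluorophores = list(f2 = fl), geometry = geo64)
  stf <- hdim_stack(lam * 10, geo64$wavelength_centers, geo64$time_bin_edges)
  bary <- map_values(mean_lifetime_map(stf, min_counts = 1))[1]
  oracle <- truncated_exp_mean(2, 12.5)          # 1.9758...
  expect_equal(oracle, 2 - 12.5 / (exp(12.5 / 2) - 1), tolerance = 1e-12)
  expect_lt(abs(bary - oracle), diff(geo64$time_bin_edges)[1] / 2)
  # truncation correction inverts back to tau within 2%
  corr <- map_values(mean_lifetime_map(stf, min_counts = 1,
                                       truncation_correction = TRUE))[1]
  expect_equal(corr, 2, tolerance = 0.02)
  # zero-count pixels are masked
  z <- hdim_stack(array(0, dim = c(2, 2, 4, 2, 10)),
                  geo$wavelength_centers, geo$time_bin_edges)
  expect_true(all(!mean_lifetime_map(z)$mask))
})

test_that("spectral peak uses parabolic refinement with edge fallbacks", {
  geo <- tiny_geometry(1, 1, n_spectral = 5)
  wl <- geo$wavelength_centers
  bw <- diff(wl)[1]
  mk <- function(spec) {
    counts <- array(0, dim = c(1, 1, 5, 2, 8))
    counts[1, 1, , 1, 1] <- spec
    hdim_stack(counts, wl, geo$time_bin_edges)
  }
  # single nonzero bin -> its center
  expect_equal(map_values(spectral_peak_map(mk(c(0, 0, 7, 0, 0)),
                                            min_counts = 1)), wl[3])
  # symmetric triplet -> no shift
  expect_equal(map_values(spectral_peak_map(mk(c(0, 1, 4, 1, 0)),
                                            min_counts = 1)), wl[3])
  # triplet (1, 4, 3): delta = +0.25 bin widths toward the larger neighbor
  expect_equal(map_values(spectral_peak_map(mk(c(0, 1, 4, 3, 0)),
                                            min_counts = 1)),
               wl[3] + 0.25 * bw)
  # edge maximum returned uninterpolated
  expect_equal(map_values(spectral_peak_map(mk(c(9, 1, 0, 0, 0)),
                                            min_counts = 1)), wl[1])
  # centroid option
  expect_equal(map_values(spectral_peak_map(mk(c(0, 2, 0, 2, 0)),
                                            min_counts = 1,
                                            method = "centroid")),
               mean(wl[c(2, 4)]))
})

test_that("feature histograms conserve pixel counts and pool additively", {
  geo <- tiny_geometry(4, 4)
  scn <- uniform_scene(4, 4, "FITC", 10)
  st1 <- simulate_stack(scn, geometry = geo, seed = 1)
  st2 <- simulate_stack(scn, geometry = geo, seed = 2)
  maps <- list(a = mean_lifetime_map(st1, min_counts = 1),
               b = mean_lifetime_map(st2, min_counts = 1))
  h <- feature_histograms(maps, bins = 16)
  per <- dplyr::filter(h, condition != "pooled")
  pooled <- dplyr::filter(h, condition == "pooled")
  expect_equal(sum(per$count), 32)          # every unmasked pixel counted
  expect_equal(sum(pooled$count), 32)       # pooled = sum of conditions
  expect_equal(sum(pooled$count), sum(per$count))
  # constant map occupies a single bin
  cm <- maps$a
  cm$values[] <- 3
  hc <- feature_histograms(list(c = cm), bins = 8)
  expect_equal(sum(dplyr::filter(hc, condition == "c")$count > 0), 1)
  # mixed units are rejected
  expect_error(feature_histograms(list(a = maps$a,
                                       b = anisotropy_map(st1, 1))),
               "units")
})

test_that("panel estimators reproduce the quenching and viscosity ordering", {
  stacks <- poisson_panel()
  med <- function(f, s) median(map_values(f(s)))
  tau_med <- vapply(stacks, function(s) med(mean_lifetime_map, s), numeric(1))
  r_med <- vapply(stacks, function(s) med(anisotropy_map, s), numeric(1))
  # quenched conditions have strictly smaller median lifetime
  for (comp in c("F", "R", "D")) {
    expect_lt(tau_med[paste0(comp, "Q")], tau_med[paste0(comp, "0")])
    expect_lt(tau_med[paste0(comp, "B")], tau_med[paste0(comp, "G")])
    # glycerol conditions have strictly larger median anisotropy
    expect_gt(r_med[paste0(comp, "G")], r_med[paste0(comp, "0")])
    expect_gt(r_med[paste0(comp, "B")], r_med[paste0(comp, "Q")])
  }
})
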
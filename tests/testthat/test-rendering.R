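make_score_map <- function(values, mask = NULL) {
  v <- as.matrix(values)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(v), ncol(v))
  hyperdim:::new_feature_map(v, "PC", "score", mask)
}

test_that("true color weights spectra into plausible RGB", {
  geo <- tiny_geometry(3, 3, n_spectral = 16)
  # all-zero stack renders black
  z <- hdim_stack(array(0, dim = c(3, 3, 16, 2, 8)),
                  default_wavelength_centers(), geo$time_bin_edges)
  expect_true(all(true_color(z)$channels == 0))
  # monochromatic 550 nm scene is green-dominant
  wl <- default_wavelength_centers()
  k550 <- which.min(abs(wl - 550))
  counts <- array(0, dim = c(3, 3, 16, 2, 8))
  counts[, , k550, , ] <- 50
  st <- hdim_stack(counts, wl, geo$time_bin_edges)
  img <- true_color(st)$channels
  expect_true(all(img[, , 2] >= img[, , 1]))
  expect_true(all(img[, , 2] >= img[, , 3]))
  # flat equal-counts spectrum renders near-neutral
  counts[] <- 10
  flat_img <- true_color(hdim_stack(counts, wl, geo$time_bin_edges))$channels
  px <- flat_img[1, 1, ]
  expect_lt(max(px) / min(px), 1.35)
  # wrong matrix shape is rejected
  expect_error(true_color(st, matrix(1, 3, 5)), "3 x 16")
})

test_that("stretch anchors map min to 0 and median + 3 SD to 1 at s = 1", {
  vals <- matrix(c(0, 1, 2, 3, 4, 5, 6, 7, 8), 3, 3)
  m <- make_score_map(vals)
  hi <- median(vals) + 3 * sd(vals)
  st <- stretch_component(m, stain_params(s = 1))
  expect_equal(st$values[vals == 0], 0)
  # a value exactly at median + 3 SD would map to 1; interpolate by formula
  expect_equal(st$values[2, 2], (vals[2, 2] - 0) / (hi - 0))
  # monotone non-decreasing in the input score
  o <- order(as.vector(vals))
  expect_true(all(diff(as.vector(st$values)[o]) >= 0))
  # values beyond the robust max clip at 1
  vals2 <- matrix(seq(0, 1, length.out = 100), 10, 10)
  vals2[10, 10] <- 3    # far above median + 3 SD on this map
  st2 <- stretch_component(make_score_map(vals2), stain_params(s = 1))
  expect_equal(st2$values[10, 10], 1)
  # constant map degenerates to zeros with a warning
  expect_warning(stc <- stretch_component(make_score_map(matrix(5, 3, 3))),
                 "constant")
  expect_true(all(stc$values == 0))
})

test_that("auto-s saturates at the requested percentile", {
  v <- matrix(seq(0, 1, length.out = 400), 20, 20)
  m <- make_score_map(v)
  st <- stretch_component(m, stain_params(s = "auto",
                                          saturation_percentile = 95))
  # at most ~5% of pixels saturate at 1
  expect_lte(mean(st$values >= 1 - 1e-12), 0.055)
  # s never drops below 1: when the percentile would not saturate at s = 1,
  # auto-s leaves s at 1 rather than shrinking it
  v2 <- v
  v2[1, 1] <- 10
  st2 <- stretch_component(make_score_map(v2), stain_params(s = "auto"))
  st2_ref <- stretch_component(make_score_map(v2), stain_params(s = 1))
  expect_equal(st2$values, st2_ref$values, tolerance = 1e-12)
})

test_that("CMYK conversion reproduces its corner cases", {
  one <- matrix(1, 2, 2)
  zero <- matrix(0, 2, 2)
  expect_true(all(cmyk_to_rgb(zero, zero, zero, zero)$channels == 1)) # white
  expect_true(all(cmyk_to_rgb(zero, zero, zero, one)$channels == 0))  # black
  cyan <- cmyk_to_rgb(one, zero, zero, zero)$channels
  expect_equal(cyan[1, 1, ], c(0, 1, 1))                              # cyan
  magenta <- cmyk_to_rgb(zero, one, zero, zero)$channels
  expect_equal(magenta[1, 1, ], c(1, 0, 1))
  expect_warning(out <- cmyk_to_rgb(matrix(2, 2, 2), zero, zero, zero),
                 "clipping")
  expect_true(all(out$channels >= 0 & out$channels <= 1))
})

test_that("digital stains compose components deterministically", {
  maps <- withr::with_seed(72, {
    lapply(1:4, function(k) make_score_map(matrix(rnorm(64), 8, 8)))
  })
  names(maps) <- paste0("PC", 1:4)
  he1 <- render_he_like(maps)
  he2 <- render_he_like(maps)
  expect_identical(he1$channels, he2$channels)
  expect_true(all(he1$channels >= 0 & he1$channels <= 1))
  expect_false(anyNA(he1$channels))
  # all-zero scores render white after the degenerate-stretch fallback
  zmaps <- lapply(maps, function(m) { m$values[] <- 0; m })
  expect_warning(stretch_component(zmaps$PC1), "constant")
  white <- suppressWarnings(render_he_like(zmaps))  # one warning per channel
  expect_true(all(white$channels == 1))
  # HE-like output is independent of PC4
  maps2 <- maps
  maps2$PC4$values <- maps2$PC4$values * 100
  expect_identical(render_he_like(maps2)$channels, he1$channels)
  # but the DAB-like stain is not
  expect_false(identical(render_dab_like(maps2)$channels,
                         render_dab_like(maps)$channels))
  # a pixel maximal in PC1 only renders magenta-dominant (G smallest)
  sel <- lapply(paste0("PC", 1:4), function(nm) {
    m <- maps[[nm]]
    m$values[] <- 0
    if (nm == "PC1") m$values[3, 3] <- 5
    m$values[1, 1] <- if (nm == "PC1") -1 else 1e-9  # avoid constant maps
    m
  })
  names(sel) <- paste0("PC", 1:4)
  img <- render_he_like(sel)$channels
  px <- img[3, 3, ]
  expect_lt(px[2], px[1])
  expect_lt(px[2], px[3])
  # missing components are named in the error
  expect_error(render_dab_like(maps[1:3]), "PC4")
  expect_error(render_he_like(maps[c(1, 3)]), "PC2")
})

test_that("RGB images export to PNG", {
  maps <- withr::with_seed(73, {
    m <- lapply(1:3, function(k) make_score_map(matrix(runif(16), 4, 4)))
    names(m) <- paste0("PC", 1:3)
    m
  })
  img <- render_he_like(maps)
  path <- withr::local_tempfile(fileext = ".png")
  write_rgb_png(img, path)
  back <- png::readPNG(path)
  expect_equal(back, img$channels, tolerance = 1 / 255)
})
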
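test_that("stack construction enforces the container invariants", {
  geo <- tiny_geometry()
  counts <- array(0L, dim = c(6, 5, 4, 2, 8))
  st <- hdim_stack(counts, geo$wavelength_centers, geo$time_bin_edges)
  expect_s3_class(st, "hdim_stack")
  expect_identical(dim(st), c(6L, 5L, 4L, 2L, 8L))
  # default geometry carries 16 x 2 x 64 = 2048 values per pixel
  g <- hdim_geometry()
  expect_identical(as.integer(g$n_spectral * 2 * g$n_time), 2048L)
  expect_error(hdim_stack(array(-1, dim = c(2, 2, 4, 2, 8)),
                          geo$wavelength_centers, geo$time_bin_edges),
               "nonnegative")
  expect_error(hdim_stack(counts, rev(geo$wavelength_centers),
                          geo$time_bin_edges), "increasing")
  expect_error(hdim_stack(counts, geo$wavelength_centers,
                          geo$time_bin_edges[-3]), "edges")
  expect_error(hdim_stack(counts, geo$wavelength_centers,
                          geo$time_bin_edges, g_factor = 0), "g_factor")
})

test_that("projection sums counts, conserves photons and commutes", {
  st <- random_stack(seed = 101)
  tot <- total_counts(st)
  # identity case
  p0 <- project(st)
  expect_identical(p0$counts, st$counts)
  # every single-axis collapse conserves the total exactly
  for (ax in c("row", "col", "spectral", "polarization", "time")) {
    expect_identical(sum(project(st, ax)$counts), tot)
  }
  # full collapse to a scalar
  expect_identical(project(st, c("row", "col", "spectral", "polarization",
                                 "time"))$counts, tot)
  # total-counts image
  img <- project(st, c("spectral", "polarization", "time"))
  expect_identical(dim(img$counts), dim(st$counts)[1:2])
  expect_identical(sum(img$counts), tot)
  # stepwise collapse equals one-step collapse (associativity)
  step1 <- project(st, c("time", "polarization"))$counts  # (row, col, spectral)
  two <- apply(step1, c(1, 2), sum)                       # then spectral
  one <- project(st, c("time", "polarization", "spectral"))$counts
  expect_equal(unname(two), unname(one))
  expect_identical(sum(step1), tot)
  # unknown axis is rejected with the valid axes listed
  expect_error(project(st, "wavelength"), "valid axes")
})

test_that("projection order does not matter", {
  st <- random_stack(seed = 7)
  a <- project(st, c("time", "polarization", "spectral"))$counts
  # collapse in two steps through an intermediate projection of the raw array
  tmp <- apply(st$counts, c(1, 2, 3), sum)   # collapse pol+time
  b <- apply(tmp, c(1, 2), sum)              # then spectral
  expect_equal(unname(a), unname(b))
  d <- project(st, c("spectral", "time", "polarization"))$counts
  expect_identical(a, d)
})

test_that("tidy() turns projections into labeled tibbles", {
  st <- random_stack(seed = 3)
  tb <- tidy(project(st, c("row", "col", "polarization")))
  expect_s3_class(tb, "tbl_df")
  expect_named(tb, c("spectral", "time", "counts"))
  expect_identical(sum(tb$counts), total_counts(st))
  # coordinates follow canonical array order: first axis varies fastest
  expect_equal(tb$spectral[1:2], st$wavelength_centers[1:2])
})

test_that("spatial binning sums blocks and drops ragged edges", {
  geo <- tiny_geometry(8, 8)
  counts <- array(1L, dim = c(8, 8, 4, 2, 8))
  st <- hdim_stack(counts, geo$wavelength_centers, geo$time_bin_edges)
  b <- spatial_bin(st, 4)
  expect_identical(dim(b)[1:2], c(2L, 2L))
  expect_true(all(b$counts == 16))
  expect_identical(total_counts(b), total_counts(st))
  # factor 1 is the identity
  expect_identical(spatial_bin(st, 1)$counts, st$counts)
  # 9 x 9 with factor 4 drops the last row/col
  st9 <- random_stack(seed = 5, rows = 9, cols = 9)
  b9 <- spatial_bin(st9, 4)
  expect_identical(dim(b9)[1:2], c(2L, 2L))
  expect_identical(sum(b9$counts), sum(st9$counts[1:8, 1:8, , , ]))
  # block content matches a direct sum
  direct <- apply(st9$counts[1:4, 5:8, , , , drop = FALSE], 3:5, sum)
  expect_equal(unname(b9$counts[1, 2, , , ]), unname(direct))
  expect_error(spatial_bin(st, 0), "factor")
})

test_that("HDF5 container round-trips counts, axes and metadata", {
  st <- random_stack(seed = 11)
  st$provenance <- list(generator = "test", seed = 11L)
  path <- withr::local_tempfile(fileext = ".h5")
  write_hdim(st, path)
  back <- read_hdim(path)
  expect_identical(unname(back$counts + 0L), unname(st$counts + 0L))
  expect_equal(back$wavelength_centers, st$wavelength_centers)
  expect_equal(back$time_bin_edges, st$time_bin_edges)
  expect_identical(back$polarization_labels, st$polarization_labels)
  expect_equal(back$g_factor, st$g_factor)
  expect_equal(back$provenance$seed, 11)
  # all-zero stack round-trips too
  z <- hdim_stack(array(0L, dim = dim(st$counts)),
                  st$wavelength_centers, st$time_bin_edges)
  p2 <- withr::local_tempfile(fileext = ".h5")
  write_hdim(z, p2)
  expect_true(all(read_hdim(p2)$counts == 0))
})

test_that("corrupt containers are rejected naming the missing dataset", {
  st <- random_stack(seed = 13)
  path <- withr::local_tempfile(fileext = ".h5")
  write_hdim(st, path)
  rhdf5::h5delete(path, "axes/wavelength_centers")
  expect_error(read_hdim(path), "wavelength_centers")
  # version mismatch
  p2 <- withr::local_tempfile(fileext = ".h5")
  write_hdim(st, p2)
  rhdf5::h5delete(p2, "format_version")
  rhdf5::h5write(99L, p2, "format_version")
  rhdf5::h5closeAll()
  expect_error(read_hdim(p2), "version")
  expect_error(read_hdim(withr::local_tempfile()), "not found")
})

test_that("TIFF import/export round-trips with the JSON sidecar", {
  st <- random_stack(seed = 17)
  tp <- withr::local_tempfile(fileext = ".tif")
  jp <- withr::local_tempfile(fileext = ".json")
  write_hdim_tiff(st, tp, jp)
  back <- read_hdim_tiff(tp, jp)
  expect_identical(unname(back$counts + 0L), unname(st$counts + 0L))
  expect_equal(back$wavelength_centers, st$wavelength_centers)
  # sidecar missing a required field is rejected by name
  meta <- jsonlite::fromJSON(jp)
  meta$time_bin_edges <- NULL
  jsonlite::write_json(meta, jp, auto_unbox = TRUE, digits = NA)
  expect_error(read_hdim_tiff(tp, jp), "time_bin_edges")
})

test_that("feature-map TIFF export inverts through its sidecar scale", {
  st <- random_stack(seed = 19, mean_counts = 20)
  m <- mean_lifetime_map(st, min_counts = 1)
  tp <- withr::local_tempfile(fileext = ".tif")
  write_feature_map_tiff(m, tp)
  back <- read_feature_map_tiff(tp)
  expect_lt(max(abs(back$values - m$values), na.rm = TRUE), 1e-6)
  expect_identical(back$mask, m$mask)
  expect_identical(back$units, "ns")
})

test_that("hdss_matrix flattens pixels in the canonical order", {
  st <- random_stack(seed = 23, rows = 3, cols = 2)
  m <- hdss_matrix(st)
  d <- dim(st$counts)
  expect_identical(dim(m), c(6L, as.integer(prod(d[3:5]))))
  # pixel (2, 1) is row 2; spectral index varies fastest in the vector
  expect_identical(m[2, ], as.vector(st$counts[2, 1, , , ]))
  # total_count normalization gives unit row sums
  mn <- hdss_matrix(st, "total_count")
  expect_equal(unname(rowSums(mn)), rep(1, 6))
})
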
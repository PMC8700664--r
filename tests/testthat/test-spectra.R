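test_that("wide CSV read-back and round trip preserve grid, ids and values", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,950,952,954",
               "s1,0.5,0.4,0.3",
               "s2,0.6,0.5,0.4",
               "s3,0.7,0.6,0.5"), path)
  s <- read_spectra_table(path, mode = "reflectance")
  expect_equal(s$grid, c(950, 952, 954))
  expect_equal(s$sample_ids, c("s1", "s2", "s3"))
  expect_equal(unname(s$intensities[2, ]), c(0.6, 0.5, 0.4))

  # full-precision round trip, including unsorted headers getting sorted
  s2 <- tiny_spectra()
  s2$intensities[1, 1] <- 1 / 3
  out <- withr::local_tempfile(fileext = ".csv")
  write_spectra_table(spectra_set(s2$grid, s2$intensities, s2$sample_ids), out)
  back <- read_spectra_table(out, mode = "reflectance")
  expect_identical(back$grid, s2$grid)
  expect_identical(back$sample_ids, s2$sample_ids)
  expect_equal(unname(back$intensities), unname(s2$intensities), tolerance = 0)
})

test_that("spectral table format errors are specific", {
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,950,952", "s1,0.5,oops"), bad)
  expect_error(read_spectra_table(bad), "non-numeric value.*952")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,950,950", "s1,0.5,0.6"), dup)
  expect_error(read_spectra_table(dup), "duplicate wavelength")

  neg <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,950,952", "s1,-0.5,0.6"), neg)
  expect_error(read_spectra_table(neg, mode = "reflectance"), "non-positive reflectance")
  expect_silent(read_spectra_table(neg, mode = "absorbance"))

  hdr <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,950,alpha", "s1,0.5,0.6"), hdr)
  expect_error(read_spectra_table(hdr), "non-numeric wavelength header")
})

test_that("average_scans groups by block or scan_of map", {
  # 5 identical scans reproduce the spectrum; means are exact
  one <- tiny_spectra()
  scans <- spectra_set(one$grid, one$intensities[rep(1, 5), ],
                       sample_ids = paste0("a_s", 1:5), mode = "reflectance")
  avg <- average_scans(scans, 5L)
  expect_equal(nrow(avg$intensities), 1L)
  expect_equal(unname(avg$intensities[1, ]), unname(one$intensities[1, ]))
  expect_equal(avg$sample_ids, "a")

  vals <- matrix(1:5, 5, 1)
  s <- spectra_set(950, vals, sample_ids = paste0("x_s", 1:5), mode = "reflectance")
  expect_equal(unname(average_scans(s, 5L)$intensities[1, 1]), 3)

  # 10 scans at 5 per sample -> 2 samples; mode unchanged
  s10 <- spectra_set(950, matrix(rep(1:2, each = 5), 10, 1),
                     sample_ids = c(paste0("p_s", 1:5), paste0("q_s", 1:5)),
                     mode = "reflectance")
  a10 <- average_scans(s10, 5L)
  expect_equal(dim(a10$intensities), c(2L, 1L))
  expect_equal(a10$mode, "reflectance")

  expect_error(average_scans(s10, 4L), "not divisible")

  # explicit scan_of map overrides block grouping
  smap <- spectra_set(950, matrix(c(1, 3, 2, 4), 4, 1),
                      sample_ids = paste0("r", 1:4), mode = "reflectance",
                      scan_of = c("u", "v", "u", "v"))
  am <- average_scans(smap)
  expect_equal(unname(am$intensities[, 1]), c(1.5, 3.5))
  expect_equal(am$sample_ids, c("u", "v"))
})

test_that("to_absorbance implements log10(1/R) with guarded domain", {
  s <- spectra_set(c(950, 952, 954), matrix(c(1, 0.1, 0.01), 1, 3), "a")
  a <- to_absorbance(s)
  expect_equal(unname(a$intensities[1, ]), c(0, 1, 2))
  expect_equal(a$mode, "absorbance")
  expect_identical(a$grid, s$grid)
  expect_identical(a$sample_ids, s$sample_ids)
  expect_error(to_absorbance(a), "already in absorbance")

  # monotone decreasing on random positive matrices
  nirfruit:::with_seed(7, {
    for (i in 1:5) {
      R1 <- matrix(stats::runif(40, 0.01, 1), 4, 10)
      R2 <- R1 + matrix(stats::runif(40, 0.01, 0.5), 4, 10)
      g <- seq(400, by = 2, length.out = 10)
      A1 <- to_absorbance(spectra_set(g, R1, mode = "reflectance"))$intensities
      A2 <- to_absorbance(spectra_set(g, R2, mode = "reflectance"))$intensities
      expect_true(all(A1 > A2))
    }
  })
})

test_that("pipeline averages scans in reflectance space before the transform", {
  # mean-then-log differs from log-then-mean, so the order is observable
  g <- c(950, 952)
  scans <- spectra_set(g, matrix(c(0.1, 0.1, 0.9, 0.9), 2, 2, byrow = TRUE),
                       sample_ids = c("a_s1", "a_s2"), mode = "reflectance",
                       scan_of = c("a", "a"))
  pre <- preprocess_spectra(scans, preprocess_config(scatter_method = "none",
                                                     threshold_rule = "none",
                                                     wavelet_level = 1L))
  expect_equal(unname(pre$intensities[1, 1]), -log10(mean(c(0.1, 0.9))))
  expect_false(isTRUE(all.equal(unname(pre$intensities[1, 1]),
                                mean(-log10(c(0.1, 0.9))))))
})
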
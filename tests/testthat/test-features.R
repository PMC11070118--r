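test_that("wavelength_index finds nearest points with lower-index ties", {
  g <- c(500, 501, 502)
  expect_equal(wavelength_index(g, 501.4), 2)
  expect_equal(wavelength_index(g, 502), 3)
  expect_equal(wavelength_index(g, 500.5), 1)   # exact midpoint -> lower
  expect_equal(wavelength_index(g, c(500.6, 501.5)), c(2, 2))
  expect_error(wavelength_index(g, 505), class = "range_error")
  expect_error(wavelength_index(c(3, 2, 1), 2), class = "argument_error")
})

test_that("full-range extraction decimates from the first point", {
  s <- fake_processed(seq(450, 1000, length.out = 732), runif(732))
  expect_identical(extract_features(s, feature_scheme("full")), s$values)
  half <- extract_features(s, feature_scheme("full", decimation = 2))
  expect_length(half, 366)
  expect_identical(half, s$values[seq(1, 732, by = 2)])
  one <- extract_features(s, feature_scheme("full", decimation = 1000))
  expect_identical(one, s$values[1])
})

test_that("band extraction concatenates closed bands in order", {
  g <- canonical_grid()
  keep <- g >= 450 & g <= 1000
  s <- fake_processed(g[keep], seq_len(sum(keep)) / sum(keep))
  v <- extract_features(s, feature_scheme("band"))
  expect_length(v, sum(g >= 470 & g <= 520) + sum(g >= 550 & g <= 890))

  whole <- extract_features(s, feature_scheme("band", bands = list(range(s$wavelengths))))
  expect_identical(whole, extract_features(s, feature_scheme("full")))

  dup <- extract_features(s, feature_scheme("band", bands = list(c(500, 600), c(550, 650))))
  expect_length(dup, sum(s$wavelengths >= 500 & s$wavelengths <= 600) +
                  sum(s$wavelengths >= 550 & s$wavelengths <= 650))
})

test_that("point features read the 25 tabulated wavelengths in order", {
  g <- canonical_grid()
  keep <- g >= 450 & g <= 1000
  s <- fake_processed(g[keep], g[keep] / 1000)  # value(lambda) = lambda/1000
  v <- extract_features(s, feature_scheme("point"))
  expect_length(v, 25)
  expect_equal(v[1], 0.485, tolerance = 1e-3)
  expect_equal(v, point_wavelengths() / 1000, tolerance = 1e-3)

  const <- fake_processed(g[keep], rep(0.3, sum(keep)))
  expect_equal(extract_features(const, feature_scheme("point")), rep(0.3, 25))

  # oracle equivalence: indexing by wavelength_index at each tabulated point
  set.seed(12)
  rnd <- fake_processed(g[keep], runif(sum(keep)))
  expect_identical(extract_features(rnd, feature_scheme("point")),
                   rnd$values[wavelength_index(rnd$wavelengths, point_wavelengths())])

  short <- fake_processed(g[g >= 600 & g <= 700], rep(1, sum(g >= 600 & g <= 700)))
  expect_error(extract_features(short, feature_scheme("point")), class = "range_error")
})

test_that("slope features are gradients over the 24 tabulated segments", {
  seg <- slope_segments()
  expect_equal(dim(seg), c(24, 2))
  expect_equal(unname(seg[1, ]), c(450, 475))
  expect_equal(unname(seg[24, ]), c(970, 1000))

  g <- canonical_grid()
  keep <- g >= 450 & g <= 1000
  lin <- fake_processed(g[keep], 0.001 * g[keep])
  v <- extract_features(lin, feature_scheme("slope"))
  expect_length(v, 24)
  # nearest-grid endpoint reads over nominal segment lengths deviate by at
  # most one grid step per endpoint over a >= 10 nm run
  expect_lt(max(abs(v - 0.001)), 1e-4)

  const <- fake_processed(g[keep], rep(0.42, sum(keep)))
  expect_equal(extract_features(const, feature_scheme("slope")), rep(0, 24))

  deg <- extract_features(lin, feature_scheme("slope", angle_degrees = TRUE))
  expect_equal(deg, atan(v) * 180 / pi)
})

test_that("slopes are offset-invariant and both point/slope scale-covariant", {
  g <- canonical_grid()
  keep <- g >= 450 & g <= 1000
  set.seed(5)
  for (i in 1:5) {
    s <- fake_processed(g[keep], runif(sum(keep)))
    shifted <- fake_processed(s$wavelengths, s$values + 0.37)
    scaled <- fake_processed(s$wavelengths, 2.5 * s$values)
    sl <- extract_features(s, feature_scheme("slope"))
    expect_equal(extract_features(shifted, feature_scheme("slope")), sl)
    expect_equal(extract_features(scaled, feature_scheme("slope")), 2.5 * sl)
    expect_equal(extract_features(scaled, feature_scheme("point")),
                 2.5 * extract_features(s, feature_scheme("point")))
  }
})

test_that("featurize stacks spectra into a consistent matrix", {
  d <- small_dataset(seed = 31, n_subjects = 1, reps = 1)
  pp <- preprocess_all(d$spectra, d$calibration)
  M <- featurize(pp, feature_scheme("slope"))
  expect_equal(dim(M), c(8, 24))
  expect_true(all(is.finite(M)))
})
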
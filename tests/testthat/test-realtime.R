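# Shared fixture: a trained full-range model plus held-out subject spectra.
rt_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    ds <- generate_dataset(synthetic_config(n_subjects = 3,
                                            spectra_per_class_per_subject = 4,
                                            noise_sd = 0.005, seed = 91))
    # pooled training: these tests probe stream bookkeeping, not generalization
    pp <- preprocess_all(ds$spectra, ds$calibration)
    sch <- feature_scheme("full", decimation = 2)
    fit <- tissue_classifier(featurize(pp, sch), ds$manifest$class,
                             scheme = sch, preprocess = preprocess_config())
    cache <<- list(ds = ds, fit = fit,
                   test_idx = which(ds$manifest$subject_id == "subject03"))
    cache
  }
})

test_that("sessions are assembled deterministically with fixed-rate timestamps", {
  fx <- rt_fixture()
  spectra <- fx$ds$spectra[fx$test_idx]
  order7 <- c("fat", "muscle", "lung", "kidney", "liver", "heart", "blood")
  sess <- make_session(spectra, order7, period = 0.5)
  expect_equal(length(sess$labels), 7 * 4)
  expect_equal(diff(sess$timestamps), rep(0.5, length(sess$labels) - 1))
  expect_equal(sess$periods$class, order7)
  expect_equal(sess$periods$end - sess$periods$start + 1, rep(4L, 7))

  expect_error(make_session(spectra, character(0)), class = "argument_error")
  expect_error(make_session(spectra[1:3], c("fat", "blood")), class = "argument_error")
  sched <- data.frame(class = "fat", n = 99)
  expect_error(make_session(spectra, sched), class = "argument_error")
})

test_that("boundary exclusion removes exactly the transition samples", {
  fx <- rt_fixture()
  spectra <- fx$ds$spectra[fx$test_idx]
  sess2 <- make_session(spectra, c("fat", "muscle"), boundary_exclusion = 1)
  res <- stream_classify(sess2, fx$fit, fx$ds$calibration)
  expect_equal(sum(res$samples$excluded), 2)  # one each side of the single boundary
  expect_true(res$samples$excluded[4] && res$samples$excluded[5])

  sess0 <- make_session(spectra, "fat", boundary_exclusion = 1)
  res0 <- stream_classify(sess0, fx$fit, fx$ds$calibration)
  expect_equal(sum(res0$samples$excluded), 0)
  expect_equal(res0$metrics$accuracy, 1.0)

  # wider exclusion never eats non-boundary samples
  sess3 <- make_session(spectra, c("fat", "muscle", "lung"), boundary_exclusion = 2)
  res3 <- stream_classify(sess3, fx$fit, fx$ds$calibration)
  expect_equal(sum(res3$samples$excluded), 2 * 2 * 2)
  first_of_first <- 1; last_of_last <- length(sess3$labels)
  expect_false(res3$samples$excluded[first_of_first])
  expect_false(res3$samples$excluded[last_of_last])
})

test_that("streaming bookkeeping matches per-period counts minus exclusions", {
  fx <- rt_fixture()
  spectra <- fx$ds$spectra[fx$test_idx]
  order7 <- c("fat", "muscle", "lung", "kidney", "liver", "heart", "blood")
  sess <- make_session(spectra, order7, boundary_exclusion = 1)
  res <- stream_classify(sess, fx$fit, fx$ds$calibration)
  expected_rows <- vapply(seq_len(nrow(sess$periods)), function(i) {
    n <- sess$periods$end[i] - sess$periods$start[i] + 1L
    internal_left <- if (i > 1) 1L else 0L
    internal_right <- if (i < nrow(sess$periods)) 1L else 0L
    n - internal_left - internal_right
  }, integer(1))
  got <- rowSums(res$confusion)[sess$periods$class]
  expect_equal(unname(got), expected_rows)
  expect_equal(res$n_errors, 0)
})

test_that("streaming equals batch prediction on the non-excluded samples", {
  fx <- rt_fixture()
  spectra <- fx$ds$spectra[fx$test_idx]
  sess <- make_session(spectra, c("fat", "muscle", "lung", "kidney",
                                  "liver", "heart", "blood"))
  res <- stream_classify(sess, fx$fit, fx$ds$calibration)
  pp <- preprocess_all(sess$spectra, fx$ds$calibration)
  batch <- predict(fx$fit, featurize(pp, fx$fit$scheme))
  expect_identical(res$samples$predicted, batch)
})

test_that("a failing sample is flagged and the stream continues", {
  fx <- rt_fixture()
  spectra <- fx$ds$spectra[fx$test_idx]
  g <- canonical_grid()
  fat <- spectra[vapply(spectra, `[[`, character(1), "class_label") == "fat"][1:3]
  dead <- raw_spectrum(g, fx$ds$calibration$noise, class_label = "fat")  # flat after calibration
  sess <- make_session(c(fat, list(dead)), data.frame(class = "fat", n = 4))
  res <- stream_classify(sess, fx$fit, fx$ds$calibration)
  expect_equal(res$n_errors, 1)
  expect_true(res$samples$error[4])
  expect_false(any(res$samples$error[1:3]))
  expect_equal(sum(res$confusion), 3)  # errored sample absent from the summary
})
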
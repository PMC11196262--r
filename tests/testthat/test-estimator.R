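test_that("central-five mean reproduces worked examples", {
  est <- central_five_mean(c(10, 11, 12, 13, 14, 15, 16, 17, 18))
  expect_equal(est$value, 14.0)
  expect_equal(est$n_trimmed_each_side, 2L)

  expect_equal(central_five_mean(rep(7.3, 9))$value, 7.3)

  x <- c(5, 5, 16, 16.5, 17, 17.5, 18, 18.5, 19, 30, 31, 40, 41)
  est <- central_five_mean(x)
  expect_equal(est$value, 18.0)
  expect_equal(est$n_trimmed_each_side, 4L)

  expect_error(central_five_mean(1:8), "protocol")
  expect_error(central_five_mean(1:18), "protocol")
})

test_that("even reading counts discard the value farthest from the median", {
  # 100 is farthest from the median of 1..9,100 and is pre-discarded
  expect_equal(central_five_mean(c(1:9, 100))$value, 5)
  # tie in distance: the larger value (10) is discarded
  expect_equal(central_five_mean(c(1, 10, rep(5.5, 8)))$value, 5.5)
})

test_that("central-five mean agrees exactly with the sort-and-slice oracle", {
  set.seed(21)
  for (i in 1:2000) {
    n <- sample(c(9L, 10L, 11L, 12L, 13L, 15L, 17L), 1)
    x <- exp(rnorm(n, log(18), 0.4))
    expect_identical(central_five_mean(x)$value, oracle_central_five(x))
  }
})

test_that("estimator is permutation-invariant, shift-equivariant and robust", {
  set.seed(22)
  for (i in 1:200) {
    n <- sample(seq(9L, 17L, by = 2L), 1)
    x <- exp(rnorm(n, log(18), 0.3))
    expect_identical(central_five_mean(sample(x))$value,
                     central_five_mean(x)$value)
    cshift <- runif(1, 0.5, 5)
    expect_equal(central_five_mean(x + cshift)$value,
                 central_five_mean(x)$value + cshift, tolerance = 1e-12)
    # up to k corrupted-low readings cannot drag the estimate outside
    # the range of the clean readings
    k <- (n - 5) %/% 2
    x_bad <- x
    bad_idx <- sample(n, sample(k, 1))
    x_bad[bad_idx] <- runif(length(bad_idx), 1e-6, 1e-3)
    est <- central_five_mean(x_bad)$value
    expect_gte(est, min(x[-bad_idx]))
    expect_lte(est, max(x[-bad_idx]))
  }
})

test_that("end-expiratory selection takes one per-cycle maximum", {
  beats <- make_beats(13)
  rs <- select_end_expiratory_maxima(beats)
  expect_s3_class(rs, "reading_set")
  expect_equal(rs$n, 13)
  expect_true(all(rs$vti_cm == 18))

  expect_error(select_end_expiratory_maxima(make_beats(1)), "insufficient")

  # a deflated end-expiratory beat propagates into its reading:
  # selection does not repair noise, trimming does
  vti_end <- rep(18, 13); vti_end[5] <- 12
  rs <- select_end_expiratory_maxima(make_beats(13, vti_end = vti_end))
  expect_equal(rs$vti_cm[5], 12)
  expect_equal(central_five_mean(rs)$value, 18)
})

test_that("selection caps accepted readings at 17, dropping earliest cycles", {
  vti_end <- seq(18, by = 0.1, length.out = 22)
  rs <- select_end_expiratory_maxima(make_beats(22, vti_end = vti_end))
  expect_equal(rs$n, 17)
  expect_equal(rs$vti_cm, vti_end[6:22])
})

test_that("inspiratory beats never contribute to readings", {
  # inspiratory beats larger than the end-expiratory one are still ignored
  beats <- make_beats(10, vti_end = 18, vti_insp = 25)
  rs <- select_end_expiratory_maxima(beats)
  expect_true(all(rs$vti_cm == 18))
})

test_that("conventional consecutive-cycle mean behaves as an unweighted mean", {
  b <- data.frame(t_s = 1:5, vti_cm = c(18, 15, 14, 15, 18),
                  pv_cm_s = 95, resp_phase = seq(0, 0.8, 0.2))
  expect_equal(conventional_consecutive_mean(b), 16.0)
  expect_equal(conventional_consecutive_mean(rep(7.1, 6)), 7.1)
  expect_equal(conventional_consecutive_mean(c(18, 15, 12, 15, 18)), 15.6)
  expect_error(conventional_consecutive_mean(c(18, 15)), "insufficient")
})

test_that("repeat-consistency uses the symmetric change against tolerance", {
  expect_true(repeat_consistency(18.0, 18.0, 5.0))
  expect_false(repeat_consistency(18.0, 16.0, 5.0))  # 11.76% apart
  expect_true(repeat_consistency(18.0, 18.9, 5.0))   # 4.88% apart
  e1 <- central_five_mean(rep(18, 9)); e2 <- central_five_mean(rep(18.9, 9))
  expect_true(repeat_consistency(e1, e2))
})

test_that("trimmed estimator beats the consecutive mean under protocol noise", {
  set.seed(23)
  n_sub <- 300
  err_trim <- err_conv <- numeric(n_sub)
  noise <- noise_params()
  for (i in 1:n_sub) {
    true_vti <- exp(rnorm(1, log(18), 0.15))
    beats <- sample_beats(true_vti, 95, duration_s = 15 * 4, noise = noise)
    rs <- select_end_expiratory_maxima(beats)
    err_trim[i] <- central_five_mean(rs)$value - true_vti
    err_conv[i] <- conventional_consecutive_mean(beats) - true_vti
  }
  expect_lt(sqrt(mean(err_trim^2)), sqrt(mean(err_conv^2)))
})
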
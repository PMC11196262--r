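test_that("Frank-Starling curve saturates, is increasing and concave", {
  fs <- list(vti_plateau_cm = 20, preload_scale = 1)
  expect_equal(frank_starling_vti(50, fs), 20, tolerance = 1e-8)
  expect_equal(frank_starling_vti(1, fs), 20 * (1 - exp(-1)),
               tolerance = 1e-12)
  p <- seq(0.1, 4, by = 0.05)
  v <- frank_starling_vti(p, fs)
  expect_true(all(diff(v) > 0))
  expect_true(all(diff(diff(v)) < 0))  # decreasing finite-difference slope
  expect_error(frank_starling_vti(-1, fs), "positive")
})

test_that("stage preload mapping is symmetric across repeats and ordered", {
  fs <- list(baseline_preload = 2.3)
  expect_identical(stage_preload("SUP1", 0.4, fs),
                   stage_preload("SUP2", 0.4, fs))
  expect_identical(stage_preload("UBE1", 0.4, fs),
                   stage_preload("UBE2", 0.4, fs))
  expect_lt(stage_preload("UBE1", 0.4, fs), stage_preload("SUP1", 0.4, fs))
  expect_gt(stage_preload("SUP_FLUID", 0.4, fs, bolus_ml = 600),
            stage_preload("SUP1", 0.4, fs))
  expect_error(stage_preload("UBE1", 2.3, fs), "degenerate")
})

test_that("euvolemic positional change is sub-screening; deficit raises the fluid response", {
  fs <- list(vti_plateau_cm = 20, preload_scale = 1, baseline_preload = 2.3)
  chg <- function(deficit) {
    v <- vapply(stage_labels(), function(st)
      frank_starling_vti(stage_preload(st, deficit, fs, bolus_ml = 600), fs),
      0)
    c(ube = symmetric_change_pct(v[["UBE1"]], v[["SUP1"]]),
      fluid = symmetric_change_pct(v[["SUP2"]], v[["SUP_FLUID"]]))
  }
  eu <- chg(0)
  expect_lt(eu[["ube"]], 7)
  expect_lt(eu[["fluid"]], 7)
  # strictly larger noiseless fluid-induced change with deficit
  defs <- seq(0, 1.6, by = 0.2)
  fl <- vapply(defs, function(d) chg(d)[["fluid"]], 0)
  expect_true(all(diff(fl) > 0))
})

test_that("beat sampler is exact under degenerate noise settings", {
  quiet <- noise_params(resp_modulation_frac = 0, misalignment_prob = 0,
                        jitter_cv = 0)
  beats <- sample_beats(18, 95, duration_s = 11 * 4, noise = quiet)
  expect_true(all(beats$vti_cm == 18))
  rs <- select_end_expiratory_maxima(beats)
  expect_true(all(rs$vti_cm == 18))
  expect_equal(central_five_mean(rs)$value, 18)

  halved <- noise_params(resp_modulation_frac = 0, misalignment_prob = 0.999999,
                         misalignment_frac_range = c(0.5, 0.5), jitter_cv = 0)
  beats <- sample_beats(18, 95, duration_s = 11 * 4, noise = halved)
  expect_true(all(abs(beats$vti_cm - 9) < 1e-9))

  expect_error(sample_beats(18, 95, duration_s = 10, noise = quiet),
               "insufficient")
})

test_that("selected end-expiratory maxima are nearly unbiased under default noise", {
  set.seed(31)
  means <- vapply(1:1000, function(i) {
    beats <- sample_beats(18, 95, duration_s = 14 * 4)
    mean(select_end_expiratory_maxima(beats)$vti_cm)
  }, 0)
  expect_lt(abs(mean(means) / 18 - 1), 0.02)
})

test_that("cohort generation is deterministic, validated, and labelled", {
  cfg <- cohort_config(n_healthy = 3, n_patients = 5, seed = 99)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  expect_length(c1, 8)

  expect_length(generate_cohort(cohort_config(n_healthy = 0, n_patients = 0,
                                              seed = 1)), 0)
  expect_error(cohort_config(deficit_rate = -1, window = 0.5),
               "deficit_rate.*window")

  tr <- cohort_truth(c1)
  # responder truth is the noiseless fluid change against the threshold
  expect_identical(tr$true_responder, tr$true_fluid_change_pct >= 10)
  for (s in c1) {
    tv <- s$true_vti_by_stage
    expect_identical(unname(tv["UBE1"]), unname(tv["UBE2"]))
    expect_identical(unname(tv["SUP1"]), unname(tv["SUP2"]))
    expect_lt(tv[["UBE1"]], tv[["SUP1"]])
    expect_gt(tv[["SUP_FLUID"]], tv[["SUP2"]])
    expect_true(all(vapply(s$reading_sets, function(r)
      r$n >= 9 && r$n <= 17, TRUE)))
  }
})

test_that("jugular-vein generation respects ordering and healthy anchors", {
  set.seed(32)
  for (i in 1:50) {
    m <- sample_ijv_and_map(sample(stage_labels(), 1), runif(1, 0, 1.5))
    expect_gte(m$ijvd_max_mm, m$ijvd_min_mm)
    expect_gte(m$ijva_max_mm2, m$ijva_min_mm2)
    expect_gt(m$ijvd_min_mm, 0)
  }
  co <- generate_cohort(cohort_config(n_healthy = 45, n_patients = 0,
                                      seed = 33))
  up <- vapply(co, function(s) s$ijv_by_stage$UBE1$ijvd_max_mm, 0)
  down <- vapply(co, function(s) s$ijv_by_stage$SUP1$ijvd_max_mm, 0)
  expect_gt(median(down), median(up))
  # healthy medians sit inside the reference interquartile ranges
  expect_gt(median(up), 1.8); expect_lt(median(up), 3.2)
  expect_gt(median(down), 6.9); expect_lt(median(down), 10.5)
})

test_that("measured fluid response of true responders exceeds non-responders", {
  res <- run_study(cohort_config(n_healthy = 45, n_patients = 120,
                                 seed = 34))
  tr <- cohort_truth(res$cohort)
  m <- res$panels$fluid_change_pct
  expect_gt(mean(m[tr$true_responder]), mean(m[!tr$true_responder]))
})

test_that("split-quantile sampler hits its median and quartiles", {
  set.seed(35)
  x <- quantile_split_sampler(1e5, 7.5, 4.1, 9.7, scale = "log")
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  expect_equal(q[1], 4.1, tolerance = 0.03)
  expect_equal(q[2], 7.5, tolerance = 0.03)
  expect_equal(q[3], 9.7, tolerance = 0.03)

  y <- quantile_split_sampler(1e5, 3.2, 0.5, 6.0, scale = "linear")
  expect_equal(median(y), 3.2, tolerance = 0.05)

  # symmetric targets collapse to a plain normal distribution
  z <- quantile_split_sampler(1e4, 0, -1, 1, scale = "linear")
  sd_n <- 1 / qnorm(0.75)
  ks <- suppressWarnings(ks.test(z, "pnorm", 0, sd_n))
  expect_gt(ks$p.value, 0.01)

  expect_error(quantile_split_sampler(10, 5, 6, 7), "q25 < median")
  expect_error(quantile_split_sampler(10, 1, -1, 2, scale = "log"), "log")
})
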
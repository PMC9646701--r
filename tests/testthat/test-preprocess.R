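# Filtering, baseline alignment, validity and UR normalization.

test_that("filter preserves DC and passband, kills stopband", {
  # constant in, constant out (unit DC gain)
  expect_equal(lowpass_zero_phase(rep(3.7, 200), fps = 300), rep(3.7, 200),
               tolerance = 1e-6)
  # 5 Hz preserved within 2%, 120 Hz attenuated below 1% (fps 300)
  fps <- 300
  t <- seq_len(1500) / fps
  x5 <- sin(2 * pi * 5 * t)
  x120 <- sin(2 * pi * 120 * t)
  y <- lowpass_zero_phase(x5 + x120, fps)
  ref5 <- oracle_fft_lowpass(x5 + x120, fps, 50)
  core <- 301:1200 # away from edges
  amp <- function(v) sqrt(mean(v[core]^2))
  expect_equal(amp(y), amp(x5), tolerance = 0.02)
  expect_lt(amp(y - ref5) / amp(x120), 0.01)
})

test_that("filter is zero-phase on a symmetric pulse", {
  x <- c(rep(0, 140), 1:10, 11, 10:1, rep(0, 139))
  m <- which.max(x)
  y <- lowpass_zero_phase(x, fps = 300)
  expect_equal(which.max(y), m)
})

test_that("filter contract errors", {
  expect_error(lowpass_zero_phase(rnorm(100), fps = 80, cutoff = 50),
               class = "eyeblinkr_invalid_argument")
  expect_error(lowpass_zero_phase(rnorm(5), fps = 300),
               class = "eyeblinkr_invalid_argument")
  expect_error(lowpass_zero_phase(c(rnorm(99), NA), fps = 300),
               class = "eyeblinkr_invalid_argument")
})

test_that("baseline alignment subtracts the pre-CS median", {
  x <- c(rep(7.3, 150), rnorm(450))
  al <- baseline_align(x, cs_onset_index = 150, fps = 300)
  expect_equal(al$baseline_offset, 7.3)
  expect_equal(al$samples[1:150], rep(0, 150))
  # median robustness: one outlier does not shift the baseline
  x2 <- c(rep(0, 149), 10, rnorm(450))
  expect_equal(baseline_align(x2, 150, 300)$baseline_offset, 0)
  expect_error(baseline_align(rnorm(600), cs_onset_index = 100, fps = 300),
               class = "eyeblinkr_invalid_argument")
})

test_that("baseline alignment is idempotent", {
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(600, mean = runif(1, -5, 5))
    a1 <- baseline_align(x, 150, 300)$samples
    a2 <- baseline_align(a1, 150, 300)$samples
    expect_equal(a2, a1, tolerance = 1e-12)
  }
})

test_that("validity follows the 7 x IQR rule", {
  # flat baseline is valid
  expect_true(trial_validity(rep(0, 600), 150, 300))
  # hand-computed fixed vector: 149 values alternating +/-0.05 (IQR 0.1),
  # one excursion to 5.0 -> deviation 5.0 > 7 * 0.1
  pre <- rep(c(-0.05, 0.05), length.out = 149)
  x <- c(pre, 5.0, rnorm(450, 0, 0.01))
  expect_equal(IQR(x[1:150]), 0.1)
  expect_false(trial_validity(x, 150, 300))
  # same shape with the excursion below the limit is valid
  x2 <- c(pre, 0.65, rnorm(450, 0, 0.01))
  expect_true(trial_validity(x2, 150, 300))
  # scale invariance of the flag
  for (c_ in c(0.01, 3, 1e4)) {
    expect_equal(trial_validity(x * c_, 150, 300), FALSE)
    expect_equal(trial_validity(x2 * c_, 150, 300), TRUE)
  }
})

test_that("larger pre-CS artifacts never flip invalid back to valid", {
  set.seed(21)
  base <- rnorm(600, 0, 0.1)
  flags <- vapply(seq(0, 6, by = 0.5), function(a) {
    x <- base
    x[60:70] <- x[60:70] + a
    trial_validity(x, 150, 300)
  }, logical(1))
  # once invalid, stays invalid as the artifact grows
  expect_true(all(diff(as.integer(flags)) <= 0))
})

test_that("UR factor averages valid US trials over the post-US window", {
  fps <- 10; cs <- 5; isi <- 250 # US impact at sample cs + 2.5 -> index 8
  ur <- function(pk) c(rep(0, 8), pk, pk / 2, 0)
  s1 <- make_session(list(ur(3.2), ur(3.2)), c("US_ONLY", "PAIRED"),
                     fps = fps, cs_idx = cs, isi = isi)
  expect_equal(session_ur_factor(s1), 3.2)
  # two identical-shape URs with peaks 2 and 4 average to 3
  s2 <- make_session(list(ur(2), ur(4)), c("US_ONLY", "US_ONLY"),
                     fps = fps, cs_idx = cs, isi = isi)
  expect_equal(session_ur_factor(s2), 3)
  # CS-only trials never feed the factor
  s3 <- make_session(list(ur(2), ur(4), c(rep(0, 8), 99, 99, 99)),
                     c("US_ONLY", "US_ONLY", "CS_ONLY"),
                     fps = fps, cs_idx = cs, isi = isi)
  expect_equal(session_ur_factor(s3), 3)
  # a CS-only deflection of 0.6 raw units becomes NEC 0.2 at factor 3
  expect_equal(0.6 / session_ur_factor(s3), 0.2)
  # us_only source ignores paired URs
  s4 <- make_session(list(ur(2), ur(10)), c("US_ONLY", "PAIRED"),
                     fps = fps, cs_idx = cs, isi = isi)
  expect_equal(session_ur_factor(s4, ur_source = "us_only"), 2)
  expect_equal(session_ur_factor(s4, ur_source = "both"), 6)
})

test_that("sessions without usable URs are rejected", {
  s <- make_session(list(rep(0, 11)), "CS_ONLY")
  expect_error(session_ur_factor(s), class = "eyeblinkr_no_ur")
  s2 <- make_session(list(rep(0, 11)), "US_ONLY", valid = FALSE)
  expect_error(session_ur_factor(s2), class = "eyeblinkr_no_ur")
  # US trial present but no closure after the US -> non-positive factor
  s3 <- make_session(list(c(rep(1, 7), 0, 0, 0, 0)), "US_ONLY")
  expect_error(session_ur_factor(s3), class = "eyeblinkr_no_ur")
})

test_that("factor and validity match the brute-force oracle on tiny sessions", {
  set.seed(33)
  fps <- 10; cs <- 5
  for (i in 1:50) {
    n_tr <- sample(2:5, 1)
    types <- c("US_ONLY",
               sample(c("CS_ONLY", "US_ONLY", "PAIRED"), n_tr - 1, TRUE))
    traces <- purrr::map(seq_len(n_tr), function(j) rnorm(30, 0, 1))
    s <- make_session(traces, types, fps = fps, cs_idx = cs, isi = 250,
                      valid = sample(c(TRUE, TRUE, TRUE, FALSE), n_tr, TRUE))
    s$valid[s$trial_type == "US_ONLY"][1] <- TRUE
    f_pkg <- tryCatch(session_ur_factor(s), error = function(e) NA_real_)
    f_orc <- tryCatch(oracle_ur_factor(s), error = function(e) NA_real_)
    if (is.na(f_pkg) || f_pkg <= 0) {
      expect_true(is.na(f_orc) || f_orc <= 0)
    } else {
      expect_identical(f_pkg, f_orc)
    }
    for (j in seq_len(n_tr)) {
      expect_identical(trial_validity(s$samples[[j]], cs, fps, pre_cs_ms = 500),
                       oracle_validity(s$samples[[j]], cs, fps, pre_cs_ms = 500))
    }
  }
})

test_that("NEC output is invariant to session-wide positive rescaling", {
  p <- sim_params(n_per_genotype = 1, days_phase1 = 1, days_phase2 = 0,
                  n_blocks = 2, seed = 13)
  co <- simulate_cohort(p)
  one <- dplyr::filter(co$trials, mouse_id == co$trials$mouse_id[1], day == 1)
  n1 <- normalize_session(one)
  for (c_ in c(0.2, 17)) {
    scaled <- one
    scaled$samples <- purrr::map(scaled$samples, ~ .x * c_)
    n2 <- normalize_session(scaled)
    expect_equal(n2$nec, n1$nec, tolerance = 1e-12)
    expect_identical(n2$valid, n1$valid)
    expect_equal(n2$norm_factor, n1$norm_factor * c_)
  }
})

test_that("noise-free US-only trials normalize to NEC peak exactly 1", {
  p <- sim_params(n_per_genotype = 1, days_phase1 = 1, days_phase2 = 0,
                  n_blocks = 2, noise_sd = 0, artifact_prob = 0, seed = 19,
                  learn_rate_by_genotype = c(WT = 1e-9, NF1_HET = 1e-9))
  co <- simulate_cohort(p)
  one <- dplyr::filter(co$trials, mouse_id == co$trials$mouse_id[1])
  norm <- normalize_session(one)
  us <- dplyr::filter(norm, trial_type == "US_ONLY")
  for (nec in us$nec) expect_equal(max(nec), 1, tolerance = 1e-12)
  # invalid trials would still be normalized (flag only)
  expect_true(all(c("valid", "norm_factor", "nec") %in% names(norm)))
})

test_that("pre-CS median of NEC traces is numerically zero", {
  p <- sim_params(n_per_genotype = 1, days_phase1 = 1, days_phase2 = 0,
                  n_blocks = 1, seed = 23)
  co <- simulate_cohort(p)
  norm <- normalize_cohort(co$trials)
  pre_meds <- purrr::map2_dbl(norm$nec, norm$cs_onset_index,
                              ~ median(.x[1:.y]))
  expect_true(all(abs(pre_meds) < 1e-9))
})
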
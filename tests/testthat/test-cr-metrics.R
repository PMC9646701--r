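# CR detection, timing flags and session summaries.

fps <- 300
cs <- 150 # 0-based CS onset

# helper: NEC trace with a linear rise crossing 0.02 at `onset_ms`, peaking
# `amp` at `peak_ms`, then symmetric decay; exact on the sample grid
linear_bump <- function(onset_ms, peak_ms, amp, n = 600) {
  t_ms <- (seq_len(n) - 1 - cs) / fps * 1000
  y <- numeric(n)
  up <- t_ms >= onset_ms & t_ms <= peak_ms
  y[up] <- 0.02 + (amp - 0.02) * (t_ms[up] - onset_ms) / (peak_ms - onset_ms)
  dn <- t_ms > peak_ms & t_ms <= 2 * peak_ms - onset_ms
  y[dn] <- 0.02 + (amp - 0.02) * (2 * peak_ms - onset_ms - t_ms[dn]) /
    (peak_ms - onset_ms)
  y
}

test_that("detect_cr applies the amplitude and window rules", {
  # no movement, no CR
  z <- detect_cr(rep(0, 600), fps, cs)
  expect_false(z$is_cr)
  expect_true(is.na(z$onset_ms))
  # constructed bump: crosses 0.02 at 130 ms, peaks 0.45 at 240 ms
  d <- detect_cr(linear_bump(130, 240, 0.45), fps, cs)
  expect_true(d$is_cr)
  expect_equal(d$onset_ms, 130)
  expect_equal(d$peak_ms, 240)
  expect_equal(d$peak_nec, 0.45)
  # amplitude below 0.1 fails the CR rule
  expect_false(detect_cr(linear_bump(130, 240, 0.09), fps, cs)$is_cr)
  # onset before the 50 ms window opens fails
  expect_false(detect_cr(linear_bump(40, 140, 0.5), fps, cs)$is_cr)
  # onset after the 500 ms window closes fails
  expect_false(detect_cr(linear_bump(510, 620, 0.5), fps, cs)$is_cr)
  # the peak search stops at 1000 ms: a trace still rising there is scored
  # at the boundary sample
  expect_equal(detect_cr(linear_bump(400, 1100, 0.5), fps, cs)$peak_ms, 1000)
  # boundary onsets are inside the closed windows
  expect_true(detect_cr(linear_bump(50, 150, 0.5), fps, cs)$is_cr)
  expect_true(detect_cr(linear_bump(500, 600, 0.5), fps, cs)$is_cr)
})

test_that("detect_cr matches the definitional oracle on random traces", {
  set.seed(77)
  for (i in 1:1000) {
    n <- 60
    fps_i <- 20
    cs_i <- 10
    nec <- cumsum(rnorm(n, 0, 0.05))
    d <- detect_cr(nec, fps_i, cs_i)
    o <- oracle_detect_cr(nec, fps_i, cs_i)
    expect_identical(d$is_cr, o$is_cr)
    expect_identical(d$onset_ms, o$onset_ms)
    expect_identical(d$peak_ms, o$peak_ms)
    expect_identical(d$peak_nec, o$peak_nec)
  }
})

test_that("every reported latency lies inside the windows when a CR fires", {
  set.seed(78)
  for (i in 1:200) {
    nec <- cumsum(rnorm(120, 0, 0.05))
    d <- detect_cr(nec, 60, 20)
    if (d$is_cr) {
      expect_true(d$onset_ms >= 50 && d$onset_ms <= 500)
      expect_true(d$peak_ms >= 100 && d$peak_ms <= 1000)
      expect_true(d$onset_ms < d$peak_ms)
      expect_gt(d$peak_nec, 0.1)
    }
  }
})

test_that("perfectly-timed window is closed and ISI-centred", {
  expect_true(perfectly_timed(250, 250))
  expect_true(perfectly_timed(549, 500))
  expect_false(perfectly_timed(551, 500))
  expect_true(perfectly_timed(300, 250)) # boundary inclusive
  expect_true(perfectly_timed(200, 250))
  expect_false(perfectly_timed(199, 250))
  expect_equal(perfectly_timed(c(450, 550, 561), 500),
               c(TRUE, TRUE, FALSE))
})

test_that("nec_at evaluates the sampled trace at the requested latency", {
  expect_equal(nec_at(rep(0, 600), 250, fps, cs), 0)
  # fps 300: 250 ms is 75 samples past CS onset
  x <- numeric(600)
  x[cs + 75 + 1] <- 0.42
  expect_equal(nec_at(x, 250, fps, cs), 0.42)
  # linear ramp nec(t) = t / 1000 from CS onset
  ramp <- c(rep(0, cs), (0:(449)) / fps * 1000 / 1000)
  expect_equal(nec_at(ramp, 500, fps, cs), 0.5)
  expect_error(nec_at(rep(0, 600), 2000, fps, cs),
               class = "eyeblinkr_invalid_argument")
})

test_that("session summaries compute proportions over valid CS-only trials", {
  scored <- tibble::tibble(
    mouse_id = "m", genotype = "WT", day = 1L, phase = "ISI250",
    isi_ms = 250,
    valid = rep(TRUE, 20),
    is_cr = rep(c(TRUE, FALSE), c(14, 6)),
    onset_ms = ifelse(rep(c(TRUE, FALSE), c(14, 6)), 120, NA),
    peak_ms = ifelse(rep(c(TRUE, FALSE), c(14, 6)), 240, NA),
    peak_nec = 0.4, perfect = rep(c(TRUE, FALSE), c(7, 13)),
    nec_250 = 0.3, nec_500 = 0.1
  )
  s <- summarize_sessions(scored)
  expect_equal(s$cr_proportion, 0.7)
  expect_equal(s$perfect_proportion, 0.35)
  expect_equal(s$n_cs_only_valid, 20)
  expect_equal(s$mean_onset_ms, 120)
  expect_equal(s$nec_250, 0.3)
  # all-invalid session is emitted with undefined metrics, never dropped
  scored$valid <- FALSE
  scored$is_cr <- NA
  s0 <- summarize_sessions(scored)
  expect_equal(nrow(s0), 1)
  expect_equal(s0$n_cs_only_valid, 0)
  expect_true(is.na(s0$cr_proportion))
})

test_that("perfect proportion never exceeds CR proportion", {
  co <- simulate_cohort(sim_params(n_per_genotype = 2, days_phase1 = 3,
                                   days_phase2 = 2, n_blocks = 2, seed = 31))
  su <- summarize_sessions(score_trials(normalize_cohort(co$trials)))
  ok <- !is.na(su$cr_proportion)
  expect_true(all(su$perfect_proportion[ok] <= su$cr_proportion[ok]))
})

test_that("noise-free summaries equal the ground-truth recomputation", {
  co <- simulate_cohort(recovery_params(107))
  scored <- score_trials(normalize_cohort(co$trials, ur_source = "us_only"))
  su <- summarize_sessions(scored)
  truth_cs <- dplyr::filter(co$truth, trial_type == "CS_ONLY")
  tsu <- truth_cs |>
    dplyr::group_by(mouse_id, day) |>
    dplyr::summarise(
      cr_proportion = mean(is_cr),
      mean_onset_ms = if (any(is_cr)) mean(onset_ms[is_cr]) else NA_real_,
      mean_peak_ms = if (any(is_cr)) mean(peak_ms[is_cr]) else NA_real_,
      perfect_proportion = mean(is_cr & !is.na(peak_ms) &
                                  peak_ms >= isi_ms - 50 &
                                  peak_ms <= isi_ms + 50),
      .groups = "drop") |>
    dplyr::arrange(mouse_id, day)
  su <- dplyr::arrange(su, mouse_id, day)
  expect_equal(su$cr_proportion, tsu$cr_proportion)
  expect_equal(su$mean_onset_ms, tsu$mean_onset_ms)
  expect_equal(su$mean_peak_ms, tsu$mean_peak_ms)
  expect_equal(su$perfect_proportion, tsu$perfect_proportion)
})

test_that("tighter timing jitter never lowers expected perfect timing", {
  rates <- vapply(c(10, 80), function(sd_ms) {
    p <- sim_params(timing_sd_ms = sd_ms, seed = 1)
    hits <- vapply(1:150, function(i) {
      tr <- simulate_trial("CS_ONLY", 9, "WT", p, seed = 5000 + i)$truth
      isTRUE(tr$is_cr && !is.na(tr$peak_ms) &&
               tr$peak_ms >= 200 && tr$peak_ms <= 300)
    }, logical(1))
    mean(hits)
  }, numeric(1))
  expect_gte(rates[1], rates[2])
})

test_that("cohort aggregation reproduces the table layout", {
  su <- tibble::tibble(
    mouse_id = c("a", "b"), genotype = "WT", day = 1L, phase = "ISI250",
    isi_ms = 250, n_cs_only_valid = 20L, n_invalid = 0L,
    cr_proportion = c(0.4, 0.6), nec_250 = c(0.1, 0.3),
    nec_500 = c(0, 0.2), mean_onset_ms = c(100, 140),
    mean_peak_ms = c(200, 260), perfect_proportion = c(0.1, 0.2)
  )
  ag <- aggregate_cohort(su)
  cr <- dplyr::filter(ag, metric == "cr_proportion")
  expect_equal(cr$mean, 0.5)
  expect_equal(cr$median, 0.5)
  expect_equal(cr$n, 2)
  # single mouse: SD undefined
  ag1 <- aggregate_cohort(su[1, ])
  expect_true(all(is.na(ag1$sd)))
  # deterministic given identical input
  expect_identical(ag, aggregate_cohort(su))
})
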
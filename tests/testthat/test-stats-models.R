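# Model battery: structure selection, per-family fits, contrasts.

# trial-level gaussian data with known multilevel structure: per-mouse
# intercepts, optional per-mouse-by-day deviations, `n_rep` trials per
# mouse-day
make_gaussian_data <- function(n_per_group = 10, n_days = 4, n_rep = 4,
                               mouse_sd = 0.3, slope_sd = 0, resid_sd = 0.2,
                               gen_shift = 0, seed = 1) {
  withr::with_seed(seed, {
    mice <- tibble::tibble(
      mouse_id = sprintf("m%02d", 1:(2 * n_per_group)),
      genotype = rep(c("WT", "NF1_HET"), each = n_per_group),
      u = rnorm(2 * n_per_group, 0, mouse_sd)
    )
    md <- tidyr::expand_grid(mice, day = seq_len(n_days))
    md$slope <- rnorm(nrow(md), 0, slope_sd)
    df <- tidyr::expand_grid(md, rep = seq_len(n_rep))
    df$y <- 0.1 * df$day + df$u + df$slope +
      gen_shift * (df$genotype == "NF1_HET") + rnorm(nrow(df), 0, resid_sd)
    df
  })
}

test_that("random-structure selection tracks the generating model", {
  # no day-specific variance: intercepts should win almost always
  hits_i <- vapply(1:40, function(i) {
    d <- make_gaussian_data(n_per_group = 10, slope_sd = 0, seed = i)
    select_random_structure(d, "y", "gaussian")$structure == "intercepts"
  }, logical(1))
  expect_gte(mean(hits_i), 0.8)
  # strong day-by-mouse variance: slopes should win almost always
  hits_s <- vapply(1:40, function(i) {
    d <- make_gaussian_data(n_per_group = 10, slope_sd = 0.6, seed = 100 + i)
    select_random_structure(d, "y", "gaussian")$structure == "slopes"
  }, logical(1))
  expect_gte(mean(hits_s), 0.8)
})

test_that("unidentifiable slopes models fall back to intercepts", {
  # one observation per mouse-day: the day-by-mouse deviation is
  # confounded with the residual and the slopes fit cannot be formed
  d <- make_gaussian_data(n_per_group = 5, n_rep = 1, seed = 3)
  expect_warning(sel <- select_random_structure(d, "y", "gaussian"),
                 "falling back")
  expect_equal(sel$structure, "intercepts")
})

test_that("LMM reports zero differences when genotypes are identical", {
  # mirrored mice: each mutant duplicates a wild-type response profile
  base <- make_gaussian_data(n_per_group = 6, seed = 11)
  wt <- base[base$genotype == "WT", ]
  het <- wt
  het$genotype <- "NF1_HET"
  het$mouse_id <- sub("m0", "x0", het$mouse_id)
  d <- rbind(wt, het)
  fit <- fit_lmm(d, "y", random = "intercepts")
  expect_true(all(abs(fit$contrasts$estimate) < 1e-6))
  expect_true(all(fit$contrasts$p.value > 0.999))
  expect_lt(fit$omnibus$statistic[fit$omnibus$term == "genotype"], 1e-6)
})

test_that("LMM recovers a known genotype shift", {
  d <- make_gaussian_data(n_per_group = 15, gen_shift = 0.5, seed = 21)
  fit <- fit_lmm(d, "y", random = "intercepts")
  gen_p <- fit$omnibus$p.value[fit$omnibus$term == "genotype"]
  expect_lt(gen_p, 0.01)
  expect_true(all(fit$omnibus$test == "LR"))
  # contrasts estimate the shift
  expect_equal(mean(fit$contrasts$estimate), 0.5, tolerance = 0.25)
  expect_true(all(fit$contrasts$p.adjusted >= fit$contrasts$p.value))
})

test_that("log-transformed LMM back-translates to a geometric-mean estimate", {
  withr::with_seed(31, {
    mice <- tibble::tibble(mouse_id = sprintf("m%02d", 1:24),
                           genotype = rep(c("WT", "NF1_HET"), each = 12))
    d <- tidyr::expand_grid(mice, rep = 1:4)
    d$force_n <- exp(log(90) + rnorm(nrow(d), 0, 0.1))
  })
  fit <- grip_analyze(d)
  bt <- fit$back_translated
  # back-translated means approximate the generating geometric mean
  expect_equal(bt$estimate[1], 90, tolerance = 0.05)
  expect_equal(bt$estimate[2], 90, tolerance = 0.05)
  expect_true(all(bt$conf.low[1:2] > 0))
})

test_that("trialwise logistic flags separation and rejects constant outcomes", {
  withr::with_seed(41, {
    mice <- tibble::tibble(mouse_id = sprintf("m%02d", 1:12),
                           genotype = rep(c("WT", "NF1_HET"), each = 6))
    d <- tidyr::expand_grid(mice, day = 1:2, trial = 1:10)
    d$is_cr <- runif(nrow(d)) < 0.4
    # quasi-complete separation on day 2: no wild-type responses at all
    d$is_cr[d$day == 2 & d$genotype == "WT"] <- FALSE
    d$is_cr[d$day == 2 & d$genotype == "NF1_HET"] <- runif(60) < 0.8
  })
  fit <- fit_trialwise_logistic(d, random = "intercepts")
  expect_true(all(fit$omnibus$test == "Wald"))
  ct <- fit$contrasts
  expect_true(ct$unstable[ct$level == "2"])
  expect_false(ct$unstable[ct$level == "1"])
  # degenerate: outcome constant
  d$is_cr <- FALSE
  expect_error(fit_trialwise_logistic(d, random = "intercepts"),
               class = "eyeblinkr_invalid_argument")
})

test_that("beta regression enforces the open-interval contract", {
  withr::with_seed(51, {
    mice <- tibble::tibble(mouse_id = sprintf("m%02d", 1:10),
                           genotype = rep(c("WT", "NF1_HET"), each = 5))
    d <- tidyr::expand_grid(mice, day = 1:3, trial = 1:5)
    d$prop <- rbeta(nrow(d), 6, 2)
  })
  bad <- d
  bad$prop[3] <- 1
  expect_error(fit_beta_mixed(bad, "prop", random = "intercepts"),
               "compress_proportions")
  fit <- fit_beta_mixed(d, "prop", random = "intercepts")
  expect_true(all(fit$omnibus$test == "LR"))
  expect_equal(fit$family, "beta")
  gen_lr <- fit$omnibus$statistic[fit$omnibus$term == "genotype"]
  expect_lt(gen_lr, 15) # null data: no huge genotype effect
})

test_that("Cox frailty model recovers a known hazard ratio", {
  est <- vapply(1:20, function(i) {
    withr::with_seed(1000 + i, {
      mice <- tibble::tibble(mouse_id = sprintf("m%02d", 1:100),
                             genotype = rep(c("WT", "NF1_HET"), each = 50))
      d <- tidyr::expand_grid(mice, trial = 1:2)
      rate <- ifelse(d$genotype == "NF1_HET", 2, 1) # HR 2 for mutants
      d$latency_s <- rexp(nrow(d), rate)
      d$event <- TRUE
    })
    fit <- fit_cox_frailty(d, time_var = NULL)
    fit$contrasts$estimate_exp[1]
  }, numeric(1))
  expect_gt(mean(est), 1.6)
  expect_lt(mean(est), 2.5)
})

test_that("Cox fit rejects event-free data", {
  d <- tibble::tibble(mouse_id = c("a", "b"), genotype = c("WT", "NF1_HET"),
                      day = 1, latency_s = c(300, 300), event = FALSE)
  expect_error(fit_cox_frailty(d), class = "eyeblinkr_invalid_argument")
})

test_that("tidy and glance expose the fit surface", {
  d <- make_gaussian_data(n_per_group = 6, seed = 61)
  fit <- fit_lmm(d, "y", random = "intercepts")
  ct <- tidy(fit)
  expect_true(all(c("level", "estimate", "conf.low", "conf.high",
                    "p.value", "p.adjusted") %in% names(ct)))
  om <- tidy(fit, "omnibus")
  expect_setequal(om$term, c("day", "genotype", "day:genotype"))
  g <- glance(fit)
  expect_equal(g$family, "gaussian")
  expect_equal(g$n_mice, 12)
  fx <- tidy(fit, "fixed")
  expect_true("(Intercept)" %in% fx$term)
})
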
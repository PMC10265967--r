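test_that("identical paired samples give p = 1 with a warning", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_warning(res <- paired_wilcoxon(x, x), "zero")
  expect_equal(res$p.value, 1)
  expect_equal(res$statistic, 0)
})

test_that("six uniformly positive differences give the exact two-sided p", {
  x <- c(2, 4, 6, 8, 10, 12)
  y <- x - c(1, 2, 3, 4, 5, 6) # all differences positive, no ties
  res <- paired_wilcoxon(x, y)
  expect_equal(res$statistic, 21)         # full positive rank sum
  expect_equal(res$p.value, 2 / 2^6)      # 0.03125
})

test_that("the exact test matches stats::wilcox.test on tie-free data", {
  set.seed(123)
  for (k in 1:100) {
    n <- sample(6:20, 1)
    x <- rnorm(n)
    y <- x + rnorm(n) # continuous: no ties, no zeros (a.s.)
    ours <- paired_wilcoxon(x, y)
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-6)
  }
})

test_that("large samples fall back to the tie-corrected normal approximation", {
  set.seed(9)
  x <- rnorm(40)
  y <- x + rnorm(40, mean = 0.4)
  ours <- paired_wilcoxon(x, y)
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(ours$method, "normal approximation")
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-6)
})

test_that("summaries collapse to the value for single observations", {
  df <- data.frame(model_id = "m1", anatomy = 1, variant = "healthy",
                   configuration = "left_apical", dft_energy_J = 7,
                   impedance_ohm = 40, mean_e_field_V_per_mm = 0.03,
                   error = NA_character_)
  s <- summarize_study(df)
  expect_true(all(s$median == s$q1 & s$median == s$q3))
  expect_equal(s$median[s$metric == "dft_energy_J"], 7)
})

test_that("summaries report every configuration and match a sort oracle", {
  set.seed(4)
  cfgs <- names(enumerate_study_configurations())
  df <- expand.grid(model_id = paste0("m", 1:7), configuration = cfgs,
                    stringsAsFactors = FALSE)
  df$anatomy <- 1
  df$variant <- "healthy"
  df$dft_energy_J <- rexp(nrow(df), 0.1)
  df$impedance_ohm <- runif(nrow(df), 30, 50)
  df$mean_e_field_V_per_mm <- runif(nrow(df), 0.02, 0.05)
  df$error <- NA_character_
  s <- summarize_study(df)
  expect_setequal(unique(s$configuration), cfgs)
  for (cf in cfgs) {
    vals <- sort(df$dft_energy_J[df$configuration == cf])
    oracle <- (vals[4] + vals[4]) / 2 # n = 7: the 4th order statistic
    got <- s$median[s$configuration == cf & s$metric == "dft_energy_J"]
    expect_equal(got, oracle, tolerance = 1e-12)
  }
  ## per-variant breakdown
  sv <- summarize_study(df, by = c("configuration", "variant"))
  expect_true("variant" %in% names(sv))
})

test_that("paired comparisons align models before testing", {
  df <- data.frame(
    model_id = rep(paste0("m", 1:6), 2),
    configuration = rep(c("a", "b"), each = 6),
    dft_energy_J = c(11:16, 1:6),
    error = NA_character_)
  ## shuffle rows: pairing must go through model_id, not row order
  df <- df[sample(nrow(df)), ]
  cmp <- compare_configurations(df, "a", "b")
  expect_equal(cmp$n, 6)
  expect_equal(cmp$median_a, 13.5)
  expect_equal(cmp$median_b, 3.5)
  expect_equal(cmp$p_value, 0.03125, tolerance = 1e-12) # all diffs positive
})

test_that("a small cohort runs end to end, caches, and records failures", {
  co <- build_cohort(1, seed = 2)[c(1, 4)] # healthy + ICM variants
  cfgs <- enumerate_study_configurations()["left_apical"]
  cache <- file.path(tempdir(), "study_cache_test")
  res <- run_cohort(co, cfgs, h = 3, cache_dir = cache, verbose = FALSE)
  expect_equal(nrow(res), 2)
  expect_true(all(is.na(res$error)))
  expect_true(all(res$dft_voltage_V > 0))
  expect_true(all(res$charge_imbalance < 0.01))
  ## resume from cache: identical rows, no recomputation
  t0 <- Sys.time()
  res2 <- run_cohort(co, cfgs, h = 3, cache_dir = cache, verbose = FALSE)
  expect_identical(res$dft_voltage_V, res2$dft_voltage_V)
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 5)

  ## a broken model is recorded as a failure and does not stop the run
  broken <- co
  broken[[1]]$phantom$landmarks$can_left$center <- c(999, 999, 999)
  expect_warning(
    res3 <- run_cohort(broken, cfgs, h = 3, cache_dir = NULL, verbose = FALSE),
    "solve failed")
  expect_equal(sum(!is.na(res3$error)), 1)
  expect_length(attr(res3, "failures"), 1)
})
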
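test_that("geometric mean matches the exp-mean-log definition", {
  expect_equal(geometric_mean(c(2, 8)), 4)
  expect_equal(geometric_mean(12.17), 12.17)

  set.seed(20)
  x <- exp(rnorm(20, log(11.28), 0.05))
  expect_equal(geometric_mean(x), exp(mean(log(x))), tolerance = 1e-12)

  expect_error(geometric_mean(numeric(0)), class = "inrmu_invalid_input")
  expect_error(geometric_mean(c(1, -2)), class = "inrmu_invalid_input")
  expect_error(geometric_mean(c(1, 0)), class = "inrmu_invalid_input")
})

test_that("INR follows the ISI model (PT/MNPT)^ISI", {
  expect_equal(inr_from_pt(25.25, 12.17, 1.11), 2.25, tolerance = 0.01 / 2.25)
  expect_equal(inr_from_pt(19.80, 11.28, 1.08), 1.84, tolerance = 0.01 / 1.84)
  # R = 1 forces INR = 1 whatever the ISI
  expect_identical(inr_from_pt(12.17, 12.17, 1.73), 1)
  expect_error(inr_from_pt(-1, 12, 1.1), class = "inrmu_invalid_input")
})

test_that("log-space propagation reproduces published per-plasma SDs", {
  for (case in list(
    list(irp = "rTF/16", plasma = "Lyo B", printed = 0.047),
    list(irp = "IRP 24/114", plasma = "Lyo C", printed = 0.032),
    list(irp = "rTF/16", plasma = "Lyo A", printed = 0.010)
  )) {
    row <- example_row(case$irp, case$plasma)
    got <- sd_log_inr(row$pt_mean_s, row$mnpt_s, row$isi, row$sd_log_pt,
                      row$n, row$sd_log_mnpt, row$m, row$sd_isi)
    expect_equal(got, case$printed, tolerance = 0.002 / case$printed)
    expect_equal(got, oracle_sd_log_inr(row), tolerance = 1e-12)
  }
  # no uncertainty sources -> exactly zero
  expect_identical(sd_log_inr(20, 10, 1.1, 0, 10, 0, 6, 0), 0)
})

test_that("a PT equal to the MNPT annihilates the ISI contribution", {
  row <- example_row("rTF/16", "Lyo A")
  res <- inr_uncertainty(row)
  expect_identical(res$term_isi, 0)
  expect_equal(res$sd_log_inr, 0.010, tolerance = 0.002 / 0.010)
  expect_equal(res$term_pt + res$term_mnpt + res$term_isi, res$sd_log_inr^2,
               tolerance = 1e-12)
})

test_that("coverage-factor intervals are log-symmetric and match the table", {
  ci <- inr_confidence_interval(log(2.2482), 0.046524, k = 2)
  expect_equal(ci$ci_lower, 2.05, tolerance = 0.03 / 2.05)
  expect_equal(ci$ci_upper, 2.47, tolerance = 0.03 / 2.47)

  # zero-width at sd = 0
  ci0 <- inr_confidence_interval(log(3.1), 0)
  expect_equal(ci0$ci_lower, 3.1)
  expect_equal(ci0$ci_upper, 3.1)

  # geometric symmetry for arbitrary inputs
  set.seed(11)
  ml <- rnorm(50, 0.5, 1)
  s <- runif(50, 0, 0.3)
  k <- runif(50, 0.5, 3)
  for (i in seq_along(ml)) {
    ci <- inr_confidence_interval(ml[i], s[i], k[i])
    expect_equal(sqrt(ci$ci_lower * ci$ci_upper), exp(ml[i]),
                 tolerance = 1e-9)
  }
  expect_error(inr_confidence_interval(0.5, 0.04, k = 0),
               class = "inrmu_invalid_input")
})

test_that("relative uncertainty: approximate vs exact log-normal conversion", {
  expect_equal(relative_uncertainty(0.047), 4.7)
  expect_equal(relative_uncertainty(0, "approximate"), 0)
  expect_equal(relative_uncertainty(0, "exact"), 0)
  expect_equal(relative_uncertainty(0.047, "exact"), 4.812, tolerance = 1e-3)

  # exact >= approximate, difference bounded by the second-order term
  s <- seq(0, 0.2, by = 0.005)
  ex <- relative_uncertainty(s, "exact")
  ap <- relative_uncertainty(s, "approximate")
  expect_true(all(ex >= ap))
  expect_true(all(ex - ap <= 100 * s^2))
})

test_that("propagated SD is monotone in each source and vanishes in the limit", {
  base <- list(pt = 25, mnpt = 12, isi = 1.1, sdpt = 0.01, n = 10,
               sdmn = 0.015, m = 6, sdisi = 0.05)
  f <- function(p) sd_log_inr(p$pt, p$mnpt, p$isi, p$sdpt, p$n, p$sdmn, p$m,
                              p$sdisi)
  grid <- seq(0, 0.1, by = 0.02)
  for (fld in c("sdpt", "sdmn", "sdisi")) {
    vals <- vapply(grid, function(v) { p <- base; p[[fld]] <- v; f(p) },
                   numeric(1))
    expect_true(all(diff(vals) >= 0), info = fld)
  }
  for (fld in c("n", "m")) {
    vals <- vapply(c(1, 2, 5, 10, 100), function(v) {
      p <- base; p[[fld]] <- v; f(p)
    }, numeric(1))
    expect_true(all(diff(vals) <= 0), info = fld)
  }
  # n, m -> infinity with no ISI uncertainty: SD -> 0
  p <- base; p$sdisi <- 0; p$n <- 1e12; p$m <- 1e12
  expect_lt(f(p), 1e-6)
})

test_that("per-preparation summaries use unrounded medians", {
  res <- inr_uncertainty(example_rows())
  summ <- summarize_irp(res)
  expect_equal(summ$median_ru[summ$irp_id == "rTF/16"], 5.8)
  expect_equal(summ$median_ru[summ$irp_id == "IRP 24/114"], 2.7)

  raw <- summarize_irp(res, digits = NULL)
  four <- sort(res$ru_percent[res$irp_id == "rTF/16"])
  expect_equal(raw$median_ru[raw$irp_id == "rTF/16"],
               mean(four[2:3]), tolerance = 1e-12)

  one <- summarize_irp(res[3, ], digits = NULL)
  expect_equal(one$median_ru, one$min_ru)
  expect_equal(one$median_ru, one$max_ru)
  expect_error(summarize_irp(res[0, ]), class = "inrmu_invalid_input")
})

test_that("measurement validation rejects malformed tables", {
  tab <- example_rows()
  expect_error(inr_uncertainty(tab[, -3]), class = "inrmu_invalid_input")
  bad <- tab; bad$n[2] <- 0
  expect_error(inr_uncertainty(bad), class = "inrmu_invalid_input")
  bad <- tab; bad$sd_isi[1] <- -0.01
  expect_error(inr_uncertainty(bad), class = "inrmu_invalid_input")
  bad <- tab; bad$plasma_id[2] <- "Lyo A"
  expect_error(inr_uncertainty(bad), class = "inrmu_invalid_input")
  expect_error(inr_uncertainty(tab, k = -2), class = "inrmu_invalid_input")
})

test_that("replicate summaries feed the same propagation as printed summaries", {
  reps <- c(12.1, 12.3, 12.0)
  ps <- plasma_summary(reps)
  expect_equal(ps$pt_mean_s, exp(mean(log(reps))), tolerance = 1e-12)
  expect_equal(ps$sd_log_pt, sd(log(reps)), tolerance = 1e-12)
  expect_identical(ps$n, 3L)
  expect_error(plasma_summary(12.1), class = "inrmu_invalid_input")
})
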
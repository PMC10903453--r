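test_that("welch_t matches the closed-form example and the stats reference", {
  res <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, -3.674235, tolerance = 1e-6)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 0.02131164, tolerance = 1e-6)

  # Independent reference on random cases.
  for (k in 1:5) {
    xy <- withr::with_seed(100 + k, list(x = rnorm(7, 1, 2), y = rnorm(12, 0, 0.5)))
    ours <- welch_t(xy$x, xy$y)
    ref <- stats::t.test(xy$x, xy$y)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("welch_t degenerate and identity cases follow the contract", {
  x <- c(2, 3, 5)
  self <- welch_t(x, x)
  expect_equal(self$statistic, 0)
  expect_equal(self$p_value, 1)
  # Zero variance in both groups, equal means.
  z <- welch_t(c(1, 1, 1), c(1, 1))
  expect_equal(z$statistic, 0)
  expect_equal(z$p_value, 1)
  expect_error(welch_t(1, c(1, 2)), class = "cristamorph_parameter_error")
})

test_that("welch_t is antisymmetric and reduces to pooled t for balanced groups", {
  x <- c(1.2, 3.1, 0.7, 2.2)
  y <- c(2.0, 2.9, 4.1, 3.3)
  ab <- welch_t(x, y)
  ba <- welch_t(y, x)
  expect_equal(ab$statistic, -ba$statistic)
  expect_equal(ab$p_value, ba$p_value)
  # Equal n and equal sample variances: Welch df equals nx + ny - 2.
  x2 <- c(0, 1, 2, 3)
  y2 <- x2 + 5          # identical variance
  expect_equal(welch_t(x2, y2)$df, length(x2) + length(y2) - 2)
})

test_that("mann_whitney_u exact p-values equal the enumeration reference for all small cases", {
  for (nx in 1:6) {
    for (ny in 1:6) {
      xy <- withr::with_seed(nx * 10 + ny, list(x = rnorm(nx), y = rnorm(ny)))
      ours <- mann_whitney_u(xy$x, xy$y)
      expect_identical(ours$approx, "exact")
      ref <- suppressWarnings(stats::wilcox.test(xy$x, xy$y, exact = TRUE))
      expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12,
                   label = sprintf("exact p at nx=%d ny=%d", nx, ny))
      # U1 is the wilcoxon W statistic; U is the smaller of the two.
      expect_equal(ours$U1, unname(ref$statistic))
      expect_equal(ours$statistic, min(ours$U1, nx * ny - ours$U1))
    }
  }
})

test_that("mann_whitney_u approximate path matches the tie/continuity-corrected reference", {
  xy <- withr::with_seed(7, list(x = round(rnorm(15), 1), y = round(rnorm(18, 0.5), 1)))
  ours <- mann_whitney_u(xy$x, xy$y)
  expect_identical(ours$approx, "normal-approx")
  ref <- suppressWarnings(stats::wilcox.test(xy$x, xy$y, exact = FALSE, correct = TRUE))
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("identical samples give the central U and p = 1", {
  x <- rep(2, 5)
  res <- mann_whitney_u(x, x)
  expect_equal(res$U1, 5 * 5 / 2)
  expect_equal(res$p_value, 1)
})

test_that("exact and approximate p agree within 0.02 at n = 6 vs 6", {
  xy <- withr::with_seed(11, list(x = rnorm(6), y = rnorm(6)))
  p_exact <- mann_whitney_u(xy$x, xy$y, exact_max_n = 12)$p_value
  p_approx <- mann_whitney_u(xy$x, xy$y, exact_max_n = 0)$p_value
  expect_lt(abs(p_exact - p_approx), 0.02)
})

test_that("mann_whitney_u is invariant under strictly monotone transforms", {
  xy <- withr::with_seed(13, list(x = abs(rnorm(9)) + 0.1, y = abs(rnorm(11)) + 0.1))
  base <- mann_whitney_u(xy$x, xy$y)
  for (f in list(function(v) log(v), function(v) v^3, function(v) exp(v))) {
    tr <- mann_whitney_u(f(xy$x), f(xy$y))
    expect_equal(tr$statistic, base$statistic)
    expect_equal(tr$p_value, base$p_value)
  }
})

test_that("significance stars follow the conventional thresholds", {
  expect_equal(significance_stars(c(0.5, 0.04, 0.009, 0.0009, 0.00009)),
               c("ns", "*", "**", "***", "****"))
  expect_equal(significance_stars(1e-4), "****")
})

test_that("compare_populations reports fold change and primary tests", {
  fake_records <- function(sav, widths) {
    tibble::tibble(
      crista_id = sprintf("c%d", seq_along(sav)),
      surface_area_nm2 = sav, volume_nm3 = 1, sa_to_v_per_nm = sav,
      n_width_samples = lengths(widths),
      mean_width_nm = purrr::map_dbl(widths, mean),
      sd_width_nm = purrr::map_dbl(widths, sd),
      widths = widths
    )
  }
  a <- withr::with_seed(1, fake_records(rnorm(20, 0.15, 0.01),
                                        purrr::map(1:20, ~ rnorm(3, 20, 1))))
  b <- withr::with_seed(2, fake_records(rnorm(20, 0.10, 0.01),
                                        purrr::map(1:20, ~ rnorm(3, 30, 1))))
  cmp <- compare_populations(a, b, group_names = c("worm", "yeast"))
  expect_equal(cmp$sa_to_v$fold_change, 1.5, tolerance = 0.05)
  expect_identical(cmp$sa_to_v$stars, "****")
  expect_lt(cmp$width$p_value, 1e-4)
  td <- tidy(cmp)
  expect_equal(nrow(td), 2L)
  expect_setequal(td$test, c("welch_t", "mann_whitney_u"))

  # A group compared with itself: fold change 1, not significant.
  self <- compare_populations(a, a, group_names = c("worm", "worm"))
  expect_equal(self$sa_to_v$fold_change, 1)
  expect_identical(self$sa_to_v$stars, "ns")
  expect_error(compare_populations(a[1, ], b), class = "cristamorph_parameter_error")
})
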
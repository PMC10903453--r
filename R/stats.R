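# Two-group comparison statistics: Welch's t-test on per-crista SA:V and
# the Mann-Whitney U-test on pooled widths, with fold change and
# significance stars.

check_sample <- function(x, name, min_n = 1L) {
  if (!is.numeric(x)) abort_param("`%s` must be numeric", name)
  x <- x[is.finite(x)]
  if (length(x) < min_n) abort_param("`%s` needs at least %d finite values", name, min_n)
  x
}

#' Welch's two-sample t-test
#'
#' Location test not assuming equal variances:
#' `t = (mean(x) - mean(y)) / sqrt(var(x)/nx + var(y)/ny)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value.
#' `t > 0` when `mean(x) > mean(y)`. When both groups have zero variance
#' and equal means, returns `t = 0, p = 1`.
#'
#' @param x,y Numeric samples (each of length >= 2).
#' @return A list of class `cm_test` with elements `statistic` (t), `df`,
#'   `p_value` and `method`.
#' @export
#' @examples
#' welch_t(c(1, 2, 3), c(4, 5, 6))
welch_t <- function(x, y) {
  x <- check_sample(x, "x", 2L)
  y <- check_sample(y, "y", 2L)
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  diff <- mean(x) - mean(y)
  if (se2 == 0) {
    t_stat <- if (diff == 0) 0 else sign(diff) * Inf
    df <- NA_real_
    p <- if (diff == 0) 1 else 0
  } else {
    t_stat <- diff / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    p <- 2 * pt(-abs(t_stat), df)
  }
  structure(
    list(statistic = t_stat, df = df, p_value = p,
         estimate = c(mean_x = mean(x), mean_y = mean(y)),
         n = c(nx = nx, ny = ny), method = "Welch two-sample t-test"),
    class = "cm_test"
  )
}

# Exact null distribution of U1 by full enumeration of the C(n, nx) rank
# assignments (untied data only).
mwu_exact_p <- function(u1, nx, ny) {
  n <- nx + ny
  combos <- combn(n, nx)
  r <- colSums(combos)
  u_all <- r - nx * (nx + 1) / 2
  p_lo <- mean(u_all <= u1)
  p_hi <- mean(u_all >= u1)
  min(1, 2 * min(p_lo, p_hi))
}

#' Mann-Whitney U-test
#'
#' Rank-sum test with `U = min(U1, U2)` computed from midranks. For small
#' untied samples (`nx + ny <= exact_max_n`) the two-sided p-value is
#' exact, by full enumeration of rank assignments; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param exact_max_n Largest pooled sample size for which the exact
#'   enumeration is used (untied data only).
#' @return A list of class `cm_test` with elements `statistic` (U), `U1`,
#'   `p_value` and `method` (`"exact"` or `"normal-approx"`).
#' @export
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))
mann_whitney_u <- function(x, y, exact_max_n = 12) {
  x <- check_sample(x, "x", 1L)
  y <- check_sample(y, "y", 1L)
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u1 <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  u2 <- nx * ny - u1
  u <- min(u1, u2)
  ties <- table(pooled)
  has_ties <- any(ties > 1L)

  if (!has_ties && (nx + ny) <= exact_max_n) {
    p <- mwu_exact_p(u1, nx, ny)
    method <- "exact"
  } else {
    n <- nx + ny
    mu <- nx * ny / 2
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u1 - mu) - 0.5) / sqrt(sigma2)   # continuity correction
      p <- min(1, 2 * pnorm(-max(0, z)))
    }
    method <- "normal-approx"
  }
  structure(
    list(statistic = u, U1 = u1, U2 = u2, p_value = p,
         n = c(nx = nx, ny = ny), method = paste0("Mann-Whitney U-test (", method, ")"),
         approx = method),
    class = "cm_test"
  )
}

#' @export
print.cm_test <- function(x, ...) {
  cat(sprintf("<%s>\n", x$method))
  if (!is.null(x$df)) {
    cat(sprintf("  t = %.4g, df = %.4g, p = %.4g\n", x$statistic, x$df, x$p_value))
  } else {
    cat(sprintf("  U = %.4g, p = %.4g\n", x$statistic, x$p_value))
  }
  invisible(x)
}

#' @method tidy cm_test
#' @export
tidy.cm_test <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    statistic = x$statistic,
    df = x$df %||% NA_real_,
    p_value = x$p_value
  )
}

#' Significance stars
#'
#' Maps a p-value to the conventional star coding:
#' `****` for p <= 0.0001, `***` for p <= 0.001, `**` for p <= 0.01,
#' `*` for p <= 0.05, `ns` otherwise.
#'
#' @param p A p-value (vectorised).
#' @return Character vector of star codes.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(
    p <= 0.0001 ~ "****",
    p <= 0.001 ~ "***",
    p <= 0.01 ~ "**",
    p <= 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

comparison_report <- function(metric, a, b, group_names, primary) {
  welch <- if (length(a) >= 2L && length(b) >= 2L) welch_t(a, b) else NULL
  mwu <- mann_whitney_u(a, b)
  primary_test <- if (primary == "welch") welch else mwu
  structure(
    list(
      metric = metric,
      group_names = group_names,
      n = c(length(a), length(b)),
      means = c(mean(a), mean(b)),
      sds = c(sd(a), sd(b)),
      fold_change = mean(a) / mean(b),
      welch = welch,
      mannwhitney = mwu,
      primary = primary,
      p_value = primary_test$p_value,
      stars = significance_stars(primary_test$p_value),
      data = tibble::tibble(
        group = rep(group_names, c(length(a), length(b))),
        value = c(a, b)
      )
    ),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report: %s>\n", x$metric))
  for (i in 1:2) {
    cat(sprintf("  %-14s n = %3d  mean = %.4g  sd = %.4g\n",
                x$group_names[i], x$n[i], x$means[i], x$sds[i]))
  }
  cat(sprintf("  fold change (%s/%s) = %.3f\n",
              x$group_names[1L], x$group_names[2L], x$fold_change))
  cat(sprintf("  %s: p = %.3g  [%s]\n",
              if (x$primary == "welch") "Welch t" else "Mann-Whitney U",
              x$p_value, x$stars))
  invisible(x)
}

#' Compare two crista populations
#'
#' Reproduces the two-group morphometric comparison: Welch's t-test on the
#' per-crista surface-area:volume ratios (with the fold change of group
#' means), and the Mann-Whitney U-test on crista widths (pooled width
#' samples by default, or per-crista mean widths).
#'
#' @param records_a,records_b Morphometric tables from [morphometrics()]
#'   (at least 2 records each).
#' @param group_names Length-2 character vector naming the groups, in the
#'   order (a, b); the fold change is a/b.
#' @param width_mode `"pooled"` (default) tests all width samples;
#'   `"per_crista"` tests per-crista mean widths.
#' @return A list of class `crista_comparison` with elements `sa_to_v` and
#'   `width`, each a `comparison_report`.
#' @export
#' @examples
#' a <- make_population("celegans", 4, extent_mean_nm = 80, extent_sd_nm = 8,
#'                      seed = 1, mesh_step_nm = 5)
#' b <- make_population("scerevisiae", 4, extent_mean_nm = 80, extent_sd_nm = 8,
#'                      seed = 2, mesh_step_nm = 5)
#' compare_populations(morphometrics(a, 5, seed = 1), morphometrics(b, 5, seed = 2),
#'                     group_names = c("celegans", "scerevisiae"))
compare_populations <- function(records_a, records_b,
                                group_names = c("group_a", "group_b"),
                                width_mode = c("pooled", "per_crista")) {
  width_mode <- match.arg(width_mode)
  for (r in list(records_a, records_b)) {
    if (!is.data.frame(r) || nrow(r) < 2L || !"sa_to_v_per_nm" %in% names(r)) {
      abort_param("each group needs a morphometrics table with at least 2 records")
    }
  }
  sa <- comparison_report(
    "sa_to_v_per_nm",
    records_a$sa_to_v_per_nm, records_b$sa_to_v_per_nm,
    group_names, primary = "welch"
  )
  get_widths <- function(r) {
    if (width_mode == "per_crista" || !"widths" %in% names(r)) {
      r$mean_width_nm
    } else {
      unlist(r$widths)
    }
  }
  wd <- comparison_report(
    "width_nm", get_widths(records_a), get_widths(records_b),
    group_names, primary = "mannwhitney"
  )
  structure(list(sa_to_v = sa, width = wd), class = "crista_comparison")
}

#' @export
print.crista_comparison <- function(x, ...) {
  print(x$sa_to_v)
  print(x$width)
  invisible(x)
}

#' @method tidy crista_comparison
#' @export
tidy.crista_comparison <- function(x, ...) {
  purrr::map_dfr(list(x$sa_to_v, x$width), function(r) {
    tibble::tibble(
      metric = r$metric,
      group_a = r$group_names[1L], group_b = r$group_names[2L],
      n_a = r$n[1L], n_b = r$n[2L],
      mean_a = r$means[1L], mean_b = r$means[2L],
      sd_a = r$sds[1L], sd_b = r$sds[2L],
      fold_change = r$fold_change,
      test = if (r$primary == "welch") "welch_t" else "mann_whitney_u",
      statistic = if (r$primary == "welch") r$welch$statistic else r$mannwhitney$statistic,
      p_value = r$p_value,
      stars = r$stars
    )
  })
}

#' @method glance crista_comparison
#' @export
glance.crista_comparison <- function(x, ...) {
  tibble::tibble(
    sa_to_v_fold_change = x$sa_to_v$fold_change,
    sa_to_v_p = x$sa_to_v$p_value,
    sa_to_v_stars = x$sa_to_v$stars,
    width_fold_change = x$width$fold_change,
    width_p = x$width$p_value,
    width_stars = x$width$stars
  )
}
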
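# ggplot2 visualisations for the main result types.

#' @method tidy dimer_measurements
#' @export
tidy.dimer_measurements <- function(x, ...) x$per_dimer

#' @method glance dimer_measurements
#' @export
glance.dimer_measurements <- function(x, ...) x$summary

#' @method glance crista_morphometry
#' @export
glance.crista_morphometry <- function(x, ...) {
  tibble::tibble(
    n_cristae = nrow(x),
    mean_sa_to_v_per_nm = mean(x$sa_to_v_per_nm),
    sd_sa_to_v_per_nm = if (nrow(x) > 1L) sd(x$sa_to_v_per_nm) else 0,
    mean_width_nm = if ("mean_width_nm" %in% names(x)) mean(x$mean_width_nm) else NA_real_
  )
}

#' Plot per-dimer angle and stalk-separation distributions
#'
#' @param object A `dimer_measurements` from [measure_dimers()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dimer_measurements
#' @export
autoplot.dimer_measurements <- function(object, ...) {
  df <- object$per_dimer |>
    tidyr::pivot_longer(c("dimer_angle_deg", "stalk_sep_nm"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey35", colour = "white") +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = "dimers") +
    ggplot2::theme_minimal()
}

#' Plot per-crista morphometrics
#'
#' @param object A `crista_morphometry` tibble from [morphometrics()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot crista_morphometry
#' @export
autoplot.crista_morphometry <- function(object, ...) {
  df <- tibble::tibble(
    crista_id = object$crista_id,
    `SA:V (1/nm)` = object$sa_to_v_per_nm,
    `width (nm)` = if ("mean_width_nm" %in% names(object)) object$mean_width_nm else NA_real_
  ) |>
    tidyr::pivot_longer(-"crista_id", names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "firebrick") +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a two-group crista comparison
#'
#' Jittered per-crista (or per-sample) values with group mean +- SD and
#' the significance stars of the primary test, one panel per metric —
#' the synthetic analogue of the classic per-crista SA:V and width
#' comparison figures.
#'
#' @param object A `crista_comparison` from [compare_populations()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot crista_comparison
#' @export
autoplot.crista_comparison <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(object$sa_to_v$data, metric = "SA:V (1/nm)"),
    dplyr::mutate(object$width$data, metric = "width (nm)")
  )
  stars <- tibble::tibble(
    metric = c("SA:V (1/nm)", "width (nm)"),
    label = c(object$sa_to_v$stars, object$width$stars)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.45, size = 1) +
    ggplot2::stat_summary(fun.data = ggplot2::mean_sdl, fun.args = list(mult = 1),
                          geom = "pointrange", colour = "firebrick") +
    ggplot2::geom_text(data = stars, ggplot2::aes(label = .data$label),
                       x = 1.5, y = Inf, vjust = 1.5, inherit.aes = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Cross-section profile of a crista mesh
#'
#' Plots the x-z cross-section of the generated lamellar sac at the mesh
#' mid-plane, showing the ridge wedge, apex fillet and rim cap.
#'
#' @param mesh A [tri_mesh()] from [make_crista_mesh()].
#' @return A ggplot.
#' @export
plot_crista_profile <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  y0 <- if (!is.null(mesh$provenance$y_range)) mean(mesh$provenance$y_range) else
    stats::median(mesh$vertices[, 2L])
  ys <- sort(unique(mesh$vertices[, 2L]))
  y0 <- ys[which.min(abs(ys - y0))]
  ring <- mesh$vertices[abs(mesh$vertices[, 2L] - y0) < 1e-9, , drop = FALSE]
  ang <- atan2(ring[, 3L] - mean(ring[, 3L]), ring[, 1L] - mean(ring[, 1L]))
  ring <- ring[order(ang), ]
  df <- tibble::tibble(x = ring[, 1L], z = ring[, 3L])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z)) +
    ggplot2::geom_path() +
    ggplot2::geom_polygon(alpha = 0.1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "z (nm)") +
    ggplot2::theme_minimal()
}
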
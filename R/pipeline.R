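# End-to-end orchestration: one call generates both species' scenes,
# measures dimer geometry and crista morphometrics, runs the two-group
# statistics, and emits a reproduction report with ground-truth recovery
# errors. Every stage is seeded from the config, so a run is
# deterministic: the same config yields a byte-identical report.

#' Default reproduction configuration
#'
#' Population sizes mirror the study design the package emulates: 47 worm
#' and 63 yeast cristae for the SA:V comparison, 63 and 61 pooled width
#' samples for the width comparison, and 200 jittered dimer poses per
#' species for angle recovery. All seeds are derived from the single
#' `seed` argument.
#'
#' @param seed Master integer seed.
#' @return A list of class `run_config`.
#' @export
#' @examples
#' cfg <- default_run_config(seed = 1)
#' names(cfg)
default_run_config <- function(seed = 1) {
  seed <- check_seed(seed)
  structure(
    list(
      seed = seed,
      species = c("celegans", "scerevisiae"),
      generator = list(
        n_cristae = c(celegans = 47L, scerevisiae = 63L),
        extent_mean_nm = 400,
        extent_sd_nm = 60,
        width_sd_nm = 2,
        apex_radius_nm = 2,
        mesh_step_nm = 5
      ),
      rows = list(
        n_poses = 200L,
        dimers_per_row = 25L,
        jitter_deg = 5,
        jitter_nm = 0.5
      ),
      reference_mesh = list(
        face_extent_nm = 100,
        apex_radius_nm = 2,
        mesh_step_nm = 1
      ),
      measure = list(
        probe_inner_nm = 3,
        probe_outer_nm = 10,
        n_width_samples = 3L,
        n_width_pooled = c(celegans = 63L, scerevisiae = 61L),
        exclusion_nm = NULL
      )
    ),
    class = "run_config"
  )
}

#' Read / write a run configuration
#'
#' Configurations round-trip losslessly through YAML (default) or JSON,
#' chosen by file extension.
#'
#' @param config A `run_config` list.
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config") || is.list(config))
  ext <- tolower(tools::file_ext(path))
  obj <- unclass(config)
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(obj, path)
  } else if (ext == "json") {
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null"), path)
  } else {
    abort_param("unsupported config format '.%s' (use .yaml or .json)", ext)
  }
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_param("file '%s' does not exist", path)
  ext <- tolower(tools::file_ext(path))
  obj <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(paste(readLines(path), collapse = "\n"), simplifyVector = TRUE)
  } else {
    abort_param("unsupported config format '.%s' (use .yaml or .json)", ext)
  }
  base <- default_run_config(obj$seed %||% 1)
  out <- utils::modifyList(unclass(base), obj, keep.null = TRUE)
  # Restore integer-ness and names lost in serialisation.
  for (nm in c("n_cristae")) {
    if (!is.null(out$generator[[nm]])) {
      out$generator[[nm]] <- setNames(as.integer(out$generator[[nm]]),
                                      names(base$generator[[nm]]))
    }
  }
  if (!is.null(out$measure$n_width_pooled)) {
    out$measure$n_width_pooled <- setNames(as.integer(out$measure$n_width_pooled),
                                           names(base$measure$n_width_pooled))
  }
  structure(out, class = "run_config")
}

stage <- function(name, report, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(list(ok = TRUE, value = expr),
                  error = function(e) list(ok = FALSE, error = conditionMessage(e)))
  message(sprintf("[cristamorph] stage %-22s %s (%.1f s)", name,
                  if (res$ok) "ok" else paste("FAILED:", res$error),
                  proc.time()[["elapsed"]] - t0))
  if (!res$ok) report$errors[[name]] <- res$error
  list(value = if (res$ok) res$value else NULL, report = report)
}

recovery <- function(measured, truth) {
  list(measured = measured, ground_truth = truth,
       abs_error = abs(measured - truth))
}

#' Run the full reproduction pipeline
#'
#' For each species preset: simulates jittered dimer poses and measures
#' the dimer-head angle, stalk separation, inter-dimer spacing and yaw
#' offset; builds a fine noiseless reference mesh and measures the
#' membrane curvature angle at the ridge; generates a crista population
#' and computes per-crista SA:V and widths. The two species are then
#' compared (Welch's t on SA:V, Mann-Whitney U on pooled widths). Every
#' measured value is reported next to its preset ground truth with the
#' absolute recovery error.
#'
#' @param config A `run_config` from [default_run_config()] or
#'   [read_run_config()].
#' @param out_dir Optional directory; when given, the JSON report and the
#'   echoed config are written there.
#' @return A list of class `reproduction_report`. Stage failures are
#'   collected under `$errors` (and the function errors only if every
#'   stage failed).
#' @export
run_reproduction <- function(config = default_run_config(), out_dir = NULL) {
  stopifnot(is.list(config))
  report <- list(
    package = "cristamorph",
    config = unclass(config),
    species = list(),
    comparisons = list(),
    errors = list()
  )
  gen <- config$generator
  msr <- config$measure
  morph_tables <- list()

  for (sp in config$species) {
    preset <- get_preset(sp)
    entry <- list()

    st <- stage(paste0(sp, ":poses"), report, {
      poses <- simulate_dimer_poses(
        preset, config$rows$n_poses,
        jitter_deg = config$rows$jitter_deg, jitter_nm = config$rows$jitter_nm,
        seed = derive_seed(config$seed, match(sp, config$species)),
        dimers_per_row = config$rows$dimers_per_row
      )
      meas <- measure_dimers(poses)
      s <- meas$summary
      list(
        dimer_angle_deg = recovery(s$dimer_angle_mean_deg, preset$dimer_angle_deg),
        stalk_sep_nm = recovery(s$stalk_sep_mean_nm, preset$stalk_sep_nm),
        inter_dimer_nm = recovery(s$inter_dimer_mean_nm, preset$inter_dimer_nm),
        yaw_offset_deg = recovery(s$yaw_offset_mean_deg, preset$yaw_offset_deg)
      )
    })
    report <- st$report
    if (!is.null(st$value)) entry <- c(entry, st$value)

    st <- stage(paste0(sp, ":wedge"), report, {
      ref <- make_crista_mesh(
        preset,
        face_extent_nm = config$reference_mesh$face_extent_nm,
        apex_radius_nm = config$reference_mesh$apex_radius_nm,
        mesh_step_nm = config$reference_mesh$mesh_step_nm
      )
      w <- membrane_wedge_angle(ref, probe_inner_nm = msr$probe_inner_nm,
                                probe_outer_nm = msr$probe_outer_nm)
      list(wedge_angle_deg = recovery(w, preset$wedge_angle_deg))
    })
    report <- st$report
    if (!is.null(st$value)) entry <- c(entry, st$value)

    st <- stage(paste0(sp, ":population"), report, {
      pop <- make_population(
        preset, gen$n_cristae[[sp]],
        extent_mean_nm = gen$extent_mean_nm, extent_sd_nm = gen$extent_sd_nm,
        width_sd_nm = gen$width_sd_nm,
        seed = derive_seed(config$seed, 100L + match(sp, config$species)),
        apex_radius_nm = gen$apex_radius_nm, mesh_step_nm = gen$mesh_step_nm
      )
      morph <- morphometrics(pop, n_width_samples = msr$n_width_samples,
                             seed = derive_seed(config$seed, 200L + match(sp, config$species)),
                             exclusion_nm = msr$exclusion_nm)
      morph
    })
    report <- st$report
    if (!is.null(st$value)) {
      morph <- st$value
      morph_tables[[sp]] <- morph
      entry$sa_to_v_per_nm <- recovery(mean(morph$sa_to_v_per_nm), NA_real_)
      entry$sa_to_v_per_nm$ground_truth <- NULL
      entry$sa_to_v_per_nm$abs_error <- NULL
      entry$mean_width_nm <- recovery(mean(unlist(morph$widths)), preset$crista_width_nm)
      entry$n_cristae <- nrow(morph)
    }
    report$species[[sp]] <- entry
  }

  if (length(morph_tables) == 2L) {
    st <- stage("comparison", report, {
      a <- morph_tables[[config$species[1L]]]
      b <- morph_tables[[config$species[2L]]]
      # Subsample pooled widths to the configured counts so the width test
      # has the intended sample size.
      sub_w <- function(tab, n, k) {
        w <- unlist(tab$widths)
        if (length(w) > n) {
          w <- withr::with_seed(derive_seed(config$seed, 300L + k),
                                sample(w, n))
        }
        w
      }
      cmp <- compare_populations(a, b, group_names = config$species)
      wa <- sub_w(a, msr$n_width_pooled[[config$species[1L]]], 1L)
      wb <- sub_w(b, msr$n_width_pooled[[config$species[2L]]], 2L)
      wd <- comparison_report("width_nm", wa, wb, config$species, "mannwhitney")
      list(
        sa_to_v = list(
          fold_change = cmp$sa_to_v$fold_change,
          welch_t = cmp$sa_to_v$welch$statistic,
          welch_df = cmp$sa_to_v$welch$df,
          p_value = cmp$sa_to_v$p_value,
          stars = cmp$sa_to_v$stars,
          n = cmp$sa_to_v$n,
          means = cmp$sa_to_v$means,
          sds = cmp$sa_to_v$sds
        ),
        width = list(
          fold_change = wd$fold_change,
          U = wd$mannwhitney$statistic,
          p_value = wd$p_value,
          method = wd$mannwhitney$approx,
          stars = wd$stars,
          n = wd$n,
          means = wd$means,
          sds = wd$sds
        )
      )
    })
    report <- st$report
    if (!is.null(st$value)) report$comparisons <- st$value
  }

  if (length(report$species) == 0L) {
    rlang::abort("all pipeline stages failed", class = "cristamorph_error")
  }
  report <- structure(report, class = "reproduction_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(report_json(report), file.path(out_dir, "reproduction_report.json"))
    write_run_config(structure(config, class = "run_config"),
                     file.path(out_dir, "run_config.yaml"))
  }
  report
}

#' Serialise a reproduction report to JSON
#'
#' Deterministic serialisation: the same report yields byte-identical
#' JSON text (no timestamps, fixed number formatting).
#'
#' @param report A `reproduction_report`.
#' @return A JSON string.
#' @export
report_json <- function(report) {
  as.character(jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                                null = "null", pretty = TRUE))
}

#' Validate the structure of a reproduction report
#'
#' Checks the report against the packaged schema
#' (`inst/schema/reproduction_report.schema.json`): required per-species
#' metrics with measured / ground-truth / error fields, and the two
#' comparison blocks.
#'
#' @param report A `reproduction_report` (or a list parsed from its JSON).
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
  need_metric <- function(m, where, with_truth = TRUE) {
    if (!is.list(m) || !is.numeric(m$measured %||% NULL)) {
      abort_param("report: missing measured value at %s", where)
    }
    if (with_truth && is.null(m$ground_truth)) {
      abort_param("report: missing ground truth at %s", where)
    }
  }
  if (!is.list(report$species) || length(report$species) == 0L) {
    abort_param("report has no species entries")
  }
  for (sp in names(report$species)) {
    e <- report$species[[sp]]
    for (nm in c("dimer_angle_deg", "stalk_sep_nm", "inter_dimer_nm",
                 "yaw_offset_deg", "wedge_angle_deg", "mean_width_nm")) {
      need_metric(e[[nm]], paste(sp, nm, sep = "$"))
    }
    need_metric(e$sa_to_v_per_nm, paste(sp, "sa_to_v_per_nm", sep = "$"),
                with_truth = FALSE)
  }
  if (length(report$comparisons) > 0L) {
    for (nm in c("sa_to_v", "width")) {
      cmp <- report$comparisons[[nm]]
      if (!is.list(cmp) || !is.numeric(cmp$fold_change %||% NULL) ||
          !is.numeric(cmp$p_value %||% NULL) || is.null(cmp$stars)) {
        abort_param("report: comparison block '%s' is incomplete", nm)
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.reproduction_report <- function(x, ...) {
  cat("<reproduction_report>\n")
  for (sp in names(x$species)) {
    e <- x$species[[sp]]
    cat(sprintf("  %s:\n", sp))
    for (nm in names(e)) {
      m <- e[[nm]]
      if (is.list(m) && !is.null(m$measured)) {
        if (!is.null(m$ground_truth) && is.finite(m$ground_truth)) {
          cat(sprintf("    %-18s %9.3f  (truth %8.3f, |err| %.3f)\n",
                      nm, m$measured, m$ground_truth, m$abs_error))
        } else {
          cat(sprintf("    %-18s %9.4f\n", nm, m$measured))
        }
      }
    }
  }
  if (length(x$comparisons) > 0L) {
    cat(sprintf("  SA:V fold change %.3f (Welch p = %.3g %s)\n",
                x$comparisons$sa_to_v$fold_change, x$comparisons$sa_to_v$p_value,
                x$comparisons$sa_to_v$stars))
    cat(sprintf("  width fold change %.3f (Mann-Whitney p = %.3g %s)\n",
                x$comparisons$width$fold_change, x$comparisons$width$p_value,
                x$comparisons$width$stars))
  }
  if (length(x$errors) > 0L) {
    cat(sprintf("  %d stage error(s): %s\n", length(x$errors),
                paste(names(x$errors), collapse = ", ")))
  }
  invisible(x)
}
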
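# Pose-table readers/writers: tab-separated text and a STAR-format dialect
# with one `data_dimers` loop (column names prefixed `_cm`).

star_cols <- function() {
  cols <- setdiff(pose_cols(), c("crista_id", "row_id", "dimer_id"))
  c("crista_id", "row_id", "dimer_id", cols)
}

#' Write a dimer pose table
#'
#' `format = "tsv"` writes plain tab-separated text with one row per dimer
#' (coordinates in nm); `format = "star"` writes an equivalent STAR file
#' with a single `data_dimers` loop.
#'
#' @param poses A pose table (e.g. from [place_dimer_row()]).
#' @param path Output path.
#' @param format `"tsv"` or `"star"` (default guessed from the extension).
#' @return `path`, invisibly.
#' @export
write_poses <- function(poses, path, format = NULL) {
  check_pose_table(poses)
  if (is.null(format)) {
    format <- if (tolower(tools::file_ext(path)) == "star") "star" else "tsv"
  }
  df <- as.data.frame(poses)[star_cols()]
  if (format == "tsv") {
    readr::write_tsv(df, path, progress = FALSE)
  } else if (format == "star") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# cristamorph dimer poses (lengths in nm)", "", "data_dimers", "", "loop_"), con)
    writeLines(sprintf("_cm%s #%d", paste0("_", names(df)), seq_along(df)), con)
    body <- do.call(paste, c(lapply(df, function(col) {
      if (is.numeric(col)) sprintf("%.9g", col) else as.character(col)
    }), list(sep = "\t")))
    writeLines(body, con)
  } else {
    abort_param("unsupported pose format '%s'", format)
  }
  invisible(path)
}

#' Read a dimer pose table
#'
#' Accepts the TSV and STAR dialects written by [write_poses()]; STAR
#' files are recognised by a `loop_` block.
#'
#' @param path Input path.
#' @return A `dimer_row` tibble.
#' @export
read_poses <- function(path) {
  if (!file.exists(path)) abort_param("file '%s' does not exist", path)
  head_txt <- readLines(path, n = 50L)
  is_star <- any(grepl("^\\s*loop_\\s*$", head_txt))
  if (is_star) {
    txt <- readLines(path)
    loop_at <- which(grepl("^\\s*loop_\\s*$", txt))[1L]
    rest <- txt[-seq_len(loop_at)]
    tag_lines <- grep("^\\s*_", rest)
    tags <- sub("^\\s*_cm_", "", sub("\\s+#\\d+\\s*$", "", rest[tag_lines]))
    body <- rest[-tag_lines]
    body <- body[nzchar(trimws(body)) & !grepl("^\\s*#", body)]
    parts <- strsplit(trimws(body), "\\s+")
    df <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
    names(df) <- tags
    num_cols <- setdiff(tags, c("crista_id", "row_id"))
    for (nm in num_cols) df[[nm]] <- as.numeric(df[[nm]])
    out <- tibble::as_tibble(df)
  } else {
    out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
  if ("dimer_id" %in% names(out)) out$dimer_id <- as.integer(out$dimer_id)
  check_pose_table(out)
  structure(out, class = c("dimer_row", class(tibble::tibble())))
}
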
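# Mesh readers/writers: binary little-endian PLY (default), ASCII PLY and
# Wavefront OBJ. Generator provenance (ridge polyline, preset, frame) is
# carried in a JSON sidecar `<path>.json` so round trips preserve it.

provenance_to_json <- function(prov) {
  p <- prov
  for (nm in c("ridge_polyline")) {
    if (!is.null(p[[nm]])) p[[nm]] <- apply(p[[nm]], 1L, identity, simplify = FALSE)
  }
  jsonlite::toJSON(p, auto_unbox = TRUE, digits = NA, null = "null")
}

provenance_from_json <- function(txt) {
  p <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
  if (!is.null(p$ridge_polyline)) {
    p$ridge_polyline <- matrix(unlist(p$ridge_polyline), ncol = 3L, byrow = !is.matrix(p$ridge_polyline))
    if (ncol(p$ridge_polyline) != 3L) p$ridge_polyline <- t(p$ridge_polyline)
  }
  p
}

#' Write a mesh to PLY or OBJ
#'
#' The format is chosen from the file extension: `.ply` (binary
#' little-endian by default) or `.obj`. Provenance, when present, is
#' written to a `<path>.json` sidecar.
#'
#' @param mesh A [tri_mesh()].
#' @param path Output path ending in `.ply` or `.obj`.
#' @param ascii For PLY, write ASCII instead of binary.
#' @param sidecar Write the provenance sidecar (default TRUE when the mesh
#'   has provenance).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, ascii = FALSE, sidecar = length(mesh$provenance) > 0L) {
  stopifnot(inherits(mesh, "tri_mesh"))
  ext <- tolower(tools::file_ext(path))
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  if (ext == "ply") {
    fmt <- if (ascii) "ascii 1.0" else "binary_little_endian 1.0"
    header <- c(
      "ply", paste("format", fmt),
      "comment produced by cristamorph (lengths in nm)",
      paste("element vertex", nv),
      "property float x", "property float y", "property float z",
      paste("element face", nf),
      "property list uchar int vertex_indices",
      "end_header"
    )
    if (ascii) {
      con <- file(path, "w")
      on.exit(close(con))
      writeLines(header, con)
      write.table(format(mesh$vertices, scientific = FALSE, trim = TRUE),
                  con, row.names = FALSE, col.names = FALSE, quote = FALSE)
      write.table(cbind(3L, mesh$faces - 1L), con, row.names = FALSE,
                  col.names = FALSE, quote = FALSE)
    } else {
      con <- file(path, "wb")
      on.exit(close(con))
      writeLines(header, con)
      writeBin(as.numeric(t(mesh$vertices)), con, size = 4L, endian = "little")
      # Interleave the uchar count with the int32 indices row by row.
      for (i in seq_len(nf)) {
        writeBin(as.raw(3L), con)
        writeBin(as.integer(mesh$faces[i, ] - 1L), con, size = 4L, endian = "little")
      }
    }
  } else if (ext == "obj") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# produced by cristamorph (lengths in nm)", con)
    writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1L],
                       mesh$vertices[, 2L], mesh$vertices[, 3L]), con)
    writeLines(sprintf("f %d %d %d", mesh$faces[, 1L], mesh$faces[, 2L],
                       mesh$faces[, 3L]), con)
  } else {
    abort_param("unsupported mesh format '.%s' (use .ply or .obj)", ext)
  }
  if (isTRUE(sidecar)) {
    writeLines(provenance_to_json(mesh$provenance), paste0(path, ".json"))
  }
  invisible(path)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) abort_param("truncated PLY header in '%s'", path)
    header <- c(header, line)
    if (line == "end_header") break
  }
  fmt <- sub("^format\\s+", "", grep("^format", header, value = TRUE)[1L])
  nv <- as.integer(sub("^element vertex\\s+", "", grep("^element vertex", header, value = TRUE)[1L]))
  nf <- as.integer(sub("^element face\\s+", "", grep("^element face", header, value = TRUE)[1L]))
  n_vprop <- sum(grepl("^property (float|double)", header))
  if (grepl("^ascii", fmt)) {
    txt <- readLines(con)
    txt <- txt[nzchar(trimws(txt))]
    vdat <- do.call(rbind, lapply(txt[seq_len(nv)], function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1L]])))
    vertices <- vdat[, 1:3, drop = FALSE]
    fdat <- lapply(txt[nv + seq_len(nf)], function(l) as.integer(strsplit(trimws(l), "\\s+")[[1L]]))
    faces <- do.call(rbind, lapply(fdat, function(f) {
      if (f[1L] != 3L) abort_param("only triangular PLY faces are supported")
      f[2:4] + 1L
    }))
  } else if (grepl("^binary_little_endian", fmt)) {
    size <- if (any(grepl("^property double", header))) 8L else 4L
    vdat <- readBin(con, "numeric", n = nv * n_vprop, size = size, endian = "little")
    vertices <- matrix(vdat, ncol = n_vprop, byrow = TRUE)[, 1:3, drop = FALSE]
    faces <- matrix(0L, nf, 3L)
    for (i in seq_len(nf)) {
      cnt <- as.integer(readBin(con, "raw", n = 1L))
      idx <- readBin(con, "integer", n = cnt, size = 4L, endian = "little")
      if (cnt != 3L) abort_param("only triangular PLY faces are supported")
      faces[i, ] <- idx + 1L
    }
  } else {
    abort_param("unsupported PLY format '%s'", fmt)
  }
  list(vertices = vertices, faces = faces)
}

read_obj <- function(path) {
  txt <- readLines(path)
  vl <- grep("^v\\s", txt, value = TRUE)
  fl <- grep("^f\\s", txt, value = TRUE)
  vertices <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x) as.numeric(x[2:4])))
  faces <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x) {
    idx <- as.integer(sub("/.*$", "", x[-1L]))
    if (length(idx) < 3L) abort_param("OBJ face with fewer than 3 vertices")
    # Fan-triangulate polygons.
    cbind(idx[1L], idx[2:(length(idx) - 1L)], idx[3:length(idx)])
  }))
  list(vertices = vertices, faces = faces)
}

#' Read a mesh from PLY or OBJ
#'
#' Reads triangulated meshes (ASCII or binary little-endian PLY; OBJ with
#' fan triangulation of polygons). A `<path>.json` provenance sidecar, if
#' present, is restored.
#'
#' @param path Path to a `.ply` or `.obj` file.
#' @return A [tri_mesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) abort_param("file '%s' does not exist", path)
  ext <- tolower(tools::file_ext(path))
  dat <- switch(ext,
    ply = read_ply(path),
    obj = read_obj(path),
    abort_param("unsupported mesh format '.%s' (use .ply or .obj)", ext)
  )
  prov <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    prov <- provenance_from_json(paste(readLines(sidecar), collapse = "\n"))
  }
  tri_mesh(dat$vertices, dat$faces, provenance = prov)
}
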
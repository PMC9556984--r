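#' Read a triangulated surface mesh from disk
#'
#' Supports STL (ASCII and binary) and ASCII PLY. Coordinates are converted to
#' meters via `unit_scale` (e.g. `1e-3` for the common millimeter-unit STL
#' convention). Degenerate faces (area below 1e-16 m^2) are dropped with a
#' message.
#'
#' @param path File path; format detected from extension and content.
#' @param unit_scale Multiplicative factor applied to coordinates (default 1,
#'   i.e. the file is already in meters).
#' @return A [surface_mesh()].
#' @export
read_mesh <- function(path, unit_scale = 1) {
  if (!is.numeric(unit_scale) || unit_scale <= 0) {
    vaa_abort("unit_scale must be a positive number", "vaaflow_invalid_parameter")
  }
  if (!file.exists(path) || file.size(path) == 0) {
    vaa_abort(sprintf("cannot read mesh '%s': missing or empty file (supported: STL, PLY)", path),
              "vaaflow_format_error")
  }
  ext <- tolower(tools::file_ext(path))
  mesh <- switch(ext,
    stl = read_stl(path),
    ply = read_ply_ascii(path),
    vaa_abort(sprintf("unsupported mesh format '%s' (supported: STL, PLY)", ext),
              "vaaflow_format_error")
  )
  surface_mesh(mesh$vertices * unit_scale, mesh$faces)
}

#' Write a mesh as ASCII STL or ASCII PLY
#'
#' @param mesh A [surface_mesh()].
#' @param path Output path; format chosen by extension (`.stl` or `.ply`).
#' @param unit_scale Factor applied to coordinates on write (default 1).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, unit_scale = 1) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    stl = write_stl_ascii(mesh, path, unit_scale),
    ply = write_ply_ascii(mesh, path, unit_scale),
    vaa_abort(sprintf("unsupported mesh format '%s' (supported: STL, PLY)", ext),
              "vaaflow_format_error")
  )
  invisible(path)
}

read_stl <- function(path) {
  head <- readBin(path, "raw", n = 512)
  txt <- suppressWarnings(rawToChar(head[head != as.raw(0)]))
  is_ascii <- suppressWarnings(
    grepl("^\\s*solid", txt, useBytes = TRUE) && grepl("facet", txt, useBytes = TRUE))
  if (isTRUE(is_ascii)) read_stl_ascii(path) else read_stl_binary(path)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0) {
    vaa_abort("corrupt ASCII STL: vertex count not a multiple of 3", "vaaflow_format_error")
  }
  nums <- t(vapply(strsplit(trimws(vl), "\\s+"),
                   function(x) as.numeric(x[2:4]), numeric(3)))
  if (any(!is.finite(nums))) vaa_abort("corrupt ASCII STL: non-numeric vertex", "vaaflow_format_error")
  dedupe_vertices(nums)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  ntri <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (is.na(ntri) || ntri <= 0 || ntri > 5e7) {
    vaa_abort("corrupt binary STL: bad triangle count", "vaaflow_format_error")
  }
  rec <- readBin(con, "raw", n = ntri * 50)
  if (length(rec) < ntri * 50) vaa_abort("corrupt binary STL: truncated", "vaaflow_format_error")
  m <- matrix(rec, nrow = 50)
  coords <- vapply(seq_len(ntri), function(i) {
    readBin(m[13:48, i], "numeric", n = 9, size = 4, endian = "little")
  }, numeric(9))
  verts <- matrix(as.numeric(coords), ncol = 3, byrow = TRUE)
  dedupe_vertices(verts)
}

# Collapse the per-triangle vertex soup into shared vertices + index faces.
dedupe_vertices <- function(verts) {
  key <- paste(signif(verts[, 1], 10), signif(verts[, 2], 10), signif(verts[, 3], 10))
  idx <- match(key, unique(key))
  uverts <- verts[!duplicated(key), , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  list(vertices = uverts, faces = faces)
}

write_stl_ascii <- function(mesh, path, unit_scale = 1) {
  v <- mesh$vertices * unit_scale
  f <- mesh$faces
  n <- mesh$face_normal
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid vaaflow", con)
  tri <- cbind(n,
               v[f[, 1], , drop = FALSE],
               v[f[, 2], , drop = FALSE],
               v[f[, 3], , drop = FALSE])
  block <- sprintf(
    "facet normal %.9g %.9g %.9g\n outer loop\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n endloop\nendfacet",
    tri[, 1], tri[, 2], tri[, 3], tri[, 4], tri[, 5], tri[, 6],
    tri[, 7], tri[, 8], tri[, 9], tri[, 10], tri[, 11], tri[, 12])
  writeLines(block, con)
  writeLines("endsolid vaaflow", con)
}

read_ply_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || lines[1] != "ply") vaa_abort("not a PLY file", "vaaflow_format_error")
  hend <- match("end_header", lines)
  if (is.na(hend)) vaa_abort("corrupt PLY: missing end_header", "vaaflow_format_error")
  header <- lines[seq_len(hend)]
  nv <- as.integer(sub("element vertex\\s+", "", grep("^element vertex", header, value = TRUE)))
  nf <- as.integer(sub("element face\\s+", "", grep("^element face", header, value = TRUE)))
  if (length(nv) != 1 || length(nf) != 1) vaa_abort("corrupt PLY header", "vaaflow_format_error")
  vlines <- lines[(hend + 1):(hend + nv)]
  flines <- lines[(hend + nv + 1):(hend + nv + nf)]
  verts <- t(vapply(strsplit(trimws(vlines), "\\s+"),
                    function(x) as.numeric(x[1:3]), numeric(3)))
  faces <- t(vapply(strsplit(trimws(flines), "\\s+"),
                    function(x) as.integer(x[2:4]) + 1L, integer(3)))
  list(vertices = verts, faces = faces)
}

write_ply_ascii <- function(mesh, path, unit_scale = 1) {
  v <- mesh$vertices * unit_scale
  f <- mesh$faces - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3]), con)
}
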
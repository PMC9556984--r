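#' Construct a triangulated vessel surface mesh
#'
#' The surface mesh is the substrate for all wall-shear maps: a set of 3-D
#' vertices and triangular faces with per-face areas and outward unit normals.
#' Meshes may be closed or open tubes; every edge must be shared by at most two
#' faces (manifold-with-boundary).
#'
#' @param vertices Numeric matrix (n x 3), coordinates in meters.
#' @param faces Integer matrix (m x 3) of 1-based vertex indices.
#' @param validate Check manifoldness and drop degenerate faces (default TRUE).
#'
#' @return An object of class `vaa_mesh`: list with `vertices`, `faces`,
#'   `face_area` (m^2), `face_normal` (unit rows), `face_centroid`.
#' @export
surface_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3 || ncol(faces) != 3) {
    vaa_abort("vertices must be n x 3 and faces m x 3", "vaaflow_invalid_parameter")
  }
  if (nrow(faces) < 1 || min(faces) < 1 || max(faces) > nrow(vertices)) {
    vaa_abort("face vertex indices out of range", "vaaflow_invalid_parameter")
  }
  v1 <- vertices[faces[, 1], , drop = FALSE]
  v2 <- vertices[faces[, 2], , drop = FALSE]
  v3 <- vertices[faces[, 3], , drop = FALSE]
  cr <- cross3_rows(v2 - v1, v3 - v1)
  area2 <- row_norms(cr)
  if (validate) {
    keep <- area2 > 2e-16
    ndrop <- sum(!keep)
    if (ndrop > 0) {
      faces <- faces[keep, , drop = FALSE]
      v1 <- v1[keep, , drop = FALSE]; v2 <- v2[keep, , drop = FALSE]
      v3 <- v3[keep, , drop = FALSE]
      cr <- cr[keep, , drop = FALSE]; area2 <- area2[keep]
      message(sprintf("surface_mesh: dropped %d degenerate faces", ndrop))
    }
    if (nrow(faces) == 0) vaa_abort("mesh has no non-degenerate faces", "vaaflow_format_error")
    ec <- edge_counts(faces)
    if (any(ec > 2L)) {
      vaa_abort("non-manifold mesh: an edge is shared by more than two faces",
                "vaaflow_geometry_error")
    }
  }
  structure(list(vertices = vertices, faces = faces,
                 face_area = area2 / 2,
                 face_normal = cr / pmax(area2, 1e-300),
                 face_centroid = (v1 + v2 + v3) / 3),
            class = "vaa_mesh")
}

# Count of faces per undirected edge; names are "i_j" with i < j.
edge_counts <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "_")
  table(key)
}

#' @export
print.vaa_mesh <- function(x, ...) {
  cat(sprintf("<vaa_mesh> %d vertices, %d faces, area %.4g mm^2\n",
              nrow(x$vertices), nrow(x$faces), 1e6 * sum(x$face_area)))
  invisible(x)
}

#' Total surface area of a mesh (m^2)
#' @param mesh A [surface_mesh()].
#' @export
mesh_area <- function(mesh) sum(mesh$face_area)

# Boundary loops of an open mesh as ordered vertex index cycles.
boundary_loops <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "_")
  cnt <- table(key)
  bkey <- names(cnt)[cnt == 1L]
  if (length(bkey) == 0) return(list())
  bm <- do.call(rbind, strsplit(bkey, "_"))
  be <- cbind(as.integer(bm[, 1]), as.integer(bm[, 2]))
  # adjacency: each boundary vertex has exactly two boundary neighbours
  adj <- split(c(be[, 2], be[, 1]), c(be[, 1], be[, 2]))
  visited <- character(0)
  loops <- list()
  verts_left <- unique(as.integer(be))
  used <- logical(max(verts_left))
  for (v0 in verts_left) {
    if (used[v0]) next
    loop <- integer(0)
    prev <- NA_integer_
    cur <- v0
    repeat {
      loop <- c(loop, cur)
      used[cur] <- TRUE
      nb <- adj[[as.character(cur)]]
      nxt <- nb[!(nb %in% c(prev))]
      nxt <- nxt[!used[nxt] | nxt == v0]
      if (length(nxt) == 0) break
      prev <- cur
      cur <- nxt[1]
      if (cur == v0) break
    }
    if (length(loop) >= 3) loops[[length(loops) + 1]] <- loop
  }
  loops
}

# Face adjacency (shared edge): list of integer vectors per face.
face_neighbors <- function(mesh) {
  f <- mesh$faces
  m <- nrow(f)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  fid <- rep(seq_len(m), 3L)
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "_")
  groups <- split(fid, key)
  nbr <- vector("list", m)
  for (g in groups) {
    if (length(g) == 2L) {
      nbr[[g[1]]] <- c(nbr[[g[1]]], g[2])
      nbr[[g[2]]] <- c(nbr[[g[2]]], g[1])
    }
  }
  nbr
}

# Minimum distance from each of a set of points to the mesh surface.
min_distance_to_mesh <- function(mesh, points) {
  v0 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  e0 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE] - v0
  e1 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE] - v0
  a <- rowSums(e0 * e0); b <- rowSums(e0 * e1); cc <- rowSums(e1 * e1)
  apply(points, 1, function(p) min(point_triangle_distances(p, v0, e0, e1, a, b, cc)))
}
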
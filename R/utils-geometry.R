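# Internal geometry helpers shared by the synthesis, centerline and excision
# stages. All lengths are SI meters.

`%||%` <- function(a, b) if (is.null(a)) b else a

vaa_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "vaaflow_error")))
}

unitize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) vaa_abort("cannot normalize zero vector", "vaaflow_geometry_error")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rows of a x rows of b, both n x 3
cross3_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

row_norms <- function(m) sqrt(rowSums(m^2))

# Rotation taking unit vector `from` onto unit vector `to` (Rodrigues).
rotation_between <- function(from, to) {
  v <- cross3(from, to)
  s2 <- sum(v^2)
  cth <- sum(from * to)
  if (s2 < 1e-30) {
    if (cth > 0) return(diag(3))
    # antiparallel: rotate pi about any axis orthogonal to `from`
    axis <- unitize(cross3(from, pick_orthogonal(from)))
    return(rotation_about(axis, pi))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - cth) / s2)
}

rotation_about <- function(axis, theta) {
  axis <- unitize(axis)
  vx <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1], axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(theta) * vx + (1 - cos(theta)) * vx %*% vx
}

pick_orthogonal <- function(v) {
  a <- abs(v)
  e <- if (a[1] <= a[2] && a[1] <= a[3]) c(1, 0, 0) else if (a[2] <= a[3]) c(0, 1, 0) else c(0, 0, 1)
  unitize(e - v * sum(e * v))
}

# Rotation-minimizing (parallel transport) frames along a polyline.
# Returns list(tangent, e1, e2): each n x 3, orthonormal per row.
transport_frames <- function(points) {
  n <- nrow(points)
  tg <- matrix(0, n, 3)
  tg[1, ] <- unitize(points[2, ] - points[1, ])
  tg[n, ] <- unitize(points[n, ] - points[n - 1, ])
  if (n > 2) {
    for (i in 2:(n - 1)) tg[i, ] <- unitize(points[i + 1, ] - points[i - 1, ])
  }
  e1 <- matrix(0, n, 3)
  e1[1, ] <- pick_orthogonal(tg[1, ])
  for (i in 2:n) {
    rot <- rotation_between(tg[i - 1, ], tg[i, ])
    v <- as.numeric(rot %*% e1[i - 1, ])
    # re-orthogonalize against accumulated numerical drift
    v <- v - tg[i, ] * sum(v * tg[i, ])
    e1[i, ] <- unitize(v)
  }
  e2 <- cross3_rows(tg, e1)
  list(tangent = tg, e1 = e1, e2 = e2)
}

# Discrete curvature (1/m) of a polyline by finite differences of the unit
# tangent with respect to arclength; end values copied from neighbours.
discrete_curvature <- function(points, arclength) {
  n <- nrow(points)
  if (n < 3) return(rep(0, n))
  k <- rep(0, n)
  for (i in 2:(n - 1)) {
    t1 <- unitize(points[i, ] - points[i - 1, ])
    t2 <- unitize(points[i + 1, ] - points[i, ])
    ds <- (arclength[i + 1] - arclength[i - 1]) / 2
    k[i] <- sqrt(sum((t2 - t1)^2)) / ds
  }
  k[1] <- k[2]
  k[n] <- k[n - 1]
  k
}

# Project points (m x 3) onto a polyline (points n x 3 with arclength),
# returning arclength coordinate and distance for each query point.
project_onto_polyline <- function(query, line_points, line_arclength) {
  nq <- nrow(query)
  np <- nrow(line_points)
  # nearest vertex first (vectorized distance matrix), then refine on the two
  # incident segments
  d2 <- outer(rowSums(query^2), rep(1, np)) +
    outer(rep(1, nq), rowSums(line_points^2)) -
    2 * query %*% t(line_points)
  nearest <- max.col(-d2, ties.method = "first")
  s_out <- numeric(nq)
  d_out <- numeric(nq)
  for (q in seq_len(nq)) {
    i <- nearest[q]
    best_s <- line_arclength[i]
    best_d2 <- max(d2[q, i], 0)
    for (j in c(i - 1L, i)) {
      if (j >= 1L && j < np) {
        a <- line_points[j, ]; b <- line_points[j + 1L, ]
        ab <- b - a
        tt <- sum((query[q, ] - a) * ab) / sum(ab^2)
        tt <- min(max(tt, 0), 1)
        p <- a + tt * ab
        dd <- sum((query[q, ] - p)^2)
        if (dd < best_d2) {
          best_d2 <- dd
          best_s <- line_arclength[j] + tt * (line_arclength[j + 1L] - line_arclength[j])
        }
      }
    }
    s_out[q] <- best_s
    d_out[q] <- sqrt(best_d2)
  }
  list(s = s_out, dist = d_out)
}

# Minimum distance from one point to every triangle of a mesh, vectorized over
# triangles (Eberly's region classification).
point_triangle_distances <- function(p, v0, e0, e1, a, b, c) {
  # v0: n x 3 triangle base vertices; e0 = v1 - v0; e1 = v2 - v0
  # a = <e0,e0>, b = <e0,e1>, c = <e1,e1> precomputed
  dvec <- matrix(p, nrow(v0), 3, byrow = TRUE) - v0
  d <- -(rowSums(e0 * dvec))
  e <- -(rowSums(e1 * dvec))
  f <- rowSums(dvec * dvec)
  det <- pmax(a * c - b * b, 1e-300)
  s <- b * e - c * d
  t <- b * d - a * e
  inside <- (s + t <= det) & (s >= 0) & (t >= 0)
  s_in <- s / det
  t_in <- t / det
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  # candidate closest points on the three edges, take the best; exact for all
  # exterior regions and coincides with the interior solution when inside
  s1 <- clamp01(-d / pmax(a, 1e-300))                        # edge t = 0
  q1 <- s1 * s1 * a + 2 * s1 * d + f
  t2 <- clamp01(-e / pmax(c, 1e-300))                        # edge s = 0
  q2 <- t2 * t2 * c + 2 * t2 * e + f
  # edge s + t = 1: substitute s = 1 - t
  num <- c + e - b - d
  den <- pmax(a - 2 * b + c, 1e-300)
  t3 <- clamp01(num / den)
  s3 <- 1 - t3
  q3 <- s3 * s3 * a + 2 * s3 * t3 * b + t3 * t3 * c + 2 * s3 * d + 2 * t3 * e + f
  q_edge <- pmin(q1, q2, q3)
  q_in <- s_in * s_in * a + 2 * s_in * t_in * b + t_in * t_in * c +
    2 * s_in * d + 2 * t_in * e + f
  sqrt(pmax(ifelse(inside, q_in, q_edge), 0))
}

# Evaluate a function under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}
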
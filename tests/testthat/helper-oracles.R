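# Independent brute-force oracles (no shared helpers with the package).

# convex hull faces by exhaustive side test, O(n^4); returns sorted
# vertex-index triples as a character key set
brute_hull_faces <- function(pts) {
  n <- nrow(pts)
  keys <- character(0)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    nrm <- c(
      (pts[j, 2] - pts[i, 2]) * (pts[k, 3] - pts[i, 3]) -
        (pts[j, 3] - pts[i, 3]) * (pts[k, 2] - pts[i, 2]),
      (pts[j, 3] - pts[i, 3]) * (pts[k, 1] - pts[i, 1]) -
        (pts[j, 1] - pts[i, 1]) * (pts[k, 3] - pts[i, 3]),
      (pts[j, 1] - pts[i, 1]) * (pts[k, 2] - pts[i, 2]) -
        (pts[j, 2] - pts[i, 2]) * (pts[k, 1] - pts[i, 1]))
    s <- as.vector((pts - matrix(pts[i, ], n, 3, byrow = TRUE)) %*% nrm)
    tol <- 1e-9 * max(abs(s))
    if (all(s <= tol) || all(s >= -tol))
      keys <- c(keys, paste(i, j, k, sep = "_"))
  }
  unique(keys)
}

# 2-D flood fill from the slice border; returns logical matrix of pixels
# reachable from outside (so !reachable & !mask = holes)
flood_from_border <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  reach <- matrix(FALSE, nr, nc)
  queue <- cbind(
    rbind(cbind(1, seq_len(nc)), cbind(nr, seq_len(nc)),
          cbind(seq_len(nr), 1), cbind(seq_len(nr), nc)))
  queue <- queue[!mask[queue], , drop = FALSE]
  reach[queue] <- TRUE
  while (nrow(queue) > 0) {
    nxt <- NULL
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      q <- sweep(queue, 2, d, "+")
      ok <- q[, 1] >= 1 & q[, 1] <= nr & q[, 2] >= 1 & q[, 2] <= nc
      q <- q[ok, , drop = FALSE]
      q <- q[!mask[q] & !reach[q], , drop = FALSE]
      if (nrow(q) > 0) { reach[q] <- TRUE; nxt <- rbind(nxt, q) }
    }
    queue <- if (is.null(nxt)) matrix(0, 0, 2) else unique(nxt)
  }
  reach
}

# per-voxel brute-force boundary scan (6-neighbourhood, out of bounds false)
brute_boundary_voxels <- function(vox) {
  d <- dim(vox)
  out <- NULL
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    if (!vox[x, y, z]) next
    nb <- rbind(c(x - 1, y, z), c(x + 1, y, z), c(x, y - 1, z),
                c(x, y + 1, z), c(x, y, z - 1), c(x, y, z + 1))
    bnd <- FALSE
    for (r in seq_len(6)) {
      p <- nb[r, ]
      if (any(p < 1) || any(p > d)) { bnd <- TRUE; break }
      if (!vox[p[1], p[2], p[3]]) { bnd <- TRUE; break }
    }
    if (bnd) out <- rbind(out, c(x, y, z))
  }
  out
}

# independent per-triangle angle/area computation (plain trigonometry,
# one triangle at a time)
oracle_triangle_angles <- function(p1, p2, p3) {
  ang <- function(a, b, c) {
    u <- b - a; v <- c - a
    acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
  }
  c(ang(p1, p2, p3), ang(p2, p3, p1), ang(p3, p1, p2))
}

oracle_triangle_area <- function(p1, p2, p3) {
  if (length(p1) == 2) { p1 <- c(p1, 0); p2 <- c(p2, 0); p3 <- c(p3, 0) }
  u <- p2 - p1; v <- p3 - p1
  cr <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  sqrt(sum(cr^2)) / 2
}

# shortest distance from a point to a triangle (vertex/edge/face cases)
point_triangle_distance <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(sqrt(sum(ap^2)))
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(sqrt(sum(bp^2)))
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    t <- d1 / (d1 - d3)
    return(sqrt(sum((p - (a + t * ab))^2)))
  }
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(sqrt(sum(cp^2)))
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    t <- d2 / (d2 - d6)
    return(sqrt(sum((p - (a + t * ac))^2)))
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    t <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(sqrt(sum((p - (b + t * (c - b)))^2)))
  }
  denom <- 1 / (va + vb + vc)
  v <- vb * denom; w <- vc * denom
  sqrt(sum((p - (a + ab * v + ac * w))^2))
}

# small solid phantom + NIfTI file fixture shared by several tests
make_phantom_fixture <- function(noise_sd = 0, defects = list(), seed = 1,
                                 shape = c(72, 72, 72), spacing = rep(1.5, 3),
                                 semi = c(42, 38, 45), thickness = 6) {
  spec <- phantom_spec(shape = shape, spacing = spacing, semi_axes = semi,
                       thickness = thickness, noise_sd = noise_sd,
                       defects = defects, seed = seed)
  generate_phantom(spec)
}
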
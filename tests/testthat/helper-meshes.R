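# Mesh fixtures built in code.

# UV-grid spherical cap: rings latitude bands from the pole down to
# polar angle `phi_max`; exactly one boundary loop (disk topology).
uv_cap <- function(n_rings = 10, n_seg = 12, radius = 1, phi_max = pi / 2,
                   center = c(0, 0, 0)) {
  verts <- matrix(c(0, 0, radius), 1, 3)
  for (i in seq_len(n_rings)) {
    phi <- phi_max * i / n_rings
    th <- 2 * pi * (seq_len(n_seg) - 1) / n_seg
    verts <- rbind(verts, cbind(radius * sin(phi) * cos(th),
                                radius * sin(phi) * sin(th),
                                radius * cos(phi)))
  }
  ring <- function(i) 1 + (i - 1) * n_seg + seq_len(n_seg)  # i >= 1
  faces <- NULL
  r1 <- ring(1)
  faces <- cbind(1, r1, c(r1[-1], r1[1]))
  for (i in seq_len(n_rings - 1)) {
    a <- ring(i); b <- ring(i + 1)
    an <- c(a[-1], a[1]); bn <- c(b[-1], b[1])
    faces <- rbind(faces, cbind(a, b, bn), cbind(a, bn, an))
  }
  triangle_mesh(sweep(verts, 2, center, "+"), faces)
}

# random disk-topology mesh: polar-grid disk with jittered vertices and a
# random height field; connectivity guarantees one boundary loop
random_disk_mesh <- function(seed, max_rings = 5, max_seg = 9) {
  set.seed(seed)
  n_rings <- sample(2:max_rings, 1)
  n_seg <- sample(5:max_seg, 1)
  m <- uv_cap(n_rings, n_seg, radius = 1, phi_max = pi / 2)
  v <- m$vertices
  # re-project the cap onto a planar disk, then perturb
  r <- sqrt(v[, 1]^2 + v[, 2]^2)
  v[, 3] <- 0.3 * sin(2 * v[, 1]) * cos(v[, 2]) * (1 - r)
  interior <- setdiff(seq_len(nrow(v)), boundary_loops(m)[[1]])
  jit <- matrix(runif(length(interior) * 2, -0.2, 0.2) / n_rings,
                ncol = 2)
  v[interior, 1:2] <- v[interior, 1:2] + jit
  triangle_mesh(v, m$faces)
}

# closed ellipsoid mesh from an octahedron refined by Loop subdivision
ellipsoid_mesh <- function(semi = c(1, 1, 1), subdiv = 3, center = c(0, 0, 0)) {
  v <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
             c(0, 0, 1), c(0, 0, -1))
  f <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
             c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  m <- triangle_mesh(v, f)
  for (i in seq_len(subdiv)) {
    m <- loop_subdivide(m, 1)
    m$vertices <- m$vertices / sqrt(rowSums(m$vertices^2))  # reproject
  }
  triangle_mesh(sweep(m$vertices %*% diag(semi), 2, center, "+"), m$faces)
}

# hemispheric open surface with about `target_faces` faces
hemisphere_surface <- function(target_faces = 20000, radius = 50) {
  n_seg <- max(8, round(sqrt(target_faces / 2)))
  n_rings <- max(2, round(target_faces / (2 * n_seg)) + 1)
  open_surface(uv_cap(n_rings, n_seg, radius = radius, phi_max = pi / 2))
}
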
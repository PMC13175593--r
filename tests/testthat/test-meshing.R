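test_that("triangle_mesh validates faces", {
  v <- diag(3)
  expect_error(triangle_mesh(v, rbind(c(1, 2, 4))), "out of range")
  expect_error(triangle_mesh(v, rbind(c(1, 2, 2))), "distinct")
  expect_silent(triangle_mesh(v, rbind(c(1, 2, 3))))
})

test_that("alpha shape of a regular tetrahedron is its 4-face surface", {
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
               c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
  m <- alpha_shape_critical(tet)
  expect_equal(nrow(m$faces), 4)
  expect_equal(nrow(m$vertices), 4)
  expect_true(is_closed(m))
  expect_gt(signed_volume(m), 0)
})

test_that("alpha shape of sphere samples is a closed genus-0 surface near all points", {
  set.seed(7)
  p <- matrix(rnorm(1500), ncol = 3)
  p <- p / sqrt(rowSums(p^2))
  m <- alpha_shape_critical(p)
  expect_true(is_closed(m))
  expect_true(is_edge_manifold(m))
  expect_equal(euler_characteristic(m), 2)
  # every input point within 2x mean spacing of the mesh (brute-force
  # nearest-triangle search)
  spacing <- sqrt(4 * pi / 500)
  dmax <- 0
  for (i in seq_len(nrow(p))) {
    best <- Inf
    for (fi in seq_len(nrow(m$faces))) {
      f <- m$faces[fi, ]
      d <- point_triangle_distance(p[i, ], m$vertices[f[1], ],
                                   m$vertices[f[2], ], m$vertices[f[3], ])
      if (d < best) best <- d
      if (best == 0) break
    }
    dmax <- max(dmax, best)
  }
  expect_lt(dmax, 2 * spacing)
})

test_that("alpha shape of convex-position points reproduces the convex hull", {
  set.seed(11)
  p <- matrix(rnorm(120), ncol = 3)
  p <- p / sqrt(rowSums(p^2))          # 40 points on the sphere
  m <- alpha_shape_critical(p)
  hull <- brute_hull_faces(p)
  # map mesh vertices back to input indices
  idx <- apply(m$vertices, 1, function(v)
    which.min(colSums((t(p) - v)^2)))
  got <- apply(m$faces, 1, function(f)
    paste(sort(idx[f]), collapse = "_"))
  expect_setequal(got, hull)
})

test_that("degenerate point sets are rejected", {
  expect_error(alpha_shape_critical(rbind(c(0, 0, 0), c(1, 1, 1),
                                          c(2, 2, 2))), "at least 4")
  flat <- cbind(matrix(runif(20), ncol = 2), 0)
  expect_error(alpha_shape_critical(flat), "coplanar")
})

test_that("cleanup_manifold is idempotent and resolves non-manifold edges", {
  sph <- ellipsoid_mesh(c(1, 1, 1), subdiv = 2)
  out <- cleanup_manifold(sph)
  expect_equal(nrow(out$faces), nrow(sph$faces))
  expect_equal(sort(as.vector(out$faces)), sort(as.vector(sph$faces)))

  # two tetrahedra sharing one edge: 6 faces share it -> smallest removed
  # until every edge has <= 2 faces (verified by brute-force edge counts)
  v <- rbind(c(0, 0, 0), c(1, 0, 0),                   # shared edge 1-2
             c(0.5, 1, 0), c(0.5, 0.5, 1),             # big tet
             c(0.5, -0.2, 0), c(0.5, -0.1, 0.2))       # small tet
  f <- rbind(c(1, 2, 3), c(1, 4, 2), c(1, 3, 4), c(2, 4, 3),
             c(1, 2, 5), c(1, 6, 2), c(1, 5, 6), c(2, 6, 5))
  fixed <- cleanup_manifold(triangle_mesh(v, f))
  ff <- fixed$faces
  ec <- table(paste(pmin(c(ff[, 1], ff[, 2], ff[, 3]),
                         c(ff[, 2], ff[, 3], ff[, 1])),
                    pmax(c(ff[, 1], ff[, 2], ff[, 3]),
                         c(ff[, 2], ff[, 3], ff[, 1]))))
  expect_true(all(ec <= 2))               # brute-force edge incidence
  expect_true(is_edge_manifold(fixed))

  # zero-area face removed
  v2 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(2, 0, 0))
  f2 <- rbind(c(1, 2, 3), c(1, 2, 4))   # second face is collinear
  out2 <- cleanup_manifold(triangle_mesh(v2, f2))
  expect_equal(nrow(out2$faces), 1)
})

test_that("loop subdivision multiplies faces by 4 and keeps boundaries", {
  tet <- alpha_shape_critical(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                    c(0, 0, 1)))
  expect_equal(nrow(loop_subdivide(tet, 1)$faces), 16)
  expect_equal(nrow(loop_subdivide(tet, 2)$faces), 64)
  expect_identical(loop_subdivide(tet, 0), tet)
  cap <- uv_cap(4, 8)
  sub <- loop_subdivide(cap, 1)
  expect_equal(nrow(sub$faces), 4 * nrow(cap$faces))
  expect_equal(length(boundary_loops(sub)), 1)
  expect_equal(length(boundary_loops(sub)[[1]]),
               2 * length(boundary_loops(cap)[[1]]))
  expect_equal(euler_characteristic(sub), 1)
})

test_that("LUFO partition yields four disk-topology patches with overlap", {
  mesh <- ellipsoid_mesh(c(65, 55, 70), subdiv = 3)
  part <- partition_lufo(mesh, overlap_fraction = 0.1)
  for (nm in c("lower", "upper", "frontal", "occipital")) {
    s <- part[[nm]]
    expect_s3_class(s, "open_surface")
    m <- s$mesh
    expect_equal(nrow(m$vertices) - nrow(skullflat:::.edge_counts(m)) +
                   nrow(m$faces), 1)
    expect_equal(length(boundary_loops(m)), 1)
  }
  # joint coverage: every input face appears in at least one patch
  fkey <- function(f, pv) apply(f, 1, function(x)
    paste(sort(pv[x]), collapse = "_"))
  all_keys <- unique(unlist(lapply(
    c("lower", "upper", "frontal", "occipital"),
    function(nm) fkey(part[[nm]]$mesh$faces, part[[nm]]$parent_vertex))))
  in_keys <- apply(mesh$faces, 1, function(x) paste(sort(x), collapse = "_"))
  expect_true(all(in_keys %in% all_keys))

  # vertices within +/- 5% of the centroid plane are in both patches
  ax <- part$axes
  proj <- as.vector(sweep(mesh$vertices, 2, ax$center) %*% ax$si)
  band <- which(abs(proj) <= 0.05 * diff(range(proj)) - 1e-9)
  expect_true(all(band %in% part$lower$parent_vertex))
  expect_true(all(band %in% part$upper$parent_vertex))

  # overlap 0: interiors disjoint apart from the cut neighbourhood
  p0 <- partition_lufo(mesh, overlap_fraction = 0)
  shared <- intersect(p0$lower$parent_vertex, p0$upper$parent_vertex)
  expect_true(all(abs(proj[shared]) <= 0.02 * diff(range(proj))))
  expect_error(partition_lufo(mesh, 0.5), "overlap_fraction")
  expect_error(partition_lufo(uv_cap(3, 6), 0.1), "not closed")
})

test_that("HU attachment interpolates trilinearly with a fill rule", {
  arr <- array(0, c(4, 4, 4))
  arr[3, 2, 2] <- 1000
  vol <- ct_volume(arr, c(1, 1, 1), c(0, 0, 0))
  v <- rbind(c(2, 1, 1),        # centre of voxel [3,2,2] -> exact
             c(1.5, 1, 1),      # midway between 0 and 1000 -> 500
             c(10, 10, 10))     # outside -> min
  m <- attach_hu(triangle_mesh(v, rbind(c(1, 2, 3))), vol)
  expect_equal(m$vertex_hu, c(1000, 500, 0))
})

test_that("mesh I/O round-trips OBJ and PLY with vertex HU", {
  m <- uv_cap(3, 7, radius = 2.5)
  m$vertex_hu <- seq_len(nrow(m$vertices)) * 10
  fo <- withr::local_tempfile(fileext = ".obj")
  fp <- withr::local_tempfile(fileext = ".ply")
  write_obj(m, fo); write_ply(m, fp)
  mo <- read_obj(fo); mp <- read_ply(fp)
  for (r in list(mo, mp)) {
    expect_equal(r$vertices, m$vertices, tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_identical(r$faces, m$faces)
    expect_equal(r$vertex_hu, m$vertex_hu, tolerance = 1e-4)
  }
})
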
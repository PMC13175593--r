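test_that("facet angles and areas match closed forms", {
  h <- sqrt(3) / 2
  eq <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, h, 0)),
                      rbind(c(1, 2, 3)))
  expect_equal(as.vector(facet_angles(eq)), rep(pi / 3, 3))
  rt <- triangle_mesh(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0)),
                      rbind(c(1, 2, 3)))
  a <- facet_angles(rt) * 180 / pi
  expect_equal(sort(as.vector(a)), sort(c(90, 53.13010235, 36.86989765)),
               tolerance = 1e-7)
  expect_equal(sum(a), 180, tolerance = 1e-9)
  expect_equal(facet_area(rt)[1], 6)
  unit <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                        rbind(c(1, 2, 3)))
  expect_equal(facet_area(unit)[1], 0.5)
  expect_equal(facet_area(triangle_mesh(
    rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0) + 1e-30), rbind(c(1, 2, 3))))[1],
    0, tolerance = 1e-12)
  big <- triangle_mesh(rt$vertices * 3, rt$faces)
  expect_equal(facet_area(big)[1], 9 * facet_area(rt)[1])
  expect_error(facet_angles(triangle_mesh(
    rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)), rbind(c(1, 2, 3)))),
    "zero-length")
})

planar_surface <- function() {
  m <- uv_cap(5, 11)
  m$vertices[, 3] <- 0
  open_surface(m)
}

as_embedding <- function(positions, surf) {
  structure(list(positions = positions, boundary_vertices = surf$boundary_loop,
                 source = surf), class = "planar_embedding")
}

test_that("identity and similarity maps have zero distortion", {
  surf <- planar_surface()
  emb <- as_embedding(surf$mesh$vertices[, 1:2], surf)
  expect_equal(max(angle_distortion(surf, emb)), 0, tolerance = 1e-9)
  ea <- area_distortion(surf, emb)
  expect_equal(max(abs(ea)), 0, tolerance = 1e-10)
  # similarity: rotation + uniform scale s = 2 -> E_theta 0, E_A log10(4)
  th <- 0.61
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  emb2 <- as_embedding(2 * surf$mesh$vertices[, 1:2] %*% R, surf)
  expect_equal(max(angle_distortion(surf, emb2)), 0, tolerance = 1e-8)
  expect_equal(as.numeric(area_distortion(surf, emb2)),
               rep(log10(4), nrow(surf$mesh$faces)), tolerance = 1e-10)
  # scale 1/10 -> E_A = -2
  emb3 <- as_embedding(surf$mesh$vertices[, 1:2] / 10, surf)
  expect_equal(as.numeric(area_distortion(surf, emb3)),
               rep(-2, nrow(surf$mesh$faces)), tolerance = 1e-10)
  # natural-log option
  expect_equal(as.numeric(area_distortion(surf, emb3, log_base = exp(1))),
               rep(-2 * log(10), nrow(surf$mesh$faces)), tolerance = 1e-9)
})

test_that("anisotropic stretch matches direct angle evaluation", {
  h <- sqrt(3) / 2
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, h, 0))
  surf <- open_surface(triangle_mesh(v, rbind(c(1, 2, 3))))
  stretch <- cbind(2 * v[, 1], v[, 2])           # x2 along x
  emb <- as_embedding(stretch, surf)
  got <- angle_distortion(surf, emb)
  a0 <- oracle_triangle_angles(v[1, ], v[2, ], v[3, ])
  a1 <- oracle_triangle_angles(c(stretch[1, ], 0), c(stretch[2, ], 0),
                               c(stretch[3, ], 0))
  expect_equal(got, mean(abs(a1 - a0)) * 180 / pi, tolerance = 1e-10)
  ea <- area_distortion(surf, emb)
  expect_equal(as.numeric(ea), log10(2), tolerance = 1e-10)
})

test_that("per-facet metrics agree with an independent per-triangle oracle", {
  surf <- open_surface(random_disk_mesh(99))
  emb <- flatten_to_disk(surf)
  et <- angle_distortion(surf, emb)
  ea <- area_distortion(surf, emb)
  v3 <- surf$mesh$vertices; v2 <- emb$positions
  for (fi in seq_len(nrow(surf$mesh$faces))) {
    f <- surf$mesh$faces[fi, ]
    o3 <- oracle_triangle_angles(v3[f[1], ], v3[f[2], ], v3[f[3], ])
    o2 <- oracle_triangle_angles(c(v2[f[1], ], 0), c(v2[f[2], ], 0),
                                 c(v2[f[3], ], 0))
    expect_equal(et[fi], mean(abs(o2 - o3)) * 180 / pi, tolerance = 1e-10)
    a3 <- oracle_triangle_area(v3[f[1], ], v3[f[2], ], v3[f[3], ])
    a2 <- oracle_triangle_area(v2[f[1], ], v2[f[2], ], v2[f[3], ])
    expect_equal(ea[fi], log10(a2 / a3), tolerance = 1e-10)
  }
  expect_true(all(et >= 0))
  expect_equal(length(et), nrow(surf$mesh$faces))
})

test_that("metrics are invariant to rigid motion of either side", {
  surf <- open_surface(random_disk_mesh(5))
  emb <- flatten_to_disk(surf)
  et <- angle_distortion(surf, emb)
  ea <- area_distortion(surf, emb)
  th <- 1.1
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  surf2 <- open_surface(triangle_mesh(surf$mesh$vertices %*% Rz - 2,
                                      surf$mesh$faces))
  expect_equal(angle_distortion(surf2, emb), et, tolerance = 1e-9)
  expect_equal(as.numeric(area_distortion(surf2, emb)), as.numeric(ea),
               tolerance = 1e-9)
  R2 <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  emb2 <- as_embedding(emb$positions %*% R2, surf)
  expect_equal(angle_distortion(surf, emb2), et, tolerance = 1e-9)
  # uniform scaling of the embedding leaves E_theta unchanged
  emb3 <- as_embedding(emb$positions * 3.7, surf)
  expect_equal(angle_distortion(surf, emb3), et, tolerance = 1e-9)
})

test_that("flipped facets are flagged and zero-area facets excluded", {
  surf <- planar_surface()
  pos <- surf$mesh$vertices[, 1:2]
  pos[1, ] <- c(0.9, 0)      # drag the centre vertex outside its ring
  emb <- as_embedding(pos, surf)
  ea <- area_distortion(surf, emb)
  expect_gt(sum(attr(ea, "flipped")), 0)
  rep <- distortion_report(surf, emb)
  expect_equal(rep$n_flipped, sum(attr(ea, "flipped")))
  expect_equal(nrow(rep$per_facet), nrow(surf$mesh$faces))
})

test_that("distortion maps rasterize facet values", {
  surf <- planar_surface()
  emb <- as_embedding(surf$mesh$vertices[, 1:2], surf)
  vals <- rep(1, nrow(surf$mesh$faces))
  img <- render_distortion_map(emb, vals, resolution = 64)
  expect_equal(dim(img), c(64, 64 + 24, 3))
  core <- img[20:44, 20:44, ]           # uniform colour in the disk centre
  expect_lt(max(apply(matrix(core, ncol = 3), 2, function(x)
    diff(range(x)))), 1e-9)
  # two-facet mesh with alternating values -> two distinct colours
  v <- rbind(c(-0.8, -0.5), c(0.8, -0.5), c(0, 0.6), c(0, -1))
  surf2 <- open_surface(triangle_mesh(cbind(v, 0), rbind(c(1, 2, 3),
                                                         c(2, 1, 4))))
  emb2 <- as_embedding(v, surf2)
  img2 <- render_distortion_map(emb2, c(0, 1), resolution = 64)
  up <- img2[45, 32, ]; down <- img2[10, 32, ]
  expect_gt(sum(abs(up - down)), 0.1)
  # empty facet list -> blank disk
  img3 <- render_distortion_map(emb2, numeric(0), faces = matrix(0L, 0, 3),
                                resolution = 64)
  expect_true(all(img3[, 1:32, ] == 1))
})
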
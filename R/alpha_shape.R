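#' Alpha-shape surface at the critical alpha
#'
#' Computes the 3-D Delaunay tetrahedralization of the point cloud and finds,
#' by bisection over the sorted circumradius spectrum, the smallest alpha for
#' which the alpha complex (tetrahedra with circumradius <= alpha) is a
#' single face-connected component whose tetrahedra reference every input
#' point and whose boundary is watertight (every boundary edge bordered by
#' exactly two boundary faces) — the operational reading of an alpha shape
#' that encloses all points. The returned surface is the largest connected component of the
#' complex boundary (faces bordering exactly one included tetrahedron),
#' consistently wound outward. For a thin shell cloud this selects the outer
#' surface.
#'
#' Input points are isotropically rescaled and symbolically jittered
#' (deterministically, ~1e-7 of the extent) before tetrahedralization so
#' that grid-aligned clouds, which are maximally degenerate for Delaunay
#' predicates, are handled robustly; output vertex coordinates are the
#' original, unjittered points.
#'
#' @param points a [surface_points][extract_surface_points()] object or an
#'   n x 3 matrix of world coordinates (mm), n >= 4, not all coplanar.
#' @return A [triangle_mesh()]; attribute `alpha` holds the critical alpha
#'   (mm) and `n_boundary_components` the boundary component count before
#'   largest-component selection.
#' @export
alpha_shape_critical <- function(points) {
  if (inherits(points, "surface_points")) points <- points$points
  points <- as.matrix(points)
  pts <- unique(points)
  if (nrow(pts) < 4)
    stop("alpha shape needs at least 4 distinct points")
  if (qr(sweep(pts, 2, colMeans(pts)))$rank < 3)
    stop("degenerate input: points are collinear or coplanar")

  ctr <- colMeans(pts)
  scale <- 1 / max(apply(pts, 2, function(c) diff(range(c))))
  p0 <- sweep(pts, 2, ctr) * scale
  # deterministic symbolic jitter (Weyl sequences per axis); if the float
  # predicates still produce an inconsistent triangulation (detected as a
  # disconnected tet graph or a skipped point), retry with larger jitter
  n <- nrow(p0)
  i <- seq_len(n)
  jit <- cbind((i * 0.7548776662466927) %% 1,
               (i * 0.5698402909980532) %% 1,
               (i * 0.3247179572447460) %% 1) - 0.5
  for (amp in c(1e-5, 1e-4, 1e-3)) {
    dt <- .delaunay3d_cpp(p0 + jit * 2 * amp)
    tets <- dt$tets
    nbr <- dt$neighbors
    r <- dt$circumradius / scale        # back to mm
    m <- nrow(tets)
    if (m == 0) stop("degenerate input: tetrahedralization is empty")
    # tet adjacency edge list (each internal face once)
    adj_a <- rep(seq_len(m), 4)
    adj_b <- as.vector(nbr)
    keep <- !is.na(adj_b) & adj_a < adj_b
    adj_a <- adj_a[keep]; adj_b <- adj_b[keep]
    g <- igraph::make_empty_graph(n = m, directed = FALSE)
    g <- igraph::add_edges(g, rbind(adj_a, adj_b))
    if (igraph::components(g)$no == 1L &&
        length(unique(as.vector(tets))) == n) break
  }

  boundary_faces <- function(sel) {
    bf <- NULL
    for (k in 1:4) {
      nb <- nbr[, k]
      s <- sel & (is.na(nb) | !sel[ifelse(is.na(nb), 1L, nb)])
      if (any(s)) bf <- rbind(bf, tets[s, -k, drop = FALSE])
    }
    bf
  }
  rs <- sort(unique(r))
  covered_single <- function(alpha) {
    inc <- which(r <= alpha)
    if (length(inc) == 0) return(FALSE)
    if (length(unique(as.vector(tets[inc, , drop = FALSE]))) < n) return(FALSE)
    sel <- logical(m); sel[inc] <- TRUE
    e <- sel[adj_a] & sel[adj_b]
    if (length(inc) > 1L) {
      if (!any(e)) return(FALSE)
      g <- igraph::make_empty_graph(n = length(inc), directed = FALSE)
      id <- integer(m); id[inc] <- seq_along(inc)
      g <- igraph::add_edges(g, rbind(id[adj_a[e]], id[adj_b[e]]))
      if (igraph::components(g)$no != 1L) return(FALSE)
    }
    # the enclosing boundary must be watertight: every boundary edge
    # bordered by exactly two boundary faces
    bf <- boundary_faces(sel)
    ek <- c(pmin(bf[, 1], bf[, 2]) * (n + 1) + pmax(bf[, 1], bf[, 2]),
            pmin(bf[, 2], bf[, 3]) * (n + 1) + pmax(bf[, 2], bf[, 3]),
            pmin(bf[, 1], bf[, 3]) * (n + 1) + pmax(bf[, 1], bf[, 3]))
    uk <- unique(ek)
    all(tabulate(match(ek, uk), length(uk)) == 2L)
  }

  if (!covered_single(rs[length(rs)])) {
    inc <- seq_len(m)
    cov <- length(unique(as.vector(tets))) / n
    stop(sprintf(paste0("no alpha encloses all points in one component ",
                        "(full complex covers %.1f%% of points)"), 100 * cov))
  }
  lo <- 1L; hi <- length(rs)
  if (covered_single(rs[1])) {
    hi <- 1L
  } else {
    while (hi - lo > 1L) {               # bracket: lo fails, hi passes
      mid <- (lo + hi) %/% 2L
      if (covered_single(rs[mid])) hi <- mid else lo <- mid
    }
  }
  alpha <- rs[hi]

  bf <- boundary_faces(r <= alpha)
  mesh <- triangle_mesh(pts, bf)
  comp <- .face_components(mesh)
  ncomp <- max(comp)
  if (ncomp > 1) {
    sizes <- tabulate(comp)
    mesh <- triangle_mesh(pts, mesh$faces[comp == which.max(sizes), ,
                                          drop = FALSE])
  }
  mesh <- .drop_unreferenced(mesh)
  mesh <- .orient_mesh(mesh)
  attr(mesh, "alpha") <- alpha
  attr(mesh, "n_boundary_components") <- ncomp
  mesh
}
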
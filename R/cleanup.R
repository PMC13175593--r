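#' Repair a mesh to an edge-manifold, consistently wound surface
#'
#' Removes zero-area and duplicate faces, then resolves every edge bordered
#' by more than two faces by deleting its smallest-area incident faces until
#' two remain, iterating until the mesh is edge-manifold. Unreferenced
#' vertices are dropped and windings are re-oriented consistently (outward,
#' i.e. positive signed volume, for closed meshes). Manifold meshes pass
#' through unchanged (idempotent).
#'
#' @param mesh a [triangle_mesh()].
#' @return A [triangle_mesh()]; attribute `parent_vertex` maps its vertices
#'   to the input's vertex indices.
#' @export
cleanup_manifold <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  f <- mesh$faces
  v <- mesh$vertices
  scale2 <- max(apply(v, 2, function(c) diff(range(c))))^2
  areas <- .face_areas(mesh)
  keep <- areas > 1e-12 * max(scale2, 1e-300)
  # duplicate faces (same vertex set)
  skey <- apply(matrix(apply(f, 1, sort), nrow = 3), 2,
                function(x) paste(x, collapse = "_"))
  keep <- keep & !duplicated(skey)
  f <- f[keep, , drop = FALSE]
  areas <- areas[keep]

  nV <- nrow(v)
  repeat {
    if (nrow(f) == 0) stop("cleanup removed every face: empty mesh")
    key <- function(a, b) pmin(a, b) * (nV + 1) + pmax(a, b)
    k <- c(key(f[, 1], f[, 2]), key(f[, 2], f[, 3]), key(f[, 3], f[, 1]))
    fid <- rep(seq_len(nrow(f)), 3)
    uk <- unique(k)
    idx <- match(k, uk)
    cnt <- tabulate(idx, length(uk))
    bad <- which(cnt > 2L)
    if (length(bad) == 0) break
    drop_faces <- integer(0)
    for (e in bad) {
      inc <- fid[idx == e]
      inc <- setdiff(inc, drop_faces)
      if (length(inc) <= 2) next
      o <- inc[order(areas[inc])]                 # smallest-area first
      drop_faces <- c(drop_faces, o[seq_len(length(o) - 2L)])
    }
    if (length(drop_faces) == 0) break
    f <- f[-drop_faces, , drop = FALSE]
    areas <- areas[-drop_faces]
  }
  out <- .drop_unreferenced(triangle_mesh(v, f, mesh$vertex_hu))
  pv <- attr(out, "parent_vertex")
  out <- .orient_mesh(out)
  attr(out, "parent_vertex") <- pv
  out
}

#' Loop subdivision
#'
#' Standard Loop subdivision: each face splits into four; new edge vertices
#' use the 3/8–1/8 interior stencil, old interior vertices the beta-weighted
#' neighbourhood average, and boundary edges/vertices the 1/2 and
#' 3/4–1/8–1/8 boundary rules, so boundary loops are preserved. Per-vertex
#' HU is carried by linear edge-midpoint averaging.
#'
#' @param mesh a [triangle_mesh()].
#' @param iterations number of rounds (each multiplies the face count by 4).
#' @return A [triangle_mesh()].
#' @export
loop_subdivide <- function(mesh, iterations = 1) {
  stopifnot(inherits(mesh, "triangle_mesh"), iterations >= 0)
  for (it in seq_len(iterations)) mesh <- .loop_once(mesh)
  mesh
}

.loop_once <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  nV <- nrow(v)
  key <- function(a, b) pmin(a, b) * (nV + 1) + pmax(a, b)
  ek <- c(key(f[, 1], f[, 2]), key(f[, 2], f[, 3]), key(f[, 3], f[, 1]))
  uk <- unique(ek)
  eid <- match(ek, uk)                      # edge id per face corner-edge
  nE <- length(uk)
  cnt <- tabulate(eid, nE)
  u <- floor(uk / (nV + 1)); w <- uk - u * (nV + 1)  # edge endpoints

  # opposite vertex of each half-edge: the face's third vertex
  opp <- c(f[, 3], f[, 1], f[, 2])
  opp_sum <- rowsum(v[opp, , drop = FALSE], eid)
  opp_n <- tabulate(eid, nE)

  mid <- matrix(0, nE, 3)
  bnd_e <- cnt == 1L
  mid[bnd_e, ] <- 0.5 * (v[u[bnd_e], , drop = FALSE] +
                         v[w[bnd_e], , drop = FALSE])
  int_e <- !bnd_e
  mid[int_e, ] <- 0.375 * (v[u[int_e], , drop = FALSE] +
                           v[w[int_e], , drop = FALSE]) +
                  0.125 * opp_sum[int_e, , drop = FALSE]

  # updated old vertex positions
  deg <- tabulate(c(u, w), nV)
  nb_sum <- rowsum(rbind(v[w, , drop = FALSE], v[u, , drop = FALSE]),
                   c(u, w), reorder = TRUE)
  full_nb <- matrix(0, nV, 3)
  full_nb[as.integer(rownames(nb_sum)), ] <- nb_sum
  beta <- ifelse(deg > 0,
                 (0.625 - (0.375 + 0.25 * cos(2 * pi / pmax(deg, 1)))^2) /
                   pmax(deg, 1), 0)
  newv <- (1 - deg * beta) * v + beta * full_nb
  # boundary vertices: 3/4 self + 1/8 each boundary neighbour
  bu <- u[bnd_e]; bw <- w[bnd_e]
  if (length(bu) > 0) {
    bvert <- unique(c(bu, bw))
    bn_sum <- rowsum(rbind(v[bw, , drop = FALSE], v[bu, , drop = FALSE]),
                     c(bu, bw), reorder = TRUE)
    bidx <- as.integer(rownames(bn_sum))
    bdeg <- tabulate(c(bu, bw), nV)[bidx]
    ok <- bdeg == 2L                 # regular boundary vertices
    newv[bidx[ok], ] <- 0.75 * v[bidx[ok], , drop = FALSE] +
      0.125 * bn_sum[ok, , drop = FALSE]
    newv[bidx[!ok], ] <- v[bidx[!ok], , drop = FALSE]
  }

  nf <- nrow(f)
  e1 <- eid[seq_len(nf)]                 # edge (v1,v2)
  e2 <- eid[nf + seq_len(nf)]            # edge (v2,v3)
  e3 <- eid[2 * nf + seq_len(nf)]        # edge (v3,v1)
  m1 <- nV + e1; m2 <- nV + e2; m3 <- nV + e3
  faces <- rbind(cbind(f[, 1], m1, m3),
                 cbind(m1, f[, 2], m2),
                 cbind(m3, m2, f[, 3]),
                 cbind(m1, m2, m3))
  hu <- NULL
  if (!is.null(mesh$vertex_hu))
    hu <- c(mesh$vertex_hu, 0.5 * (mesh$vertex_hu[u] + mesh$vertex_hu[w]))
  triangle_mesh(rbind(newv, mid), faces, hu)
}
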
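#' Triangle mesh container
#'
#' Vertices are world coordinates in mm; faces are 1-based triples with
#' consistent winding (outward for closed meshes). An optional per-vertex
#' HU scalar can be carried along.
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 integer matrix of vertex indices.
#' @param vertex_hu optional numeric length n.
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, vertex_hu = NULL) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3) stop("vertices must be an n x 3 matrix")
  if (nrow(faces) > 0) {
    if (min(faces) < 1 || max(faces) > nrow(vertices))
      stop("face indices out of range")
    if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
            faces[, 1] == faces[, 3]))
      stop("faces must reference 3 distinct vertices")
  }
  if (!is.null(vertex_hu) && length(vertex_hu) != nrow(vertices))
    stop("vertex_hu length must match vertex count")
  structure(list(vertices = vertices, faces = faces, vertex_hu = vertex_hu),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat("<triangle_mesh> V=", nrow(x$vertices), " F=", nrow(x$faces),
      if (!is.null(x$vertex_hu)) " (with HU)", "\n", sep = "")
  invisible(x)
}

# undirected edge/face incidence: matrix [u, v, count], u < v
.edge_counts <- function(mesh) {
  .edge_face_count_cpp(mesh$faces, nrow(mesh$vertices))
}

#' Mesh topology counts
#'
#' @param mesh a [triangle_mesh()].
#' @return V - E + F (2 for a closed genus-0 surface, 1 for a disk).
#' @export
euler_characteristic <- function(mesh) {
  nrow(mesh$vertices) - nrow(.edge_counts(mesh)) + nrow(mesh$faces)
}

#' @rdname euler_characteristic
#' @return `is_edge_manifold`: TRUE when every edge borders at most 2 faces.
#' @export
is_edge_manifold <- function(mesh) {
  all(.edge_counts(mesh)[, 3] <= 2L)
}

#' @rdname euler_characteristic
#' @return `is_closed`: TRUE when no edge borders exactly 1 face.
#' @export
is_closed <- function(mesh) {
  ec <- .edge_counts(mesh)
  nrow(ec) > 0 && all(ec[, 3] != 1L)
}

.face_cross <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  u <- vertices[faces[, 2], , drop = FALSE] - a
  v <- vertices[faces[, 3], , drop = FALSE] - a
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

.face_areas <- function(mesh) {
  cr <- .face_cross(mesh$vertices, mesh$faces)
  0.5 * sqrt(rowSums(cr^2))
}

#' Signed volume enclosed by a closed mesh
#'
#' Positive when faces wind outward.
#' @param mesh a closed [triangle_mesh()].
#' @return volume in mm^3.
#' @export
signed_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
      a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

# drop vertices not referenced by any face; returns mesh + old->new map
.drop_unreferenced <- function(mesh) {
  used <- sort(unique(as.vector(mesh$faces)))
  map <- integer(nrow(mesh$vertices))
  map[used] <- seq_along(used)
  mesh2 <- triangle_mesh(mesh$vertices[used, , drop = FALSE],
                         matrix(map[mesh$faces], ncol = 3),
                         mesh$vertex_hu[used])
  attr(mesh2, "parent_vertex") <- used
  mesh2
}

# connected components of faces across shared edges; returns component id
# per face
.face_components <- function(mesh) {
  f <- mesh$faces
  m <- nrow(f)
  if (m == 0) return(integer(0))
  nV <- nrow(mesh$vertices)
  key <- function(a, b) pmin(a, b) * (nV + 1) + pmax(a, b)
  k <- c(key(f[, 1], f[, 2]), key(f[, 2], f[, 3]), key(f[, 3], f[, 1]))
  fid <- rep(seq_len(m), 3)
  o <- order(k)
  k <- k[o]; fid <- fid[o]
  # pair up consecutive equal keys
  same <- which(k[-1] == k[-length(k)])
  if (length(same) == 0) return(seq_len(m))
  g <- igraph::make_empty_graph(n = m, directed = FALSE)
  g <- igraph::add_edges(g, rbind(fid[same], fid[same + 1L]))
  unname(igraph::components(g)$membership)
}

# orient faces consistently; closed meshes get positive signed volume
.orient_mesh <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(mesh)
  mesh$faces <- .orient_faces_cpp(mesh$faces, nrow(mesh$vertices))
  if (is_closed(mesh) && signed_volume(mesh) < 0)
    mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh
}

#' Boundary loops of a triangle mesh
#'
#' Boundary edges (bordering exactly one face) are traversed in the
#' direction induced by the face winding, so each loop runs with the
#' surface on its left.
#'
#' @param mesh a [triangle_mesh()].
#' @return A list of integer vectors, one ordered cyclic vertex sequence
#'   per boundary loop.
#' @export
boundary_loops <- function(mesh) {
  f <- mesh$faces
  nV <- nrow(mesh$vertices)
  key <- function(a, b) pmin(a, b) * (nV + 1) + pmax(a, b)
  from <- c(f[, 1], f[, 2], f[, 3])
  to <- c(f[, 2], f[, 3], f[, 1])
  k <- key(from, to)
  uk <- unique(k)
  idx <- match(k, uk)
  bnd <- tabulate(idx, length(uk))[idx] == 1L
  from <- from[bnd]; to <- to[bnd]
  if (length(from) == 0) return(list())
  nxt <- integer(nV)
  nxt[from] <- to
  visited <- logical(nV)
  loops <- list()
  for (s in from) {
    if (visited[s]) next
    loop <- integer(0)
    v <- s
    repeat {
      loop <- c(loop, v)
      visited[v] <- TRUE
      v <- nxt[v]
      if (v == s) break
      if (v == 0 || visited[v]) {  # open chain: non-manifold boundary
        loop <- NULL
        break
      }
    }
    if (is.null(loop)) stop("boundary edges do not form closed loops ",
                            "(non-manifold boundary)")
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Sample volume HU onto mesh vertices
#'
#' Trilinear interpolation at each vertex's world position; vertices outside
#' the volume receive the volume's minimum HU.
#'
#' @param mesh a [triangle_mesh()].
#' @param vol a [ct_volume()].
#' @return The mesh with `vertex_hu` set.
#' @export
attach_hu <- function(mesh, vol) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(vol, "ct_volume"))
  coords <- sweep(mesh$vertices, 2, vol$origin, "-")
  coords <- sweep(coords, 2, vol$spacing, "/")
  mesh$vertex_hu <- .trilinear_cpp(as.double(vol$voxels), dim(vol$voxels),
                                   coords, min(vol$voxels))
  mesh
}
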
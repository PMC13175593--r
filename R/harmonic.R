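#' Arc-length boundary parametrization onto the unit circle
#'
#' Traverses the single boundary loop from the anchor vertex in the
#' direction induced by the face winding (counterclockwise image). Each
#' boundary vertex receives the angle
#' `theta = 2 * pi * (cumulative arc length from the anchor) / perimeter`
#' and the circle position `z = exp(1i * theta)`, so the anchor itself sits
#' at angle `2 * pi` (equivalently 0). Equal edge lengths therefore produce
#' equal angular steps.
#'
#' @param surface an [open_surface()].
#' @param anchor boundary vertex index to start from; defaults to the
#'   lowest vertex index on the loop (deterministic, documented so outputs
#'   are bit-for-bit reproducible).
#' @return An object of class `boundary_param`: `boundary_vertices`
#'   (ordered, ending at the anchor), `edge_lengths` (mm, edge arriving at
#'   each vertex), `angles` (strictly increasing, last = 2 * pi) and
#'   `circle_positions` (unit-modulus complex).
#' @export
parametrize_boundary <- function(surface, anchor = NULL) {
  stopifnot(inherits(surface, "open_surface"))
  loop <- surface$boundary_loop
  if (is.null(anchor)) anchor <- min(loop)
  pos <- match(anchor, loop)
  if (is.na(pos)) stop("anchor vertex ", anchor, " is not on the boundary loop")
  # order: successor of anchor first, anchor last
  ord <- c(loop[-seq_len(pos)], loop[seq_len(pos)])
  v <- surface$mesh$vertices
  prev <- c(anchor, ord[-length(ord)])
  s <- sqrt(rowSums((v[ord, , drop = FALSE] - v[prev, , drop = FALSE])^2))
  if (any(s == 0)) stop("zero-length boundary edge")
  theta <- 2 * pi * cumsum(s) / sum(s)
  structure(list(boundary_vertices = ord, edge_lengths = s, angles = theta,
                 circle_positions = exp(1i * theta)),
            class = "boundary_param")
}

#' Cotangent Laplacian of a triangle mesh
#'
#' Off-diagonal weights are `w_ij = (cot(a_ij) + cot(b_ij)) / 2` over the
#' angles opposite edge (i, j) in its one or two incident triangles
#' (boundary edges contribute a single cotangent); the diagonal is the
#' negated row sum, so rows sum to zero exactly. Negative weights from
#' obtuse triangles are kept as-is. Stored as a sparse symmetric
#' `dgCMatrix`.
#'
#' @param surface an [open_surface()] or [triangle_mesh()].
#' @return A sparse matrix over all vertices.
#' @export
build_cotangent_laplacian <- function(surface) {
  mesh <- if (inherits(surface, "open_surface")) surface$mesh else surface
  v <- mesh$vertices
  f <- mesh$faces
  n <- nrow(v)
  ii <- jj <- xx <- vector("list", 3)
  for (k in 1:3) {
    a <- f[, k]; b <- f[, k %% 3 + 1]; cc <- f[, (k + 1) %% 3 + 1]
    # angle at vertex a is opposite edge (b, cc)
    u1 <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
    u2 <- v[cc, , drop = FALSE] - v[a, , drop = FALSE]
    l1 <- sqrt(rowSums(u1^2)); l2 <- sqrt(rowSums(u2^2))
    if (any(l1 == 0) || any(l2 == 0))
      stop("triangle with a zero-length edge")
    dot <- rowSums(u1 * u2)
    crs <- sqrt(pmax(rowSums(.cross3(u1, u2)^2), 0))
    if (any(crs == 0)) stop("degenerate (zero-area) triangle")
    cot <- dot / crs
    ii[[k]] <- c(b, cc); jj[[k]] <- c(cc, b); xx[[k]] <- rep(cot / 2, 2)
  }
  L <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n, n))
  Matrix::diag(L) <- 0
  Matrix::diag(L) <- -Matrix::rowSums(L)
  L
}

.cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Solve the Dirichlet-constrained harmonic system
#'
#' Boundary rows of the Laplacian are replaced by identity with the circle
#' positions as right-hand side; interior rows keep the Laplacian with a
#' zero right-hand side. The solution is the discrete harmonic extension of
#' the boundary values (the well-posed form of inverting the constrained
#' Laplacian). One sparse LU factorization solves both coordinates;
#' deterministic, no iterative tolerance.
#'
#' @param L sparse cotangent Laplacian from [build_cotangent_laplacian()].
#' @param bp a [parametrize_boundary()] result from the same surface.
#' @param surface the source [open_surface()] (kept as a reference on the
#'   embedding; optional).
#' @return An object of class `planar_embedding`: `positions` (n x 2, unit
#'   disk), `boundary_vertices`, and `source`.
#' @export
solve_harmonic <- function(L, bp, surface = NULL) {
  n <- nrow(L)
  bidx <- bp$boundary_vertices
  A <- L
  A[bidx, ] <- 0
  A[cbind(bidx, bidx)] <- 1
  rhs <- matrix(0, n, 2)
  rhs[bidx, 1] <- Re(bp$circle_positions)
  rhs[bidx, 2] <- Im(bp$circle_positions)
  sol <- tryCatch(
    as.matrix(Matrix::solve(A, rhs)),
    error = function(e) stop("harmonic system is singular ",
                             "(disconnected interior?): ",
                             conditionMessage(e), call. = FALSE))
  colnames(sol) <- c("u", "v")
  structure(list(positions = sol, boundary_vertices = bidx,
                 source = surface),
            class = "planar_embedding")
}

#' @export
print.planar_embedding <- function(x, ...) {
  r <- sqrt(rowSums(x$positions^2))
  cat("<planar_embedding> ", nrow(x$positions), " vertices, max |z'| = ",
      format(max(r), digits = 6), "\n", sep = "")
  invisible(x)
}

#' Flatten an open surface to the unit disk
#'
#' Composition of [parametrize_boundary()] (anchor = lowest boundary vertex
#' index), [build_cotangent_laplacian()] and [solve_harmonic()]: the disk
#' harmonic map with circle-mapped Dirichlet boundary.
#'
#' @param surface an [open_surface()].
#' @return A `planar_embedding`.
#' @export
flatten_to_disk <- function(surface) {
  bp <- parametrize_boundary(surface)
  L <- build_cotangent_laplacian(surface)
  solve_harmonic(L, bp, surface)
}
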
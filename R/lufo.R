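#' Validate a mesh as a simply connected open surface
#'
#' Checks disk topology: exactly one boundary loop, edge-manifold, and
#' Euler characteristic V - E + F = 1.
#'
#' @param mesh a [triangle_mesh()].
#' @param parent_vertex optional integer map from this mesh's vertices to a
#'   parent mesh's vertex indices (kept for patch bookkeeping).
#' @return An object of class `open_surface` with fields `mesh`,
#'   `boundary_loop` (ordered cyclic vertex indices, surface to the left)
#'   and `parent_vertex`.
#' @export
open_surface <- function(mesh, parent_vertex = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (!is_edge_manifold(mesh))
    stop("surface is not edge-manifold")
  loops <- boundary_loops(mesh)
  if (length(loops) != 1L)
    stop("surface has ", length(loops), " boundary loops; need exactly 1")
  chi <- euler_characteristic(mesh)
  if (chi != 1L)
    stop("surface is not a topological disk (V - E + F = ", chi, ")")
  structure(list(mesh = mesh, boundary_loop = loops[[1]],
                 parent_vertex = parent_vertex),
            class = "open_surface")
}

#' @export
print.open_surface <- function(x, ...) {
  cat("<open_surface> V=", nrow(x$mesh$vertices), " F=", nrow(x$mesh$faces),
      " boundary=", length(x$boundary_loop), " vertices\n", sep = "")
  invisible(x)
}

# split axes for the hemispheric partition: PCA of the vertex cloud.
# AP = principal axis of largest extent; SI = remaining axis most aligned
# with the world axial direction (+z). Signs fixed deterministically
# (SI towards +z; AP towards +y, the anterior direction in RAS-oriented
# volumes).
.lufo_axes <- function(vertices) {
  pc <- prcomp(vertices, center = TRUE, scale. = FALSE)
  ap <- pc$rotation[, 1]
  cand <- pc$rotation[, 2:3, drop = FALSE]
  si <- cand[, which.max(abs(cand[3, ]))]
  if (si[3] < 0) si <- -si
  if (abs(ap[2]) >= 1e-8) { if (ap[2] < 0) ap <- -ap } else if (ap[1] < 0) ap <- -ap
  list(ap = ap, si = si, center = colMeans(vertices))
}

#' Partition a closed skull mesh into four hemispheric patches
#'
#' The four views — lower, upper, frontal, occipital — are cut by two
#' orthogonal centroid planes derived from the principal axes of the vertex
#' cloud: the axis of largest extent separates frontal from occipital and
#' the remaining principal axis most aligned with the volume's axial
#' direction separates upper from lower. Each half is widened by
#' `overlap_fraction` of the extent along its split axis (half the band on
#' each side of the centroid plane), so fractures near a cut remain visible
#' in both adjacent views. A face is kept when all three of its vertices
#' are kept; each patch is then reduced to its largest edge-connected
#' component and validated as an [open_surface()].
#'
#' @param mesh a closed, edge-manifold, genus-0 [triangle_mesh()].
#' @param overlap_fraction fraction of the split-axis extent shared between
#'   adjacent patches, in `[0, 0.5)`. Default 0.1.
#' @return An object of class `lufo_partition`: list with `lower`, `upper`,
#'   `frontal`, `occipital` ([open_surface()] each, vertices carrying
#'   `parent_vertex` indices into `mesh`), `overlap_fraction` and `axes`.
#' @export
partition_lufo <- function(mesh, overlap_fraction = 0.1) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (overlap_fraction < 0 || overlap_fraction >= 0.5)
    stop("overlap_fraction must be in [0, 0.5)")
  if (!is_edge_manifold(mesh)) stop("input mesh is not edge-manifold")
  if (!is_closed(mesh)) stop("input mesh is not closed")
  chi <- euler_characteristic(mesh)
  if (chi != 2L) stop("input mesh is not genus 0 (V - E + F = ", chi, ")")

  ax <- .lufo_axes(mesh$vertices)
  ctr <- sweep(mesh$vertices, 2, ax$center)
  proj_si <- as.vector(ctr %*% ax$si)
  proj_ap <- as.vector(ctr %*% ax$ap)

  take <- function(proj, sign) {
    ext <- diff(range(proj))
    band <- overlap_fraction / 2 * ext
    if (sign > 0) proj >= -band else proj <= band
  }
  sel <- list(lower = take(proj_si, -1), upper = take(proj_si, +1),
              frontal = take(proj_ap, +1), occipital = take(proj_ap, -1))

  patches <- lapply(names(sel), function(nm) {
    keep_v <- sel[[nm]]
    keep_f <- keep_v[mesh$faces[, 1]] & keep_v[mesh$faces[, 2]] &
      keep_v[mesh$faces[, 3]]
    sub <- triangle_mesh(mesh$vertices, mesh$faces[keep_f, , drop = FALSE],
                         mesh$vertex_hu)
    comp <- .face_components(sub)
    sub$faces <- sub$faces[comp == which.max(tabulate(comp)), , drop = FALSE]
    sub <- .drop_unreferenced(sub)
    pv <- attr(sub, "parent_vertex")
    surf <- tryCatch(open_surface(sub, parent_vertex = pv), error = function(e)
      stop("LUFO patch '", nm, "' failed disk-topology validation: ",
           conditionMessage(e), call. = FALSE))
    surf
  })
  names(patches) <- names(sel)
  structure(c(patches, list(overlap_fraction = overlap_fraction, axes = ax)),
            class = "lufo_partition")
}

#' @export
print.lufo_partition <- function(x, ...) {
  cat("<lufo_partition> overlap =", x$overlap_fraction, "\n")
  for (nm in c("lower", "upper", "frontal", "occipital"))
    cat(sprintf("  %-9s V=%d F=%d\n", nm, nrow(x[[nm]]$mesh$vertices),
                nrow(x[[nm]]$mesh$faces)))
  invisible(x)
}
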
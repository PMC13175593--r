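#' Specification of a synthetic head-CT phantom
#'
#' A closed, roughly ellipsoidal bone shell with configurable thickness,
#' bone/tissue/air HU levels, optional thin low-HU defects (fracture slits,
#' suture lines, cylindrical vein channels) and additive Gaussian noise.
#' The shell is centred in the grid; world coordinates put the centre at
#' the origin.
#'
#' @param shape grid dimensions (voxels). Default `c(160, 160, 160)`.
#' @param spacing voxel size mm per axis. Default 1 mm isotropic.
#' @param semi_axes outer ellipsoid semi-axes (mm); must exceed the
#'   thickness everywhere.
#' @param thickness shell thickness in mm: a positive scalar, or a function
#'   of an n x 3 matrix of unit directions returning per-direction
#'   thickness (smoothly varying shells).
#' @param bone_hu,tissue_hu,air_hu HU levels of shell, interior and
#'   exterior. Defaults 1200 / 40 / -1000.
#' @param defects list of defect descriptors; each a list with `type`
#'   (`"fracture_slit"`, `"suture"` or `"vein_channel"`), `hu`, and
#'   geometry: slits/sutures take `normal`, `point` (mm), `width_mm`,
#'   optional `depth_mm` (radial extent from the outer surface; default:
#'   full through), optional `axis_dir` + `ang_radius` (radians) limiting
#'   the angular footprint; vein channels take `point`, `direction`,
#'   `radius_mm`.
#' @param noise_sd additive Gaussian noise SD in HU. Default 20 (typical
#'   head-CT noise).
#' @param seed RNG seed for the noise (volume is bit-identical for a fixed
#'   seed).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(160, 160, 160), spacing = c(1, 1, 1),
                         semi_axes = c(65, 55, 70), thickness = 6,
                         bone_hu = 1200, tissue_hu = 40, air_hu = -1000,
                         defects = list(), noise_sd = 20, seed = 1) {
  tfun <- if (is.function(thickness)) thickness
          else function(dirs) rep(thickness, nrow(dirs))
  probe <- tfun(diag(3))
  if (any(probe <= 0)) stop("thickness must be positive everywhere")
  if (any(semi_axes <= max(probe)))
    stop("semi-axes must exceed the shell thickness")
  for (d in defects) {
    if (is.null(d$type) ||
        !d$type %in% c("fracture_slit", "suture", "vein_channel"))
      stop("unknown defect type: ", d$type %||% "<missing>")
    w <- d$width_mm %||% (2 * (d$radius_mm %||% 1))
    if (w < min(spacing))
      stop("defect width must be at least one voxel at this spacing")
  }
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 semi_axes = as.numeric(semi_axes), thickness = thickness,
                 thickness_fun = tfun, bone_hu = bone_hu,
                 tissue_hu = tissue_hu, air_hu = air_hu, defects = defects,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# evaluate RNG-dependent code under a local seed, restoring global state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic head-CT phantom volume
#'
#' Voxels take `bone_hu` inside the shell (between the outer ellipsoid and
#' the inward-offset inner ellipsoid), `tissue_hu` inside and `air_hu`
#' outside; defect regions overwrite their HU within the shell; Gaussian
#' noise is added last under the spec's seed.
#'
#' @param spec a [phantom_spec()].
#' @return A list: `volume` ([ct_volume()]), `shell_mask`, `defect_masks`
#'   (list of logical arrays), `shell_voxel_count` (pre-defect), `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sh <- spec$shape; sp <- spec$spacing
  origin <- -(sh - 1) / 2 * sp
  xs <- origin[1] + (seq_len(sh[1]) - 1) * sp[1]
  ys <- origin[2] + (seq_len(sh[2]) - 1) * sp[2]
  zs <- origin[3] + (seq_len(sh[3]) - 1) * sp[3]
  X <- array(xs, dim = sh)
  Y <- array(rep(ys, each = sh[1]), dim = sh)
  Z <- array(rep(zs, each = sh[1] * sh[2]), dim = sh)
  a <- spec$semi_axes
  q_out <- (X / a[1])^2 + (Y / a[2])^2 + (Z / a[3])^2
  r <- sqrt(X^2 + Y^2 + Z^2)
  r[r == 0] <- 1e-9
  dirs <- cbind(as.vector(X), as.vector(Y), as.vector(Z)) / as.vector(r)
  tvox <- spec$thickness_fun(dirs)
  ain <- cbind(a[1] - tvox, a[2] - tvox, a[3] - tvox)
  q_in <- array((as.vector(X) / ain[, 1])^2 + (as.vector(Y) / ain[, 2])^2 +
                  (as.vector(Z) / ain[, 3])^2, dim = sh)
  outer_m <- q_out <= 1
  inner_m <- q_in <= 1
  shell <- outer_m & !inner_m
  hu <- array(spec$air_hu, dim = sh)
  hu[inner_m] <- spec$tissue_hu
  hu[shell] <- spec$bone_hu
  shell_count <- sum(shell)

  defect_masks <- list()
  for (i in seq_along(spec$defects)) {
    d <- spec$defects[[i]]
    type <- d$type %||% stop("defect needs a type")
    if (type %in% c("fracture_slit", "suture")) {
      nrm <- d$normal / sqrt(sum(d$normal^2))
      p0 <- d$point %||% c(0, 0, 0)
      dist <- (X - p0[1]) * nrm[1] + (Y - p0[2]) * nrm[2] +
        (Z - p0[3]) * nrm[3]
      m <- shell & abs(dist) <= d$width_mm / 2
      if (!is.null(d$depth_mm)) {
        ad <- pmax(a - d$depth_mm, 1e-6)
        q_d <- (X / ad[1])^2 + (Y / ad[2])^2 + (Z / ad[3])^2
        m <- m & q_d > 1       # only within depth_mm of the outer surface
      }
      if (!is.null(d$axis_dir)) {
        u <- d$axis_dir / sqrt(sum(d$axis_dir^2))
        cosang <- (X * u[1] + Y * u[2] + Z * u[3]) / r
        m <- m & cosang >= cos(d$ang_radius %||% (pi / 4))
      }
    } else if (type == "vein_channel") {
      u <- d$direction / sqrt(sum(d$direction^2))
      p0 <- d$point %||% c(0, 0, 0)
      dx <- X - p0[1]; dy <- Y - p0[2]; dz <- Z - p0[3]
      t <- dx * u[1] + dy * u[2] + dz * u[3]
      d2 <- (dx - t * u[1])^2 + (dy - t * u[2])^2 + (dz - t * u[3])^2
      m <- shell & d2 <= (d$radius_mm)^2
    } else stop("unknown defect type: ", type)
    hu[m] <- d$hu %||% spec$tissue_hu
    defect_masks[[i]] <- m
  }
  if (spec$noise_sd > 0)
    hu <- hu + .with_seed(spec$seed,
                          array(rnorm(length(hu), 0, spec$noise_sd),
                                dim = sh))
  list(volume = ct_volume(hu, spacing = sp, origin = origin),
       shell_mask = shell, defect_masks = defect_masks,
       shell_voxel_count = shell_count, spec = spec)
}

#' Signed distance to the phantom's outer ellipsoid surface
#'
#' Negative inside. Solved per point from the Lagrange stationarity
#' condition of nearest-point projection (exact for spheres), to 1e-6 mm.
#'
#' @param points n x 3 matrix of world coordinates (mm).
#' @param spec a [phantom_spec()].
#' @return Numeric vector of signed distances (mm).
#' @export
analytic_surface_distance <- function(points, spec) {
  points <- matrix(as.numeric(points), ncol = 3)
  a <- spec$semi_axes
  if (max(a) - min(a) < 1e-12) {      # sphere: exact
    return(sqrt(rowSums(points^2)) - a[1])
  }
  vapply(seq_len(nrow(points)), function(i) {
    p <- points[i, ]
    inside <- sum((p / a)^2) <= 1
    g <- function(lam) sum((a * p / (a^2 + lam))^2) - 1
    lo <- if (inside) -min(a)^2 * (1 - 1e-12) else 0
    # bracket upward
    hi <- max(a) * max(sqrt(sum(p^2)), 1)
    while (g(hi) > 0) hi <- hi * 2
    if (sqrt(sum(p^2)) < 1e-12) return(-min(a))
    lam <- uniroot(g, c(lo, hi), tol = 1e-10)$root
    q <- a^2 * p / (a^2 + lam)
    d <- sqrt(sum((p - q)^2))
    if (inside) -d else d
  }, 0)
}
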
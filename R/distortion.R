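# positions: n x 2 or n x 3 matrix from a mesh or planar embedding
.positions_of <- function(x) {
  if (inherits(x, "planar_embedding")) return(cbind(x$positions, 0))
  if (inherits(x, "open_surface")) return(x$mesh$vertices)
  if (inherits(x, "triangle_mesh")) return(x$vertices)
  x <- as.matrix(x)
  if (ncol(x) == 2) cbind(x, 0) else x
}

.faces_of <- function(x, faces) {
  if (!is.null(faces)) return(faces)
  if (inherits(x, "open_surface")) return(x$mesh$faces)
  if (inherits(x, "triangle_mesh")) return(x$faces)
  if (inherits(x, "planar_embedding") && !is.null(x$source))
    return(x$source$mesh$faces)
  stop("faces must be supplied for a bare coordinate matrix")
}

#' Interior angles of mesh facets
#'
#' For each corner the angle between the two emanating edge vectors,
#' `acos(u . v / (|u| |v|))`; the three angles of a facet sum to pi.
#'
#' @param x an [open_surface()], [triangle_mesh()], `planar_embedding`, or
#'   a coordinate matrix.
#' @param faces face matrix when `x` is a bare coordinate matrix.
#' @return m x 3 matrix of angles (radians), columns matching face corners.
#' @export
facet_angles <- function(x, faces = NULL) {
  v <- .positions_of(x)
  f <- .faces_of(x, faces)
  out <- matrix(0, nrow(f), 3)
  for (k in 1:3) {
    a <- f[, k]; b <- f[, k %% 3 + 1]; cc <- f[, (k + 1) %% 3 + 1]
    u1 <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
    u2 <- v[cc, , drop = FALSE] - v[a, , drop = FALSE]
    l1 <- sqrt(rowSums(u1^2)); l2 <- sqrt(rowSums(u2^2))
    if (any(l1 == 0) || any(l2 == 0)) stop("zero-length edge in facet")
    out[, k] <- acos(pmin(1, pmax(-1, rowSums(u1 * u2) / (l1 * l2))))
  }
  out
}

#' Facet areas (and signed areas for planar embeddings)
#'
#' Half the cross-product magnitude of two facet edge vectors. For 2-D
#' input the signed z-component is returned in attribute `signed` for flip
#' detection.
#'
#' @inheritParams facet_angles
#' @return length-m vector of areas; attribute `signed` for planar input.
#' @export
facet_area <- function(x, faces = NULL) {
  v <- .positions_of(x)
  f <- .faces_of(x, faces)
  cr <- .face_cross(v, f)
  area <- 0.5 * sqrt(rowSums(cr^2))
  planar <- inherits(x, "planar_embedding") ||
    (is.matrix(x) && ncol(x) == 2)
  if (planar) attr(area, "signed") <- 0.5 * cr[, 3]
  area
}

#' Per-facet angle distortion of a flattening
#'
#' Mean over the three corners of the absolute angle difference between the
#' 3-D facet and its planar image, in degrees. Zero for conformal
#' (similarity) maps.
#'
#' @param surface the [open_surface()] that was flattened.
#' @param emb its `planar_embedding`.
#' @return Numeric vector, one value (degrees) per facet.
#' @export
angle_distortion <- function(surface, emb) {
  f <- surface$mesh$faces
  if (nrow(emb$positions) != nrow(surface$mesh$vertices))
    stop("embedding and surface have different vertex counts")
  th3 <- facet_angles(surface$mesh)
  th2 <- facet_angles(emb$positions, faces = f)
  rowMeans(abs(th2 - th3)) * 180 / pi
}

#' Per-facet area distortion of a flattening
#'
#' `log(A_image / A_surface)` per facet, base 10 by default so the values
#' read as orders of magnitude. Facets whose image is flipped (signed area
#' against the dominant orientation) are measured on `|A|` and flagged in
#' attribute `flipped`; facets with zero original area are returned as `NA`
#' and counted in attribute `excluded`.
#'
#' @inheritParams angle_distortion
#' @param log_base 10 (default) or `exp(1)`.
#' @return Numeric vector of log area ratios; attributes `flipped`
#'   (logical) and `excluded` (count).
#' @export
area_distortion <- function(surface, emb, log_base = 10) {
  f <- surface$mesh$faces
  a3 <- facet_area(surface$mesh)
  a2 <- facet_area(emb$positions[, 1:2], faces = f)
  signed <- attr(a2, "signed")
  dom <- sign(sum(signed))
  if (dom == 0) dom <- 1
  flipped <- sign(signed) == -dom
  ok <- a3 > 0
  ea <- rep(NA_real_, length(a3))
  ea[ok] <- log(abs(a2[ok]) / a3[ok], base = log_base)
  attr(ea, "flipped") <- flipped
  attr(ea, "excluded") <- sum(!ok)
  ea
}

#' Distortion report for a flattened surface
#'
#' Bundles per-facet angle (degrees) and area (log ratio) distortion with
#' summary statistics and histogram bins.
#'
#' @inheritParams area_distortion
#' @param bins histogram bin count.
#' @return An object of class `distortion_report`: `per_facet` data frame
#'   (`E_theta`, `E_A` raw log ratio, `E_A_norm` with the constant
#'   disk-vs-surface total-area offset removed, `flipped`), `summary`
#'   (mean/median/max per metric),
#'   `hist_angle`, `hist_area`, `n_flipped`, `n_excluded`.
#' @export
distortion_report <- function(surface, emb, log_base = 10, bins = 60) {
  et <- angle_distortion(surface, emb)
  ea <- area_distortion(surface, emb, log_base = log_base)
  flipped <- attr(ea, "flipped")
  # scale-normalized variant: the raw ratio carries the constant offset
  # log(disk area / surface area); removing the total-area ratio leaves
  # pure relative (local) area distortion centred at 0
  a3 <- facet_area(surface$mesh)
  a2 <- abs(facet_area(emb$positions[, 1:2], faces = surface$mesh$faces))
  offset <- log(sum(a2) / sum(a3), base = log_base)
  ean <- ea - offset
  df <- data.frame(facet = seq_along(et), E_theta = et,
                   E_A = as.numeric(ea), E_A_norm = as.numeric(ean),
                   flipped = flipped)
  smry <- data.frame(
    metric = c("angle_deg", "area_log", "area_log_norm"),
    mean = c(mean(et), mean(ea, na.rm = TRUE), mean(ean, na.rm = TRUE)),
    median = c(stats::median(et), stats::median(ea, na.rm = TRUE),
               stats::median(ean, na.rm = TRUE)),
    max = c(max(et), max(abs(ea), na.rm = TRUE),
            max(abs(ean), na.rm = TRUE)))
  structure(list(per_facet = df, summary = smry,
                 hist_angle = graphics::hist(et, breaks = bins, plot = FALSE),
                 hist_area = graphics::hist(ea[!is.na(ea)], breaks = bins,
                                            plot = FALSE),
                 n_flipped = sum(flipped), n_excluded = attr(ea, "excluded"),
                 log_base = log_base),
            class = "distortion_report")
}

#' @export
print.distortion_report <- function(x, ...) {
  cat("<distortion_report> ", nrow(x$per_facet), " facets, ",
      x$n_flipped, " flipped\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a distortion report to CSV + JSON
#'
#' @param report a [distortion_report()].
#' @param csv_path,json_path output paths (either may be NULL to skip).
#' @return invisibly, the paths written.
#' @export
write_distortion_report <- function(report, csv_path = NULL,
                                    json_path = NULL) {
  if (!is.null(csv_path))
    write.csv(report$per_facet, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(summary = report$summary, n_flipped = report$n_flipped,
           n_excluded = report$n_excluded, log_base = report$log_base),
      json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(csv = csv_path, json = json_path))
}

#' Render per-facet values on the flattened disk
#'
#' Facets are rasterized flat-shaded in the unit disk; a vertical colorbar
#' strip is appended on the right with a black tick at the undistorted
#' reference value 0 (when 0 lies in the value range).
#'
#' @param emb a `planar_embedding`.
#' @param values one scalar per facet.
#' @param path optional PNG output path.
#' @param resolution pixels across the disk (default 512).
#' @param palette a palette function such as [grDevices::hcl.colors]
#'   applied to 256 levels.
#' @param faces face matrix override.
#' @return The RGB raster array (res x width x 3), invisibly if written.
#' @export
render_distortion_map <- function(emb, values, path = NULL, resolution = 512,
                                  palette = function(n)
                                    grDevices::hcl.colors(n, "Viridis"),
                                  faces = NULL) {
  f <- .faces_of(emb, faces)
  if (length(values) == 0) {
    img <- matrix(NA_real_, resolution, resolution)
  } else {
    if (length(values) != nrow(f))
      stop("need one value per facet")
    px <- (emb$positions + 1) / 2 * (resolution - 1)
    img <- .rasterize_cpp(px, f, as.double(values), as.integer(resolution),
                          TRUE)
  }
  rng <- if (any(is.finite(values))) range(values, finite = TRUE) else c(0, 1)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  cols <- t(col2rgb(palette(256))) / 255
  level <- function(v) pmin(256, pmax(1, 1 + floor((v - rng[1]) /
                                                     diff(rng) * 255)))
  res <- resolution
  rgb <- array(1, dim = c(res, res + 24, 3))       # white background
  covered <- which(!is.na(img))
  li <- level(img[covered])
  for (ch in 1:3) {
    plane <- matrix(1, res, res)
    plane[covered] <- cols[li, ch]
    rgb[, 1:res, ch] <- plane
  }
  # colorbar strip (columns res+9..res+20), value increasing upward
  barlev <- level(seq(rng[2], rng[1], length.out = res))
  for (ch in 1:3) rgb[, res + 9:20, ch] <- cols[barlev, ch]
  if (rng[1] <= 0 && rng[2] >= 0) {
    zr <- 1 + round((rng[2] - 0) / diff(rng) * (res - 1))
    rgb[max(1, zr - 1):min(res, zr + 1), res + 5:24, ] <- 0
  }
  rgb <- rgb[rev(seq_len(res)), , , drop = FALSE]  # v axis up
  if (!is.null(path)) {
    png::writePNG(rgb, path)
    return(invisible(rgb))
  }
  rgb
}
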
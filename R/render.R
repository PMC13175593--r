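#' Rasterize a flattened layer into a disk image
#'
#' Each image triangle is filled by barycentric interpolation of its vertex
#' values; where triangles overlap (flipped or folded facets) the pixel
#' takes the maximum, so bone signal cannot be hidden. Pixels inside the
#' unit disk not covered by any triangle, and all pixels outside the disk,
#' carry the background sentinel `NA`.
#'
#' @param emb a `planar_embedding`.
#' @param vertex_values one HU value per vertex (e.g. a stack layer row).
#' @param resolution pixels per disk diameter, >= 16. Default 1024.
#' @param faces face matrix override (defaults to the embedding's source).
#' @return An object of class `disk_raster`: `pixels` (resolution x
#'   resolution, row = v axis), `resolution`, `mask` (inside-disk
#'   indicator).
#' @export
rasterize_layer <- function(emb, vertex_values, resolution = 1024,
                            faces = NULL) {
  if (resolution < 16) stop("resolution must be >= 16")
  f <- .faces_of(emb, faces)
  if (length(vertex_values) != nrow(emb$positions))
    stop("need one value per vertex")
  px <- (emb$positions + 1) / 2 * (resolution - 1)
  img <- .rasterize_cpp(px, f, as.double(vertex_values),
                        as.integer(resolution), FALSE)
  ax <- (seq_len(resolution) - 1) / (resolution - 1) * 2 - 1
  mask <- outer(ax^2, ax^2, "+") <= 1   # [y, x]
  img[!mask] <- NA_real_
  structure(list(pixels = img, resolution = resolution, mask = mask),
            class = "disk_raster")
}

#' @export
print.disk_raster <- function(x, ...) {
  cat("<disk_raster> ", x$resolution, "px, ",
      round(100 * mean(!is.na(x$pixels))), "% covered\n", sep = "")
  invisible(x)
}

#' Project a stack of disk rasters
#'
#' Per-pixel maximum (`mip`) or mean (`aip`) over the layers in which the
#' pixel is covered; pixels covered in no layer stay background.
#'
#' @param rasters list of [rasterize_layer()] results with identical
#'   resolution.
#' @param mode `"mip"` or `"aip"`.
#' @return A `disk_raster`.
#' @export
project_stack <- function(rasters, mode = c("mip", "aip")) {
  mode <- match.arg(mode)
  if (length(rasters) == 0) stop("empty raster list")
  res <- vapply(rasters, function(r) r$resolution, 0)
  if (length(unique(res)) != 1) stop("rasters differ in resolution")
  mats <- lapply(rasters, `[[`, "pixels")
  if (mode == "mip") {
    out <- Reduce(function(a, b) {
      m <- pmax(a, b, na.rm = TRUE)
      m[is.na(a) & is.na(b)] <- NA_real_
      m
    }, mats)
  } else {
    sum0 <- Reduce(`+`, lapply(mats, function(m) ifelse(is.na(m), 0, m)))
    cnt <- Reduce(`+`, lapply(mats, function(m) !is.na(m)))
    out <- ifelse(cnt > 0, sum0 / pmax(cnt, 1), NA_real_)
  }
  structure(list(pixels = out, resolution = res[1], mask = rasters[[1]]$mask),
            class = "disk_raster")
}

#' Write a windowed 8-bit grayscale PNG of a disk raster
#'
#' Conventional radiology window/level: HU at `center - width/2` maps to 0,
#' `center + width/2` to 255, linearly in between, clamped outside; ties at
#' .5 round half down (so the window center maps to 127). Background pixels
#' render black.
#'
#' @param raster a `disk_raster`.
#' @param window numeric `c(center, width)` in HU; width > 0. Default bone
#'   window c(500, 2500).
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
save_view <- function(raster, window = c(500, 2500), path) {
  center <- window[1]; width <- window[2]
  if (width <= 0) stop("window width must be > 0")
  byte <- raster$pixels
  byte[] <- ceiling(pmin(1, pmax(0, (as.vector(byte) - (center - width / 2)) /
                                   width)) * 255 - 0.5)   # round half down
  byte[is.na(byte)] <- 0
  img <- byte[rev(seq_len(nrow(byte))), , drop = FALSE] / 255
  png::writePNG(img, path)
  invisible(path)
}
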
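.config_defaults <- function() list(
  input = NULL, format = "auto", out_dir = "skullflat_out",
  hu_threshold = 300, sigma_mm = 0.5, dilate_r = 3, erode_r = 3,
  connectivity = 26, subdivide_iterations = 1, overlap_fraction = 0.1,
  max_depth = 20, resolution = 1024, window_center = 500,
  window_width = 2500, log_base = 10, seed = 1)

#' Pipeline configuration
#'
#' All stage parameters with their defaults; unknown keys are rejected.
#'
#' @param ... named overrides of the defaults: `input`, `format`,
#'   `out_dir`, `hu_threshold` (300 HU), `sigma_mm` (0.5), `dilate_r` /
#'   `erode_r` (3 voxels), `connectivity` (26), `subdivide_iterations` (1),
#'   `overlap_fraction` (0.1), `max_depth` (20 mm), `resolution` (1024 px),
#'   `window_center` / `window_width` (500 / 2500 HU), `log_base` (10),
#'   `seed` (1).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  def <- .config_defaults()
  unknown <- setdiff(names(over), names(def))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  structure(modifyList(def, over), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A [pipeline_config()].
#' @export
load_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
          else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, vals)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm,
                                   paste(x[[nm]], collapse = ", ")))
  invisible(x)
}

.stage <- function(name, log, expr) {
  t0 <- proc.time()[3]
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  dt <- proc.time()[3] - t0
  log(sprintf("[%s] done in %.2f s", name, dt))
  attr(res, "elapsed") <- dt
  res
}

#' Run the full flattening pipeline
#'
#' Load -> preprocess (smooth/threshold, largest component, per-slice
#' close+fill, surface points) -> mesh (critical alpha shape, manifold
#' cleanup, Loop subdivision, HU attachment) -> hemispheric partition ->
#' per-patch disk harmonic flattening -> subsurface stack -> per-layer
#' rasters -> MIP/AIP PNGs -> distortion reports. Writes a JSON manifest
#' listing every artifact with an MD5 hash of the configuration and
#' per-stage timings plus mesh statistics. Partial outputs are retained on
#' stage failure; the failing stage is named in the error.
#'
#' @param config a [pipeline_config()]; `input` and `out_dir` must be set.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the manifest (also written to
#'   `manifest.json`), the mesh, partition, embeddings, stacks and
#'   distortion reports.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$input)) stop("config$input is required")
  if (!file.exists(config$input))
    stop("input path does not exist: ", config$input)
  log <- if (quiet) function(...) invisible() else function(...) message(...)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  tick <- function(x, nm) { timings[[nm]] <<- attr(x, "elapsed"); x }

  vol <- tick(.stage("load", log,
                     load_volume(config$input, config$format)), "load")
  solid <- tick(.stage("preprocess", log, {
    m <- smooth_and_threshold(vol, config$sigma_mm, config$hu_threshold)
    m <- largest_component(m, config$connectivity)
    axial_close_and_fill(m, config$dilate_r, config$erode_r)
  }), "preprocess")
  mesh <- tick(.stage("mesh", log, {
    pts <- extract_surface_points(solid)
    log(sprintf("[mesh] %d surface points", nrow(pts$points)))
    m <- alpha_shape_critical(pts)
    m <- cleanup_manifold(m)
    m <- loop_subdivide(m, config$subdivide_iterations)
    attach_hu(m, vol)
  }), "mesh")
  part <- tick(.stage("partition", log,
                      partition_lufo(mesh, config$overlap_fraction)),
               "partition")

  views <- c("lower", "upper", "frontal", "occipital")
  artifacts <- character(0)
  embeddings <- stacks <- reports <- setNames(vector("list", 4), views)
  stats <- list()
  for (vn in views) {
    surf <- part[[vn]]
    emb <- .stage(paste0("flatten_", vn), log, flatten_to_disk(surf))
    thick <- estimate_thickness(surf, vol, config$hu_threshold,
                                config$max_depth)
    stack <- .stage(paste0("stack_", vn), log,
                    build_stack(surf, vol, thick))
    rasters <- .stage(paste0("raster_", vn), log,
                      lapply(seq_along(stack$depths), function(k)
                        rasterize_layer(emb, stack$layer_hu[k, ],
                                        config$resolution)))
    win <- c(config$window_center, config$window_width)
    for (mode in c("mip", "aip")) {
      f <- file.path(out, sprintf("%s_%s.png", vn, mode))
      save_view(project_stack(rasters, mode), win, f)
      artifacts <- c(artifacts, f)
    }
    rep <- distortion_report(surf, emb, log_base = config$log_base)
    fcsv <- file.path(out, sprintf("%s_distortion.csv", vn))
    fjson <- file.path(out, sprintf("%s_distortion.json", vn))
    write_distortion_report(rep, fcsv, fjson)
    fmap <- file.path(out, sprintf("%s_angle_map.png", vn))
    render_distortion_map(emb, rep$per_facet$E_theta, fmap,
                          resolution = min(512, config$resolution))
    artifacts <- c(artifacts, fcsv, fjson, fmap)
    m <- surf$mesh
    stats[[vn]] <- list(
      V = nrow(m$vertices), E = nrow(.edge_counts(m)), F = nrow(m$faces),
      boundary_vertices = length(surf$boundary_loop),
      boundary_length_mm = sum(parametrize_boundary(surf)$edge_lengths),
      n_layers = length(stack$depths), thickness_mm = as.numeric(thick),
      flipped_facets = rep$n_flipped)
    log(sprintf("[%s] V=%d F=%d layers=%d flipped=%d", vn, stats[[vn]]$V,
                stats[[vn]]$F, stats[[vn]]$n_layers, rep$n_flipped))
    embeddings[[vn]] <- emb; stacks[[vn]] <- stack; reports[[vn]] <- rep
  }

  cfgjson <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                              null = "null")
  cfgfile <- file.path(out, "config.json")
  writeLines(cfgjson, cfgfile)
  manifest <- list(
    config_md5 = unname(tools::md5sum(cfgfile)),
    artifacts = basename(artifacts),
    mesh_stats = stats,
    timings_s = timings)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, mesh = mesh, partition = part,
                 embeddings = embeddings, stacks = stacks,
                 reports = reports, volume = vol))
}
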
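# ASCII OBJ and PLY mesh I/O. Per-vertex HU travels as a PLY "quality"
# property or as an OBJ sidecar CSV (<file>.hu.csv).

#' Read and write triangle meshes (ASCII OBJ / PLY)
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path; `write_obj` stores `vertex_hu` (if present) in a
#'   sidecar `<path>.hu.csv`, `write_ply` as a `quality` vertex property.
#' @return `path` invisibly for writers; a [triangle_mesh()] for readers.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  if (!is.null(mesh$vertex_hu))
    write.csv(data.frame(vertex = seq_len(nrow(mesh$vertices)),
                         hu = mesh$vertex_hu),
              paste0(path, ".hu.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_obj
#' @export
read_obj <- function(path) {
  ln <- readLines(path)
  vl <- ln[startsWith(ln, "v ")]
  fl <- ln[startsWith(ln, "f ")]
  verts <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                                 function(x) as.numeric(x[1:3])))
  faces <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fl)), "\\s+"),
                                 function(x) as.integer(sub("/.*", "", x[1:3]))))
  hu <- NULL
  sc <- paste0(path, ".hu.csv")
  if (file.exists(sc)) hu <- utils::read.csv(sc)$hu
  triangle_mesh(verts, faces, hu)
}

#' @rdname write_obj
#' @export
write_ply <- function(mesh, path) {
  n <- nrow(mesh$vertices); m <- nrow(mesh$faces)
  has_hu <- !is.null(mesh$vertex_hu)
  hdr <- c("ply", "format ascii 1.0",
           paste("element vertex", n),
           "property float x", "property float y", "property float z",
           if (has_hu) "property float quality",
           paste("element face", m),
           "property list uchar int vertex_indices",
           "end_header")
  vfmt <- if (has_hu)
    sprintf("%.9g %.9g %.9g %.9g", mesh$vertices[, 1], mesh$vertices[, 2],
            mesh$vertices[, 3], mesh$vertex_hu)
  else
    sprintf("%.9g %.9g %.9g", mesh$vertices[, 1], mesh$vertices[, 2],
            mesh$vertices[, 3])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, vfmt,
               sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                       mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L)), con)
  invisible(path)
}

#' @rdname write_obj
#' @export
read_ply <- function(path) {
  ln <- readLines(path)
  if (ln[1] != "ply" || !any(grepl("^format ascii", ln)))
    stop("only ASCII PLY is supported")
  endh <- match("end_header", ln)
  hdr <- ln[seq_len(endh)]
  n <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr,
                                                  value = TRUE)))
  m <- as.integer(sub("element face ", "", grep("^element face", hdr,
                                                value = TRUE)))
  vprops <- sub(".* ", "", grep("^property (float|double)", hdr, value = TRUE))
  vl <- ln[endh + seq_len(n)]
  vm <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), as.numeric))
  fl <- ln[endh + n + seq_len(m)]
  fm <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), as.integer))
  if (any(fm[, 1] != 3L)) stop("non-triangular PLY faces are not supported")
  hu <- if ("quality" %in% vprops) vm[, match("quality", vprops)]
  triangle_mesh(vm[, 1:3, drop = FALSE], fm[, 2:4, drop = FALSE] + 1L, hu)
}

#' Export a planar embedding
#'
#' Writes the flattened coordinates as a z = 0 OBJ or as a CSV of
#' `vertex, u, v`.
#'
#' @param emb a [planar_embedding][flatten_to_disk()].
#' @param path output file; extension `.obj` or `.csv`.
#' @param faces face matrix to use for OBJ output (defaults to the source
#'   surface's faces).
#' @return `path`, invisibly.
#' @export
write_embedding <- function(emb, path, faces = NULL) {
  if (grepl("\\.csv$", path)) {
    write.csv(data.frame(vertex = seq_len(nrow(emb$positions)),
                         u = emb$positions[, 1], v = emb$positions[, 2]),
              path, row.names = FALSE)
  } else {
    if (is.null(faces)) faces <- emb$source$mesh$faces
    write_obj(triangle_mesh(cbind(emb$positions, 0), faces), path)
  }
  invisible(path)
}
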
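# Minimal single-series CT DICOM reader: uncompressed little-endian
# explicit or implicit VR only. Reads the handful of tags needed to
# assemble an HU volume with correct spacing; anything fancier (compressed
# transfer syntaxes, sequences of undefined length, multi-frame) is
# rejected with an explicit error.

.dcm_tag <- function(group, elem) sprintf("%04x,%04x", group, elem)

.dcm_uint16 <- function(raw, off) {
  as.integer(raw[off + 1]) + 256L * as.integer(raw[off + 2])
}
.dcm_uint32 <- function(raw, off) {
  sum(as.double(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
}

.dcm_parse_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file (missing DICM marker): ", path)
  tags <- list()
  pos <- 132L            # 0-based offset just past preamble+DICM
  explicit <- TRUE       # file meta group is always explicit LE
  ts <- NULL
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  n <- length(raw)
  while (pos + 8 <= n) {
    group <- .dcm_uint16(raw, pos); elem <- .dcm_uint16(raw, pos + 2L)
    if (group != 2L && is.null(ts)) {
      # leaving file meta: switch per the declared transfer syntax
      ts <- tags[["0002,0010"]] %||% "1.2.840.10008.1.2.1"
      if (ts == "1.2.840.10008.1.2") explicit <- FALSE
      else if (ts != "1.2.840.10008.1.2.1")
        stop("unsupported (compressed?) transfer syntax: ", ts)
    }
    if (explicit || group == 2L) {
      vr <- rawToChar(raw[pos + 5:6])
      if (vr %in% long_vrs) {
        len <- .dcm_uint32(raw, pos + 8L); hdr <- 12L
      } else {
        len <- .dcm_uint16(raw, pos + 6L); hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- .dcm_uint32(raw, pos + 4L); hdr <- 8L
    }
    if (len == 4294967295)  # undefined length (sequences) unsupported
      stop("undefined-length element ", .dcm_tag(group, elem),
           " not supported by the minimal DICOM reader")
    body <- pos + hdr
    if (body + len > n) break
    key <- .dcm_tag(group, elem)
    if (is.na(vr))          # implicit VR: known binary tags, else string
      vr <- if (key %in% c("0028,0010", "0028,0011", "0028,0100",
                           "0028,0101", "0028,0102", "0028,0103")) "US"
            else "??"
    if (key == "7fe0,0010") {
      tags[[key]] <- raw[(body + 1):(body + len)]
    } else if (len > 0 && !vr %in% c("SQ", "OB", "OW", "UN")) {
      val <- raw[(body + 1):(body + len)]
      if (vr %in% c("US", "SS")) {
        tags[[key]] <- readBin(val, "integer", n = len %/% 2, size = 2,
                               signed = (vr == "SS"), endian = "little")
      } else if (vr == "UL") {
        tags[[key]] <- readBin(val, "integer", n = len %/% 4, size = 4,
                               endian = "little")
      } else {
        s <- tryCatch(rawToChar(val[val != as.raw(0)]),
                      error = function(e) NULL)
        if (!is.null(s) && validUTF8(s)) tags[[key]] <- sub(" +$", "", s)
      }
    }
    pos <- body + len
  }
  tags
}

.dcm_num <- function(tags, key, what, default = NULL) {
  v <- tags[[key]]
  if (is.null(v)) {
    if (!is.null(default)) return(default)
    stop("DICOM series is missing required field ", what, " (", key, ")")
  }
  if (is.character(v)) as.numeric(strsplit(v, "\\\\")[[1]]) else as.numeric(v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a single-series DICOM directory as a CT volume
#'
#' Supports uncompressed little-endian explicit/implicit VR CT series.
#' Stored values are rescaled to HU, slices are sorted by their axial
#' position, and uniform slice spacing is required.
#'
#' @param dir directory containing the `.dcm` files of exactly one series.
#' @return A [ct_volume()].
#' @export
read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) stop("no files in DICOM directory: ", dir)
  slices <- lapply(files, .dcm_parse_file)
  uids <- vapply(slices, function(t) t[["0020,000e"]] %||% "", "")
  if (length(unique(uids)) > 1)
    stop("directory holds ", length(unique(uids)),
         " DICOM series; expected a single series")
  rows <- vapply(slices, function(t) .dcm_num(t, "0028,0010", "Rows"), 0)
  cols <- vapply(slices, function(t) .dcm_num(t, "0028,0011", "Columns"), 0)
  if (length(unique(rows)) != 1 || length(unique(cols)) != 1)
    stop("inconsistent slice dimensions across the series")
  ps <- .dcm_num(slices[[1]], "0028,0030", "PixelSpacing")  # row, col (mm)
  if (length(ps) != 2 || any(!is.finite(ps)) || any(ps <= 0))
    stop("DICOM series is missing required field PixelSpacing (0028,0030)")
  ipp <- lapply(slices, function(t)
    .dcm_num(t, "0020,0032", "ImagePositionPatient", default = c(0, 0, NA)))
  zs <- vapply(ipp, function(p) p[3], 0)
  if (anyNA(zs)) {
    if (length(slices) > 1)
      stop("DICOM series is missing required field ImagePositionPatient ",
           "(0020,0032) needed to order slices")
    zs <- 0
  }
  ord <- order(zs)
  slices <- slices[ord]; ipp <- ipp[ord]; zs <- zs[ord]
  if (length(zs) > 1) {
    dz <- diff(zs)
    if (any(dz <= 0) || diff(range(dz)) > 1e-3 * mean(dz) + 1e-6)
      stop("non-uniform or duplicated slice positions in DICOM series")
    sz <- mean(dz)
  } else {
    sz <- .dcm_num(slices[[1]], "0018,0050", "SliceThickness", default = NA)
    if (!is.finite(sz) || sz <= 0)
      stop("DICOM series is missing required field SliceThickness (0018,0050)")
  }
  nr <- rows[1]; nc <- cols[1]
  vol <- array(0, dim = c(nc, nr, length(slices)))
  for (k in seq_along(slices)) {
    t <- slices[[k]]
    bits <- .dcm_num(t, "0028,0100", "BitsAllocated", default = 16)
    if (bits != 16) stop("only 16-bit DICOM pixel data is supported")
    signed <- .dcm_num(t, "0028,0103", "PixelRepresentation", default = 0) == 1
    pd <- t[["7fe0,0010"]]
    if (is.null(pd))
      stop("DICOM slice is missing PixelData (7fe0,0010)")
    px <- readBin(pd, "integer", n = nr * nc, size = 2, signed = signed,
                  endian = "little")
    slope <- .dcm_num(t, "0028,1053", "RescaleSlope", default = 1)
    inter <- .dcm_num(t, "0028,1052", "RescaleIntercept", default = 0)
    # stored row-major: rows of the image along the second world axis
    vol[, , k] <- matrix(px * slope + inter, nrow = nc, ncol = nr)
  }
  origin <- ipp[[1]]
  if (anyNA(origin)) origin <- c(0, 0, 0)
  ct_volume(vol, spacing = c(ps[2], ps[1], sz), origin = origin)
}
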
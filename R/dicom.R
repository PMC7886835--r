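# Minimal DICOM CT-series reader: explicit-VR little-endian single-frame
# slices, the handful of tags a voxel-phantom build needs. Slices are
# sorted by slice position; non-uniform inter-slice spacing (e.g. a missing
# slice) is a format error.

.dcm_read_file <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 136 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  pos <- 133L
  u16 <- function(i) as.integer(raw[i]) + 256L * as.integer(raw[i + 1L])
  u32 <- function(i) u16(i) + 65536 * u16(i + 2L)
  tags <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 8L <= length(raw)) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% long_vrs) {
      len <- u32(pos + 8L); vstart <- pos + 12L
    } else {
      len <- u16(pos + 6L); vstart <- pos + 8L
    }
    if (len == 4294967295) stop("undefined-length element unsupported")
    key <- sprintf("%04x,%04x", group, elem)
    val <- raw[vstart:(vstart + len - 1L)]
    if (vr %in% c("DS", "IS", "CS", "LO", "UI", "SH", "PN", "DA", "TM", "AS"))
      tags[[key]] <- trimws(rawToChar(val))
    else if (vr == "US")
      tags[[key]] <- u16(vstart)
    else tags[[key]] <- val
    pos <- vstart + len
    if (key == "7fe0,0010") break
  }
  tags
}

.dcm_numeric <- function(s) as.numeric(strsplit(s, "\\\\")[[1]])

.read_dicom_series <- function(dir) {
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE,
                      ignore.case = TRUE)
  if (length(files) < 2) stop("need at least two DICOM slices in ", dir)
  slices <- lapply(files, .dcm_read_file)
  need <- c("0028,0010", "0028,0011", "0028,0030", "0020,0032", "7fe0,0010")
  for (s in slices) for (t in need)
    if (is.null(s[[t]])) stop("DICOM slice missing required tag ", t)
  zpos <- vapply(slices, function(s) .dcm_numeric(s[["0020,0032"]])[3],
                 numeric(1))
  ord <- order(zpos)
  slices <- slices[ord]; zpos <- zpos[ord]
  dz <- diff(zpos)
  if (length(unique(round(dz, 4))) != 1 || any(dz <= 0))
    stop("inconsistent slice spacing (missing or duplicated slice?)")
  rows <- slices[[1]][["0028,0010"]]; cols <- slices[[1]][["0028,0011"]]
  ps <- .dcm_numeric(slices[[1]][["0028,0030"]])
  slope <- if (!is.null(slices[[1]][["0028,1053"]]))
    as.numeric(slices[[1]][["0028,1053"]]) else 1
  inter <- if (!is.null(slices[[1]][["0028,1052"]]))
    as.numeric(slices[[1]][["0028,1052"]]) else 0
  hu <- array(0, c(cols, rows, length(slices)))
  for (k in seq_along(slices)) {
    px <- slices[[k]][["7fe0,0010"]]
    if (length(px) != 2 * rows * cols) stop("pixel data size mismatch")
    v <- readBin(px, "integer", n = rows * cols, size = 2, signed = FALSE,
                 endian = "little")
    hu[, , k] <- slope * v + inter
  }
  ipp <- .dcm_numeric(slices[[1]][["0020,0032"]])
  spacing <- c(ps[2], ps[1], dz[1])           # PixelSpacing is row\col
  # IPP addresses the first voxel center; container origin is the corner
  list(hu = hu, spacing = spacing, origin = ipp - spacing / 2)
}
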
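# Minimal DICOM codec: single-frame MR slices, explicit VR little endian.
# Covers the tags needed for geometry (position/orientation/spacing),
# rescale slope/intercept and TR/TE. Not a general DICOM implementation.

.dcmU16 <- function(x) as.integer(x) %*% c(1L, 256L) |> as.integer()
.dcmU32 <- function(x) sum(as.numeric(x) * c(1, 256, 65536, 16777216))

.dcmRawU16 <- function(v) {
  v <- as.integer(v)
  as.raw(c(v %% 256L, v %/% 256L))[c(matrix(seq_len(2 * length(v)),
                                            nrow = 2, byrow = TRUE))]
}

# one explicit-VR element as a raw vector
.dcmElement <- function(group, elem, vr, value) {
  if (vr %in% c("UI", "DS", "IS", "CS", "LO", "SH")) {
    bytes <- charToRaw(value)
    if (length(bytes) %% 2L == 1L)
      bytes <- c(bytes, if (vr == "UI") as.raw(0) else charToRaw(" "))
  } else if (vr == "US") {
    bytes <- .dcmRawU16(value)
  } else if (vr == "UL") {
    v <- as.numeric(value)
    bytes <- as.raw(c(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256,
                      (v %/% 16777216) %% 256))
  } else if (vr == "OW") {
    bytes <- value # already raw
  } else stop("unsupported VR: ", vr)
  head <- c(.dcmRawU16(group), .dcmRawU16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "UT", "UN")) {
    n <- length(bytes)
    len <- as.raw(c(0, 0, n %% 256, (n %/% 256) %% 256,
                    (n %/% 65536) %% 256, (n %/% 16777216) %% 256))
  } else {
    len <- .dcmRawU16(length(bytes))
  }
  c(head, len, bytes)
}

.dcmDS <- function(x) paste(formatC(x, format = "g", digits = 10),
                            collapse = "\\")

#' Write a volume as a single-frame DICOM series
#'
#' One explicit-VR little-endian file per slice, with geometry
#' (ImagePositionPatient, ImageOrientationPatient, PixelSpacing,
#' SliceThickness), rescale slope/intercept spanning the volume's value
#' range, and TR/TE when present in the metadata.
#'
#' @param volume a \code{\linkS4class{Volume3D}}.
#' @param dir output directory (created if needed).
#' @param seriesUID series instance UID (one per call by default).
#' @return The directory, invisibly.
#' @export
writeDicomSeries <- function(volume, dir,
                             seriesUID = paste0("2.25.",
                               paste(sample.int(9, 12, replace = TRUE) - 1,
                                     collapse = ""))) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(volume@values)
  vals <- volume@values
  vals[is.na(vals)] <- 0
  lo <- min(vals); hi <- max(vals)
  slope <- if (hi > lo) (hi - lo) / 65000 else 1
  intercept <- lo
  raws <- round((vals - intercept) / slope)
  tsuid <- "1.2.840.10008.1.2.1"
  meta <- c(
    .dcmElement(0x0002, 0x0010, "UI", tsuid))
  metaLen <- .dcmElement(0x0002, 0x0000, "UL", length(meta))
  iop <- c(volume@direction[, 1], volume@direction[, 2])
  for (k in seq_len(d[3])) {
    ipp <- volume@origin + volume@direction[, 3] * volume@spacing[3] * (k - 1)
    slice <- raws[, , k]
    slice[slice > 32767] <- slice[slice > 32767] - 65536
    px <- writeBin(as.integer(slice), raw(), size = 2, endian = "little")
    ds <- c(
      .dcmElement(0x0008, 0x0060, "CS", "MR"),
      .dcmElement(0x0018, 0x0050, "DS", .dcmDS(volume@spacing[3])),
      if (!is.null(volume@meta$TR_ms))
        .dcmElement(0x0018, 0x0080, "DS", .dcmDS(volume@meta$TR_ms)),
      if (!is.null(volume@meta$TE_ms))
        .dcmElement(0x0018, 0x0081, "DS", .dcmDS(volume@meta$TE_ms)),
      .dcmElement(0x0020, 0x000E, "UI", seriesUID),
      .dcmElement(0x0020, 0x0013, "IS", as.character(k)),
      .dcmElement(0x0020, 0x0032, "DS", .dcmDS(ipp)),
      .dcmElement(0x0020, 0x0037, "DS", .dcmDS(iop)),
      .dcmElement(0x0028, 0x0002, "US", 1L),
      .dcmElement(0x0028, 0x0010, "US", d[2]),        # Rows (j)
      .dcmElement(0x0028, 0x0011, "US", d[1]),        # Columns (i)
      .dcmElement(0x0028, 0x0030, "DS",
                  .dcmDS(c(volume@spacing[2], volume@spacing[1]))),
      .dcmElement(0x0028, 0x0100, "US", 16L),
      .dcmElement(0x0028, 0x0101, "US", 16L),
      .dcmElement(0x0028, 0x0102, "US", 15L),
      .dcmElement(0x0028, 0x0103, "US", 0L),
      .dcmElement(0x0028, 0x1052, "DS", .dcmDS(intercept)),
      .dcmElement(0x0028, 0x1053, "DS", .dcmDS(slope)),
      .dcmElement(0x7FE0, 0x0010, "OW", px))
    con <- file(file.path(dir, sprintf("slice%03d.dcm", k)), "wb")
    writeBin(c(raw(128), charToRaw("DICM"), metaLen, meta, ds), con)
    close(con)
  }
  invisible(dir)
}

# parse one explicit-VR little-endian DICOM file into a tag list
.dcmParse <- function(path) {
  r <- readBin(path, raw(), file.info(path)$size)
  if (length(r) < 140 || rawToChar(r[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM marker): ", path)
  pos <- 133L
  tags <- list()
  knownShort <- c("UI", "DS", "IS", "CS", "US", "UL", "LO", "SH", "AE", "AS",
                  "AT", "DA", "DT", "FL", "FD", "PN", "SL", "SS", "ST", "TM")
  known4 <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7L <= length(r)) {
    group <- .dcmU16(r[pos:(pos + 1L)])
    elem <- .dcmU16(r[(pos + 2L):(pos + 3L)])
    vr <- rawToChar(r[(pos + 4L):(pos + 5L)])
    if (vr %in% known4) {
      len <- .dcmU32(r[(pos + 8L):(pos + 11L)])
      pos <- pos + 12L
    } else if (vr %in% knownShort) {
      len <- .dcmU16(r[(pos + 6L):(pos + 7L)])
      pos <- pos + 8L
    } else {
      stop(sprintf("unsupported or implicit VR '%s' at tag (%04X,%04X) in %s",
                   vr, group, elem, path))
    }
    if (len == 4294967295) stop("undefined-length elements unsupported: ", path)
    value <- if (len > 0) r[pos:(pos + len - 1L)] else raw()
    pos <- pos + as.integer(len)
    key <- sprintf("%04X%04X", group, elem)
    tags[[key]] <- list(vr = vr, value = value)
  }
  tags
}

# decode a string value, dropping trailing padding (space or NUL bytes)
.dcmTrim <- function(bytes) {
  keep <- which(!(bytes %in% as.raw(c(0L, 32L))))
  if (!length(keep)) return("")
  rawToChar(bytes[seq_len(max(keep))])
}

.dcmGet <- function(tags, key, what = c("string", "numbers", "u16", "raw"),
                    required = FALSE, path = "") {
  what <- match.arg(what)
  el <- tags[[key]]
  if (is.null(el)) {
    if (required) stop(sprintf("missing required DICOM tag %s in %s", key, path))
    return(NULL)
  }
  switch(what,
    string = .dcmTrim(el$value),
    numbers = as.numeric(strsplit(.dcmTrim(el$value), "\\\\")[[1]]),
    u16 = .dcmU16(el$value[1:2]),
    raw = el$value)
}

#' Read a single-series DICOM directory as a 3D volume
#'
#' Slices are sorted by the projection of ImagePositionPatient onto the
#' slice normal (so shuffled file order on disk gives the same volume);
#' rescale slope/intercept are applied; spacing, origin and direction come
#' from the headers, TR/TE are captured when present. Files from more than
#' one series are rejected.
#'
#' @param path directory containing the slice files.
#' @return A \code{\linkS4class{Volume3D}}.
#' @export
readDicomSeries <- function(path) {
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no files in ", path)
  parsed <- lapply(files, .dcmParse)
  uids <- vapply(seq_along(parsed), function(q)
    .dcmGet(parsed[[q]], "0020000E", "string", required = TRUE,
            path = files[q]), "")
  if (length(unique(uids)) != 1L)
    stop("directory mixes multiple series UIDs: ",
         paste(unique(uids), collapse = ", "))
  first <- parsed[[1]]
  iop <- .dcmGet(first, "00200037", "numbers", required = TRUE,
                 path = files[1])
  ps <- .dcmGet(first, "00280030", "numbers", required = TRUE,
                path = files[1])
  rows <- .dcmGet(first, "00280010", "u16", required = TRUE, path = files[1])
  cols <- .dcmGet(first, "00280011", "u16", required = TRUE, path = files[1])
  rdir <- iop[1:3]; cdir <- iop[4:6]
  normal <- c(rdir[2] * cdir[3] - rdir[3] * cdir[2],
              rdir[3] * cdir[1] - rdir[1] * cdir[3],
              rdir[1] * cdir[2] - rdir[2] * cdir[1])
  ipps <- t(vapply(seq_along(parsed), function(q)
    .dcmGet(parsed[[q]], "00200032", "numbers", required = TRUE,
            path = files[q]), numeric(3)))
  ord <- order(ipps %*% normal)
  parsed <- parsed[ord]
  ipps <- ipps[ord, , drop = FALSE]
  nz <- length(parsed)
  zsp <- if (nz > 1) {
    proj <- as.numeric(ipps %*% normal)
    mean(diff(proj))
  } else {
    st <- .dcmGet(first, "00180050", "numbers")
    if (is.null(st)) 1 else st[1]
  }
  values <- array(NA_real_, c(cols, rows, nz))
  for (q in seq_len(nz)) {
    tg <- parsed[[q]]
    slope <- .dcmGet(tg, "00281053", "numbers") %||% 1
    icpt <- .dcmGet(tg, "00281052", "numbers") %||% 0
    px <- .dcmGet(tg, "7FE00010", "raw", required = TRUE)
    v <- readBin(px, "integer", n = rows * cols, size = 2, signed = FALSE,
                 endian = "little")
    values[, , q] <- v * slope + icpt
  }
  meta <- list(seriesUID = uids[1], source = path)
  tr <- .dcmGet(first, "00180080", "numbers")
  te <- .dcmGet(first, "00180081", "numbers")
  if (!is.null(tr)) meta$TR_ms <- tr[1]
  if (!is.null(te)) meta$TE_ms <- te[1]
  Volume3D(values, spacing = c(ps[2], ps[1], abs(zsp)), origin = ipps[1, ],
           direction = cbind(rdir, cdir, normal * sign(zsp)), meta = meta)
}
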
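# Volume, mask and seed I/O. NIfTI goes through RNifti; MetaImage
# (.mha / .mhd + .raw) is read and written directly (uncompressed,
# little-endian), since the format is a plain text header plus a raw block.

fileExt <- function(path) {
  p <- tolower(path)
  if (grepl("\\.nii\\.gz$", p)) return("nii.gz")
  sub(".*\\.", "", p)
}

metaTypes <- list(
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT  = list(what = "double",  size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "double",  size = 8L, signed = TRUE))

readMetaImage <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  hdr <- list()
  pos <- 0L
  dataStart <- NA_integer_
  nl <- which(raw == as.raw(10L))
  for (end in c(nl, length(raw))) {
    if (end <= pos) next
    line <- rawToChar(raw[(pos + 1L):end])
    pos <- end
    line <- sub("\r?\n?$", "", line)
    m <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(m) < 3)
      stopfmt("malformed MetaImage header line in %s: '%s'", path, line)
    hdr[[m[2]]] <- m[3]
    if (m[2] == "ElementDataFile") { dataStart <- pos + 1L; break }
  }
  if (is.na(dataStart))
    stopfmt("MetaImage header of %s has no ElementDataFile", path)
  if (identical(hdr$CompressedData, "True"))
    stopfmt("compressed MetaImage not supported: %s", path)
  if (identical(hdr$BinaryDataByteOrderMSB, "True"))
    stopfmt("big-endian MetaImage not supported: %s", path)
  nd <- as.integer(hdr$NDims)
  if (!identical(nd, 3L))
    stopfmt("%s is %d-dimensional; expected a 3D image", path, nd)
  d <- as.integer(strsplit(trimws(hdr$DimSize), "\\s+")[[1]])
  if (length(d) != 3L) stopfmt("bad DimSize in %s", path)
  if (is.null(hdr$ElementSpacing))
    stopfmt("MetaImage %s lacks ElementSpacing", path)
  sp <- as.numeric(strsplit(trimws(hdr$ElementSpacing), "\\s+")[[1]])
  orig <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(trimws(hdr$Offset), "\\s+")[[1]]) else c(0, 0, 0)
  ty <- metaTypes[[hdr$ElementType]]
  if (is.null(ty)) stopfmt("unsupported ElementType %s", hdr$ElementType)
  n <- prod(d)
  dataRaw <- if (identical(hdr$ElementDataFile, "LOCAL")) {
    raw[dataStart:length(raw)]
  } else {
    rawPath <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(rawPath)) stopfmt("missing raw file %s", rawPath)
    readBin(rawPath, "raw", file.size(rawPath))
  }
  if (length(dataRaw) < n * ty$size)
    stopfmt("truncated MetaImage data in %s", path)
  vals <- readBin(dataRaw, ty$what, n = n, size = ty$size,
                  signed = ty$signed, endian = "little")
  list(intensities = array(as.double(vals), d), spacing = sp, origin = orig)
}

writeMetaImage <- function(a, sp, orig, path, elementType) {
  ext <- fileExt(path)
  ty <- metaTypes[[elementType]]
  local <- ext == "mha"
  dataFile <- if (local) "LOCAL" else paste0(
    sub("\\.mhd$", "", basename(path), ignore.case = TRUE), ".raw")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("DimSize =", paste(dim(a), collapse = " ")),
    paste("ElementSpacing =", paste(format(sp, digits = 17), collapse = " ")),
    paste("Offset =", paste(format(orig, digits = 17), collapse = " ")),
    paste("ElementType =", elementType),
    paste("ElementDataFile =", dataFile))
  vals <- as.vector(a)
  if (ty$what == "integer") vals <- as.integer(round(vals))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  if (local) {
    writeBin(vals, con, size = ty$size, endian = "little")
  } else {
    rcon <- file(file.path(dirname(path), dataFile), "wb")
    on.exit(close(rcon), add = TRUE)
    writeBin(vals, rcon, size = ty$size, endian = "little")
  }
  invisible(NULL)
}

#' Read a CT volume
#'
#' Reads a 3D scalar image from NIfTI (`.nii`, `.nii.gz`) or MetaImage
#' (`.mha`, `.mhd` + `.raw`). Arrays are indexed `(x, y, z)` with `z` the
#' slice axis; spacing is taken from the file header.
#'
#' @param path file path; the extension selects the format.
#' @return A [CtVolume-class].
#' @examples
#' vol <- CtVolume(array(0, c(6, 6, 4)), c(1, 1, 2))
#' f <- tempfile(fileext = ".mha")
#' writeVolume(vol, f)
#' identical(dim(readVolume(f)), c(6L, 6L, 4L))
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stopfmt("file not found: %s", path)
  ext <- fileExt(path)
  if (ext %in% c("nii", "nii.gz")) {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 3L)
      stopfmt("%s is %d-dimensional; expected a 3D image", path, length(d))
    sp <- RNifti::pixdim(img)
    if (length(sp) < 3L || any(sp[1:3] <= 0))
      stopfmt("%s lacks valid voxel spacing", path)
    CtVolume(array(as.double(img), d), sp[1:3])
  } else if (ext %in% c("mha", "mhd")) {
    m <- readMetaImage(path)
    CtVolume(m$intensities, m$spacing, m$origin)
  } else {
    stopfmt("unsupported volume format '.%s' (use .nii, .nii.gz, .mha, .mhd)",
            ext)
  }
}

#' Write a CT volume
#'
#' Intensities round-trip bit-exactly (doubles are stored as 64-bit floats)
#' and spacing to well below 1e-6 mm.
#'
#' @param vol a [CtVolume-class].
#' @param path output path; extension selects NIfTI or MetaImage.
#' @return Invisibly, `path`.
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "CtVolume"))
  ext <- fileExt(path)
  if (ext %in% c("nii", "nii.gz")) {
    img <- RNifti::asNifti(vol@intensities)
    RNifti::pixdim(img) <- vol@spacing
    RNifti::writeNifti(img, path, datatype = "double")
  } else if (ext %in% c("mha", "mhd")) {
    writeMetaImage(vol@intensities, vol@spacing, vol@origin, path,
                   "MET_DOUBLE")
  } else {
    stopfmt("unsupported volume format '.%s'", ext)
  }
  invisible(path)
}

#' Read a binary mask
#'
#' Masks are stored as 0/1 integer volumes in the same image formats and
#' mapped to the internal \{-1, +1\} alphabet (0 to -1, 1 to +1).
#'
#' @param path file path.
#' @return A [BinaryMask-class].
#' @export
readMask <- function(path) {
  vol <- readVolume(path)
  a <- vol@intensities
  if (!all(a %in% c(0, 1)))
    stopfmt("%s holds non-binary values; not a 0/1 mask", path)
  BinaryMask(a == 1, vol@spacing, vol@origin)
}

#' Write a binary mask
#'
#' @param mask a [BinaryMask-class]; written as a 0/1 integer volume.
#' @param path output path (NIfTI or MetaImage).
#' @return Invisibly, `path`.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "BinaryMask"))
  a01 <- array(ifelse(mask@labels == 1L, 1, 0), dim(mask))
  ext <- fileExt(path)
  if (ext %in% c("nii", "nii.gz")) {
    img <- RNifti::asNifti(a01)
    RNifti::pixdim(img) <- mask@spacing
    RNifti::writeNifti(img, path, datatype = "uint8")
  } else if (ext %in% c("mha", "mhd")) {
    writeMetaImage(a01, mask@spacing, mask@origin, path, "MET_UCHAR")
  } else {
    stopfmt("unsupported mask format '.%s'", ext)
  }
  invisible(path)
}

#' Read a seed point
#'
#' Accepts a plain-text file holding one whitespace-separated integer
#' triple (`"x y z"`, 1-based voxel indices) or a JSON file
#' `{"index": [x, y, z]}`.
#'
#' @param path file path.
#' @return A [SeedPoint-class].
#' @export
readSeed <- function(path) {
  if (!file.exists(path)) stopfmt("file not found: %s", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = " ")
  if (grepl("^\\s*\\{", txt)) {
    obj <- tryCatch(jsonlite::fromJSON(txt),
                    error = function(e) stopfmt(
                      "cannot parse seed JSON %s: %s", path, conditionMessage(e)))
    idx <- obj$index
    if (is.null(idx) || length(idx) != 3L)
      stopfmt("seed JSON %s must hold one 'index' triple", path)
  } else {
    toks <- strsplit(trimws(txt), "\\s+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) != 3L)
      stopfmt("seed file %s must hold exactly one integer triple (found %d numbers)",
              path, length(toks))
    idx <- suppressWarnings(as.numeric(toks))
    if (any(is.na(idx))) stopfmt("seed file %s holds non-numeric tokens", path)
  }
  if (any(idx != round(idx))) stopfmt("seed indices in %s must be integers", path)
  SeedPoint(idx)
}

#' Write a seed point
#'
#' @param seed a [SeedPoint-class].
#' @param path output path; `.json` writes JSON, anything else plain text.
#' @return Invisibly, `path`.
#' @export
writeSeed <- function(seed, path) {
  stopifnot(is(seed, "SeedPoint"))
  if (fileExt(path) == "json") {
    jsonlite::write_json(list(index = seed@index), path, auto_unbox = FALSE)
  } else {
    writeLines(paste(seed@index, collapse = " "), path)
  }
  invisible(path)
}
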
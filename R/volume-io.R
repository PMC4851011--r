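## Volume I/O: NIfTI-1 via RNifti; MetaImage (.mha/.mhd) read/write
## implemented here (text header + raw block, x-fastest voxel order,
## which matches R's column-major layout).

volExtension <- function(path) {
  p <- tolower(path)
  if (grepl("\\.nii\\.gz$", p)) return("nii.gz")
  if (grepl("\\.nii$", p)) return("nii")
  if (grepl("\\.mha$", p)) return("mha")
  if (grepl("\\.mhd$", p)) return("mhd")
  sub(".*\\.", "", p)
}

metTypes <- list(
  MET_UCHAR  = list(what = "integer", size = 1, signed = FALSE),
  MET_CHAR   = list(what = "integer", size = 1, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2, signed = FALSE),
  MET_SHORT  = list(what = "integer", size = 2, signed = TRUE),
  MET_UINT   = list(what = "integer", size = 4, signed = TRUE),
  MET_INT    = list(what = "integer", size = 4, signed = TRUE),
  MET_FLOAT  = list(what = "double", size = 4, signed = TRUE),
  MET_DOUBLE = list(what = "double", size = 8, signed = TRUE))

readMetaImage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("truncated MetaImage header: ", path)
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3L) stop("malformed MetaImage header line: ", line)
    hdr[[kv[2]]] <- trimws(kv[3])
    if (kv[2] == "ElementDataFile") break
  }
  ndims <- as.integer(hdr$NDims)
  if (is.na(ndims) || ndims != 3L)
    stop("expected a 3D image, got NDims = ", hdr$NDims)
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- if (!is.null(hdr$ElementSpacing))
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]]) else c(1, 1, 1)
  origin <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  type <- metTypes[[hdr$ElementType]]
  if (is.null(type)) stop("unsupported ElementType: ", hdr$ElementType)
  msb <- identical(hdr$BinaryDataByteOrderMSB, "True")
  n <- prod(dims)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    raw <- readBin(con, "raw", n = n * type$size + 8192L)
  } else {
    rawPath <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(rawPath)) stop("missing raw data file: ", rawPath)
    raw <- readBin(rawPath, "raw", n = file.size(rawPath))
  }
  if (identical(hdr$CompressedData, "True"))
    raw <- memDecompress(raw, type = "gzip")
  if (length(raw) < n * type$size) stop("truncated MetaImage data: ", path)
  vals <- readBin(raw, type$what, n = n, size = type$size,
                  signed = type$signed, endian = if (msb) "big" else "little")
  Volume3D(array(as.numeric(vals), dim = dims), spacing = spacing,
           origin = origin)
}

writeMetaImage <- function(vol, path, elementType) {
  ext <- volExtension(path)
  local <- ext == "mha"
  dataFile <- if (local) "LOCAL" else paste0(sub("\\.mhd$", "",
                                                 basename(path)), ".raw")
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           "TransformMatrix = 1 0 0 0 1 0 0 0 1",
           paste("Offset =", paste(format(vol@origin, digits = 17),
                                   collapse = " ")),
           paste("ElementSpacing =", paste(format(vol@spacing, digits = 17),
                                           collapse = " ")),
           paste("DimSize =", paste(dim(vol@data), collapse = " ")),
           paste("ElementType =", elementType),
           paste("ElementDataFile =", dataFile))
  type <- metTypes[[elementType]]
  vals <- as.vector(vol@data)
  if (type$what == "integer") vals <- as.integer(round(vals))
  con <- file(path, "wb")
  writeLines(hdr, con)
  if (local) {
    writeBin(vals, con, size = type$size, endian = "little")
    close(con)
  } else {
    close(con)
    rawCon <- file(file.path(dirname(path), dataFile), "wb")
    writeBin(vals, rawCon, size = type$size, endian = "little")
    close(rawCon)
  }
  invisible(path)
}

#' Read a 3D volume from NIfTI or MetaImage
#'
#' Supported extensions: \code{.nii}, \code{.nii.gz}, \code{.mha},
#' \code{.mhd}. Spacing is taken from the header voxel dimensions and the
#' origin from the header offset (for NIfTI, the translation column of
#' the sform/qform; any rotation or axis flip encoded there is ignored —
#' volumes are used in their stored axis order (x, y, z)).
#'
#' @param path file path
#' @return a [Volume3D-class]; intensities are returned unchanged
#' @seealso [writeVolume()]
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- volExtension(path)
  if (ext %in% c("nii", "nii.gz")) {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 3L)
      stop("expected a 3D image, got ", length(d), " dimensions: ", path)
    sp <- RNifti::pixdim(img)[1:3]
    xf <- try(RNifti::xform(img), silent = TRUE)
    org <- if (inherits(xf, "try-error")) c(0, 0, 0) else xf[1:3, 4]
    Volume3D(array(as.numeric(img), dim = d), spacing = abs(sp),
             origin = as.numeric(org))
  } else if (ext %in% c("mha", "mhd")) {
    readMetaImage(path)
  } else {
    stop("unsupported volume format: .", ext,
         " (supported: .nii, .nii.gz, .mha, .mhd)")
  }
}

#' Write a 3D volume to NIfTI or MetaImage
#'
#' Numeric volumes are written as 64-bit floats (bit-compatible
#' round-trip); [BinaryMask3D-class] objects are written as 8-bit
#' unsigned integers.
#'
#' @param vol a [Volume3D-class]
#' @param path output path with extension \code{.nii}, \code{.nii.gz},
#'   \code{.mha} or \code{.mhd}
#' @return \code{path}, invisibly
#' @seealso [readVolume()]
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "Volume3D"))
  ext <- volExtension(path)
  isMask <- is(vol, "BinaryMask3D")
  if (ext %in% c("nii", "nii.gz")) {
    img <- RNifti::asNifti(vol@data)
    RNifti::pixdim(img) <- vol@spacing
    m <- diag(4)
    diag(m)[1:3] <- vol@spacing
    m[1:3, 4] <- vol@origin
    img <- RNifti::`qform<-`(img, structure(m, code = 2L))
    RNifti::writeNifti(img, path,
                       datatype = if (isMask) "uint8" else "double")
  } else if (ext %in% c("mha", "mhd")) {
    writeMetaImage(vol, path, if (isMask) "MET_UCHAR" else "MET_DOUBLE")
  } else {
    stop("unsupported volume format: .", ext,
         " (supported: .nii, .nii.gz, .mha, .mhd)")
  }
  invisible(path)
}
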
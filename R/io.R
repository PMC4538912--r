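#' Read a 3D volume from NIfTI or MetaImage
#'
#' Supported formats are NIfTI (`.nii`, `.nii.gz`, via RNifti) and
#' MetaImage (`.mha` single file or `.mhd` + raw pair). Geometry (dims,
#' spacing, origin) is taken from the header; the origin is the world
#' coordinate of the first voxel centre, matching the package's index
#' convention.
#'
#' @param path path to the volume file.
#' @param format `"auto"` (from the extension), `"nifti"` or `"metaimage"`.
#' @return a [voxel_grid]. If the file has anisotropic spacing the grid is
#'   returned as-is; kernel-based engines will refuse it later.
#' @export
read_volume <- function(path, format = c("auto", "nifti", "metaimage")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file does not exist: %s", path))
  if (format == "auto") format <- guess_format(path)
  switch(format,
    nifti = read_nifti_volume(path),
    metaimage = read_metaimage_volume(path)
  )
}

#' Write a 3D volume to NIfTI or MetaImage
#'
#' Scalar volumes are stored as float32, masks (see `type = "mask"`) as
#' unsigned 8-bit. Spacing and origin are written to the header (sform for
#' NIfTI, `ElementSpacing`/`Offset` for MetaImage).
#'
#' @param grid a [voxel_grid].
#' @param path output path; extension selects the format.
#' @param type `"scalar"` (float32) or `"mask"` (uint8, values must be 0/1).
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path, type = c("scalar", "mask")) {
  stopifnot_grid(grid)
  type <- match.arg(type)
  if (type == "mask" && !all(grid$values %in% c(0, 1)))
    stop("mask volumes must contain only 0/1")
  format <- guess_format(path)
  switch(format,
    nifti = write_nifti_volume(grid, path, type),
    metaimage = write_metaimage_volume(grid, path, type)
  )
  invisible(path)
}

guess_format <- function(path) {
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) return("nifti")
  if (grepl("\\.(mha|mhd)$", low)) return("metaimage")
  stop(sprintf("unsupported format: %s (expected .nii, .nii.gz, .mha or .mhd)",
               basename(path)))
}

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    if (length(d) > 3L && all(d[-(1:3)] == 1L)) {
      img <- array(as.numeric(img), dim = d[1:3])
      d <- d[1:3]
    } else stop("not a 3D volume")
  }
  sp <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  origin <- as.numeric(xf %*% c(0, 0, 0, 1))[1:3]
  voxel_grid(array(as.numeric(img), dim = d), spacing = sp, origin = origin)
}

write_nifti_volume <- function(grid, path, type) {
  img <- grid$values
  RNifti::pixdim(img) <- grid$spacing
  m <- rbind(cbind(diag(grid$spacing), grid$origin), c(0, 0, 0, 1))
  m <- structure(m, code = 2L)
  RNifti::sform(img) <- m
  RNifti::qform(img) <- m
  dtype <- if (type == "mask") "uint8" else "float"
  RNifti::writeNifti(img, path, datatype = dtype)
}

# MetaImage: minimal reader/writer for the subset the package emits
# (3D MET_FLOAT / MET_UCHAR, LOCAL or sidecar raw data, no compression).
read_metaimage_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- read_header_line(con)
    if (is.null(line)) stop("truncated MetaImage header")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop(sprintf("malformed MetaImage header line: %s", line))
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  ndims <- as.integer(hdr[["NDims"]] %||% "0")
  if (ndims != 3L) stop("not a 3D volume")
  dims <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr[["ElementSpacing"]] %||% "1 1 1", "\\s+")[[1]])
  origin <- as.numeric(strsplit(hdr[["Offset"]] %||% "0 0 0", "\\s+")[[1]])
  etype <- hdr[["ElementType"]] %||% "MET_FLOAT"
  n <- prod(dims)
  datafile <- hdr[["ElementDataFile"]]
  if (identical(datafile, "LOCAL")) {
    raw <- read_met_payload(con, etype, n)
  } else {
    rawpath <- file.path(dirname(path), datafile)
    if (!file.exists(rawpath)) stop(sprintf("raw data file missing: %s", rawpath))
    con2 <- file(rawpath, "rb")
    on.exit(close(con2), add = TRUE)
    raw <- read_met_payload(con2, etype, n)
  }
  voxel_grid(array(raw, dim = dims), spacing = spacing, origin = origin)
}

# Read one header line byte-by-byte so the connection is positioned exactly
# at the start of the binary payload afterwards (readLines buffers ahead).
read_header_line <- function(con) {
  bytes <- raw(0)
  repeat {
    b <- readBin(con, "raw", n = 1L)
    if (length(b) == 0L) return(if (length(bytes)) rawToChar(bytes) else NULL)
    if (b == as.raw(10L)) return(rawToChar(bytes))
    if (b != as.raw(13L)) bytes <- c(bytes, b)
  }
}

read_met_payload <- function(con, etype, n) {
  switch(etype,
    MET_FLOAT = readBin(con, "double", n = n, size = 4L, endian = "little"),
    MET_DOUBLE = readBin(con, "double", n = n, size = 8L, endian = "little"),
    MET_UCHAR = as.numeric(readBin(con, "integer", n = n, size = 1L,
                                   signed = FALSE, endian = "little")),
    MET_SHORT = as.numeric(readBin(con, "integer", n = n, size = 2L,
                                   signed = TRUE, endian = "little")),
    stop(sprintf("unsupported MetaImage ElementType: %s", etype))
  )
}

write_metaimage_volume <- function(grid, path, type) {
  dims <- dim(grid$values)
  etype <- if (type == "mask") "MET_UCHAR" else "MET_FLOAT"
  is_mhd <- grepl("\\.mhd$", tolower(path))
  datafile <- if (is_mhd) sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
              else "LOCAL"
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    sprintf("TransformMatrix = %s", paste(c(1,0,0,0,1,0,0,0,1), collapse = " ")),
    sprintf("Offset = %s", paste(format(grid$origin, trim = TRUE), collapse = " ")),
    sprintf("ElementSpacing = %s", paste(format(grid$spacing, trim = TRUE), collapse = " ")),
    sprintf("DimSize = %s", paste(dims, collapse = " ")),
    sprintf("ElementType = %s", etype),
    sprintf("ElementDataFile = %s", datafile)
  )
  payload_con <- if (is_mhd) {
    writeLines(hdr, path)
    file(file.path(dirname(path), datafile), "wb")
  } else {
    con <- file(path, "wb")
    writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
    con
  }
  on.exit(close(payload_con))
  v <- as.numeric(grid$values)
  if (type == "mask") {
    writeBin(as.raw(as.integer(v)), payload_con)
  } else {
    writeBin(v, payload_con, size = 4L, endian = "little")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
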
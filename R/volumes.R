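#' Construct a voxel volume
#'
#' A voxel volume is an ordinary 3-D R array carrying per-axis physical
#' spacing (mm) and a world origin as attributes. Axis 3 is the axial (slice)
#' axis by convention; indices are 1-based `[i, j, k]`.
#'
#' @param grid A 3-D array (numeric or logical).
#' @param spacing Numeric length-3, physical voxel size per axis in mm.
#' @param origin Numeric length-3 world coordinate of voxel `[1, 1, 1]`.
#' @return The array with `spacing` and `origin` attributes set.
#' @export
vox_volume <- function(grid, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(grid)) != 3L) abort("`grid` must be a 3-D array")
  if (any(dim(grid) < 1L)) abort("all three dimensions must be >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    abort("`spacing` must be three positive numbers")
  attr(grid, "spacing") <- spacing
  attr(grid, "origin") <- as.numeric(origin)
  grid
}

#' @rdname vox_volume
#' @param x A volume created by [vox_volume()] or any array.
#' @export
voxel_spacing <- function(x) attr(x, "spacing") %||% c(1, 1, 1)

#' Interpret a volume as binary foreground
#'
#' Values greater than zero are foreground. Non-finite values are rejected.
#'
#' @param x A 3-D array.
#' @return A logical 3-D array with the same spacing attributes.
#' @export
as_binary_volume <- function(x) {
  if (length(dim(x)) != 3L) abort("`x` must be a 3-D array")
  v <- x
  if (!is.logical(v)) {
    if (any(!is.finite(v))) abort("volume contains non-finite values")
    v <- v > 0
  }
  vox_volume(v, voxel_spacing(x), attr(x, "origin") %||% c(0, 0, 0))
}

#' Read a volume from disk
#'
#' NIfTI (`.nii`, `.nii.gz`) is read through RNifti; MetaImage
#' (`.mhd`/`.mha`, uncompressed) through a built-in reader.
#'
#' @param path Path to the image file.
#' @return A 3-D array with `spacing`/`origin` attributes.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) > 3L) arr <- array(arr, dim(arr)[1:3])
    sp <- RNifti::pixdim(img)[1:3]
    return(vox_volume(arr, spacing = sp))
  }
  if (grepl("\\.mh[da]$", path, ignore.case = TRUE)) return(read_metaimage(path))
  abort("unsupported volume format (expected .nii, .nii.gz, .mhd or .mha)")
}

#' Write a volume to disk
#'
#' Integer-valued volumes are written as such. Format is chosen from the
#' file extension (NIfTI or uncompressed MetaImage).
#'
#' @param vol A 3-D array (logical or numeric).
#' @param path Output path ending in `.nii`, `.nii.gz`, `.mhd` or `.mha`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (length(dim(vol)) != 3L) abort("`vol` must be a 3-D array")
  sp <- voxel_spacing(vol)
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    arr <- vol
    if (is.logical(arr)) arr <- array(as.integer(arr), dim(vol))
    attributes(arr) <- list(dim = dim(vol))
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- sp
    RNifti::writeNifti(img, path)
    return(invisible(path))
  }
  if (grepl("\\.mh[da]$", path, ignore.case = TRUE))
    return(write_metaimage(vol, path))
  abort("unsupported volume format (expected .nii, .nii.gz, .mhd or .mha)")
}

# Minimal MetaImage support: plain-text header + uncompressed raw block.
# Only the fields this package writes are interpreted on read.
read_metaimage <- function(path) {
  is_mha <- grepl("\\.mha$", path, ignore.case = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) abort("truncated MetaImage header")
    hdr <- c(hdr, line)
    if (grepl("^ElementDataFile", line)) break
  }
  kv <- strsplit(hdr, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = " = "), "")
  get_field <- function(k, default = NULL) {
    i <- match(k, keys)
    if (is.na(i)) default else vals[i]
  }
  dims <- as.integer(strsplit(get_field("DimSize"), "\\s+")[[1]])
  sp <- as.numeric(strsplit(get_field("ElementSpacing", "1 1 1"), "\\s+")[[1]])
  off <- as.numeric(strsplit(get_field("Offset", "0 0 0"), "\\s+")[[1]])
  type <- get_field("ElementType", "MET_UCHAR")
  rd <- switch(type,
    MET_UCHAR  = function(n) as.numeric(readBin(con, "integer", n, size = 1L, signed = FALSE)),
    MET_SHORT  = function(n) as.numeric(readBin(con, "integer", n, size = 2L, signed = TRUE)),
    MET_INT    = function(n) as.numeric(readBin(con, "integer", n, size = 4L)),
    MET_FLOAT  = function(n) readBin(con, "numeric", n, size = 4L),
    MET_DOUBLE = function(n) readBin(con, "numeric", n, size = 8L),
    abort(sprintf("unsupported ElementType: %s", type))
  )
  datafile <- get_field("ElementDataFile")
  if (!is_mha && !identical(datafile, "LOCAL")) {
    close(con)
    on.exit()
    con <- file(file.path(dirname(path), datafile), "rb")
    on.exit(close(con))
  }
  vals <- rd(prod(dims))
  vox_volume(array(vals, dim = dims), spacing = sp, origin = off)
}

write_metaimage <- function(vol, path) {
  is_mha <- grepl("\\.mha$", path, ignore.case = TRUE)
  arr <- vol
  if (is.logical(arr)) arr <- array(as.integer(arr), dim(vol))
  int_like <- is.integer(arr) ||
    (is.numeric(arr) && all(arr == floor(arr)) && max(abs(arr)) < 2^31)
  type <- if (int_like) "MET_INT" else "MET_DOUBLE"
  datafile <- if (is_mha) "LOCAL" else sub("\\.mhd$", ".raw", basename(path))
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    sprintf("DimSize = %s", paste(dim(vol), collapse = " ")),
    sprintf("ElementSpacing = %s", paste(voxel_spacing(vol), collapse = " ")),
    sprintf("Offset = %s", paste(attr(vol, "origin") %||% c(0, 0, 0), collapse = " ")),
    sprintf("ElementType = %s", type),
    sprintf("ElementDataFile = %s", datafile)
  )
  write_block <- function(con) {
    if (type == "MET_INT") writeBin(as.integer(arr), con, size = 4L)
    else writeBin(as.numeric(arr), con, size = 8L)
  }
  if (is_mha) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    write_block(con)
  } else {
    writeLines(hdr, path)
    con <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(con))
    write_block(con)
  }
  invisible(path)
}
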
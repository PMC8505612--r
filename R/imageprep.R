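#' Read a 3D volume from an NRRD file
#'
#' Minimal NRRD (NRRD0004) reader for attached-header files: 3D data, `raw`
#' or `ascii`/`text` encodings, little-endian, axis-aligned `space
#' directions` (or `spacings`). Data are returned in `[x, y, z]` index order
#' (x fastest, as stored).
#'
#' @param path Path to a `.nrrd` file.
#' @return An [ImageVolume-class].
#' @seealso [writeNRRD()]
#' @export
readNRRD <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000", magic))
    stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L)
      stop("NRRD header ended without a data section")
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  if (is.null(fields$dimension) || as.integer(fields$dimension) != 3L)
    stop("only 3-dimensional NRRD volumes are supported")
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  n <- prod(sizes)

  spacing <- NULL
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    if (length(vecs) != 3L)
      stop("space directions must give three vectors")
    M <- vapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]), numeric(3))
    offdiag <- M; diag(offdiag) <- 0
    if (any(abs(offdiag) > 1e-9))
      stop("only axis-aligned space directions are supported")
    spacing <- abs(diag(M))
  } else if (!is.null(fields$spacings)) {
    spacing <- abs(as.numeric(strsplit(fields$spacings, "\\s+")[[1]]))
  }
  if (is.null(spacing) || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("NRRD header lacks usable spacing metadata")
  if (!is.null(fields[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "",
                                       fields[["space origin"]]), ",")[[1]])

  type <- fields$type
  enc <- tolower(fields$encoding)
  if (enc %in% c("ascii", "text", "txt")) {
    txt <- readLines(con)
    vals <- as.numeric(scan(text = txt, what = numeric(), quiet = TRUE))
  } else if (enc == "raw") {
    endian <- if (!is.null(fields$endian)) fields$endian else "little"
    rd <- switch(type,
      "unsigned char" = , "uint8" = , "uchar" =
        list(what = "integer", size = 1L, signed = FALSE),
      "short" = , "int16" = list(what = "integer", size = 2L, signed = TRUE),
      "int" = , "int32" = list(what = "integer", size = 4L, signed = TRUE),
      "float" = list(what = "numeric", size = 4L, signed = TRUE),
      "double" = list(what = "numeric", size = 8L, signed = TRUE),
      stop("unsupported NRRD type: ", type)
    )
    vals <- readBin(con, what = rd$what, n = n, size = rd$size,
                    signed = rd$signed, endian = endian)
  } else {
    stop("unsupported NRRD encoding: ", enc)
  }
  if (length(vals) != n)
    stop("NRRD data length mismatch: expected ", n, ", got ", length(vals))
  ImageVolume(array(as.numeric(vals), sizes), spacing = spacing,
              origin = origin)
}

#' Write a 3D volume to an NRRD file
#'
#' Writes an attached-header NRRD0004 file with diagonal `space directions`
#' encoding the voxel spacing and a `space origin`.
#'
#' @param vol An [ImageVolume-class].
#' @param path Output path.
#' @param encoding `"raw"` (little-endian) or `"ascii"`.
#' @param type Stored scalar type: `"double"`, `"float"`, `"int16"` or
#'   `"uint8"` (use `"uint8"` for masks).
#' @return `path`, invisibly.
#' @export
writeNRRD <- function(vol, path, encoding = c("raw", "ascii"),
                      type = c("double", "float", "int16", "uint8")) {
  encoding <- match.arg(encoding)
  type <- match.arg(type)
  v <- voxelData(vol)
  sp <- spacingMm(vol)
  org <- originMm(vol)
  tname <- c(double = "double", float = "float", int16 = "short",
             uint8 = "unsigned char")[[type]]
  hdr <- c(
    "NRRD0004",
    paste0("type: ", tname),
    "dimension: 3",
    "space: left-posterior-superior",
    paste("sizes:", paste(dim(v), collapse = " ")),
    sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
            sp[1], sp[2], sp[3]),
    "kinds: domain domain domain",
    if (encoding == "raw") "endian: little",
    paste0("encoding: ", encoding),
    sprintf("space origin: (%.17g,%.17g,%.17g)", org[1], org[2], org[3]),
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (encoding == "ascii") {
    writeLines(paste(format(as.vector(v), digits = 17, trim = TRUE,
                            scientific = NA), collapse = " "), con)
  } else {
    if (type %in% c("int16", "uint8"))
      writeBin(as.integer(v), con, size = c(int16 = 2L, uint8 = 1L)[[type]],
               endian = "little")
    else
      writeBin(as.numeric(v), con,
               size = c(double = 8L, float = 4L)[[type]], endian = "little")
  }
  invisible(path)
}

#' Resample an image and its mask to an isotropic grid
#'
#' Resamples the image with order-3 B-spline interpolation and the mask with
#' nearest-neighbour interpolation (preserving binarity) onto a grid of
#' `targetMm` isotropic spacing anchored at the input origin. When the input
#' already has the target spacing on every axis the pair is returned
#' unchanged, so the operation is idempotent on the grid.
#'
#' @param image An [ImageVolume-class].
#' @param mask Binary mask on the same grid.
#' @param targetMm Target isotropic spacing in mm (default 1).
#' @return A list with elements `image` and `mask`.
#' @export
resampleIsotropic <- function(image, mask, targetMm = 1.0) {
  checkSameGrid(image, mask)
  if (!isBinaryMask(mask)) stop("mask must be binary and nonempty")
  sp <- spacingMm(image)
  if (max(abs(sp - targetMm)) < 1e-9)
    return(list(image = image, mask = mask))
  d <- dim(voxelData(image))
  outDim <- pmax(1L, as.integer(round(d * sp / targetMm)))
  A <- diag(targetMm / sp)
  b <- c(0, 0, 0)
  imgOut <- cpp_resample_affine(as.numeric(voxelData(image)), d, A, b,
                                outDim, 3L)
  mskOut <- cpp_resample_affine(as.numeric(voxelData(mask)), d, A, b,
                                outDim, 0L)
  mskOut <- as.numeric(mskOut > 0.5)
  if (!any(mskOut == 1))
    stop("mask is empty after resampling")
  list(
    image = ImageVolume(array(imgOut, outDim), spacing = targetMm,
                        origin = originMm(image), meta = metaInfo(image)),
    mask = ImageVolume(array(mskOut, outDim), spacing = targetMm,
                       origin = originMm(mask))
  )
}

#' Crop an image and mask to the padded lesion bounding box
#'
#' The output grid is the tight bounding box of the mask dilated by
#' `ceiling(padMm / spacing)` voxels per side and clamped to the image
#' extent. The mask voxel count is unchanged.
#'
#' @param image An [ImageVolume-class].
#' @param mask Binary lesion mask on the same grid.
#' @param padMm Padding distance in mm (default 10).
#' @return A list with elements `image` and `mask`.
#' @export
cropToLesion <- function(image, mask, padMm = 10) {
  checkSameGrid(image, mask)
  m <- maskArray(mask)
  d <- dim(m)
  sp <- spacingMm(image)
  padVox <- ceiling(padMm / sp)
  idx <- which(m, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - padVox, 1L)
  hi <- pmin(apply(idx, 2, max) + padVox, d)
  sub <- function(a) a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  newOrigin <- originMm(image) + (lo - 1L) * sp
  list(
    image = ImageVolume(sub(voxelData(image)), spacing = sp,
                        origin = newOrigin, meta = metaInfo(image)),
    mask = ImageVolume(sub(voxelData(mask)), spacing = sp,
                       origin = newOrigin)
  )
}
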
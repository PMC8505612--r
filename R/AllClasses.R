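#' @import methods
NULL

# ---------------------------------------------------------------------------
# ImageVolume: a 3D scalar grid with physical metadata
# ---------------------------------------------------------------------------

#' ImageVolume: a 3D scalar volume with grid metadata
#'
#' Container for a 3D scalar image (Hounsfield-unit semantics for CT) on a
#' regular grid. The array is indexed `[x, y, z]`; world coordinates are in
#' millimetres, with `origin` the world position of voxel `[1, 1, 1]`.
#' Binary lesion masks are represented as `ImageVolume` objects whose values
#' are 0/1 on the same grid as their paired image.
#'
#' @slot values 3D numeric array of voxel values.
#' @slot spacing Numeric length-3, voxel size in mm per axis (all > 0).
#' @slot origin Numeric length-3, world position (mm) of the first voxel.
#' @slot meta Named list of provenance (free-form; e.g. applied transforms).
#'
#' @aliases ImageVolume-class
#' @export
setClass("ImageVolume",
  representation(
    values = "array",
    spacing = "numeric",
    origin = "numeric",
    meta = "list"
  ),
  prototype(
    spacing = c(1, 1, 1),
    origin = c(0, 0, 0),
    meta = list()
  )
)

setValidity("ImageVolume", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive finite numbers (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite numbers (mm)")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "voxel values must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct an ImageVolume
#'
#' @param values 3D numeric array (`[x, y, z]` index order).
#' @param spacing Voxel size in mm, length 1 (isotropic) or 3.
#' @param origin World position (mm) of voxel `[1, 1, 1]`.
#' @param meta Named list of provenance entries.
#' @return An [ImageVolume-class] object.
#' @examples
#' vol <- ImageVolume(array(0, c(8, 8, 8)), spacing = 1)
#' dim(voxelData(vol))
#' @export
ImageVolume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        meta = list()) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("ImageVolume", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin), meta = meta)
}

#' @describeIn ImageVolume Voxel value array.
#' @param x,object An `ImageVolume`.
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname ImageVolume
#' @export
setMethod("voxelData", "ImageVolume", function(x) x@values)

#' @describeIn ImageVolume Voxel spacing in mm.
#' @export
setGeneric("spacingMm", function(x) standardGeneric("spacingMm"))

#' @rdname ImageVolume
#' @export
setMethod("spacingMm", "ImageVolume", function(x) x@spacing)

#' @describeIn ImageVolume Grid origin in mm.
#' @export
setGeneric("originMm", function(x) standardGeneric("originMm"))

#' @rdname ImageVolume
#' @export
setMethod("originMm", "ImageVolume", function(x) x@origin)

#' @describeIn ImageVolume Provenance list.
#' @export
setGeneric("metaInfo", function(x) standardGeneric("metaInfo"))

#' @rdname ImageVolume
#' @export
setMethod("metaInfo", "ImageVolume", function(x) x@meta)

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("ImageVolume %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 4), collapse = " x ")))
  rng <- range(object@values)
  cat(sprintf("  values in [%.6g, %.6g]; origin (%s) mm\n", rng[1], rng[2],
              paste(format(object@origin, digits = 4), collapse = ", ")))
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), collapse = ", "), "\n")
})

#' Test or enforce that a volume is a binary mask
#'
#' A mask is an `ImageVolume` whose values are exactly 0 or 1 with at least
#' one foreground voxel.
#'
#' @param x An [ImageVolume-class].
#' @return `isBinaryMask` returns a logical scalar; `maskArray` returns the
#'   logical 3D array of the mask, erroring if `x` is not a valid mask.
#' @export
isBinaryMask <- function(x) {
  v <- voxelData(x)
  all(v %in% c(0, 1)) && any(v == 1)
}

#' @rdname isBinaryMask
#' @export
maskArray <- function(x) {
  if (!isBinaryMask(x))
    stop("mask must be binary (0/1) and nonempty")
  voxelData(x) > 0
}

# check that a mask shares its grid with an image
checkSameGrid <- function(image, mask) {
  if (!identical(dim(voxelData(image)), dim(voxelData(mask))))
    stop("image and mask must share the same grid shape")
  if (max(abs(spacingMm(image) - spacingMm(mask))) > 1e-6 ||
      max(abs(originMm(image) - originMm(mask))) > 1e-6)
    stop("image and mask must share spacing and origin")
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# ExtractionParams
# ---------------------------------------------------------------------------

#' GLCM extraction parameters
#'
#' @slot binWidth Fixed bin width B in HU for intensity discretization.
#' @slot kernelRadius Kernel radius R in voxels; the cubic kernel has edge
#'   `2 * R + 1`.
#' @slot distance Co-occurrence offset distance \eqn{\delta} in voxels.
#' @slot maskedKernel If `TRUE`, only in-mask voxels contribute pairs; if
#'   `FALSE` (default) the kernel draws on all voxels of the padded crop.
#' @slot featureList Character vector of feature names to compute (subset of
#'   [glcmFeatureNames()]).
#'
#' @aliases ExtractionParams-class
#' @export
setClass("ExtractionParams",
  representation(
    binWidth = "numeric",
    kernelRadius = "integer",
    distance = "integer",
    maskedKernel = "logical",
    featureList = "character"
  )
)

setValidity("ExtractionParams", function(object) {
  msg <- character()
  if (object@binWidth <= 0) msg <- c(msg, "binWidth must be > 0")
  if (object@kernelRadius < 1L) msg <- c(msg, "kernelRadius must be >= 1")
  if (object@distance < 1L) msg <- c(msg, "distance must be >= 1")
  bad <- setdiff(object@featureList, glcmFeatureNames())
  if (length(bad))
    msg <- c(msg, paste("unknown features:", paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' @param binWidth,kernelRadius,distance,maskedKernel,featureList See slots.
#' @return An `ExtractionParams` object.
#' @rdname ExtractionParams-class
#' @examples
#' extractionParams(binWidth = 12, kernelRadius = 1)
#' @export
extractionParams <- function(binWidth = 12, kernelRadius = 1L,
                             distance = 1L, maskedKernel = FALSE,
                             featureList = glcmFeatureNames()) {
  new("ExtractionParams", binWidth = as.numeric(binWidth),
      kernelRadius = as.integer(kernelRadius),
      distance = as.integer(distance),
      maskedKernel = isTRUE(maskedKernel),
      featureList = featureList)
}

setMethod("show", "ExtractionParams", function(object) {
  cat(sprintf(
    "ExtractionParams: B = %g HU, R = %d (kernel edge %d), delta = %d, %s kernel, %d features\n",
    object@binWidth, object@kernelRadius, 2L * object@kernelRadius + 1L,
    object@distance, if (object@maskedKernel) "masked" else "unmasked",
    length(object@featureList)))
})

# ---------------------------------------------------------------------------
# FeatureMapSet
# ---------------------------------------------------------------------------

#' A named set of voxel-wise feature maps
#'
#' One map per feature for a single (image, mask, B, R) combination. Maps are
#' 3D arrays on the crop grid, finite on the mask and `NA` elsewhere.
#'
#' @slot maps Named list of 3D arrays.
#' @slot params The [ExtractionParams-class] used.
#' @slot sourceId Character provenance tag (lesion/scan identifier).
#' @slot spacing Voxel spacing (mm) of the maps' grid.
#'
#' @aliases FeatureMapSet-class
#' @export
setClass("FeatureMapSet",
  representation(
    maps = "list",
    params = "ExtractionParams",
    sourceId = "character",
    spacing = "numeric"
  )
)

setValidity("FeatureMapSet", function(object) {
  msg <- character()
  nm <- names(object@maps)
  if (is.null(nm) || anyDuplicated(nm))
    msg <- c(msg, "maps must be uniquely named")
  if (length(object@maps)) {
    d <- dim(object@maps[[1]])
    for (m in object@maps)
      if (!identical(dim(m), d)) {
        msg <- c(msg, "all maps must share one grid")
        break
      }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn FeatureMapSet Names of the feature maps.
#' @param x,object A `FeatureMapSet`.
#' @export
setGeneric("mapNames", function(x) standardGeneric("mapNames"))

#' @rdname FeatureMapSet
#' @export
setMethod("mapNames", "FeatureMapSet", function(x) names(x@maps))

#' @describeIn FeatureMapSet Extract one feature map (3D array) by name.
#' @param name Feature name.
#' @export
setGeneric("featureMap", function(x, name) standardGeneric("featureMap"))

#' @rdname FeatureMapSet
#' @export
setMethod("featureMap", "FeatureMapSet", function(x, name) {
  if (!name %in% names(x@maps))
    stop("no such feature map: ", name)
  x@maps[[name]]
})

setMethod("show", "FeatureMapSet", function(object) {
  d <- if (length(object@maps)) dim(object@maps[[1]]) else c(0, 0, 0)
  cat(sprintf("FeatureMapSet '%s': %d maps on %d x %d x %d grid\n",
              object@sourceId, length(object@maps), d[1], d[2], d[3]))
  show(object@params)
})

# ---------------------------------------------------------------------------
# GammaCriterion
# ---------------------------------------------------------------------------

#' Gamma-index acceptance criterion
#'
#' The gamma criterion pairs a distance-to-agreement tolerance (DTA, mm) with
#' a feature-difference tolerance expressed as a percentage of the reference
#' map's maximum (`F_max`). The conventional 2 mm / 1 % criterion is the
#' default.
#'
#' @slot dtaMm Distance-to-agreement in mm (> 0).
#' @slot dfPercent Feature-difference criterion in percent of `F_max`.
#' @slot fMax Reference maximum; `NA` means recompute from the reference map.
#' @slot searchCapMm Maximum search distance in mm (>= `dtaMm`).
#' @slot upsampleFactor Integer sub-voxel interpolation factor (>= 1).
#'
#' @aliases GammaCriterion-class
#' @export
setClass("GammaCriterion",
  representation(
    dtaMm = "numeric",
    dfPercent = "numeric",
    fMax = "numeric",
    searchCapMm = "numeric",
    upsampleFactor = "integer"
  )
)

setValidity("GammaCriterion", function(object) {
  msg <- character()
  if (object@dtaMm <= 0) msg <- c(msg, "dtaMm must be > 0")
  if (object@dfPercent <= 0 || object@dfPercent > 100)
    msg <- c(msg, "dfPercent must be in (0, 100]")
  if (!is.na(object@fMax) && object@fMax <= 0)
    msg <- c(msg, "fMax must be > 0 when supplied")
  if (object@searchCapMm < object@dtaMm)
    msg <- c(msg, "searchCapMm must be >= dtaMm")
  if (object@upsampleFactor < 1L)
    msg <- c(msg, "upsampleFactor must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @param dtaMm,dfPercent,fMax,searchCapMm,upsampleFactor See slots.
#' @return A `GammaCriterion` object.
#' @rdname GammaCriterion-class
#' @examples
#' gammaCriterion()            # 2 mm / 1 %
#' gammaCriterion(3, 2)        # 3 mm / 2 %
#' @export
gammaCriterion <- function(dtaMm = 2, dfPercent = 1, fMax = NA_real_,
                           searchCapMm = 3 * dtaMm, upsampleFactor = 3L) {
  new("GammaCriterion", dtaMm = as.numeric(dtaMm),
      dfPercent = as.numeric(dfPercent), fMax = as.numeric(fMax),
      searchCapMm = as.numeric(searchCapMm),
      upsampleFactor = as.integer(upsampleFactor))
}

setMethod("show", "GammaCriterion", function(object) {
  cat(sprintf(
    "GammaCriterion: %g mm / %g%% of F_max (search cap %g mm, upsample x%d)\n",
    object@dtaMm, object@dfPercent, object@searchCapMm,
    object@upsampleFactor))
})

# ---------------------------------------------------------------------------
# HabitatMap
# ---------------------------------------------------------------------------

#' Imaging-habitat label map
#'
#' An integer-labelled volume on the lesion mask: labels 1..k inside the
#' mask, 0 outside, with clustering provenance.
#'
#' @slot labels 3D integer array.
#' @slot k Cluster count used.
#' @slot provenance Named list: features used, variance explained per
#'   principal component, seed, fit mode.
#'
#' @aliases HabitatMap-class
#' @export
setClass("HabitatMap",
  representation(
    labels = "array",
    k = "integer",
    provenance = "list"
  )
)

setValidity("HabitatMap", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L)
    msg <- c(msg, "labels must be a 3D array")
  lab <- unique(as.integer(object@labels))
  if (any(lab < 0L) || any(lab > object@k))
    msg <- c(msg, "labels must lie in 0..k")
  if (object@k < 1L) msg <- c(msg, "k must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @param labels,k,provenance See slots.
#' @return A `HabitatMap` object.
#' @rdname HabitatMap-class
#' @export
HabitatMap <- function(labels, k, provenance = list()) {
  storage.mode(labels) <- "integer"
  new("HabitatMap", labels = labels, k = as.integer(k),
      provenance = provenance)
}

#' @describeIn HabitatMap The integer label array (0 outside the mask).
#' @param x,object A `HabitatMap`.
#' @export
setGeneric("habitatLabels", function(x) standardGeneric("habitatLabels"))

#' @rdname HabitatMap
#' @export
setMethod("habitatLabels", "HabitatMap", function(x) x@labels)

#' @describeIn HabitatMap Number of clusters.
#' @export
setGeneric("nHabitats", function(x) standardGeneric("nHabitats"))

#' @rdname HabitatMap
#' @export
setMethod("nHabitats", "HabitatMap", function(x) x@k)

setMethod("show", "HabitatMap", function(object) {
  d <- dim(object@labels)
  tab <- table(object@labels[object@labels > 0])
  cat(sprintf("HabitatMap: k = %d on %d x %d x %d grid, %d labelled voxels\n",
              object@k, d[1], d[2], d[3], sum(tab)))
  if (length(tab))
    cat("  voxels per habitat:", paste(as.integer(tab), collapse = ", "), "\n")
})
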
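#' @import methods
NULL

#' Multichannel 3D image stack
#'
#' Container for a 3D multichannel fluorescence volume. Voxel data are held
#' as a 4D array indexed (z, y, x, channel); the channel axis carries the
#' channel names. Physical voxel sizes are micrometres in (z, y, x) order.
#' Time-lapse calcium recordings are handled separately by
#' \linkS4class{CalciumTraceSet}.
#'
#' @slot data 4D numeric array (z, y, x, channel); finite, non-negative.
#' @slot channelNames character vector naming the channel axis.
#' @slot voxelSize numeric length 3, micrometres per voxel (z, y, x).
#' @slot frameInterval seconds between frames for time-resolved data;
#'   \code{NA} for a single time point.
#' @exportClass MultichannelStack
setClass("MultichannelStack",
  representation(
    data = "array",
    channelNames = "character",
    voxelSize = "numeric",
    frameInterval = "numeric"
  )
)

setValidity("MultichannelStack", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L) return("data must be a 4D (z, y, x, channel) array")
  if (length(object@channelNames) != d[4L])
    return("channelNames length must match the channel axis")
  if (anyDuplicated(object@channelNames))
    return("channel names must be unique")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be 3 positive values (z, y, x)")
  if (any(!is.finite(object@data)) || any(object@data < 0))
    return("intensities must be finite and >= 0")
  TRUE
})

#' Parameters of the synthetic epidermis phantom
#'
#' Complete description of one synthetic epidermis volume: geometry of the
#' keratinocyte partition, the intraepidermal nerve fiber, Cx43 puncta, the
#' forward imaging model (PSF, illumination gain field, photon noise) and
#' the seed that makes the phantom reproducible. All physical quantities
#' are micrometres; fractions are in [0, 1]. Build with
#' \code{\link{phantomSpec}}.
#'
#' @slot shape integer voxel counts (z, y, x); at least (8, 32, 32).
#' @slot voxelSize micrometres per voxel (z, y, x).
#' @slot nCells number of keratinocytes tiling the interior.
#' @slot nucleusRadius nucleus radius, um.
#' @slot membraneThickness half-thickness of the membrane shell, um.
#' @slot fiberRadius fiber radius, um (diameter of intraepidermal fibers is
#'   at most ~1 um, hence the default 0.5).
#' @slot ensheathedFraction target fraction of fiber voxels routed through
#'   cell interiors (membrane-negative).
#' @slot nFibers number of fibers (default 1).
#' @slot cx43Count number of Cx43 puncta.
#' @slot cx43Diameter range (min, max) of punctum diameters, um; plaques
#'   span roughly 200-400 nm.
#' @slot cx43ContactFraction fraction of puncta placed in fiber contact.
#' @slot psfSigma Gaussian PSF sigma per axis (z, y, x), um.
#' @slot photonScale expected photons at unit truth intensity.
#' @slot background pre-gain background photon level as a fraction of
#'   \code{photonScale} (autofluorescence / stray light).
#' @slot readNoiseSd Gaussian read-noise SD as a fraction of
#'   \code{photonScale}.
#' @slot gainAmplitude relative amplitude of the smooth multiplicative
#'   illumination field.
#' @slot dermisMargin,cornifiedMargin z-extents (voxels) excluded from the
#'   epidermal box at the bottom (dermis) and top (stratum corneum).
#' @slot seed integer seed driving all phantom randomness.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(
    shape = "integer",
    voxelSize = "numeric",
    nCells = "integer",
    nucleusRadius = "numeric",
    membraneThickness = "numeric",
    fiberRadius = "numeric",
    ensheathedFraction = "numeric",
    nFibers = "integer",
    cx43Count = "integer",
    cx43Diameter = "numeric",
    cx43ContactFraction = "numeric",
    psfSigma = "numeric",
    photonScale = "numeric",
    background = "numeric",
    readNoiseSd = "numeric",
    gainAmplitude = "numeric",
    dermisMargin = "integer",
    cornifiedMargin = "integer",
    seed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  s <- object
  if (length(s@shape) != 3L || any(s@shape < c(8L, 32L, 32L)))
    return("shape must be (z, y, x) with at least (8, 32, 32) voxels")
  if (any(s@voxelSize <= 0)) return("voxel sizes must be positive")
  for (nm in c("nucleusRadius", "membraneThickness", "fiberRadius",
               "photonScale")) {
    if (slot(s, nm) <= 0) return(paste(nm, "must be positive"))
  }
  for (nm in c("ensheathedFraction", "cx43ContactFraction")) {
    v <- slot(s, nm)
    if (v < 0 || v > 1) return(paste(nm, "must be in [0, 1]"))
  }
  if (s@nCells < 1L) return("nCells must be >= 1")
  if (s@nFibers < 1L) return("nFibers must be >= 1")
  if (s@cx43Count < 0L) return("cx43Count must be >= 0")
  if (length(s@cx43Diameter) != 2L || any(s@cx43Diameter <= 0) ||
      diff(s@cx43Diameter) < 0)
    return("cx43Diameter must be an increasing positive (min, max) pair")
  if (any(s@psfSigma < 0) || s@gainAmplitude < 0 || s@background < 0 ||
      s@readNoiseSd < 0)
    return("psfSigma, gainAmplitude, background, readNoiseSd must be >= 0")
  if (s@fiberRadius / s@voxelSize[2L] < 1 || s@fiberRadius / s@voxelSize[3L] < 1)
    return("fiberRadius must be at least 1 voxel in y and x")
  if (s@dermisMargin < 0L || s@cornifiedMargin < 0L)
    return("z margins must be >= 0")
  if (s@dermisMargin + s@cornifiedMargin + 2L >= s@shape[1L])
    return("z margins leave no epidermal planes")
  TRUE
})

#' Voxel-level ground truth of a phantom
#'
#' All truth masks of one synthetic epidermis volume plus the designed
#' ratio statistics evaluated on those masks inside the epidermal box. The
#' ensheathed-fiber mask is exactly the set of fiber voxels that are
#' membrane-negative, mirroring the WGA-negativity definition of
#' ensheathment used for the real image analysis.
#'
#' @slot cellLabels integer array (z, y, x); 0 = extracellular.
#' @slot nucleusMask,membraneMask,fiberMask,cx43Mask logical arrays.
#' @slot fiberEnsheathedMask logical array; subset of \code{fiberMask},
#'   disjoint from \code{membraneMask}.
#' @slot epidermalBox \code{\link{epidermalBox}} delimiting the epidermis.
#' @slot trueEnsheathmentRatio,trueCx43ContactRatio designed ratios,
#'   computed from the truth masks by the same counting code used for real
#'   data.
#' @slot spec the generating \linkS4class{PhantomSpec}.
#' @exportClass PhantomTruth
setClass("PhantomTruth",
  representation(
    cellLabels = "array",
    nucleusMask = "array",
    membraneMask = "array",
    fiberMask = "array",
    cx43Mask = "array",
    fiberEnsheathedMask = "array",
    epidermalBox = "list",
    trueEnsheathmentRatio = "numeric",
    trueCx43ContactRatio = "numeric",
    spec = "PhantomSpec"
  )
)

setValidity("PhantomTruth", function(object) {
  d <- dim(object@cellLabels)
  for (nm in c("nucleusMask", "membraneMask", "fiberMask", "cx43Mask",
               "fiberEnsheathedMask")) {
    m <- slot(object, nm)
    if (!identical(dim(m), d)) return(paste(nm, "shape mismatch"))
    if (!is.logical(m)) return(paste(nm, "must be logical"))
  }
  if (any(object@fiberEnsheathedMask & !object@fiberMask))
    return("fiberEnsheathedMask must be a subset of fiberMask")
  if (any(object@fiberEnsheathedMask & object@membraneMask))
    return("fiberEnsheathedMask must be disjoint from membraneMask")
  TRUE
})

#' Rendered phantom: synthetic microscope output
#'
#' The forward-imaged phantom: a four-channel stack (dapi, wga, pgp95,
#' cx43) produced from the truth masks by PSF blur, multiplicative
#' illumination gain, Poisson photon noise and Gaussian read noise, plus
#' the gain field that was applied (unit mean).
#'
#' @slot stack \linkS4class{MultichannelStack} with channels
#'   dapi, wga, pgp95, cx43.
#' @slot gainField numeric (y, x) matrix, unit mean, strictly positive.
#' @slot spec the generating \linkS4class{PhantomSpec}.
#' @exportClass RenderedPhantom
setClass("RenderedPhantom",
  representation(
    stack = "MultichannelStack",
    gainField = "matrix",
    spec = "PhantomSpec"
  )
)

setValidity("RenderedPhantom", function(object) {
  if (abs(mean(object@gainField) - 1) > 1e-6)
    return("gainField must have unit mean")
  if (any(object@gainField <= 0)) return("gainField must be positive")
  TRUE
})

#' Trainable voxel classifier
#'
#' A per-channel binary voxel classifier (random forest over a multi-scale
#' image feature bank) trained on fully annotated consecutive z-planes,
#' following the training protocol of segmenting each channel from manual
#' annotation of a small block of consecutive planes.
#'
#' @slot model the fitted random-forest ensemble (an xgboost booster in
#'   random-forest mode: one round of bagged, feature-subsampled trees).
#' @slot channel channel name the classifier was trained for.
#' @slot scales feature scales (sigma, voxels) used to build features.
#' @slot threshold probability threshold for foreground (ties at the
#'   threshold are foreground).
#' @slot trainPlanes z-indices of the annotated planes.
#' @slot seed training seed.
#' @exportClass VoxelClassifier
setClass("VoxelClassifier",
  representation(
    model = "ANY",
    channel = "character",
    scales = "numeric",
    threshold = "numeric",
    trainPlanes = "integer",
    seed = "integer"
  )
)

#' Set of calcium fluorescence traces
#'
#' Per-ROI calcium time series from a keratinocyte / sensory-neurite
#' co-culture recording, with cell-type labels. Raw traces are intensities
#' F(t); \code{\link{normalizeTraces}} converts them to dF = F/F0 with F0
#' the first time point.
#'
#' @slot traces numeric matrix, frames x ROIs; column names are ROI ids.
#' @slot cellType character per ROI, "keratinocyte" or "neurite".
#' @slot samplingRate frames per second (recordings here use 4 Hz).
#' @slot normalized logical; TRUE once traces are dF = F/F0.
#' @exportClass CalciumTraceSet
setClass("CalciumTraceSet",
  representation(
    traces = "matrix",
    cellType = "character",
    samplingRate = "numeric",
    normalized = "logical"
  )
)

setValidity("CalciumTraceSet", function(object) {
  if (ncol(object@traces) != length(object@cellType))
    return("one cellType per trace required")
  if (!all(object@cellType %in% c("keratinocyte", "neurite")))
    return("cellType must be 'keratinocyte' or 'neurite'")
  if (is.null(colnames(object@traces)))
    return("traces must have ROI ids as column names")
  if (object@samplingRate <= 0) return("samplingRate must be positive")
  TRUE
})
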
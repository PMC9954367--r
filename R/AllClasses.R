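#' @useDynLib heteromap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' 3D scalar image volume
#'
#' Minimal container for a 3D scalar image with voxel geometry. Carries the
#' T2-weighted volume, per-b-value diffusion-weighted volumes, ADC maps and
#' filter responses throughout the pipeline. The grid is axis-aligned with
#' origin at the first voxel centre; physical coordinates (mm) of 0-based
#' voxel index i are \code{i * spacing}.
#'
#' @slot data 3D numeric array of voxel values.
#' @slot spacing numeric(3), voxel spacing in mm.
#' @export
setClass("MRIVolume",
  representation(data = "array", spacing = "numeric"),
  validity = function(object) {
    if (length(dim(object@data)) != 3L) return("data must be a 3D array")
    if (length(object@spacing) != 3L) return("spacing must have length 3")
    if (any(object@spacing <= 0)) return("spacing must be positive")
    TRUE
  })

#' Construct an MRIVolume
#'
#' @param data 3D numeric array.
#' @param spacing voxel spacing in mm (length 3).
#' @return An \linkS4class{MRIVolume}.
#' @export
MRIVolume <- function(data, spacing = c(1, 1, 1)) {
  new("MRIVolume", data = data, spacing = as.numeric(spacing))
}

#' Synthetic phantom specification
#'
#' Parameters of the synthetic MRI study generator: grid geometry, an
#' ellipsoidal tumor with spatially structured high- and low-ADC subregions,
#' a monoexponential diffusion signal model over the acquired b-values,
#' T2 contrast and texture parameters, additive Gaussian noise, and the
#' affine + elastic misalignment applied to the DWI/ADC frame.
#'
#' ADC values are in mm^2/s, lengths in mm, b-values in s/mm^2 and signal
#' amplitudes in arbitrary units.
#'
#' @slot shape integer(3), grid size in voxels.
#' @slot spacing numeric(3), voxel spacing in mm.
#' @slot center numeric(3), tumor centre in mm.
#' @slot radii numeric(3), tumor ellipsoid radii in mm.
#' @slot adcBackground background ADC (mm^2/s).
#' @slot adcLow ADC of the low-ADC (highly cellular) subregion.
#' @slot adcHigh ADC of the high-ADC (low-cellularity) subregion.
#' @slot lowFraction fraction of tumor volume assigned to the low-ADC
#'   subregion.
#' @slot subregionScale smoothness (mm) of the random field that shapes the
#'   subregion layout.
#' @slot bValues diffusion weightings acquired (must include 0 and 1200).
#' @slot s0Background,s0Tumor baseline (b = 0) signal amplitudes.
#' @slot t2Background,t2Low,t2High mean T2 intensity of background and of the
#'   low-/high-ADC subregions.
#' @slot t2TextureAmpLow,t2TextureAmpHigh amplitude of the spatially
#'   correlated T2 texture in each subregion.
#' @slot t2TextureScaleLow,t2TextureScaleHigh correlation length (mm) of that
#'   texture.
#' @slot anatomyScale,anatomyAmpT2,anatomyAmpS0 correlation length (mm) and
#'   amplitudes of the shared background anatomy field: one smooth random
#'   field modulates both the background T2 intensity (additively,
#'   \code{anatomyAmpT2}) and the background baseline signal
#'   (multiplicatively, relative amplitude \code{anatomyAmpS0}), giving the
#'   two modalities the spatially correlated background structure real
#'   anatomy provides.
#' @slot noiseSigma additive Gaussian noise sd on T2 and DWI.
#' @slot translation,rotation misalignment translation (mm) and rotation
#'   (degrees, about the through-plane axis order x,y,z).
#' @slot warpAmplitude,warpScale elastic warp amplitude (mm) and smoothness
#'   (mm).
#' @slot seed integer seed fixing every sampled quantity.
#' @export
setClass("PhantomSpec",
  representation(
    shape = "integer", spacing = "numeric",
    center = "numeric", radii = "numeric",
    adcBackground = "numeric", adcLow = "numeric", adcHigh = "numeric",
    lowFraction = "numeric", subregionScale = "numeric",
    bValues = "numeric", s0Background = "numeric", s0Tumor = "numeric",
    t2Background = "numeric", t2Low = "numeric", t2High = "numeric",
    t2TextureAmpLow = "numeric", t2TextureAmpHigh = "numeric",
    t2TextureScaleLow = "numeric", t2TextureScaleHigh = "numeric",
    anatomyScale = "numeric", anatomyAmpT2 = "numeric",
    anatomyAmpS0 = "numeric",
    noiseSigma = "numeric",
    translation = "numeric", rotation = "numeric",
    warpAmplitude = "numeric", warpScale = "numeric",
    seed = "integer"),
  validity = function(object) {
    if (any(object@radii <= 0)) return("tumor radii must be positive")
    if (any(c(object@adcBackground, object@adcLow, object@adcHigh) <= 0))
      return("ADC values must be positive")
    if (object@noiseSigma < 0) return("noise sigma must be >= 0")
    if (any(object@bValues < 0)) return("b-values must be non-negative")
    if (anyDuplicated(object@bValues)) return("b-values must be distinct")
    if (!0 %in% object@bValues || !1200 %in% object@bValues)
      return("b-values must include 0 and 1200")
    if (object@lowFraction <= 0 || object@lowFraction >= 1)
      return("lowFraction must be in (0, 1)")
    TRUE
  })

#' One patient's MRI study bundle
#'
#' Bundles the T2-weighted volume, the DWI series keyed by b-value and the
#' ADC map, together with the alignment state and (for phantoms) ground
#' truth: tumor mask, cellularity labels, and the true misalignment
#' transform.
#'
#' @slot caseId character case identifier.
#' @slot t2 \linkS4class{MRIVolume}, the reference T2-weighted volume.
#' @slot dwi named list of \linkS4class{MRIVolume}, names are b-values.
#' @slot adc \linkS4class{MRIVolume}, ADC map in mm^2/s.
#' @slot aligned logical, whether DWI/ADC are in the T2 frame.
#' @slot truthMask logical array or NULL, ground-truth tumor mask.
#' @slot truthLabels integer array or NULL, ground-truth cellularity codes
#'   (0 background, 1 high, 2 low).
#' @slot trueTransform list, parameters of the applied misalignment.
#' @slot meta list of free-form metadata (alignment RMS report etc).
#' @export
setClass("StudyCase",
  representation(
    caseId = "character", t2 = "MRIVolume", dwi = "list",
    adc = "MRIVolume", aligned = "logical",
    truthMask = "ANY", truthLabels = "ANY",
    trueTransform = "list", meta = "list"),
  validity = function(object) {
    if (!"1200" %in% names(object@dwi))
      return("DWI series must include b = 1200")
    shp <- dim(object@t2@data)
    for (nm in names(object@dwi)) {
      if (!identical(dim(object@dwi[[nm]]@data), shp))
        return(sprintf("DWI b=%s grid differs from T2 grid", nm))
    }
    if (!identical(dim(object@adc@data), shp))
      return("ADC grid differs from T2 grid")
    if (min(object@adc@data) < 0) return("ADC values must be >= 0")
    TRUE
  })

#' Binary tumor mask on the T2 grid
#'
#' @slot mask logical 3D array.
#' @slot spacing numeric(3) voxel spacing (mm).
#' @export
setClass("TumorMask",
  representation(mask = "array", spacing = "numeric"),
  validity = function(object) {
    if (!is.logical(object@mask)) return("mask must be logical")
    if (length(dim(object@mask)) != 3L) return("mask must be 3D")
    TRUE
  })

#' Per-voxel cellularity label map
#'
#' Integer codes: 0 background, 1 high cellularity (ADC below the cut-off),
#' 2 low cellularity, 3 uncertain (inside the optional uncertain ADC band).
#'
#' @slot labels integer 3D array of codes.
#' @slot cutoff ADC cut-off (mm^2/s) used for the high class.
#' @slot band numeric(2) or NULL, uncertain ADC band.
#' @export
setClass("CellularityLabelMap",
  representation(labels = "array", cutoff = "numeric", band = "ANY"),
  validity = function(object) {
    if (!all(object@labels %in% 0:3)) return("labels must be codes 0..3")
    if (object@cutoff <= 0) return("cutoff must be positive")
    TRUE
  })

#' Affine transform (fixed -> moving coordinates, mm)
#'
#' @slot matrix 3x3 linear part.
#' @slot translation numeric(3), mm.
#' @slot center numeric(3), centre of rotation in mm.
#' @slot converged logical, FALSE when the optimizer hit its iteration cap
#'   or the metric was degenerate.
#' @slot trace data.frame optimizer trace (iteration, metric).
#' @export
setClass("AffineTransform",
  representation(matrix = "matrix", translation = "numeric",
                 center = "numeric", converged = "logical",
                 trace = "data.frame"),
  validity = function(object) {
    if (!all(dim(object@matrix) == c(3, 3))) return("matrix must be 3x3")
    if (abs(det(object@matrix)) < 1e-12) return("matrix must be invertible")
    TRUE
  })

#' Dense deformation field on the reference grid
#'
#' @slot field 4D array (x, y, z, 3) of displacements in mm on the
#'   reference grid.
#' @slot spacing numeric(3) voxel spacing (mm).
#' @slot trace data.frame of per-iteration RMS intensity difference.
#' @slot converged logical.
#' @export
setClass("DeformationField",
  representation(field = "array", spacing = "numeric",
                 trace = "data.frame", converged = "logical"),
  validity = function(object) {
    d <- dim(object@field)
    if (length(d) != 4L || d[4] != 3L) return("field must be (x,y,z,3)")
    if (!all(is.finite(object@field))) return("field must be finite")
    TRUE
  })

#' Per-pixel radiomic feature matrix
#'
#' Rows are tumor pixels (grouped into blocks of at most \code{blockSize}),
#' columns are named radiomic features. Row metadata carries the case id,
#' slice, in-slice coordinates, block index and the binary cellularity label
#' (1 = high, 0 = low).
#'
#' @slot features numeric matrix, rows = pixels, columns = features.
#' @slot info data.frame with columns case, slice, y, x, block, label.
#' @slot blockSize integer, pixels per prediction block.
#' @export
setClass("PixelFeatureMatrix",
  representation(features = "matrix", info = "data.frame",
                 blockSize = "integer"),
  validity = function(object) {
    if (nrow(object@features) != nrow(object@info))
      return("features and info must have the same number of rows")
    need <- c("case", "slice", "y", "x", "block", "label")
    if (!all(need %in% names(object@info)))
      return(paste("info must have columns:", paste(need, collapse = ", ")))
    if (anyNA(object@features) || any(!is.finite(object@features)))
      return("features must be finite and non-missing")
    TRUE
  })

#' Result of recursive feature elimination with cross-validation
#'
#' @slot ranking character, features in elimination order (first eliminated
#'   first; the strongest survivors last).
#' @slot selected character, the chosen subset.
#' @slot cvScores data.frame with columns size and score (mean CV balanced
#'   accuracy at each subset size).
#' @slot estimator character, estimator kind used for ranking.
#' @export
setClass("SelectionResult",
  representation(ranking = "character", selected = "character",
                 cvScores = "data.frame", estimator = "character"),
  validity = function(object) {
    if (!all(object@selected %in% object@ranking))
      return("selected must be a subset of ranking")
    sc <- object@cvScores$score
    if (length(sc) && (min(sc) < 0 || max(sc) > 1))
      return("CV scores must lie in [0, 1]")
    TRUE
  })

#' Trained linear classifier (SVM or SGD)
#'
#' @slot kind "svm" or "sgd".
#' @slot featureNames selected feature names, in weight order.
#' @slot weights numeric weight vector.
#' @slot intercept numeric scalar.
#' @slot center,scale feature standardization parameters fitted on training
#'   data only.
#' @slot config list of training configuration.
#' @export
setClass("TrainedClassifier",
  representation(kind = "character", featureNames = "character",
                 weights = "numeric", intercept = "numeric",
                 center = "numeric", scale = "numeric", config = "list"),
  validity = function(object) {
    if (!object@kind %in% c("svm", "sgd")) return("kind must be svm or sgd")
    if (length(object@weights) != length(object@featureNames))
      return("weights length must match featureNames")
    TRUE
  })

#' Leave-one-patient-out evaluation report
#'
#' @slot perCase data.frame, one row per held-out case with accuracy,
#'   balanced accuracy, sensitivity and specificity per estimator kind.
#' @slot summary data.frame with the cohort averages and standard
#'   deviations (undefined per-case metrics excluded).
#' @slot notes character log of degenerate cases.
#' @export
setClass("EvalReport",
  representation(perCase = "data.frame", summary = "data.frame",
                 notes = "character"))
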
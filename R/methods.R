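#' @describeIn MRIVolume-class voxel data array
#' @param object,x an object of the documented class
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))
#' @export
setMethod("volData", "MRIVolume", function(x) x@data)

#' @describeIn MRIVolume-class voxel spacing in mm
#' @export
setGeneric("volSpacing", function(x) standardGeneric("volSpacing"))
#' @export
setMethod("volSpacing", "MRIVolume", function(x) x@spacing)

#' @export
setMethod("dim", "MRIVolume", function(x) dim(x@data))

setMethod("show", "MRIVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("MRIVolume %dx%dx%d voxels, spacing %s mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3],
              paste(format(object@spacing), collapse = "x"),
              min(object@data), max(object@data)))
})

#' @describeIn StudyCase-class case identifier
#' @export
setGeneric("caseId", function(x) standardGeneric("caseId"))
#' @export
setMethod("caseId", "StudyCase", function(x) x@caseId)

#' @describeIn StudyCase-class the reference T2-weighted volume
#' @export
setGeneric("t2Volume", function(x) standardGeneric("t2Volume"))
#' @export
setMethod("t2Volume", "StudyCase", function(x) x@t2)

#' @describeIn StudyCase-class DWI volume for one b-value
#' @param b diffusion weighting (s/mm^2)
#' @export
setGeneric("dwiVolume", function(x, b) standardGeneric("dwiVolume"))
#' @export
setMethod("dwiVolume", "StudyCase", function(x, b = 1200) {
  key <- as.character(b)
  if (!key %in% names(x@dwi))
    stop("no DWI series for b = ", b, "; available: ",
         paste(names(x@dwi), collapse = ", "))
  x@dwi[[key]]
})

#' @describeIn StudyCase-class ADC map volume
#' @export
setGeneric("adcVolume", function(x) standardGeneric("adcVolume"))
#' @export
setMethod("adcVolume", "StudyCase", function(x) x@adc)

#' @describeIn StudyCase-class TRUE once DWI/ADC are in the T2 frame
#' @export
setGeneric("isAligned", function(x) standardGeneric("isAligned"))
#' @export
setMethod("isAligned", "StudyCase", function(x) x@aligned)

#' @describeIn StudyCase-class acquired b-values (numeric)
#' @export
setGeneric("bValues", function(x) standardGeneric("bValues"))
#' @export
setMethod("bValues", "StudyCase", function(x) as.numeric(names(x@dwi)))

setMethod("show", "StudyCase", function(object) {
  cat(sprintf("StudyCase '%s': %s, b-values {%s}, %s\n",
              object@caseId,
              paste(dim(object@t2@data), collapse = "x"),
              paste(names(object@dwi), collapse = ", "),
              if (object@aligned) "aligned" else "raw"))
  if (!is.null(object@truthMask))
    cat(sprintf("  ground truth attached (%d tumor voxels)\n",
                sum(object@truthMask)))
})

#' @describeIn TumorMask-class logical mask array
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))
#' @export
setMethod("maskArray", "TumorMask", function(x) x@mask)

#' @describeIn TumorMask-class number of voxels in the mask
#' @export
setGeneric("voxelCount", function(x) standardGeneric("voxelCount"))
#' @export
setMethod("voxelCount", "TumorMask", function(x) sum(x@mask))

setMethod("show", "TumorMask", function(object) {
  cat(sprintf("TumorMask: %d voxels on a %s grid\n", sum(object@mask),
              paste(dim(object@mask), collapse = "x")))
})

#' @describeIn CellularityLabelMap-class integer label code array
#' @export
setGeneric("labelArray", function(x) standardGeneric("labelArray"))
#' @export
setMethod("labelArray", "CellularityLabelMap", function(x) x@labels)

#' @describeIn CellularityLabelMap-class ADC cut-off used (mm^2/s)
#' @export
setGeneric("adcCutoff", function(x) standardGeneric("adcCutoff"))
#' @export
setMethod("adcCutoff", "CellularityLabelMap", function(x) x@cutoff)

setMethod("show", "CellularityLabelMap", function(object) {
  tab <- tabulate(object@labels + 1L, nbins = 4L)
  cat(sprintf(paste0("CellularityLabelMap (cutoff %.3g mm^2/s): ",
                     "%d high, %d low, %d uncertain, %d background\n"),
              object@cutoff, tab[2], tab[3], tab[4], tab[1]))
})

#' @describeIn PixelFeatureMatrix-class feature value matrix
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @export
setMethod("featureValues", "PixelFeatureMatrix", function(x) x@features)

#' @describeIn PixelFeatureMatrix-class per-pixel row metadata
#' @export
setGeneric("featureInfo", function(x) standardGeneric("featureInfo"))
#' @export
setMethod("featureInfo", "PixelFeatureMatrix", function(x) x@info)

#' @describeIn PixelFeatureMatrix-class feature (column) names
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))
#' @export
setMethod("featureNames", "PixelFeatureMatrix",
          function(x) colnames(x@features))

#' @export
setMethod("dim", "PixelFeatureMatrix", function(x) dim(x@features))

setMethod("show", "PixelFeatureMatrix", function(object) {
  cat(sprintf(paste0("PixelFeatureMatrix: %d pixels x %d features, ",
                     "%d case(s), %d block(s) of <= %d\n"),
              nrow(object@features), ncol(object@features),
              length(unique(object@info$case)),
              length(unique(paste(object@info$case, object@info$block))),
              object@blockSize))
})

#' @describeIn SelectionResult-class names of the selected features
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))
#' @export
setMethod("selectedFeatures", "SelectionResult", function(x) x@selected)

#' @describeIn SelectionResult-class CV score per candidate subset size
#' @export
setGeneric("cvScores", function(x) standardGeneric("cvScores"))
#' @export
setMethod("cvScores", "SelectionResult", function(x) x@cvScores)

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult (%s): %d of %d features selected\n",
              object@estimator, length(object@selected),
              length(object@ranking)))
  best <- object@cvScores[which.max(object@cvScores$score), , drop = FALSE]
  if (nrow(best))
    cat(sprintf("  best CV balanced accuracy %.3f at size %d\n",
                best$score[1], best$size[1]))
})

setMethod("show", "TrainedClassifier", function(object) {
  cat(sprintf("TrainedClassifier (%s): %d features\n",
              object@kind, length(object@weights)))
})

#' @describeIn EvalReport-class per-case metric rows
#' @export
setGeneric("perCaseMetrics", function(x) standardGeneric("perCaseMetrics"))
#' @export
setMethod("perCaseMetrics", "EvalReport", function(x) x@perCase)

#' @describeIn EvalReport-class cohort averages and standard deviations
#' @export
setGeneric("summaryMetrics", function(x) standardGeneric("summaryMetrics"))
#' @export
setMethod("summaryMetrics", "EvalReport", function(x) x@summary)

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport (leave-one-patient-out)\n")
  print(object@perCase, digits = 3)
  cat("--\n")
  print(object@summary, digits = 3)
  if (length(object@notes)) cat("notes:", object@notes, sep = "\n  ")
})
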
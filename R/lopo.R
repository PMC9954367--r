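#' Full pipeline configuration
#'
#' Collects the stage configurations of the end-to-end pipeline:
#' registration, K-means segmentation, ADC-threshold labeling, feature
#' extraction, recursive feature elimination and classifier training.
#'
#' @param cutoff ADC cut-off (mm^2/s) defining the highly cellular class.
#' @param uncertainBand optional ADC band labelled uncertain (for
#'   visualization; binary training labels ignore it).
#' @param k K-means cluster count for tumor detection.
#' @param affine,demons registration settings.
#' @param feature feature-extraction settings.
#' @param rfe list: nFolds, step, maxRows for \code{\link{rfeCV}}.
#' @param classifier classifier settings.
#' @param seed master seed; all stage seeds derive from it.
#' @return List of settings.
#' @export
pipelineConfig <- function(cutoff = 0.85e-3, uncertainBand = NULL,
                           k = 2L,
                           affine = affineConfig(),
                           demons = demonsConfig(maxit = 3L,
                                                 sigmaField = 12),
                           feature = featureConfig(),
                           rfe = list(nFolds = 3L, step = 0.1,
                                      maxRows = 1200L),
                           classifier = classifierConfig(), seed = 1L) {
  list(cutoff = cutoff, uncertainBand = uncertainBand, k = as.integer(k),
       affine = affine, demons = demons, feature = feature, rfe = rfe,
       classifier = classifier, seed = as.integer(seed))
}

#' Process one study case to a per-pixel feature matrix
#'
#' Runs alignment (if the case is raw), K-means tumor segmentation on the
#' b = 1200 DWI volume, ADC-threshold labeling, ROI extraction and
#' per-pixel radiomic feature extraction.
#'
#' @param case a \linkS4class{StudyCase}.
#' @param config see \code{\link{pipelineConfig}}.
#' @return A \linkS4class{PixelFeatureMatrix}; the segmentation mask,
#'   label map and crop offset are attached as attributes \code{"mask"},
#'   \code{"labels"} and \code{"offset"}.
#' @export
processCase <- function(case, config = pipelineConfig()) {
  if (!isAligned(case))
    case <- alignStudy(case, config$affine, config$demons)
  mask <- segmentTumorKmeans(dwiVolume(case, 1200), k = config$k,
                             seed = deriveSeed(config$seed, 3L))
  labels <- labelCellularity(adcVolume(case), mask, cutoff = config$cutoff,
                             uncertainBand = config$uncertainBand)
  roi <- extractRoi(t2Volume(case), mask)
  off <- roi$offset
  d <- dim(roi$roi@data)
  croppedLabels <- new("CellularityLabelMap",
                       labels = labels@labels[off[1] + seq_len(d[1]),
                                              off[2] + seq_len(d[2]),
                                              off[3] + seq_len(d[3]),
                                              drop = FALSE],
                       cutoff = labels@cutoff, band = labels@band)
  fm <- pixelFeatureMatrix(roi$roi, roi$mask, croppedLabels,
                           config$feature, caseId = caseId(case))
  attr(fm, "mask") <- mask
  attr(fm, "labels") <- labels
  attr(fm, "offset") <- off
  fm
}

#' Leave-one-patient-out evaluation
#'
#' For each case in turn: the remaining cases' pixels form the training
#' set, constant features are removed, an optimal subset is selected by
#' recursive feature elimination with grouped cross-validation, SVM and
#' SGD classifiers are trained on it, and the held-out case's pixels are
#' predicted block-wise and scored against its ADC-derived labels.
#' Undefined per-case metrics (zero denominators) are reported as missing
#' and excluded from the averages, with a note.
#'
#' @param cohort list of \linkS4class{StudyCase} (processed internally) or
#'   of \linkS4class{PixelFeatureMatrix} (already processed).
#' @param config see \code{\link{pipelineConfig}}.
#' @param kinds estimator kinds to train (default both).
#' @return An \linkS4class{EvalReport}.
#' @export
lopoEvaluate <- function(cohort, config = pipelineConfig(),
                         kinds = c("svm", "sgd")) {
  if (length(cohort) < 2) stop("leave-one-patient-out needs >= 2 cases")
  fms <- lapply(cohort, function(x) {
    if (is(x, "StudyCase")) processCase(x, config) else x
  })
  notes <- character(0)
  rows <- list()
  for (i in seq_along(fms)) {
    train <- removeConstantFeatures(bindFeatureMatrices(fms[-i]))
    sel <- rfeCV(train, estimator = "svm", nFolds = config$rfe$nFolds,
                 step = config$rfe$step, seed = deriveSeed(config$seed, i),
                 config = config$classifier, maxRows = config$rfe$maxRows)
    test <- fms[[i]]
    row <- list(case = featureInfo(test)$case[1],
                n = nrow(featureValues(test)),
                n_features = length(selectedFeatures(sel)))
    for (kind in kinds) {
      model <- trainClassifier(train, kind, config$classifier,
                               seed = deriveSeed(config$seed, 1000L + i),
                               features = selectedFeatures(sel))
      pred <- predictBlocks(model, test)
      m <- classificationMetrics(
        confusionCounts(pred, featureInfo(test)$label))
      if (anyNA(m))
        notes <- c(notes, sprintf(
          "case %s (%s): undefined %s excluded from averages",
          row$case, kind,
          paste(names(m)[is.na(m)], collapse = "/")))
      names(m) <- paste(kind, names(m), sep = "_")
      row <- c(row, as.list(m))
    }
    rows[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  perCase <- do.call(rbind, rows)
  metricCols <- setdiff(names(perCase), c("case", "n", "n_features"))
  summary <- data.frame(
    statistic = c("average", "std_dev"),
    rbind(vapply(perCase[metricCols], mean, numeric(1), na.rm = TRUE),
          vapply(perCase[metricCols], stats::sd, numeric(1), na.rm = TRUE)))
  names(summary) <- c("statistic", metricCols)
  new("EvalReport", perCase = perCase, summary = summary, notes = notes)
}
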
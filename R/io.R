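#' Write a study case to disk
#'
#' One NIfTI file per volume (T2, each DWI b-value, ADC, optional ground
#' truth) plus a JSON sidecar holding the case id, b-values, alignment
#' state and (for phantoms) the true misalignment parameters.
#'
#' @param case a \linkS4class{StudyCase}.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
writeStudy <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- case@t2@spacing
  wr <- function(arr, name)
    RNifti::writeNifti(RNifti::asNifti(arr, pixdim = sp),
                       file.path(dir, paste0(name, ".nii.gz")))
  wr(case@t2@data, "t2")
  for (b in names(case@dwi)) wr(case@dwi[[b]]@data, paste0("dwi_b", b))
  wr(case@adc@data, "adc")
  sidecar <- list(caseId = case@caseId,
                  bValues = as.numeric(names(case@dwi)),
                  spacing = sp, aligned = case@aligned,
                  hasTruth = !is.null(case@truthMask))
  if (!is.null(case@truthMask)) {
    wr(array(as.integer(case@truthMask), dim(case@truthMask)), "truth_mask")
    wr(case@truthLabels, "truth_labels")
  }
  if (length(case@trueTransform))
    sidecar$trueTransform <- list(
      rotation = case@trueTransform$rotation,
      translation = case@trueTransform$translation)
  jsonlite::write_json(sidecar, file.path(dir, "study.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a study case from disk
#'
#' Reads the NIfTI volumes and JSON sidecar written by
#' \code{\link{writeStudy}}. Validates that a b = 1200 series is present
#' and that all volumes share the T2 grid; if no ADC map is found it is
#' fitted from the DWI series with \code{\link{computeAdc}} (with a
#' message).
#'
#' @param dir study directory.
#' @return A \linkS4class{StudyCase}.
#' @export
readStudy <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "study.json"),
                                 simplifyVector = TRUE)
  sp <- as.numeric(sidecar$spacing)
  rd <- function(name) {
    arr <- as.array(RNifti::readNifti(file.path(dir, paste0(name, ".nii.gz"))))
    MRIVolume(array(as.numeric(arr), dim(arr)), sp)
  }
  t2 <- rd("t2")
  if (!1200 %in% sidecar$bValues)
    stop("study lacks the b = 1200 DWI series")
  dwi <- list()
  for (b in sidecar$bValues) {
    v <- rd(paste0("dwi_b", b))
    if (!identical(dim(v@data), dim(t2@data)))
      stop(sprintf("grid mismatch: T2 is %s but DWI b=%s is %s",
                   paste(dim(t2@data), collapse = "x"), b,
                   paste(dim(v@data), collapse = "x")))
    dwi[[as.character(b)]] <- v
  }
  adcFile <- file.path(dir, "adc.nii.gz")
  adc <- if (file.exists(adcFile)) rd("adc") else {
    message("no ADC map found; fitting one from the DWI series")
    computeAdc(dwi)
  }
  if (!identical(dim(adc@data), dim(t2@data)))
    stop(sprintf("grid mismatch: T2 is %s but ADC is %s",
                 paste(dim(t2@data), collapse = "x"),
                 paste(dim(adc@data), collapse = "x")))
  truthMask <- NULL; truthLabels <- NULL
  if (isTRUE(sidecar$hasTruth)) {
    truthMask <- as.array(RNifti::readNifti(
      file.path(dir, "truth_mask.nii.gz"))) > 0
    truthLabels <- array(as.integer(as.array(RNifti::readNifti(
      file.path(dir, "truth_labels.nii.gz")))), dim(truthMask))
  }
  trueTransform <- if (!is.null(sidecar$trueTransform))
    lapply(sidecar$trueTransform, as.numeric) else list()
  new("StudyCase", caseId = sidecar$caseId, t2 = t2, dwi = dwi, adc = adc,
      aligned = isTRUE(sidecar$aligned), truthMask = truthMask,
      truthLabels = truthLabels, trueTransform = trueTransform,
      meta = list())
}

overlayColors <- list(high = c(1, 0, 0), low = c(0, 0, 1),
                      uncertain = c(1, 1, 0))

overlaySlice <- function(t2s, labs, alpha = 0.5) {
  rng <- range(t2s)
  g <- if (diff(rng) > 0) (t2s - rng[1]) / diff(rng) else t2s * 0
  rgb <- array(rep(g, 3), dim = c(dim(t2s), 3))
  for (code in 1:3) {
    sel <- labs == code
    if (!any(sel)) next
    col <- overlayColors[[code]]
    for (ch in 1:3)
      rgb[, , ch][sel] <- (1 - alpha) * g[sel] + alpha * col[ch]
  }
  rgb
}

#' Export per-slice overlay images
#'
#' Writes one PNG per slice with the cellularity classes painted over the
#' grayscale T2: red = highly cellular, blue = low cellularity, yellow =
#' uncertain. With predictions supplied, a side-by-side panel shows the
#' ADC-derived truth (left) and the classifier output (right). A JSON
#' color-code table is written alongside.
#'
#' @param t2 \linkS4class{MRIVolume}.
#' @param labels \linkS4class{CellularityLabelMap} on the same grid.
#' @param pred optional integer array of predicted codes on the same grid.
#' @param dir output directory.
#' @return Character vector of written files, invisibly.
#' @export
exportOverlay <- function(t2, labels, pred = NULL, dir) {
  stopifnot(identical(dim(t2@data), dim(labels@labels)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (all(labels@labels == 0))
    warning("label map is all background; writing grayscale images only")
  files <- character(0)
  for (k in seq_len(dim(t2@data)[3])) {
    panel <- overlaySlice(t2@data[, , k], labels@labels[, , k])
    if (!is.null(pred)) {
      right <- overlaySlice(t2@data[, , k], pred[, , k])
      d <- dim(panel)
      both <- array(0, c(d[1], 2 * d[2], 3))
      both[, seq_len(d[2]), ] <- panel
      both[, d[2] + seq_len(d[2]), ] <- right
      panel <- both
    }
    f <- file.path(dir, sprintf("slice_%03d.png", k))
    png::writePNG(aperm(panel, c(2, 1, 3)), f)
    files <- c(files, f)
  }
  cmap <- file.path(dir, "colors.json")
  jsonlite::write_json(
    list(high = "red", low = "blue", uncertain = "yellow",
         background = "grayscale"), cmap, auto_unbox = TRUE)
  invisible(c(files, cmap))
}
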
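#' Accessors for karyotypeR classes
#'
#' @param object,x a karyotypeR object.
#' @param ... ignored.
#' @name accessors
NULL

#' @describeIn accessors Per-chromosome counts (named integer, 24 entries).
#' @export
setGeneric("counts", function(object, ...) standardGeneric("counts"))

#' @describeIn accessors Sample identifier.
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @describeIn accessors Total retained read count.
#' @export
setGeneric("nTotal", function(object) standardGeneric("nTotal"))

#' @describeIn accessors Calibration/run mode ("shotgun" or "capture").
#' @export
setGeneric("calibrationMode", function(object) standardGeneric("calibrationMode"))

#' @describeIn accessors Named per-copy mass vector of a calibration.
#' @export
setGeneric("perCopyMass", function(object) standardGeneric("perCopyMass"))

#' Theoretical ratio centroid for k copies
#'
#' The expected ratio value \eqn{r(k) = k\,e_c/(2\Sigma_A)} for \code{k}
#' copies of the axis chromosome under a calibration, where
#' \eqn{\Sigma_A} is the summed per-copy mass of the 19 baseline
#' autosomes.
#'
#' @param calib a [CalibrationTable-class].
#' @param axis \code{"X"} or \code{"Y"} (or any canonical chromosome
#'   label, for autosomal expectations).
#' @param k integer copy number (vectorised).
#' @return Numeric vector of centroids, one per element of \code{k}.
#' @examples
#' cal <- builtinCalibration("shotgun")
#' centroid(cal, "X", 1:2)   # 0.028, 0.056
#' centroid(cal, "Y", 1)     # 0.0026
#' @export
setGeneric("centroid", function(calib, axis, k) standardGeneric("centroid"))

setMethod("counts", "ChromCountTable", function(object, ...) object@counts)
setMethod("sampleId", "ChromCountTable", function(object) object@sampleId)
setMethod("nTotal", "ChromCountTable", function(object) sum(object@counts))
setMethod("sampleId", "ChromCopyProfile", function(object) object@sampleId)
setMethod("sampleId", "KaryotypeCall", function(object) object@sampleId)
setMethod("calibrationMode", "CalibrationTable", function(object) object@mode)
setMethod("perCopyMass", "CalibrationTable", function(object) object@perCopyMass)

#' @describeIn accessors MAPQ filter recorded on a count table.
#' @export
mapqMin <- function(object) object@mapqMin

#' @describeIn accessors Whether a region mask restricted the counting.
#' @export
maskApplied <- function(object) object@maskApplied

#' @describeIn accessors Ratio value of a RatioEstimate.
#' @export
ratioValue <- function(object) object@value

#' @describeIn accessors Standard error of a RatioEstimate or CopyCall.
#' @export
ratioSE <- function(object) object@se

#' @describeIn accessors Copy-number estimate of a CopyCall.
#' @export
kHat <- function(object) object@kHat

#' @describeIn accessors Status ("confident"/"uncertain") of a CopyCall.
#' @export
callStatus <- function(object) object@status

#' @describeIn accessors Signed z-score to the assigned centroid.
#' @export
zToCentroid <- function(object) object@z

#' @describeIn accessors ISCN karyotype string of a KaryotypeCall.
#' @export
iscn <- function(object) object@iscn

#' @describeIn accessors Quality flags of a KaryotypeCall.
#' @export
callFlags <- function(object) object@flags

#' @describeIn accessors Trisomy set of a KaryotypeCall.
#' @export
trisomies <- function(object) object@trisomies

#' @describeIn accessors Per-chromosome profile data.frame.
#' @export
profileTable <- function(object) object@profile

#' @describeIn accessors Per-replicate results of a PowerResult.
#' @export
powerReplicates <- function(object) object@replicates

#' @describeIn accessors Per-level summary of a PowerResult.
#' @export
powerSummary <- function(object) object@summary
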
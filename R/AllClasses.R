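#' @import methods
NULL

#' Canonical chromosome labels
#'
#' The 24 canonical human nuclear chromosome labels used throughout the
#' package: \code{"1"}--\code{"22"}, \code{"X"}, \code{"Y"}.
#' Mitochondria, decoys and unplaced contigs are never part of this set.
#'
#' @return Character vector of length 24.
#' @examples
#' canonicalChromosomes()
#' @export
canonicalChromosomes <- function() c(as.character(1:22), "X", "Y")

#' Autosomal baseline chromosomes
#'
#' The 19 autosomes entering the baseline denominator \eqn{N_a}:
#' chromosomes 1--22 excluding 13, 18 and 21.  The excluded three are the
#' only autosomal trisomies compatible with live birth, so the baseline
#' remains euploid even in affected individuals.
#'
#' @return Character vector of length 19.
#' @examples
#' baselineChromosomes()
#' @export
baselineChromosomes <- function()
    setdiff(as.character(1:22), c("13", "18", "21"))

.zeroCounts <- function() {
    x <- integer(24L)
    names(x) <- canonicalChromosomes()
    x
}

#' ChromCountTable: per-chromosome aligned-read counts for one sample
#'
#' The method's sole data input: the number of quality-filtered primary
#' alignments on each of the 24 canonical chromosomes.  Counts exclude
#' unmapped, secondary, supplementary and duplicate-flagged records;
#' chromosomes absent from the input are zero-filled so all 24 labels are
#' always present.
#'
#' @slot sampleId character(1) sample identifier.
#' @slot counts named integer(24), non-negative, names
#'   \code{canonicalChromosomes()} in order.
#' @slot mapqMin integer(1), the minimum mapping quality applied upstream.
#' @slot maskApplied logical(1), whether counting was restricted to a
#'   region mask.
#'
#' @seealso [chromCountTable()], [countAlignments()], [readCountTable()]
#' @aliases ChromCountTable
#' @export
setClass("ChromCountTable",
    representation(
        sampleId = "character",
        counts = "integer",
        mapqMin = "integer",
        maskApplied = "logical"
    )
)

setValidity("ChromCountTable", function(object) {
    msg <- NULL
    if (length(object@sampleId) != 1L)
        msg <- c(msg, "sampleId must be a single string")
    if (!identical(names(object@counts), canonicalChromosomes()))
        msg <- c(msg, "counts must be named by the 24 canonical chromosomes in order")
    if (anyNA(object@counts) || any(object@counts < 0L))
        msg <- c(msg, "counts must be non-negative and non-missing")
    if (length(object@mapqMin) != 1L || is.na(object@mapqMin) || object@mapqMin < 0L)
        msg <- c(msg, "mapqMin must be a single non-negative integer")
    if (length(object@maskApplied) != 1L || is.na(object@maskApplied))
        msg <- c(msg, "maskApplied must be TRUE or FALSE")
    if (is.null(msg)) TRUE else msg
})

#' Construct a ChromCountTable
#'
#' @param counts named numeric/integer vector of per-chromosome counts.
#'   Names are normalised via [normalizeContigName()]; entries on
#'   non-canonical contigs are dropped; missing chromosomes are
#'   zero-filled.
#' @param sampleId sample identifier.
#' @param mapqMin the mapping-quality filter the counts reflect.
#' @param maskApplied whether the counts were restricted to a region mask.
#' @return A [ChromCountTable-class] object.
#' @examples
#' tab <- chromCountTable(c(chr1 = 90, X = 10), sampleId = "s1")
#' counts(tab)[["X"]]
#' nTotal(tab)
#' @export
chromCountTable <- function(counts, sampleId = "sample",
                            mapqMin = 30L, maskApplied = FALSE) {
    if (is.null(names(counts)))
        stop("'counts' must be a named vector")
    canon <- vapply(names(counts), normalizeContigName, character(1))
    keep <- !is.na(canon)
    counts <- counts[keep]
    canon <- canon[keep]
    full <- .zeroCounts()
    for (i in seq_along(counts)) {
        v <- counts[[i]]
        if (is.na(v) || v < 0)
            stop("negative or missing count for chromosome ", canon[i])
        full[[canon[i]]] <- full[[canon[i]]] + as.integer(v)
    }
    new("ChromCountTable", sampleId = as.character(sampleId), counts = full,
        mapqMin = as.integer(mapqMin), maskApplied = isTRUE(maskApplied))
}

#' CalibrationTable: per-chromosome per-copy effective alignment mass
#'
#' Holds, for each canonical chromosome, the effective alignable mass
#' contributed by a single copy of that chromosome, on an arbitrary common
#' scale.  Effective mass is not sequence length: mapping-quality
#' filtering and repeat content shrink it, drastically so for chromosome
#' Y.  The table derives the theoretical centroids against which observed
#' ratios are classified:
#' \deqn{r_X(k) = k\,e_X / (2 \Sigma_A), \quad r_Y(k) = k\,e_Y / (2 \Sigma_A)}
#' where \eqn{\Sigma_A} sums per-copy masses over the 19 baseline
#' autosomes.
#'
#' @slot mode character(1), \code{"shotgun"} or \code{"capture"}.
#' @slot perCopyMass named numeric(24), strictly positive.
#'
#' @seealso [builtinCalibration()], [centroid()], [calibrateFromCohort()]
#' @aliases CalibrationTable
#' @export
setClass("CalibrationTable",
    representation(mode = "character", perCopyMass = "numeric")
)

setValidity("CalibrationTable", function(object) {
    msg <- NULL
    if (!object@mode %in% c("shotgun", "capture"))
        msg <- c(msg, "mode must be 'shotgun' or 'capture'")
    if (!identical(names(object@perCopyMass), canonicalChromosomes()))
        msg <- c(msg, "perCopyMass must be named by the 24 canonical chromosomes in order")
    if (anyNA(object@perCopyMass) || any(object@perCopyMass <= 0))
        msg <- c(msg, "all per-copy masses must be > 0")
    if (is.null(msg)) TRUE else msg
})

#' RatioEstimate: a chromosome ratio with binomial-approximation error
#'
#' The ratio of a chromosome's read count to the autosomal baseline
#' (e.g. Rx, Ry or a per-chromosome Rc), with a delta-method standard
#' error computed on the underlying binomial proportion.
#'
#' @slot value numeric(1), the ratio \eqn{n_c / N_a} (0 when \eqn{n_c=0}).
#' @slot se numeric(1), delta-method standard error, always > 0 when
#'   \eqn{N_a > 0} (a 0.5 pseudocount on both counts keeps zero
#'   numerators informative).
#' @slot nC integer(1) numerator count.
#' @slot nA integer(1) denominator count (\eqn{N_a}).
#'
#' @seealso [ratioEstimate()]
#' @aliases RatioEstimate
#' @export
setClass("RatioEstimate",
    representation(value = "numeric", se = "numeric",
                   nC = "integer", nA = "integer")
)

setValidity("RatioEstimate", function(object) {
    msg <- NULL
    if (object@value < 0) msg <- c(msg, "value must be >= 0")
    if (object@se < 0) msg <- c(msg, "se must be >= 0")
    if (object@nC < 0L || object@nA < 0L) msg <- c(msg, "counts must be >= 0")
    if (object@nA > 0L && !isTRUE(all.equal(object@value, object@nC / object@nA)))
        msg <- c(msg, "value must equal nC/nA")
    if (is.null(msg)) TRUE else msg
})

#' CopyCall: an integer copy-number assignment for one sex chromosome
#'
#' The result of classifying a ratio estimate against the calibrated
#' centroids of one axis (X or Y): the nearest-centroid copy number, a
#' confidence status, the signed z-score to the assigned centroid, and an
#' estimated mosaic fraction when the mosaicism criteria are met.
#'
#' @slot axis character(1), \code{"X"} or \code{"Y"}.
#' @slot kHat integer(1) copy estimate (X in 0..3, Y in 0..2).
#' @slot status character(1), \code{"confident"} or \code{"uncertain"}.
#' @slot z numeric(1), \eqn{(value - r(\hat k))/se}; signed.
#' @slot value,se numeric(1), the classified ratio and its standard error.
#' @slot mosaicFraction numeric(1), estimated fraction of the adjacent
#'   karyotype when the call is a mosaic candidate; \code{NA} otherwise.
#'
#' @seealso [assignCopies()], [mosaicCandidate()]
#' @aliases CopyCall
#' @export
setClass("CopyCall",
    representation(axis = "character", kHat = "integer", status = "character",
                   z = "numeric", value = "numeric", se = "numeric",
                   mosaicFraction = "numeric")
)

setValidity("CopyCall", function(object) {
    msg <- NULL
    if (!object@axis %in% c("X", "Y")) msg <- c(msg, "axis must be 'X' or 'Y'")
    if (!object@status %in% c("confident", "uncertain"))
        msg <- c(msg, "status must be 'confident' or 'uncertain'")
    kmax <- if (object@axis == "X") 3L else 2L
    if (object@kHat < 0L || object@kHat > kmax)
        msg <- c(msg, sprintf("kHat out of range 0..%d for axis %s", kmax, object@axis))
    if (is.null(msg)) TRUE else msg
})

#' KaryotypeCall: the full inferred karyotype for one sample
#'
#' Composes the X and Y copy calls, the autosomal trisomy scan, the
#' ISCN-style karyotype string and quality flags, together with the
#' underlying ratio evidence.
#'
#' @slot sampleId character(1).
#' @slot xCall,yCall [CopyCall-class] for the X and Y axes.
#' @slot rx,ry [RatioEstimate-class] for Rx and Ry.
#' @slot na integer(1), the autosomal baseline count \eqn{N_a}.
#' @slot nTotal integer(1), total retained reads.
#' @slot trisomies character vector, subset of \code{c("13","18","21")}.
#' @slot iscn character(1), e.g. \code{"47,XXY"}, \code{"45,X0"},
#'   \code{"47,XY,+21"}; \code{"NA"} when either sex axis is uncertain.
#' @slot flags character vector, subset of
#'   \code{c("contamination_suspect","mosaic_candidate","low_count","uncertain")}.
#'
#' @seealso [callKaryotype()]
#' @aliases KaryotypeCall
#' @export
setClass("KaryotypeCall",
    representation(sampleId = "character",
                   xCall = "CopyCall", yCall = "CopyCall",
                   rx = "RatioEstimate", ry = "RatioEstimate",
                   na = "integer", nTotal = "integer",
                   trisomies = "character", iscn = "character",
                   flags = "character")
)

setValidity("KaryotypeCall", function(object) {
    msg <- NULL
    if (!all(object@trisomies %in% c("13", "18", "21")))
        msg <- c(msg, "trisomies must be a subset of {13, 18, 21}")
    bad <- setdiff(object@flags,
                   c("contamination_suspect", "mosaic_candidate",
                     "low_count", "uncertain", "no_call"))
    if (length(bad))
        msg <- c(msg, paste("unknown flags:", paste(bad, collapse = ", ")))
    if (is.null(msg)) TRUE else msg
})

#' ChromCopyProfile: per-chromosome normalised copy-number estimates
#'
#' For every canonical chromosome: the ratio \eqn{R_c = n_c/N_a}, the
#' expected two-copy ratio \eqn{E2_c} under the calibration, the copy
#' estimate \eqn{\hat c = 2 R_c / E2_c} and the z-score
#' \eqn{(R_c - E2_c)/se_c}.  The denominator \eqn{N_a} is the fixed
#' baseline (13/18/21 excluded) for every chromosome.
#'
#' @slot sampleId character(1).
#' @slot profile data.frame with columns \code{chrom}, \code{count},
#'   \code{Rc}, \code{E2}, \code{c_hat}, \code{z}, one row per canonical
#'   chromosome.
#'
#' @seealso [copyProfile()], [callTrisomies()]
#' @aliases ChromCopyProfile
#' @export
setClass("ChromCopyProfile",
    representation(sampleId = "character", profile = "data.frame")
)

setValidity("ChromCopyProfile", function(object) {
    need <- c("chrom", "count", "Rc", "E2", "c_hat", "z")
    if (!all(need %in% names(object@profile)))
        return(paste("profile must have columns", paste(need, collapse = ", ")))
    if (any(object@profile$c_hat < 0, na.rm = TRUE))
        return("copy estimates must be >= 0")
    TRUE
})

#' SimSpec: generative description of a synthetic sample
#'
#' Fully specifies one simulated sample: its karyotype (X copies, Y
#' copies, autosomal trisomies), sequencing effort as a read count or
#' fold-coverage, an optional two-individual contamination mixture, the
#' calibration providing per-copy masses, and a seed.
#'
#' @slot xCopies,yCopies integer(1); X in 0..3, Y in 0..2.
#' @slot trisomies character vector, subset of \code{c("13","18","21")}.
#' @slot nReads integer(1) total reads to draw.
#' @slot contamXCopies,contamYCopies integer(1) contaminant karyotype
#'   (\code{NA} when no contaminant).
#' @slot contamFraction numeric(1) contaminant mixture fraction
#'   \eqn{\alpha \in [0,1)}; 0 = no contamination.
#' @slot calib [CalibrationTable-class].
#' @slot seed integer(1) RNG seed.
#'
#' @seealso [simSpec()], [simulateCounts()]
#' @aliases SimSpec
#' @export
setClass("SimSpec",
    representation(xCopies = "integer", yCopies = "integer",
                   trisomies = "character", nReads = "integer",
                   contamXCopies = "integer", contamYCopies = "integer",
                   contamFraction = "numeric",
                   calib = "CalibrationTable", seed = "integer")
)

setValidity("SimSpec", function(object) {
    msg <- NULL
    if (object@xCopies < 0L || object@xCopies > 3L)
        msg <- c(msg, "xCopies must be in 0..3")
    if (object@yCopies < 0L || object@yCopies > 2L)
        msg <- c(msg, "yCopies must be in 0..2")
    if (!all(object@trisomies %in% c("13", "18", "21")))
        msg <- c(msg, "trisomies must be a subset of {13, 18, 21}")
    if (object@nReads < 1L) msg <- c(msg, "nReads must be positive")
    if (object@contamFraction < 0 || object@contamFraction >= 1)
        msg <- c(msg, "contamFraction must be in [0, 1)")
    if (object@contamFraction > 0 &&
        (is.na(object@contamXCopies) || is.na(object@contamYCopies)))
        msg <- c(msg, "contaminant karyotype required when contamFraction > 0")
    if (is.null(msg)) TRUE else msg
})

#' PowerResult: outcome of a downsampling power experiment
#'
#' @slot replicates data.frame, one row per (level, replicate):
#'   \code{level}, \code{replicate}, \code{n_reads}, \code{Rx},
#'   \code{Ry}, \code{x_call}, \code{y_call}, \code{x_status},
#'   \code{y_status}, \code{correct}.
#' @slot summary data.frame, one row per level: \code{level},
#'   \code{replicates}, \code{concordance}, \code{Rx_mean}, \code{Rx_sd},
#'   \code{Ry_mean}, \code{Ry_sd}.
#'
#' @seealso [powerExperiment()]
#' @aliases PowerResult
#' @export
setClass("PowerResult",
    representation(replicates = "data.frame", summary = "data.frame")
)

setValidity("PowerResult", function(object) {
    s <- object@summary
    if (nrow(s) && (any(s$concordance < 0) || any(s$concordance > 1)))
        return("concordance must lie in [0, 1]")
    TRUE
})
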
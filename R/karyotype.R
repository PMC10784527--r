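#' Autosomal baseline count Na
#'
#' Sum of retained reads over chromosomes 1--22 excluding 13, 18 and 21.
#' Excluding the three viable trisomies keeps the denominator euploid
#' even in affected samples, so Rx/Ry (and R21 itself) stay centred on
#' their expectations.
#'
#' @param table a [ChromCountTable-class].
#' @return integer(1), \eqn{N_a}.
#' @examples
#' tab <- chromCountTable(stats::setNames(rep(1, 22), 1:22))
#' autosomalBaseline(tab)   # 19
#' @export
autosomalBaseline <- function(table) {
    stopifnot(is(table, "ChromCountTable"))
    sum(counts(table)[baselineChromosomes()])
}

#' Ratio estimate with binomial-approximation standard error
#'
#' The ratio \eqn{r = n_c/N_a} and a delta-method standard error derived
#' from the binomial proportion \eqn{p = n_c/(n_c + N_a)}: with a 0.5
#' pseudocount added to both counts (so zero numerators still carry
#' finite uncertainty),
#' \deqn{se(r) = \sqrt{p(1-p)/n} \, / \, (1-p)^2, \quad n = n_c' + N_a'.}
#'
#' @param nC numerator count (reads on the chromosome of interest).
#' @param nA denominator count (\eqn{N_a}).
#' @return A [RatioEstimate-class].
#' @examples
#' ratioEstimate(56, 1000)   # value 0.056
#' ratioEstimate(0, 10000)   # value 0, se > 0
#' @export
ratioEstimate <- function(nC, nA) {
    nC <- as.integer(nC); nA <- as.integer(nA)
    if (is.na(nA) || nA < 0L) stop("nA must be a non-negative integer")
    if (is.na(nC) || nC < 0L) stop("nC must be a non-negative integer")
    if (nA == 0L) stop("undefined ratio: autosomal baseline is zero")
    np <- nC + 0.5
    na <- nA + 0.5
    n <- np + na
    p <- np / n
    se <- sqrt(p * (1 - p) / n) / (1 - p)^2
    new("RatioEstimate", value = nC / nA, se = se, nC = nC, nA = nA)
}

.axisKMax <- function(axis) if (axis == "X") 3L else 2L

#' Assign a copy number from a ratio estimate
#'
#' Classifies a ratio against the calibrated centroids
#' \eqn{r(0), r(1), \ldots} of one axis by nearest centroid, with an
#' acceptance band \eqn{\max(3\,se,\ \beta\,gap)} around the winner
#' (\eqn{gap} = spacing between adjacent centroids, \eqn{\beta = 0.25}
#' by default).  Inside the band the call is \code{"confident"};
#' outside, or exactly midway between two centroids, it is
#' \code{"uncertain"}.  The band degrades gracefully: at very low
#' coverage \eqn{3\,se} dominates and borderline values become
#' uncertain rather than wrong.
#'
#' The signed z-score to the assigned centroid is always reported; a
#' confident call deviating at least \code{mosaicZ} standard errors
#' toward an adjacent centroid is annotated with an estimated mosaic
#' fraction (see [mosaicCandidate()]).
#'
#' @param estimate a [RatioEstimate-class].
#' @param axis \code{"X"} or \code{"Y"}.
#' @param calib a [CalibrationTable-class].
#' @param beta band half-width as a fraction of the centroid gap.
#' @param mosaicZ z threshold for mosaic annotation (default 4).
#' @return A [CopyCall-class].
#' @examples
#' cal <- builtinCalibration()
#' assignCopies(ratioEstimate(3300, 100000), "X", cal)  # one X, large +z
#' @export
assignCopies <- function(estimate, axis = c("X", "Y"), calib,
                         beta = 0.25, mosaicZ = 4) {
    axis <- match.arg(axis)
    stopifnot(is(estimate, "RatioEstimate"), is(calib, "CalibrationTable"))
    value <- ratioValue(estimate)
    se <- ratioSE(estimate)
    kmax <- .axisKMax(axis)
    cent <- centroid(calib, axis, 0:kmax)
    d <- abs(value - cent)
    kHat <- which.min(d) - 1L
    gap <- centroid(calib, axis, 1)        # centroids are equally spaced
    band <- max(3 * se, beta * gap)
    tie <- sum(abs(d - min(d)) < .Machine$double.eps^0.5 * max(gap, 1)) > 1L
    confident <- !tie && d[kHat + 1L] <= band
    z <- if (se > 0) (value - cent[kHat + 1L]) / se else 0
    call <- new("CopyCall", axis = axis, kHat = kHat,
                status = if (confident) "confident" else "uncertain",
                z = z, value = value, se = se,
                mosaicFraction = NA_real_)
    if (confident) {
        mc <- mosaicCandidate(call, calib, zThreshold = mosaicZ)
        if (mc$candidate)
            call@mosaicFraction <- mc$fraction
    }
    call
}

#' Mosaicism candidate test
#'
#' A confident copy call whose ratio deviates at least
#' \code{zThreshold} standard errors from its centroid, in the direction
#' of an adjacent integer copy number, is consistent with a mosaic of the
#' two karyotypes.  The mixture fraction of the adjacent karyotype is
#' estimated linearly:
#' \eqn{f = (value - r(\hat k)) / (r(k_{adj}) - r(\hat k))}, clamped to
#' \eqn{[0, 1]}.
#'
#' @param call a confident [CopyCall-class].
#' @param calib the [CalibrationTable-class] used for the call.
#' @param zThreshold minimum |z| (default 4).
#' @return list(candidate = logical, fraction = numeric or NA).
#' @examples
#' cal <- builtinCalibration()
#' cc <- assignCopies(ratioEstimate(33000, 1000000), "X", cal)
#' mosaicCandidate(cc, cal)   # fraction ~ 0.18 toward two X copies
#' @export
mosaicCandidate <- function(call, calib, zThreshold = 4) {
    stopifnot(is(call, "CopyCall"), is(calib, "CalibrationTable"))
    if (callStatus(call) != "uncertain" && abs(zToCentroid(call)) >= zThreshold) {
        kAdj <- kHat(call) + ifelse(zToCentroid(call) > 0, 1L, -1L)
        if (kAdj >= 0L && kAdj <= .axisKMax(call@axis)) {
            r0 <- centroid(calib, call@axis, kHat(call))
            r1 <- centroid(calib, call@axis, kAdj)
            f <- (ratioValue(call) - r0) / (r1 - r0)
            return(list(candidate = TRUE,
                        fraction = min(max(f, 0), 1)))
        }
    }
    list(candidate = FALSE, fraction = NA_real_)
}

#' Contamination flag from Rx/Ry geometry
#'
#' Different-sex contamination produces intermediate values on both
#' axes simultaneously: the contaminant's extra autosomes dilute the
#' denominator, inflating Rx while deflating Ry for an XY individual
#' (and the reverse for XX), so both ratios land strictly between
#' adjacent centroids — a region no pure sex-chromosome aneuploidy
#' occupies.  The flag is raised only when both axes are uncertain with
#' Rx strictly between \eqn{r_X(1)} and \eqn{r_X(2)} and Ry strictly
#' between 0 and \eqn{r_Y(1)}.
#'
#' Same-sex contamination leaves the ratios at their pure-karyotype
#' values and is invisible to this geometry (roughly half of
#' contamination scenarios are detectable).
#'
#' @param xCall,yCall [CopyCall-class] for the two axes.
#' @param calib the [CalibrationTable-class] used for the calls.
#' @return logical(1).
#' @export
contaminationFlag <- function(xCall, yCall, calib) {
    stopifnot(is(xCall, "CopyCall"), is(yCall, "CopyCall"))
    if (callStatus(xCall) != "uncertain" || callStatus(yCall) != "uncertain")
        return(FALSE)
    rxMid <- ratioValue(xCall) > centroid(calib, "X", 1) &&
        ratioValue(xCall) < centroid(calib, "X", 2)
    ryMid <- ratioValue(yCall) > 0 &&
        ratioValue(yCall) < centroid(calib, "Y", 1)
    rxMid && ryMid
}

#' z-score of a value against a cohort
#'
#' \eqn{(value - \bar x) / s} with the sample (n-1) standard deviation —
#' used to quantify how far one individual's Rx or Ry sits from the
#' empirical distribution of a reference cohort (e.g. all XY samples in
#' a study).
#'
#' @param value numeric(1).
#' @param cohortValues numeric vector, length >= 2.
#' @return numeric(1).
#' @examples
#' cohortZ(3, c(0, 2))   # 1.414
#' @export
cohortZ <- function(value, cohortValues) {
    if (length(cohortValues) < 2L)
        stop("cohort must contain at least 2 values")
    s <- stats::sd(cohortValues)
    if (s == 0) stop("cohort standard deviation is zero; z undefined")
    (value - mean(cohortValues)) / s
}

.iscnString <- function(xK, yK, tris) {
    total <- 44L + xK + yK + length(tris)
    sex <- paste0(strrep("X", xK), strrep("Y", yK))
    if (xK + yK <= 1L) sex <- paste0(sex, "0")
    s <- paste0(total, ",", sex)
    if (length(tris))
        s <- paste0(s, paste0(",+", sort(as.integer(tris)), collapse = ""))
    s
}

#' Call the full karyotype of one sample
#'
#' Composes the pipeline: autosomal baseline, Rx/Ry ratio estimates,
#' X and Y copy assignment, autosomal trisomy scan (13/18/21),
#' contamination and mosaicism flagging.  When either sex axis is
#' uncertain the ISCN string is \code{"NA"} and the \code{uncertain}
#' flag is set; \code{low_count} is set when \eqn{N_a} falls below
#' \code{naFloor}.  \eqn{N_a = 0} yields a no-call rather than an error.
#'
#' @param table a [ChromCountTable-class].
#' @param calib a [CalibrationTable-class]
#'   (default [builtinCalibration()]).
#' @param beta acceptance-band fraction of the centroid gap.
#' @param mosaicZ z threshold for mosaic annotation.
#' @param trisomyZ z threshold for trisomy calls.
#' @param naFloor minimum \eqn{N_a} before the \code{low_count} flag.
#' @return A [KaryotypeCall-class].
#' @examples
#' cal <- builtinCalibration()
#' tab <- simulateCounts(simSpec(xCopies = 2, yCopies = 1, nReads = 1e5,
#'                               calib = cal, seed = 1))
#' iscn(callKaryotype(tab, cal))   # "47,XXY"
#' @export
callKaryotype <- function(table, calib = builtinCalibration(),
                          beta = 0.25, mosaicZ = 4, trisomyZ = 5,
                          naFloor = 1000L) {
    stopifnot(is(table, "ChromCountTable"), is(calib, "CalibrationTable"))
    na <- autosomalBaseline(table)
    if (na == 0L) {
        empty <- new("RatioEstimate", value = 0, se = 0, nC = 0L, nA = 0L)
        noCall <- function(ax) new("CopyCall", axis = ax, kHat = 0L,
                                   status = "uncertain", z = 0, value = 0,
                                   se = 0, mosaicFraction = NA_real_)
        return(new("KaryotypeCall", sampleId = sampleId(table),
                   xCall = noCall("X"), yCall = noCall("Y"),
                   rx = empty, ry = empty, na = 0L,
                   nTotal = nTotal(table), trisomies = character(0),
                   iscn = "NA", flags = c("no_call", "low_count")))
    }
    rx <- ratioEstimate(counts(table)[["X"]], na)
    ry <- ratioEstimate(counts(table)[["Y"]], na)
    xCall <- assignCopies(rx, "X", calib, beta = beta, mosaicZ = mosaicZ)
    yCall <- assignCopies(ry, "Y", calib, beta = beta, mosaicZ = mosaicZ)

    prof <- copyProfile(table, calib)
    tris <- callTrisomies(prof, zThreshold = trisomyZ)

    flags <- character(0)
    if (na < naFloor) flags <- c(flags, "low_count")
    bothConfident <- callStatus(xCall) == "confident" &&
        callStatus(yCall) == "confident"
    if (!bothConfident) flags <- c(flags, "uncertain")
    if (contaminationFlag(xCall, yCall, calib))
        flags <- c(flags, "contamination_suspect")
    if (!is.na(xCall@mosaicFraction) || !is.na(yCall@mosaicFraction))
        flags <- c(flags, "mosaic_candidate")

    iscnStr <- if (bothConfident)
        .iscnString(kHat(xCall), kHat(yCall), tris) else "NA"

    new("KaryotypeCall", sampleId = sampleId(table),
        xCall = xCall, yCall = yCall, rx = rx, ry = ry,
        na = as.integer(na), nTotal = as.integer(nTotal(table)),
        trisomies = tris, iscn = iscnStr, flags = flags)
}

#' One-row summary of a karyotype call
#'
#' The standard report row: counts, ratios with standard errors, copy
#' numbers, statuses, trisomies, ISCN string and flags.
#'
#' @param call a [KaryotypeCall-class] or list thereof.
#' @return A data.frame, one row per call.
#' @export
karyotypeReport <- function(call) {
    if (is(call, "KaryotypeCall")) call <- list(call)
    stopifnot(all(vapply(call, is, logical(1), "KaryotypeCall")))
    do.call(rbind, lapply(call, function(k) data.frame(
        sample_id = sampleId(k),
        n_total = k@nTotal,
        Na = k@na,
        nX = k@rx@nC,
        nY = k@ry@nC,
        Rx = ratioValue(k@rx),
        Rx_se = ratioSE(k@rx),
        Ry = ratioValue(k@ry),
        Ry_se = ratioSE(k@ry),
        x_copies = kHat(k@xCall),
        y_copies = kHat(k@yCall),
        x_status = callStatus(k@xCall),
        y_status = callStatus(k@yCall),
        trisomies = paste(trisomies(k), collapse = ","),
        iscn = iscn(k),
        flags = paste(callFlags(k), collapse = ","),
        stringsAsFactors = FALSE
    )))
}
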
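## Build-37 chromosome lengths (bases). Autosomal per-copy masses are
## taken proportional to these; X and Y effective masses are calibration
## constants (mapping-quality filtering shrinks them well below sequence
## length, drastically for Y) fixed so the derived centroids reproduce
## the established shotgun reference values rX(2)=0.056, rX(1)=0.028,
## rY(1)=0.0026.
.GRCH37_LEN <- c(
    `1` = 249250621, `2` = 243199373, `3` = 198022430, `4` = 191154276,
    `5` = 180915260, `6` = 171115067, `7` = 159138663, `8` = 146364022,
    `9` = 141213431, `10` = 135534747, `11` = 135006516, `12` = 133851895,
    `13` = 115169878, `14` = 107349540, `15` = 102531392, `16` = 90354753,
    `17` = 81195210, `18` = 78077248, `19` = 59128983, `20` = 63025520,
    `21` = 48129895, `22` = 51304566, X = 155270560, Y = 59373566
)

.RX2_SHOTGUN <- 0.056
.RY1_SHOTGUN <- 0.0026

#' Built-in calibration tables
#'
#' Returns the per-copy effective-mass calibration shipped with the
#' package.  Autosomal masses are proportional to build-37 chromosome
#' lengths (in Mb); the X and Y masses are calibration constants chosen
#' so that the derived shotgun centroids are \eqn{r_X(2)=0.056},
#' \eqn{r_X(1)=0.028} and \eqn{r_Y(1)=0.0026}.  The \code{"capture"}
#' table is a seed only — target enrichment (e.g. the 1240k panel)
#' reshapes per-chromosome mass, so capture data should be recalibrated
#' from a cohort with [calibrateFromCohort()].
#'
#' @param mode \code{"shotgun"} (default) or \code{"capture"}.
#' @return A [CalibrationTable-class].
#' @examples
#' cal <- builtinCalibration()
#' centroid(cal, "X", 2)   # 0.056
#' @export
builtinCalibration <- function(mode = c("shotgun", "capture")) {
    mode <- match.arg(mode)
    mass <- .GRCH37_LEN / 1e6
    sA <- sum(mass[baselineChromosomes()])
    mass[["X"]] <- .RX2_SHOTGUN * sA           # rX(2) = eX / sumA
    mass[["Y"]] <- 2 * .RY1_SHOTGUN * sA       # rY(1) = eY / (2 sumA)
    mass <- mass[canonicalChromosomes()]
    new("CalibrationTable", mode = mode, perCopyMass = mass)
}

#' Summed per-copy mass over the baseline autosomes
#'
#' @param calib a [CalibrationTable-class].
#' @return numeric(1), \eqn{\Sigma_A}.
#' @export
baselineMass <- function(calib) {
    stopifnot(is(calib, "CalibrationTable"))
    sum(perCopyMass(calib)[baselineChromosomes()])
}

#' @rdname centroid
setMethod("centroid", "CalibrationTable", function(calib, axis, k) {
    axis <- as.character(axis)
    if (!axis %in% canonicalChromosomes())
        stop("unknown axis: ", axis)
    k * perCopyMass(calib)[[axis]] / (2 * baselineMass(calib))
})

#' Read and write calibration tables as TSV
#'
#' The file carries a \code{# mode=<shotgun|capture>} comment line, a
#' header, and columns \code{chrom} and \code{per_copy_mass}.
#'
#' @param path TSV path.
#' @return \code{readCalibration} returns a [CalibrationTable-class];
#'   \code{writeCalibration} returns \code{path} invisibly.
#' @export
readCalibration <- function(path) {
    if (!file.exists(path)) stop("calibration file not readable: ", path)
    lines <- readLines(path)
    modeLine <- grep("^#\\s*mode\\s*=", lines, value = TRUE)
    mode <- if (length(modeLine))
        trimws(sub("^#\\s*mode\\s*=", "", modeLine[[1L]])) else "shotgun"
    df <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                            stringsAsFactors = FALSE)
    if (!all(c("chrom", "per_copy_mass") %in% names(df)))
        stop("calibration TSV needs 'chrom' and 'per_copy_mass' columns")
    mass <- stats::setNames(rep(NA_real_, 24L), canonicalChromosomes())
    canon <- .normalizeContigNames(as.character(df$chrom))
    mass[canon[!is.na(canon)]] <- df$per_copy_mass[!is.na(canon)]
    if (anyNA(mass))
        stop("calibration missing chromosomes: ",
             paste(names(mass)[is.na(mass)], collapse = ", "))
    new("CalibrationTable", mode = mode, perCopyMass = mass)
}

#' @rdname readCalibration
#' @param calib a [CalibrationTable-class].
#' @export
writeCalibration <- function(calib, path) {
    stopifnot(is(calib, "CalibrationTable"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# mode=", calibrationMode(calib)), con)
    utils::write.table(
        data.frame(chrom = names(perCopyMass(calib)),
                   per_copy_mass = unname(perCopyMass(calib))),
        con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Calibrate per-copy masses from a cohort of count tables
#'
#' Re-estimates the calibration empirically from a cohort expected to be
#' dominated by the two common karyotypes (46,XX and 46,XY).  Samples are
#' split into Y-bearing and Y-absent groups by thresholding Ry at half
#' the current \eqn{r_Y(1)}; the Y mass is estimated from the Y-bearing
#' group's median Ry (one copy), the X mass from the Y-absent group's
#' median Rx (two copies) combined with the Y-bearing group's median Rx
#' (one copy) as a size-weighted average; autosomal masses come from
#' cohort-median per-chromosome ratios.  The grouping threshold is then
#' updated and the estimation repeated once.
#'
#' Mixed-mode cohorts are pooled as given: calibration reflects the
#' pooled medians, and stratifying by platform/mode is the caller's
#' responsibility.
#'
#' @param tables list of [ChromCountTable-class] (at least 20,
#'   spanning both common karyotypes).
#' @param mode mode label for the returned calibration.
#' @param seed a [CalibrationTable-class] providing the initial grouping
#'   threshold; default the built-in shotgun table.
#' @return A new [CalibrationTable-class].
#' @export
calibrateFromCohort <- function(tables, mode = c("shotgun", "capture"),
                                seed = builtinCalibration("shotgun")) {
    mode <- match.arg(mode)
    if (length(tables) < 20L)
        stop("cohort calibration requires at least 20 samples")
    stopifnot(all(vapply(tables, is, logical(1), "ChromCountTable")))
    na <- vapply(tables, autosomalBaseline, numeric(1))
    if (any(na == 0)) stop("cohort contains samples with empty baseline")
    rx <- vapply(tables, function(t) counts(t)[["X"]], numeric(1)) / na
    ry <- vapply(tables, function(t) counts(t)[["Y"]], numeric(1)) / na
    rc <- vapply(canonicalChromosomes(), function(ch)
        stats::median(vapply(tables, function(t) counts(t)[[ch]], numeric(1)) / na),
        numeric(1))

    rY1 <- centroid(seed, "Y", 1)
    for (iter in 1:2) {
        yBearing <- ry > rY1 / 2
        if (!any(yBearing) || all(yBearing))
            stop("cohort calibration needs both Y-bearing and Y-absent samples")
        ## on a scale where sumA = 1: rX(2) = eX, rY(1) = eY/2
        eY <- 2 * stats::median(ry[yBearing])
        eX_xx <- stats::median(rx[!yBearing])          # 2 copies
        eX_xy <- 2 * stats::median(rx[yBearing])       # 1 copy
        eX <- (sum(!yBearing) * eX_xx + sum(yBearing) * eX_xy) /
            length(tables)
        rY1 <- eY / 2
    }
    mass <- rc / 2                                     # two copies each
    mass <- mass / sum(mass[baselineChromosomes()])    # scale: sumA = 1
    ## observed ratios are relative to the true baseline mass, so the
    ## eX/eY estimates above are already on the sumA = 1 scale
    mass[["X"]] <- eX
    mass[["Y"]] <- eY
    if (any(mass <= 0))
        stop("degenerate calibration: a chromosome has zero median ratio")
    new("CalibrationTable", mode = mode,
        perCopyMass = mass[canonicalChromosomes()])
}
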
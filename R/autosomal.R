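#' Per-chromosome copy-number profile
#'
#' For every canonical chromosome computes the ratio \eqn{R_c = n_c/N_a},
#' the calibration-expected two-copy ratio
#' \eqn{E2_c = e_c / \Sigma_A}, the normalised copy estimate
#' \eqn{\hat c = 2 R_c / E2_c}, and the z-score \eqn{(R_c - E2_c)/se_c}
#' with the delta-method standard error of [ratioEstimate()].  The
#' denominator \eqn{N_a} is the fixed baseline (13/18/21 excluded),
#' identical for every chromosome — baseline chromosomes are not removed
#' from their own denominator, which biases their \eqn{\hat c} only by
#' \eqn{O(1/19)} relative shrinkage shared by all of them.
#'
#' Because \eqn{\hat c} is a ratio (cancelling sequencing effort) scaled
#' by per-copy mass (cancelling chromosome size), profiles are directly
#' comparable between chromosomes and across individuals.
#'
#' @param table a [ChromCountTable-class].
#' @param calib a [CalibrationTable-class].
#' @return A [ChromCopyProfile-class].
#' @examples
#' cal <- builtinCalibration()
#' tab <- simulateCounts(simSpec(nReads = 1e5, calib = cal, seed = 1))
#' head(profileTable(copyProfile(tab, cal)))
#' @export
copyProfile <- function(table, calib = builtinCalibration()) {
    stopifnot(is(table, "ChromCountTable"), is(calib, "CalibrationTable"))
    na <- autosomalBaseline(table)
    if (na == 0L) stop("cannot profile: autosomal baseline is zero")
    sA <- baselineMass(calib)
    chroms <- canonicalChromosomes()
    cnt <- counts(table)
    e2 <- perCopyMass(calib)[chroms] / sA
    rc <- cnt[chroms] / na
    se <- vapply(chroms, function(ch) ratioSE(ratioEstimate(cnt[[ch]], na)),
                 numeric(1))
    df <- data.frame(
        chrom = chroms,
        count = unname(cnt[chroms]),
        Rc = unname(rc),
        E2 = unname(e2),
        c_hat = unname(2 * rc / e2),
        z = unname((rc - e2) / se),
        stringsAsFactors = FALSE
    )
    new("ChromCopyProfile", sampleId = sampleId(table), profile = df)
}

#' Call autosomal trisomies from a copy profile
#'
#' Chromosome \eqn{c} in the tested set is called trisomic when its copy
#' estimate is nearer 3 than 2 (\eqn{\hat c > 2.5}) and its z-score
#' exceeds \code{zThreshold}.  Only 13, 18 and 21 are tested by default:
#' they are outside the baseline, so an extra copy never perturbs the
#' denominator.  Testing a baseline chromosome is possible via
#' \code{leaveOneOut = TRUE}, which removes the tested chromosome from
#' its own denominator — an extension beyond the core method, off by
#' default.
#'
#' @param profile a [ChromCopyProfile-class], or the
#'   [ChromCountTable-class]/calibration pair via [copyProfile()].
#' @param zThreshold minimum z (default 5 — conservative against the
#'   implicit multiplicity of scanning several chromosomes).
#' @param tested chromosomes to test (default \code{c("13","18","21")}).
#' @param table,calib required only when \code{leaveOneOut = TRUE} and a
#'   baseline chromosome is tested.
#' @param leaveOneOut recompute the denominator without the tested
#'   chromosome (needed for baseline chromosomes).
#' @return Character vector: the trisomic subset of \code{tested}.
#' @export
callTrisomies <- function(profile, zThreshold = 5,
                          tested = c("13", "18", "21"),
                          table = NULL, calib = NULL,
                          leaveOneOut = FALSE) {
    stopifnot(is(profile, "ChromCopyProfile"))
    tested <- as.character(tested)
    if (!length(tested)) return(character(0))
    bad <- setdiff(tested, canonicalChromosomes())
    if (length(bad)) stop("cannot test non-canonical chromosomes: ",
                          paste(bad, collapse = ", "))
    baselineTested <- intersect(tested, baselineChromosomes())
    if (length(baselineTested) && !leaveOneOut)
        stop("testing baseline chromosome(s) ",
             paste(baselineTested, collapse = ", "),
             " biases their own denominator; use leaveOneOut = TRUE")
    df <- profileTable(profile)
    hits <- character(0)
    for (ch in tested) {
        row <- df[df$chrom == ch, ]
        cHat <- row$c_hat
        z <- row$z
        if (leaveOneOut && ch %in% baselineChromosomes()) {
            if (is.null(table) || is.null(calib))
                stop("leaveOneOut requires 'table' and 'calib'")
            naLoo <- autosomalBaseline(table) - counts(table)[[ch]]
            if (naLoo == 0L) next
            est <- ratioEstimate(counts(table)[[ch]], naLoo)
            sLoo <- baselineMass(calib) - perCopyMass(calib)[[ch]]
            e2 <- perCopyMass(calib)[[ch]] / sLoo
            cHat <- 2 * ratioValue(est) / e2
            z <- (ratioValue(est) - e2) / ratioSE(est)
        }
        if (!is.na(cHat) && !is.na(z) && cHat > 2.5 && z >= zThreshold)
            hits <- c(hits, ch)
    }
    hits
}

#' Long-format TSV export of a copy profile
#'
#' @param profile a [ChromCopyProfile-class].
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeCopyProfile <- function(profile, path) {
    stopifnot(is(profile, "ChromCopyProfile"))
    df <- cbind(sample_id = sampleId(profile), profileTable(profile))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
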
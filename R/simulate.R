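#' Convert fold-coverage to a read count
#'
#' \eqn{n = fold \times genomeSize / readLength}; defaults 3.1 Gb and a
#' 60 nt mean fragment length typical of ancient DNA, so 0.0001-fold is
#' about 5,167 reads.
#'
#' @param fold mean fold-coverage.
#' @param genomeSize genome size in bases.
#' @param readLength mean aligned fragment length in nt.
#' @return integer read count (at least 1).
#' @examples
#' coverageToReads(1e-4)   # ~5167
#' @export
coverageToReads <- function(fold, genomeSize = 3.1e9, readLength = 60) {
    stopifnot(fold > 0, genomeSize > 0, readLength > 0)
    max(1L, as.integer(round(fold * genomeSize / readLength)))
}

#' Construct a simulation specification
#'
#' @param xCopies,yCopies sex chromosome copy numbers (defaults 2, 0 =
#'   46,XX).
#' @param trisomies character vector among \code{c("13","18","21")}.
#' @param nReads total reads to draw; alternatively give
#'   \code{foldCoverage}.
#' @param foldCoverage mean fold-coverage, converted via
#'   [coverageToReads()].
#' @param contaminant optional \code{list(xCopies=, yCopies=, fraction=)}
#'   describing a second individual contributing fraction
#'   \eqn{\alpha \in [0,1)} of the reads (same platform/calibration).
#' @param calib a [CalibrationTable-class].
#' @param seed RNG seed.
#' @param genomeSize,readLength passed to [coverageToReads()].
#' @return A [SimSpec-class].
#' @examples
#' simSpec(xCopies = 1, yCopies = 0, foldCoverage = 1e-4, seed = 7)
#' @export
simSpec <- function(xCopies = 2, yCopies = 0, trisomies = character(0),
                    nReads = NULL, foldCoverage = NULL,
                    contaminant = NULL, calib = builtinCalibration(),
                    seed = 1L, genomeSize = 3.1e9, readLength = 60) {
    if (is.null(nReads)) {
        if (is.null(foldCoverage))
            stop("give either nReads or foldCoverage")
        nReads <- coverageToReads(foldCoverage, genomeSize, readLength)
    }
    cx <- cy <- NA_integer_
    alpha <- 0
    if (!is.null(contaminant)) {
        cx <- as.integer(contaminant$xCopies)
        cy <- as.integer(contaminant$yCopies)
        alpha <- as.numeric(contaminant$fraction)
    }
    new("SimSpec", xCopies = as.integer(xCopies),
        yCopies = as.integer(yCopies),
        trisomies = as.character(trisomies), nReads = as.integer(nReads),
        contamXCopies = cx, contamYCopies = cy, contamFraction = alpha,
        calib = calib, seed = as.integer(seed))
}

.karyotypeMass <- function(calib, xCopies, yCopies, trisomies = character(0)) {
    copies <- stats::setNames(rep(2, 24L), canonicalChromosomes())
    copies[trisomies] <- 3
    copies[["X"]] <- xCopies
    copies[["Y"]] <- yCopies
    copies * perCopyMass(calib)
}

#' Expected chromosome probabilities and ratios under a SimSpec
#'
#' Closed-form expectations of the multinomial cell probabilities and of
#' Rx/Ry for a (possibly contaminated) specification — mixtures combine
#' unnormalised per-copy masses on the shared calibration scale, so a
#' 50:50 XX/XY mixture has \eqn{E[R_x] = (r_X(2)+r_X(1))/2} and
#' \eqn{E[R_y] = r_Y(1)/2} exactly.
#'
#' @param spec a [SimSpec-class].
#' @return list(p = named numeric(24), Rx = numeric(1), Ry = numeric(1)).
#' @export
expectedRatios <- function(spec) {
    stopifnot(is(spec, "SimSpec"))
    m <- .karyotypeMass(spec@calib, spec@xCopies, spec@yCopies,
                        spec@trisomies)
    if (spec@contamFraction > 0) {
        mc <- .karyotypeMass(spec@calib, spec@contamXCopies,
                             spec@contamYCopies)
        m <- (1 - spec@contamFraction) * m + spec@contamFraction * mc
    }
    p <- m / sum(m)
    sA <- sum(m[baselineChromosomes()])
    list(p = p, Rx = m[["X"]] / sA, Ry = m[["Y"]] / sA)
}

#' Simulate a per-chromosome count table
#'
#' Draws \code{nReads} reads multinomially over the 24 canonical
#' chromosomes with probabilities proportional to
#' \eqn{(1-\alpha)\,m_c(\mathrm{endogenous}) +
#'      \alpha\,m_c(\mathrm{contaminant})},
#' \eqn{m_c = copies_c \times perCopyMass_c}.  Deterministic given the
#' spec's seed; counts sum exactly to \code{nReads}.  Simulation is at
#' the count level: the classifier consumes counts, so no sequence-level
#' features (damage, GC bias, fragment length) are modelled.
#'
#' @param spec a [SimSpec-class].
#' @return A [ChromCountTable-class] with \code{sampleId} describing the
#'   generating karyotype.
#' @examples
#' cal <- builtinCalibration()
#' tab <- simulateCounts(simSpec(xCopies = 1, yCopies = 1, nReads = 1e5,
#'                               calib = cal, seed = 42))
#' nTotal(tab)   # 100000
#' @export
simulateCounts <- function(spec) {
    stopifnot(is(spec, "SimSpec"))
    p <- expectedRatios(spec)$p
    set.seed(spec@seed)
    draw <- as.integer(stats::rmultinom(1L, spec@nReads, p)[, 1L])
    names(draw) <- canonicalChromosomes()
    id <- sprintf("sim_%dX%dY%s_n%d_s%d", spec@xCopies, spec@yCopies,
                  if (length(spec@trisomies))
                      paste0("+", paste(spec@trisomies, collapse = "+"))
                  else "",
                  spec@nReads, spec@seed)
    new("ChromCountTable", sampleId = id, counts = draw,
        mapqMin = 30L, maskApplied = FALSE)
}

#' Binomially thin a count table
#'
#' Each chromosome's count is replaced by a Binomial(count, fraction)
#' draw — the count-level equivalent of retaining each read
#' independently with probability \code{fraction}, as in coverage
#' downsampling.  \code{fraction = 1} returns the table unchanged.
#'
#' @param table a [ChromCountTable-class].
#' @param fraction retention probability in (0, 1].
#' @param seed RNG seed.
#' @return A thinned [ChromCountTable-class].
#' @export
thinCounts <- function(table, fraction, seed = 1L) {
    stopifnot(is(table, "ChromCountTable"))
    if (!is.numeric(fraction) || length(fraction) != 1L ||
        is.na(fraction) || fraction <= 0 || fraction > 1)
        stop("fraction must lie in (0, 1]")
    if (fraction == 1) return(table)
    set.seed(as.integer(seed))
    cnt <- counts(table)
    thinned <- as.integer(stats::rbinom(length(cnt), cnt, fraction))
    names(thinned) <- names(cnt)
    new("ChromCountTable", sampleId = sampleId(table), counts = thinned,
        mapqMin = table@mapqMin, maskApplied = table@maskApplied)
}

## Deterministic child seed for (level i, replicate j) under a root seed,
## independent of evaluation order; kept within 32-bit signed range.
.childSeed <- function(root, i, j) {
    as.integer((as.double(root) * 48271 + i * 1000003 + j * 7919) %%
               2147483647)
}

#' Downsampling power experiment
#'
#' Reproduces the downsampling design used to validate low-coverage
#' karyotype assignment: for each coverage level and replicate, a table
#' is produced (by thinning a base table, or thinning a fresh simulation
#' of a [SimSpec-class]), the karyotype is called, and Rx/Ry and
#' call correctness are recorded.  Correctness compares the X/Y copy
#' calls to the spec's karyotype (for a SimSpec base) or to the call on
#' the untouched base table.
#'
#' Each (level, replicate) cell gets its own child seed derived from the
#' root seed by counter, so any replicate is reproducible in isolation.
#'
#' @param base a [SimSpec-class] or [ChromCountTable-class].
#' @param levels numeric vector of retention fractions in (0, 1].
#' @param replicates replicates per level (default 100).
#' @param calib a [CalibrationTable-class].
#' @param seed root seed.
#' @param ... further arguments to [callKaryotype()].
#' @return A [PowerResult-class].
#' @examples
#' cal <- builtinCalibration()
#' pr <- powerExperiment(simSpec(xCopies = 1, yCopies = 0, nReads = 5e4,
#'                               calib = cal, seed = 3),
#'                       levels = c(1, 0.1), replicates = 5, calib = cal)
#' powerSummary(pr)
#' @export
powerExperiment <- function(base, levels, replicates = 100L,
                            calib = builtinCalibration(), seed = 1L, ...) {
    stopifnot(is.numeric(levels), length(levels) >= 1L,
              all(levels > 0), all(levels <= 1))
    replicates <- as.integer(replicates)
    fromSpec <- is(base, "SimSpec")
    if (!fromSpec && !is(base, "ChromCountTable"))
        stop("base must be a SimSpec or ChromCountTable")
    if (fromSpec) {
        truthX <- base@xCopies
        truthY <- base@yCopies
    } else {
        full <- callKaryotype(base, calib, ...)
        truthX <- kHat(full@xCall)
        truthY <- kHat(full@yCall)
    }
    rows <- vector("list", length(levels) * replicates)
    idx <- 0L
    for (i in seq_along(levels)) {
        for (j in seq_len(replicates)) {
            s <- .childSeed(seed, i, j)
            tab <- if (fromSpec) {
                sp <- base
                sp@seed <- s
                t0 <- simulateCounts(sp)
                if (levels[i] < 1)
                    thinCounts(t0, levels[i], seed = .childSeed(s, i, j))
                else t0
            } else {
                thinCounts(base, levels[i], seed = s)
            }
            kc <- callKaryotype(tab, calib, ...)
            idx <- idx + 1L
            rows[[idx]] <- data.frame(
                level = levels[i], replicate = j, n_reads = nTotal(tab),
                Rx = ratioValue(kc@rx), Ry = ratioValue(kc@ry),
                x_call = kHat(kc@xCall), y_call = kHat(kc@yCall),
                x_status = callStatus(kc@xCall),
                y_status = callStatus(kc@yCall),
                correct = callStatus(kc@xCall) == "confident" &&
                    callStatus(kc@yCall) == "confident" &&
                    kHat(kc@xCall) == truthX && kHat(kc@yCall) == truthY,
                stringsAsFactors = FALSE)
        }
    }
    rep <- do.call(rbind, rows)
    summ <- do.call(rbind, lapply(split(rep, rep$level), function(d)
        data.frame(level = d$level[1L], replicates = nrow(d),
                   concordance = mean(d$correct),
                   Rx_mean = mean(d$Rx), Rx_sd = stats::sd(d$Rx),
                   Ry_mean = mean(d$Ry), Ry_sd = stats::sd(d$Ry))))
    summ <- summ[order(summ$level, decreasing = TRUE), ]
    rownames(summ) <- NULL
    new("PowerResult", replicates = rep, summary = summ)
}
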
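# Fixture builders shared across the suite. Everything is generated in
# code; no binary fixtures are stored.

# One headerless SAM record (the shape `samtools view` emits).
samRecord <- function(qname = "r", flag = 0L, rname = "1", pos = 100L,
                      mapq = 37L) {
    paste(qname, flag, rname, pos, mapq, "30M", "*", 0, 0,
          strrep("A", 30), strrep("I", 30), sep = "\t")
}

# A SAM text vector with the given per-chromosome record counts, all
# primary/mapped at the given MAPQ, positions spread deterministically.
samFixture <- function(counts, mapq = 37L, posStart = 100L, posStep = 50L) {
    lines <- character(0)
    i <- 0L
    for (chrom in names(counts)) {
        for (j in seq_len(counts[[chrom]])) {
            i <- i + 1L
            lines <- c(lines, samRecord(paste0("r", i), 0L, chrom,
                                        posStart + (j - 1L) * posStep,
                                        mapq))
        }
    }
    lines
}

# SAM header lines for the canonical contigs (needed to build BAMs).
samHeader <- function(chrPrefix = FALSE) {
    chroms <- canonicalChromosomes()
    if (chrPrefix) chroms <- paste0("chr", chroms)
    c("@HD\tVN:1.6\tSO:coordinate",
      paste0("@SQ\tSN:", chroms, "\tLN:250000000"))
}

# Write SAM text (with header) and convert to an indexed BAM; returns
# the BAM path. Records must be coordinate-sorted per contig.
bamFixture <- function(samLines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
    samPath <- file.path(dir, "fixture.sam")
    writeLines(c(samHeader(), samLines), samPath)
    Rsamtools::asBam(samPath, file.path(dir, "fixture"),
                     overwrite = TRUE, indexDestination = TRUE)
}

shotgunCal <- builtinCalibration("shotgun")

# Simulated cohort of common karyotypes for calibration tests.
simCohort <- function(n, nReads = 2e5, seed = 100L,
                      calib = shotgunCal) {
    lapply(seq_len(n), function(i) {
        xx <- i %% 2L == 0L
        simulateCounts(simSpec(xCopies = if (xx) 2L else 1L,
                               yCopies = if (xx) 0L else 1L,
                               nReads = nReads, calib = calib,
                               seed = seed + i))
    })
}
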
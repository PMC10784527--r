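#' Normalise a contig name to a canonical chromosome label
#'
#' Maps reference contig names, with or without a \code{"chr"} prefix and
#' case-insensitively, onto the 24 canonical labels.  Mitochondrial
#' contigs (\code{"MT"}, \code{"chrM"}), decoys and unplaced contigs map
#' to \code{NA}.
#'
#' @param rawName character(1) contig name as it appears in the alignment
#'   or TSV.
#' @return The canonical label (\code{"1"}..\code{"22"}, \code{"X"},
#'   \code{"Y"}) or \code{NA_character_}.
#' @examples
#' normalizeContigName("chrY")        # "Y"
#' normalizeContigName("21")          # "21"
#' normalizeContigName("GL000220.1")  # NA
#' @export
normalizeContigName <- function(rawName) {
    if (length(rawName) != 1L || is.na(rawName)) return(NA_character_)
    nm <- sub("^chr", "", rawName, ignore.case = TRUE)
    nm <- toupper(nm)
    if (nm %in% canonicalChromosomes()) return(nm)
    NA_character_
}

.normalizeContigNames <- function(rawNames) {
    nm <- toupper(sub("^chr", "", rawNames, ignore.case = TRUE))
    nm[!nm %in% canonicalChromosomes()] <- NA_character_
    nm
}

#' Load a BED region mask
#'
#' Reads a BED file (0-based half-open intervals) into a
#' \code{\link[GenomicRanges]{GRanges}} restricted to canonical
#' chromosomes, sorted and with overlapping intervals merged, for use as
#' the \code{mask} argument of [countAlignments()].  Suitable for
#' accessibility masks such as the 1000 Genomes strict mask.
#'
#' @param path path to a BED file.
#' @return A \code{GRanges} with canonical seqnames, reduced and sorted.
#' @export
loadRegionMask <- function(path) {
    if (!file.exists(path)) stop("mask file not readable: ", path)
    gr <- rtracklayer::import(path, format = "BED")
    canon <- .normalizeContigNames(as.character(GenomicRanges::seqnames(gr)))
    gr <- gr[!is.na(canon)]
    canon <- canon[!is.na(canon)]
    gr <- GenomicRanges::GRanges(canon, IRanges::ranges(gr))
    GenomicRanges::sort(GenomicRanges::reduce(gr))
}

## Positions are 1-based leftmost aligned coordinates; mask GRanges is
## 1-based closed (rtracklayer converts BED on import).
.inMask <- function(chrom, pos, mask) {
    q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
    IRanges::overlapsAny(q, mask)
}

.countRecords <- function(chrom, pos, mask = NULL) {
    canon <- .normalizeContigNames(chrom)
    keep <- !is.na(canon)
    canon <- canon[keep]
    pos <- pos[keep]
    if (!is.null(mask) && length(canon)) {
        keep2 <- .inMask(canon, pos, mask)
        canon <- canon[keep2]
    }
    tab <- table(factor(canon, levels = canonicalChromosomes()))
    x <- as.integer(tab)
    names(x) <- canonicalChromosomes()
    x
}

.parseSamLines <- function(lines) {
    lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
    if (!length(lines))
        return(data.frame(flag = integer(0), rname = character(0),
                          pos = integer(0), mapq = integer(0)))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 11L))
        stop("malformed SAM record at line ", which(nf < 11L)[1L],
             " (fewer than 11 fields)")
    data.frame(
        flag = as.integer(vapply(fields, `[[`, "", 2L)),
        rname = vapply(fields, `[[`, "", 3L),
        pos = as.integer(vapply(fields, `[[`, "", 4L)),
        mapq = as.integer(vapply(fields, `[[`, "", 5L)),
        stringsAsFactors = FALSE
    )
}

.FLAG_UNMAPPED <- 0x4L
.FLAG_SECONDARY <- 0x100L
.FLAG_DUPLICATE <- 0x400L
.FLAG_SUPPLEMENTARY <- 0x800L

.retainSam <- function(rec, mapqMin) {
    drop <- bitwAnd(rec$flag,
                    .FLAG_UNMAPPED + .FLAG_SECONDARY +
                    .FLAG_DUPLICATE + .FLAG_SUPPLEMENTARY) != 0L
    rec[!drop & rec$mapq >= mapqMin & rec$rname != "*", , drop = FALSE]
}

#' Count quality-filtered alignments per chromosome
#'
#' Produces a [ChromCountTable-class] from an alignment source.  Retained
#' records are primary, mapped, non-duplicate, non-supplementary
#' alignments with mapping quality at least \code{mapqMin}; each retained
#' record increments exactly one chromosome.  Records on non-canonical
#' contigs (mitochondria, decoys, unplaced) are excluded entirely.  When
#' a mask is supplied, a record is retained only if its leftmost aligned
#' position falls inside a mask interval — a cheap, deterministic
#' criterion adequate for short ancient-DNA fragments.
#'
#' Sources: a BAM/CRAM path (read via \pkg{Rsamtools}), a SAM text file
#' path, a character vector of SAM lines, or a connection streaming
#' headerless SAM text — the latter mirrors the published
#' \code{samtools view -q30 file.bam | <caller>} pipe contract, and
#' yields counts identical to reading the BAM directly with the same
#' filter.
#'
#' @param source BAM/CRAM/SAM path, connection, or character vector of
#'   SAM lines.
#' @param mapqMin minimum mapping quality (default 30).
#' @param mask optional \code{GRanges} from [loadRegionMask()].
#' @param sampleId sample identifier; defaults to the file basename.
#' @return A [ChromCountTable-class].  Zero retained records yields a
#'   zero table with a warning, not an error.
#' @examples
#' sam <- c("r1\t0\tX\t100\t37\t30M\t*\t0\t0\t*\t*",
#'          "r2\t0\tchr1\t200\t37\t30M\t*\t0\t0\t*\t*")
#' tab <- countAlignments(sam, mapqMin = 30)
#' counts(tab)[c("1", "X")]
#' @export
countAlignments <- function(source, mapqMin = 30L, mask = NULL,
                            sampleId = NULL) {
    mapqMin <- as.integer(mapqMin)
    if (is.character(source) && length(source) == 1L && file.exists(source) &&
        grepl("\\.(bam|cram)$", source, ignore.case = TRUE)) {
        if (is.null(sampleId))
            sampleId <- sub("\\.[^.]+$", "", basename(source))
        cnt <- .countBam(source, mapqMin, mask)
    } else {
        if (inherits(source, "connection")) {
            lines <- readLines(source)
        } else if (is.character(source) && length(source) == 1L &&
                   file.exists(source)) {
            if (is.null(sampleId))
                sampleId <- sub("\\.[^.]+$", "", basename(source))
            lines <- readLines(source)
        } else if (is.character(source)) {
            lines <- source
        } else {
            stop("unreadable alignment source")
        }
        rec <- .retainSam(.parseSamLines(lines), mapqMin)
        cnt <- .countRecords(rec$rname, rec$pos, mask)
    }
    if (is.null(sampleId)) sampleId <- "sample"
    if (sum(cnt) == 0L)
        warning("no records retained; returning an empty count table")
    new("ChromCountTable", sampleId = as.character(sampleId), counts = cnt,
        mapqMin = mapqMin, maskApplied = !is.null(mask))
}

.countBam <- function(path, mapqMin, mask) {
    flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                   isSecondaryAlignment = FALSE,
                                   isSupplementaryAlignment = FALSE,
                                   isDuplicate = FALSE)
    param <- Rsamtools::ScanBamParam(flag = flag, what = c("rname", "pos"),
                                     mapqFilter = mapqMin)
    res <- Rsamtools::scanBam(path, param = param)[[1L]]
    keep <- !is.na(res$pos)
    .countRecords(as.character(res$rname)[keep], res$pos[keep], mask)
}

#' Read and write per-chromosome count tables as TSV
#'
#' The TSV has a header line and columns \code{chrom} and \code{count};
#' chromosomes absent from the file are zero-filled on read, and writing
#' then reading any valid table is the identity.
#'
#' @param path TSV path.
#' @param sampleId sample identifier; defaults to the file basename.
#' @param mapqMin,maskApplied provenance recorded on the returned table.
#' @return \code{readCountTable} returns a [ChromCountTable-class];
#'   \code{writeCountTable} returns \code{path} invisibly.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeCountTable(chromCountTable(c(X = 10, `1` = 90), "s1"), tf)
#' nTotal(readCountTable(tf))   # 100
#' @export
readCountTable <- function(path, sampleId = NULL, mapqMin = 30L,
                           maskApplied = FALSE) {
    if (!file.exists(path)) stop("count table not readable: ", path)
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#")]
    if (!length(lines)) stop("empty count table: ", path)
    header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
    if (!all(c("chrom", "count") %in% header))
        stop("count table must have 'chrom' and 'count' columns: ", path)
    ci <- match(c("chrom", "count"), header)
    cnt <- .zeroCounts()
    for (i in seq_along(lines)[-1L]) {
        f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
        if (length(f) < length(header))
            stop("malformed row at line ", i, " of ", path)
        v <- suppressWarnings(as.numeric(f[ci[2L]]))
        if (is.na(v) || v < 0 || v != floor(v))
            stop("invalid count at line ", i, " of ", path,
                 " (must be a non-negative integer)")
        canon <- normalizeContigName(f[ci[1L]])
        if (!is.na(canon)) cnt[[canon]] <- cnt[[canon]] + as.integer(v)
    }
    if (is.null(sampleId))
        sampleId <- sub("\\.[^.]+$", "", basename(path))
    new("ChromCountTable", sampleId = as.character(sampleId), counts = cnt,
        mapqMin = as.integer(mapqMin), maskApplied = isTRUE(maskApplied))
}

#' @rdname readCountTable
#' @param table a [ChromCountTable-class].
#' @export
writeCountTable <- function(table, path) {
    stopifnot(is(table, "ChromCountTable"))
    df <- data.frame(chrom = names(counts(table)),
                     count = unname(counts(table)))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}
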
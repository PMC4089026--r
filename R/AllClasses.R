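#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges
#'   rowData colData colData<-
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand
#' @importFrom IRanges IRanges findOverlaps overlapsAny
NULL

.validCrosses <- c("BxD", "DxB")
.validSexes  <- c("M", "F")
.annotationLevels <- c("intronic", "exonic", "utr", "synonymous",
                       "nonsynonymous", "stop_gain", "stop_loss")

#' AlleleCounts: per-SNP, per-sample allele-specific read counts
#'
#' The central container of the pipeline: a
#' \linkS4class{RangedSummarizedExperiment} whose rows are biallelic SNPs
#' between the two parental strains (B = reference strain, D = alternate
#' strain) and whose columns are sequenced F1 samples.  Three integer assays
#' hold, for every SNP and sample, the number of uniquely mapped reads
#' carrying the B allele (\code{"b"}), the D allele (\code{"d"}), and any
#' other base (\code{"other"}).  Row ranges carry the SNP coordinates with
#' metadata columns \code{gene_id}, \code{annotation} (one of
#' \code{intronic}, \code{exonic}, \code{utr}, \code{synonymous},
#' \code{nonsynonymous}, \code{stop_gain}, \code{stop_loss}),
#' \code{b_allele} and \code{d_allele}.  Column data carry the pool
#' metadata: \code{cross} (\code{"BxD"} or \code{"DxB"}, maternal strain
#' first) and \code{sex} (\code{"M"}/\code{"F"}).
#'
#' @seealso [alleleCounts()] for the constructor, [countAlleles()] and
#'   [simulateCounts()] which produce these objects, [aggregateCounts()]
#'   which turns them into an [ASEMatrix].
#' @aliases AlleleCounts
#' @exportClass AlleleCounts
setClass("AlleleCounts", contains = "RangedSummarizedExperiment")

setValidity("AlleleCounts", function(object) {
    msg <- character()
    need <- c("b", "d", "other")
    if (!all(need %in% names(assays(object))))
        msg <- c(msg, sprintf("assays must include %s",
                              paste(need, collapse = ", ")))
    else {
        for (a in need) {
            m <- assay(object, a)
            if (any(m < 0) || any(m != round(m)))
                msg <- c(msg, sprintf("assay '%s' must hold non-negative integer counts", a))
        }
    }
    cd <- colData(object)
    if (!all(c("cross", "sex") %in% colnames(cd)))
        msg <- c(msg, "colData must have 'cross' and 'sex'")
    else {
        if (!all(cd$cross %in% .validCrosses))
            msg <- c(msg, "cross must be 'BxD' or 'DxB'")
        if (!all(cd$sex %in% .validSexes))
            msg <- c(msg, "sex must be 'M' or 'F'")
    }
    rd <- mcols(rowRanges(object))
    for (f in c("gene_id", "annotation", "b_allele", "d_allele"))
        if (!f %in% colnames(rd))
            msg <- c(msg, sprintf("rowRanges metadata must have '%s'", f))
    if ("annotation" %in% colnames(rd) &&
        !all(rd$annotation %in% .annotationLevels))
        msg <- c(msg, "unknown annotation level in rowRanges")
    if (length(msg)) msg else TRUE
})

#' Construct an AlleleCounts object
#'
#' @param variants `GRanges` of SNP positions (width 1) with metadata columns
#'   `gene_id`, `annotation`, `b_allele`, `d_allele`, e.g. from
#'   [readVariants()].
#' @param b,d,other integer matrices, SNPs x samples, of reads supporting the
#'   B allele, the D allele, and any third base. `other` defaults to zeros.
#' @param cross,sex character vectors, one entry per sample: cross direction
#'   (`"BxD"`/`"DxB"`, maternal strain first) and sex (`"M"`/`"F"`).
#' @param sample_id optional sample names; defaults to `colnames(b)` or
#'   `sample1..sampleN`.
#' @return An [AlleleCounts-class] object.
#' @export
alleleCounts <- function(variants, b, d, other = NULL,
                         cross, sex, sample_id = NULL) {
    b <- as.matrix(b); d <- as.matrix(d)
    if (is.null(other)) other <- matrix(0L, nrow(b), ncol(b))
    other <- as.matrix(other)
    storage.mode(b) <- "integer"
    storage.mode(d) <- "integer"
    storage.mode(other) <- "integer"
    if (is.null(sample_id))
        sample_id <- if (!is.null(colnames(b))) colnames(b)
                     else paste0("sample", seq_len(ncol(b)))
    dimnames(b) <- dimnames(d) <- dimnames(other) <- list(NULL, sample_id)
    cd <- DataFrame(cross = as.character(cross), sex = as.character(sex),
                    row.names = sample_id)
    new("AlleleCounts", SummarizedExperiment(
        assays = list(b = b, d = d, other = other),
        rowRanges = variants, colData = cd))
}

#' ASEMatrix: aggregated counts over pseudo-samples
#'
#' A \linkS4class{SummarizedExperiment} holding the design of Figure-style
#' replicate-based ASE testing: rows are analysis units (SNPs, exons or
#' genes), columns are \emph{pseudo-samples} -- one per (mouse sample x
#' allele), so a 4-pool experiment yields 8 columns.  The single assay
#' \code{"counts"} holds summed allele-specific read counts.  Column data
#' carry \code{sample_id}, \code{allele} (B/D), \code{cross} and \code{sex};
#' row data carry \code{unit_id} and \code{gene_id}.  The aggregation level
#' (\code{"snp"}, \code{"exon"} or \code{"gene"}) is stored in
#' \code{metadata(x)$level}.
#'
#' @aliases ASEMatrix
#' @exportClass ASEMatrix
setClass("ASEMatrix", contains = "SummarizedExperiment")

setValidity("ASEMatrix", function(object) {
    msg <- character()
    if (!"counts" %in% names(assays(object)))
        msg <- c(msg, "assay 'counts' required")
    else {
        m <- assay(object, "counts")
        if (any(m < 0) || any(m != round(m)))
            msg <- c(msg, "counts must be non-negative integers")
    }
    cd <- colData(object)
    for (f in c("sample_id", "allele", "cross", "sex"))
        if (!f %in% colnames(cd))
            msg <- c(msg, sprintf("colData must have '%s'", f))
    if ("allele" %in% colnames(cd)) {
        if (!all(cd$allele %in% c("B", "D")))
            msg <- c(msg, "allele must be 'B' or 'D'")
        else if (!all(table(cd$sample_id) == 2L))
            msg <- c(msg, "each sample must contribute exactly 2 pseudo-samples")
    }
    lev <- metadata(object)$level
    if (is.null(lev) || !lev %in% c("snp", "exon", "gene"))
        msg <- c(msg, "metadata level must be snp, exon or gene")
    if (length(msg)) msg else TRUE
})

.makeASEMatrix <- function(counts, rowdat, coldat, level) {
    storage.mode(counts) <- "integer"
    se <- SummarizedExperiment(assays = list(counts = counts),
                               rowData = rowdat, colData = coldat)
    metadata(se)$level <- level
    new("ASEMatrix", se)
}
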
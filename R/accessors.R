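#' @include AllClasses.R
NULL

#' Accessors for AlleleCounts and ASEMatrix
#'
#' `bCounts`, `dCounts` and `otherCounts` return the per-SNP count matrices
#' of an [AlleleCounts-class] object; `sampleCross` and `sampleSex` return
#' per-sample (or per-pseudo-sample) metadata; `unitLevel` returns the
#' aggregation level of an [ASEMatrix-class].
#'
#' @param x an `AlleleCounts` or `ASEMatrix` object.
#' @return A matrix (count accessors) or character vector (metadata
#'   accessors).
#' @name accessors
#' @aliases bCounts dCounts otherCounts sampleCross sampleSex unitLevel
NULL

#' @rdname accessors
#' @export
setGeneric("bCounts", function(x) standardGeneric("bCounts"))
#' @rdname accessors
#' @export
setGeneric("dCounts", function(x) standardGeneric("dCounts"))
#' @rdname accessors
#' @export
setGeneric("otherCounts", function(x) standardGeneric("otherCounts"))
#' @rdname accessors
#' @export
setGeneric("sampleCross", function(x) standardGeneric("sampleCross"))
#' @rdname accessors
#' @export
setGeneric("sampleSex", function(x) standardGeneric("sampleSex"))
#' @rdname accessors
#' @export
setGeneric("unitLevel", function(x) standardGeneric("unitLevel"))

#' @rdname accessors
setMethod("bCounts", "AlleleCounts", function(x) assay(x, "b"))
#' @rdname accessors
setMethod("dCounts", "AlleleCounts", function(x) assay(x, "d"))
#' @rdname accessors
setMethod("otherCounts", "AlleleCounts", function(x) assay(x, "other"))
#' @rdname accessors
setMethod("sampleCross", "AlleleCounts", function(x) colData(x)$cross)
#' @rdname accessors
setMethod("sampleSex", "AlleleCounts", function(x) colData(x)$sex)
#' @rdname accessors
setMethod("sampleCross", "ASEMatrix", function(x) colData(x)$cross)
#' @rdname accessors
setMethod("sampleSex", "ASEMatrix", function(x) colData(x)$sex)
#' @rdname accessors
setMethod("unitLevel", "ASEMatrix", function(x) metadata(x)$level)

setMethod("show", "AlleleCounts", function(object) {
    cat(sprintf("AlleleCounts: %d SNPs x %d samples\n",
                nrow(object), ncol(object)))
    cd <- colData(object)
    cat(sprintf("  samples: %s\n",
                paste(sprintf("%s(%s,%s)", rownames(cd), cd$cross, cd$sex),
                      collapse = " ")))
    cat(sprintf("  genes: %d; total B reads %.0f, D reads %.0f\n",
                length(unique(rowRanges(object)$gene_id)),
                sum(bCounts(object)), sum(dCounts(object))))
    invisible(NULL)
})

setMethod("show", "ASEMatrix", function(object) {
    cat(sprintf("ASEMatrix (%s level): %d units x %d pseudo-samples (%d samples)\n",
                unitLevel(object), nrow(object), ncol(object),
                length(unique(colData(object)$sample_id))))
    invisible(NULL)
})
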
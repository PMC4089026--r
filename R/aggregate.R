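#' @include AllClasses.R
NULL

# SNP -> gene assignment by overlap with gene models; a SNP inside two
# genes is duplicated into both (flagged multi_gene)
.assignGenes <- function(variants, genes) {
    gr <- unlist(range(genes))
    hits <- findOverlaps(variants, gr)
    idx <- S4Vectors::queryHits(hits)
    gid <- names(gr)[S4Vectors::subjectHits(hits)]
    multi <- idx %in% idx[duplicated(idx)]
    v <- variants[idx]
    v$gene_id <- gid
    v$multi_gene <- multi
    v
}

#' Aggregate per-SNP allele counts into a pseudo-sample count matrix
#'
#' Reshapes an [AlleleCounts-class] table into the replicate design used by
#' the NB test: each mouse sample contributes two pseudo-sample columns,
#' one per allele, and rows are units -- single SNPs, exons, or whole
#' genes (counts summed over member SNPs).  With `exonic_only` (the
#' default), intronic SNPs are dropped before aggregation; at exon level
#' SNPs are assigned to exons by overlap with the gene models, and at gene
#' level a SNP overlapping two genes is counted in both (flagged
#' `multi_gene` in the row data).
#'
#' @param x an [AlleleCounts-class] object.
#' @param genes `GRangesList` of exons per gene ([readGeneModels()]);
#'   required for `level = "exon"`, optional otherwise (gene ids on the
#'   variants are used when absent).
#' @param level aggregation unit: `"gene"` (default), `"exon"` or
#'   `"snp"`.
#' @param exonic_only drop intronic SNPs before aggregating.
#' @return An [ASEMatrix-class] object.
#' @examples
#' cfg <- simConfig(seed = 7, n_genes = 20)
#' ann <- simulateAnnotation(cfg, sequence = FALSE)
#' ac <- simulateCounts(ann, simulateTruth(cfg), cfg)
#' aggregateCounts(ac, level = "gene")
#' @export
aggregateCounts <- function(x, genes = NULL,
                            level = c("gene", "exon", "snp"),
                            exonic_only = TRUE) {
    stopifnot(is(x, "AlleleCounts"))
    level <- match.arg(level)
    v <- rowRanges(x)
    b <- bCounts(x); d <- dCounts(x)
    if (exonic_only) {
        keep <- v$annotation != "intronic"
        v <- v[keep]; b <- b[keep, , drop = FALSE]; d <- d[keep, , drop = FALSE]
    }
    multi <- rep(FALSE, length(v))
    if (level == "exon") {
        if (is.null(genes)) stop("exon-level aggregation requires gene models")
        ex <- unlist(genes)
        exon_id <- paste0(names(ex), ":exon",
                          unlist(lapply(lengths(genes), seq_len)))
        hits <- findOverlaps(v, ex)
        qi <- S4Vectors::queryHits(hits)
        v <- v[qi]; b <- b[qi, , drop = FALSE]; d <- d[qi, , drop = FALSE]
        v$gene_id <- names(ex)[S4Vectors::subjectHits(hits)]
        unit <- exon_id[S4Vectors::subjectHits(hits)]
    } else if (level == "gene") {
        if (!is.null(genes)) {
            hits <- findOverlaps(v, unlist(range(genes)))
            qi <- S4Vectors::queryHits(hits)
            multi <- (qi %in% qi[duplicated(qi)])[seq_along(qi)]
            gid <- names(genes)[S4Vectors::subjectHits(hits)]
            v <- v[qi]; b <- b[qi, , drop = FALSE]; d <- d[qi, , drop = FALSE]
            v$gene_id <- gid
        }
        drop <- is.na(v$gene_id)
        if (any(drop)) {
            v <- v[!drop]; b <- b[!drop, , drop = FALSE]
            d <- d[!drop, , drop = FALSE]; multi <- multi[!drop]
        }
        unit <- v$gene_id
    } else {
        unit <- sprintf("%s:%d", as.character(seqnames(v)), start(v))
    }

    if (level == "snp") {
        ub <- b; ud <- d
        rowdat <- DataFrame(unit_id = unit, gene_id = v$gene_id,
                            annotation = v$annotation, n_snps = 1L)
    } else {
        f <- factor(unit, levels = unique(unit))
        ub <- apply(b, 2, function(col) as.integer(rowsum(col, f)))
        ud <- apply(d, 2, function(col) as.integer(rowsum(col, f)))
        if (is.null(dim(ub))) { ub <- rbind(ub); ud <- rbind(ud) }
        gid <- tapply(v$gene_id, f, `[`, 1L)
        rowdat <- DataFrame(unit_id = levels(f), gene_id = as.character(gid),
                            n_snps = as.integer(table(f)),
                            multi_gene = as.logical(
                                tapply(multi, f, any)))
    }
    cd <- colData(x)
    samples <- rownames(cd)
    counts <- matrix(0L, nrow(ub), 2L * length(samples))
    coldat <- DataFrame(sample_id = rep(samples, each = 2L),
                        allele = rep(c("B", "D"), length(samples)),
                        cross = rep(cd$cross, each = 2L),
                        sex = rep(cd$sex, each = 2L))
    for (j in seq_along(samples)) {
        counts[, 2L * j - 1L] <- ub[, j]
        counts[, 2L * j] <- ud[, j]
    }
    colnames(counts) <- paste0(coldat$sample_id, ".", coldat$allele)
    rownames(counts) <- rowdat$unit_id
    .makeASEMatrix(counts, rowdat, coldat, level)
}

#' Remove units with exclusive single-allele expression
#'
#' Drops every unit (or SNP) for which one allele has zero counts in every
#' sample -- the failure mode of spurious variant calls, which manifest as
#' B-only expression.  The removed units, with the identity of the absent
#' allele, are recorded in `metadata(x)$removed_exclusive`.
#'
#' @param x an [ASEMatrix-class] or [AlleleCounts-class] object.
#' @return The filtered object, same class as the input.
#' @export
filterExclusive <- function(x) {
    if (is(x, "ASEMatrix")) {
        cnt <- assay(x, "counts")
        isB <- colData(x)$allele == "B"
        b_zero <- rowSums(cnt[, isB, drop = FALSE]) == 0L
        d_zero <- rowSums(cnt[, !isB, drop = FALSE]) == 0L
        drop <- b_zero | d_zero
        removed <- data.frame(
            unit_id = rowData(x)$unit_id[drop],
            gene_id = rowData(x)$gene_id[drop],
            absent_allele = ifelse(d_zero[drop], "D", "B"),
            stringsAsFactors = FALSE)
        out <- x[!drop, ]
        metadata(out)$removed_exclusive <- removed
        metadata(out)$level <- metadata(x)$level
        return(out)
    }
    stopifnot(is(x, "AlleleCounts"))
    b_zero <- rowSums(bCounts(x)) == 0L
    d_zero <- rowSums(dCounts(x)) == 0L
    drop <- b_zero | d_zero
    rr <- rowRanges(x)
    removed <- data.frame(
        unit_id = sprintf("%s:%d", as.character(seqnames(rr))[drop],
                          start(rr)[drop]),
        gene_id = rr$gene_id[drop],
        absent_allele = ifelse(d_zero[drop], "D", "B"),
        stringsAsFactors = FALSE)
    out <- x[!drop, ]
    metadata(out)$removed_exclusive <- removed
    out
}

#' Build the two-condition contrast over pseudo-samples
#'
#' In `strain` mode the condition of each pseudo-sample is its allele (B
#' vs D): significant units are cis-eQTLs.  In `parent` mode it is the
#' parental origin of the allele, derived from allele x cross direction
#' (maternal strain named first: in BxD the B allele is maternal, in DxB
#' the D allele is): significant units are imprinted.  A sex filter
#' restricts the design to male or female samples.
#'
#' @param x an [ASEMatrix-class] object.
#' @param mode `"strain"` or `"parent"`.
#' @param sex_filter `"all"` (default), `"male"` or `"female"`.
#' @return A list with `condition` (factor over retained pseudo-samples,
#'   reference level first: B or paternal), `columns` (indices into
#'   `x`'s columns), `mode` and `sex_filter`.
#' @export
makeDesign <- function(x, mode = c("strain", "parent"),
                       sex_filter = c("all", "male", "female")) {
    stopifnot(is(x, "ASEMatrix"))
    mode <- match.arg(mode)
    sex_filter <- match.arg(sex_filter)
    cd <- colData(x)
    cols <- seq_len(ncol(x))
    if (sex_filter != "all")
        cols <- cols[cd$sex[cols] == c(male = "M", female = "F")[sex_filter]]
    if (!length(cols)) stop("no samples left after sex filter")
    if (mode == "strain") {
        cond <- factor(cd$allele[cols], levels = c("B", "D"))
    } else {
        maternal <- (cd$allele[cols] == "B" & cd$cross[cols] == "BxD") |
                    (cd$allele[cols] == "D" & cd$cross[cols] == "DxB")
        cond <- factor(ifelse(maternal, "maternal", "paternal"),
                       levels = c("paternal", "maternal"))
    }
    if (nlevels(droplevels(cond)) != 2L)
        stop("design must have exactly two condition levels; ",
             "parent mode needs both reciprocal crosses")
    list(condition = cond, columns = cols, mode = mode,
         sex_filter = sex_filter)
}
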
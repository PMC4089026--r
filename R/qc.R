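#' @include AllClasses.R
NULL

#' Discordant significant pairs within a shared parent unit
#'
#' The internal-consistency error estimator: among SNPs of the same exon
#' (`snp_in_exon`) or exons of the same gene (`exon_in_gene`), a pair in
#' which both members are significant but with opposite fold-change signs
#' cannot reflect a single shared allelic effect, so the discordant-pair
#' rate serves as an empirical false-positive proxy.  For exon-level
#' reports the number of known splice isoforms of each offending gene is
#' attached: discordance in single-isoform genes cannot be explained by
#' isoform-specific regulation.
#'
#' @param results a [runASE()] result at snp or exon level (the level is
#'   read from the result's attributes).
#' @param genes `GRangesList` from [readGeneModels()]; required at snp
#'   level (to place SNPs into exons) and for isoform counts at exon
#'   level.
#' @param alpha significance threshold on `padj`.
#' @return list with `level`, `n_units_tested`, `n_pairs_tested`,
#'   `n_significant_pairs`, `n_discordant`, and `pairs` (data.frame of
#'   offending pairs with directions, plus `n_isoforms` at exon level).
#' @export
discordantPairs <- function(results, genes = NULL, alpha = 0.05) {
    level <- attr(results, "level")
    if (is.null(level) || !level %in% c("snp", "exon"))
        stop("results must be at snp or exon level")
    if (level == "snp") {
        if (is.null(genes)) stop("snp-level pairing needs gene models")
        parts <- strsplit(results$unit_id, ":")
        pos <- as.integer(vapply(parts, `[`, character(1), 2L))
        chrom <- vapply(parts, `[`, character(1), 1L)
        snp <- GRanges(chrom, IRanges(pos, width = 1L))
        ex <- unlist(genes)
        exon_id <- paste0(names(ex), ":exon",
                          unlist(lapply(lengths(genes), seq_len)))
        hits <- findOverlaps(snp, ex)
        parent <- rep(NA_character_, nrow(results))
        parent[S4Vectors::queryHits(hits)] <-
            exon_id[S4Vectors::subjectHits(hits)]
        if (anyNA(parent)) {
            if (all(is.na(parent))) stop("no unit could be mapped to an exon")
            results <- results[!is.na(parent), ]
            parent <- parent[!is.na(parent)]
        }
        plevel <- "snp_in_exon"
    } else {
        parent <- results$gene_id
        plevel <- "exon_in_gene"
    }
    sig <- results$padj < alpha
    pairs <- list()
    n_pairs <- 0L; n_sig_pairs <- 0L
    for (p in unique(parent[duplicated(parent)])) {
        idx <- which(parent == p)
        cmb <- utils::combn(idx, 2L)
        n_pairs <- n_pairs + ncol(cmb)
        for (k in seq_len(ncol(cmb))) {
            i <- cmb[1, k]; j <- cmb[2, k]
            if (!(sig[i] && sig[j])) next
            n_sig_pairs <- n_sig_pairs + 1L
            if (sign(results$log2fc[i]) * sign(results$log2fc[j]) < 0)
                pairs[[length(pairs) + 1L]] <- data.frame(
                    parent = p,
                    unit_a = results$unit_id[i],
                    unit_b = results$unit_id[j],
                    log2fc_a = results$log2fc[i],
                    log2fc_b = results$log2fc[j],
                    gene_id = results$gene_id[i],
                    stringsAsFactors = FALSE)
        }
    }
    pairs <- if (length(pairs)) do.call(rbind, pairs)
             else data.frame(parent = character(), unit_a = character(),
                             unit_b = character(), log2fc_a = numeric(),
                             log2fc_b = numeric(), gene_id = character(),
                             stringsAsFactors = FALSE)
    if (level == "exon" && !is.null(genes) && nrow(pairs))
        pairs$n_isoforms <- mcols(genes)$n_isoforms[
            match(pairs$gene_id, mcols(genes)$gene_id)]
    list(level = plevel,
         n_units_tested = nrow(results),
         n_pairs_tested = n_pairs,
         n_significant_pairs = n_sig_pairs,
         n_discordant = nrow(pairs),
         pairs = pairs)
}

#' Genes with exclusive single-allele expression
#'
#' Lists genes whose every informative exonic SNP shows reads from only
#' one and the same allele across all samples -- the signature of
#' spurious variant calls (a truly monomorphic site yields B-only
#' counts).  A minimum total coverage guards against calling noise at
#' barely covered genes.
#'
#' @param x an [AlleleCounts-class] object.
#' @param min_coverage minimum summed coverage (both alleles, all
#'   samples, all SNPs) for a gene to be reported (default 8).
#' @return data.frame with `gene_id`, `allele` (the only expressed one),
#'   `n_exonic_snps`, `total_count`.
#' @export
exclusiveReport <- function(x, min_coverage = 8L) {
    stopifnot(is(x, "AlleleCounts"))
    v <- rowRanges(x)
    keep <- v$annotation != "intronic" & !is.na(v$gene_id)
    b <- rowSums(bCounts(x)[keep, , drop = FALSE])
    d <- rowSums(dCounts(x)[keep, , drop = FALSE])
    gid <- v$gene_id[keep]
    out <- lapply(split(seq_along(gid), gid), function(idx) {
        bi <- b[idx]; di <- d[idx]
        inf <- bi + di > 0
        if (!any(inf)) return(NULL)
        total <- sum(bi) + sum(di)
        if (total < min_coverage) return(NULL)
        if (all(di[inf] == 0)) allele <- "B"
        else if (all(bi[inf] == 0)) allele <- "D"
        else return(NULL)
        data.frame(gene_id = gid[idx][1], allele = allele,
                   n_exonic_snps = length(idx),
                   total_count = total, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    if (is.null(out))
        out <- data.frame(gene_id = character(), allele = character(),
                          n_exonic_snps = integer(),
                          total_count = numeric(),
                          stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Allelic expression of premature stop-codon variants
#'
#' For every variant annotated `stop_gain` or `stop_loss` (the stop
#' change carried on the D allele), pools counts across samples and
#' reports the impaired-over-intact expression ratio (impaired allele =
#' D).  A variant shows a "marked reduction" when that ratio falls at or
#' below `reduction_threshold` -- transcripts degraded by
#' nonsense-mediated decay are expected in this class, while variants
#' escaping it show near-equal expression of both alleles.
#'
#' @param x an [AlleleCounts-class] object whose variants carry stop
#'   annotations (e.g. from [simulateCounts()] or [countAlleles()]).
#' @param reduction_threshold marked-reduction cutoff on impaired/intact
#'   (default 0.5, i.e. 2-fold).
#' @return list with `variants` (per-variant data.frame: position, class,
#'   counts, ratio, marked) and `summary` (per-class n, n_marked,
#'   fraction_marked); variants without counts are skipped and counted in
#'   `n_skipped`.
#' @export
stopCodonASE <- function(x, reduction_threshold = 0.5) {
    stopifnot(is(x, "AlleleCounts"))
    v <- rowRanges(x)
    idx <- which(v$annotation %in% c("stop_gain", "stop_loss"))
    if (!length(idx)) stop("no stop-annotated variants in the table")
    b <- rowSums(bCounts(x)[idx, , drop = FALSE])
    d <- rowSums(dCounts(x)[idx, , drop = FALSE])
    covered <- b + d > 0
    vt <- data.frame(
        chrom = as.character(seqnames(v))[idx][covered],
        pos = start(v)[idx][covered],
        gene_id = v$gene_id[idx][covered],
        class = v$annotation[idx][covered],
        intact_count = b[covered],
        impaired_count = d[covered],
        ratio = d[covered] / pmax(1, b[covered]),
        stringsAsFactors = FALSE)
    vt$marked <- vt$ratio <= reduction_threshold
    summ <- do.call(rbind, lapply(split(vt, vt$class), function(g)
        data.frame(class = g$class[1], n = nrow(g),
                   n_marked = sum(g$marked),
                   fraction_marked = mean(g$marked),
                   stringsAsFactors = FALSE)))
    rownames(summ) <- NULL
    list(variants = vt, summary = summ, n_skipped = sum(!covered))
}

#' Cross-dataset concordance of allelic fold changes
#'
#' Measures how well allelic log2 fold changes agree between two result
#' sets over their shared units (e.g. two tissues, or two analysis
#' variants), optionally summarized within externally supplied gene
#' groups.
#'
#' @param res_a,res_b [runASE()] results sharing unit ids.
#' @param labels optional named character vector (names = unit ids)
#'   grouping the shared units, e.g. by local-eQTL overlap status.
#' @return list with `r_squared`, `slope` (regression of b on a),
#'   `n_shared`, and `by_label` (per-group n and r_squared) when labels
#'   are given.
#' @export
aseConcordance <- function(res_a, res_b, labels = NULL) {
    shared <- intersect(res_a$unit_id, res_b$unit_id)
    if (length(shared) < 3L) stop("need at least 3 shared units")
    a <- res_a$log2fc[match(shared, res_a$unit_id)]
    b <- res_b$log2fc[match(shared, res_b$unit_id)]
    fit <- stats::lm(b ~ a)
    out <- list(r_squared = cor(a, b)^2,
                slope = unname(coef(fit)[2]),
                n_shared = length(shared))
    if (!is.null(labels)) {
        lab <- labels[shared]
        lab[is.na(lab)] <- "unlabelled"
        out$by_label <- do.call(rbind, lapply(split(seq_along(a), lab),
            function(i) data.frame(
                label = lab[i][1], n = length(i),
                r_squared = if (length(i) >= 3L) cor(a[i], b[i])^2
                            else NA_real_,
                stringsAsFactors = FALSE)))
        rownames(out$by_label) <- NULL
    }
    out
}
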
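#' @include AllClasses.R
#' @importFrom stats phyper wilcox.test prop.test lm
NULL

#' Conserved DNase I peaks across two replicates
#'
#' Retains the replicate-1 peaks that overlap (by at least 1 bp) any
#' replicate-2 peak; the retained interval is the replicate-1 interval
#' and its signal is the mean of the replicate-1 signal and the signal of
#' the best-overlapping (largest overlap width) replicate-2 peak.
#'
#' @param rep1,rep2 `GRanges` from [readNarrowPeak()].
#' @return `GRanges` of conserved peaks with averaged `signal`.
#' @export
conservedPeaks <- function(rep1, rep2) {
    hits <- findOverlaps(rep1, rep2)
    if (!length(hits)) return(rep1[0])
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    ow <- width(IRanges::pintersect(IRanges::ranges(rep1)[qh],
                                    IRanges::ranges(rep2)[sh]))
    best <- tapply(seq_along(qh), qh, function(i) i[which.max(ow[i])])
    keep <- as.integer(names(best))
    out <- rep1[keep]
    out$signal <- (rep1$signal[keep] +
                   rep2$signal[sh[unlist(best)]]) / 2
    out
}

#' Partition peaks into intact versus polymorphic
#'
#' A peak is polymorphic when any SNP position or indel interval overlaps
#' it; intact peaks carry no polymorphism between the two strains.  The
#' partition is exhaustive and disjoint.
#'
#' @param peaks `GRanges` of (conserved) peaks.
#' @param variants `GRanges` of SNPs and indels ([readVariants()]).
#' @return list with `intact` and `polymorphic` `GRanges`.
#' @export
intactPeaks <- function(peaks, variants) {
    poly <- overlapsAny(peaks, variants)
    list(intact = peaks[!poly], polymorphic = peaks[poly])
}

#' Per-gene DNase peak summary and F ratio
#'
#' Assigns peaks to genes when they overlap the gene span extended by
#' `window_bp` on both sides (a peak near two genes counts for both),
#' and computes for each gene with at least one peak: peak and
#' intact-peak counts, total and intact signal, and the F ratio -- the
#' proportion of the gene's DNase I signal that derives from intact
#' (non-polymorphic) peaks.
#'
#' @param genes `GRangesList` from [readGeneModels()].
#' @param intact,polymorphic the partition from [intactPeaks()].
#' @param window_bp flank added to the gene span, in \[0, 10000\].
#' @param ase_groups optional named character vector (names = gene ids)
#'   with values `"B"`, `"D"` or `"NS"` assigning each gene's ASE
#'   direction group; genes absent from it get `"NS"`.
#' @return data.frame with `gene_id`, `n_peaks`, `n_intact_peaks`,
#'   `total_signal`, `intact_signal`, `f_ratio`, `ase_group`.
#' @export
geneRegSummary <- function(genes, intact, polymorphic, window_bp = 10000,
                           ase_groups = NULL) {
    stopifnot(window_bp >= 0, window_bp <= 10000)
    spans <- unlist(range(genes))
    spans <- suppressWarnings(GenomicRanges::resize(
        spans, width(spans) + 2 * window_bp, fix = "center"))
    spans <- GenomicRanges::trim(spans)
    tally <- function(peaks) {
        hits <- findOverlaps(spans, peaks)
        gi <- S4Vectors::queryHits(hits)
        n <- tabulate(gi, length(spans))
        sig <- rep(0, length(spans))
        if (length(hits)) {
            agg <- tapply(peaks$signal[S4Vectors::subjectHits(hits)], gi, sum)
            sig[as.integer(names(agg))] <- agg
        }
        list(n = n, signal = sig)
    }
    ti <- tally(intact); tp <- tally(polymorphic)
    n_peaks <- ti$n + tp$n
    total_signal <- ti$signal + tp$signal
    keep <- n_peaks > 0L
    gid <- names(spans)[keep]
    grp <- rep("NS", sum(keep))
    if (!is.null(ase_groups)) {
        m <- ase_groups[gid]
        grp[!is.na(m)] <- m[!is.na(m)]
    }
    data.frame(gene_id = gid,
               n_peaks = n_peaks[keep],
               n_intact_peaks = ti$n[keep],
               total_signal = total_signal[keep],
               intact_signal = ti$signal[keep],
               f_ratio = ti$signal[keep] / total_signal[keep],
               ase_group = grp,
               stringsAsFactors = FALSE)
}

#' Compare F ratios and intact-peak fractions across ASE groups
#'
#' Pairwise two-sided rank-sum (Wilcoxon) tests on per-gene F ratios and
#' two-proportion tests on pooled intact-peak counts, for every pair of
#' ASE direction groups (B overexpressed, D overexpressed, NS).
#'
#' @param summaries data.frame from [geneRegSummary()] with non-empty
#'   `ase_group`s.
#' @return data.frame with one row per group pair: group sizes, median F
#'   ratios, rank-sum p-value, pooled intact-peak fractions and
#'   two-proportion p-value.
#' @export
groupCompare <- function(summaries) {
    groups <- split(summaries, summaries$ase_group)
    if (length(groups) < 2L) stop("need at least two non-empty groups")
    empty <- names(groups)[vapply(groups, nrow, integer(1)) == 0L]
    if (length(empty)) stop("empty group: ", paste(empty, collapse = ", "))
    prs <- utils::combn(names(groups), 2L)
    out <- lapply(seq_len(ncol(prs)), function(k) {
        a <- groups[[prs[1, k]]]; b <- groups[[prs[2, k]]]
        w <- suppressWarnings(wilcox.test(a$f_ratio, b$f_ratio))
        pt <- suppressWarnings(prop.test(
            c(sum(a$n_intact_peaks), sum(b$n_intact_peaks)),
            c(sum(a$n_peaks), sum(b$n_peaks))))
        data.frame(group_a = prs[1, k], group_b = prs[2, k],
                   n_a = nrow(a), n_b = nrow(b),
                   median_f_a = median(a$f_ratio),
                   median_f_b = median(b$f_ratio),
                   p_f_ratio = w$p.value,
                   intact_frac_a = sum(a$n_intact_peaks) / sum(a$n_peaks),
                   intact_frac_b = sum(b$n_intact_peaks) / sum(b$n_peaks),
                   p_intact_fraction = pt$p.value,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Hypergeometric enrichment of a set overlap
#'
#' One-sided upper-tail hypergeometric test of the observed overlap
#' between two gene sets drawn from a common universe; with three sets
#' the seven Venn region counts are reported as well.
#'
#' @param setA,setB character vectors of gene ids.
#' @param universe character vector containing both sets.
#' @param setC optional third set for the Venn counts.
#' @return list with `n_overlap`, `p_value`, set sizes, and `venn`
#'   (named counts of exclusive regions) when `setC` is given.
#' @examples
#' setOverlap(letters[1:5], letters[1:5], letters[1:10])  # p = 1/252
#' @export
setOverlap <- function(setA, setB, universe, setC = NULL) {
    setA <- unique(setA); setB <- unique(setB); universe <- unique(universe)
    if (!all(setA %in% universe) || !all(setB %in% universe) ||
        (!is.null(setC) && !all(setC %in% universe)))
        stop("sets must be subsets of the universe")
    k <- length(intersect(setA, setB))
    N <- length(universe)
    p <- phyper(k - 1L, length(setA), N - length(setA), length(setB),
                lower.tail = FALSE)
    out <- list(n_overlap = k, p_value = p,
                n_a = length(setA), n_b = length(setB), n_universe = N)
    if (!is.null(setC)) {
        setC <- unique(setC)
        inA <- universe %in% setA
        inB <- universe %in% setB
        inC <- universe %in% setC
        out$venn <- c(
            a_only = sum(inA & !inB & !inC),
            b_only = sum(!inA & inB & !inC),
            c_only = sum(!inA & !inB & inC),
            ab = sum(inA & inB & !inC),
            ac = sum(inA & !inB & inC),
            bc = sum(!inA & inB & inC),
            abc = sum(inA & inB & inC))
    }
    out
}

#' Overlap fraction as a function of significance stringency
#'
#' For each p-value cutoff, the fraction of A-significant genes that are
#' also B-significant.  If poor overlap between two studies reflected
#' lack of power, this fraction should rise as the cutoff tightens.
#'
#' @param pvals_a,pvals_b named numeric vectors of p-values (names =
#'   gene ids) over a shared universe.
#' @param cutoffs decreasing grid of cutoffs applied to both sets.
#' @return data.frame with `cutoff`, `n_a`, `n_overlap`, `fraction`;
#'   attribute `monotone_increasing` summarizes whether the fraction
#'   rises monotonically with stringency.
#' @export
thresholdSweep <- function(pvals_a, pvals_b, cutoffs) {
    if (!length(cutoffs)) stop("empty cutoff grid")
    shared <- intersect(names(pvals_a), names(pvals_b))
    if (!length(shared)) stop("no shared universe")
    pa <- pvals_a[shared]; pb <- pvals_b[shared]
    cutoffs <- sort(cutoffs, decreasing = TRUE)
    out <- do.call(rbind, lapply(cutoffs, function(ct) {
        a <- names(pa)[pa < ct]
        ov <- sum(pb[a] < ct)
        data.frame(cutoff = ct, n_a = length(a), n_overlap = ov,
                   fraction = if (length(a)) ov / length(a) else NA_real_)
    }))
    # rows are ordered by decreasing cutoff, i.e. increasing stringency
    fr <- out$fraction[!is.na(out$fraction)]
    attr(out, "monotone_increasing") <-
        length(fr) >= 2L && all(diff(fr) >= -1e-12)
    out
}

#' Effect sizes by cross-study overlap category
#'
#' Groups genes by their significance pattern in the ASE study versus an
#' external local-eQTL dataset (+/+, +/-, -/+, -/-) and summarizes effect
#' sizes per group: the ASE effect is the linear allelic fold change
#' `2^|log2fc|`, restricted to genes expressing both alleles
#' (exclusive-expression genes are excluded); the eQTL effect is the
#' fold change between homozygous genotypes carried in the record table.
#'
#' @param ase_results a [runASE()] result (gene level).
#' @param eqtl data.frame with columns `gene_id`, `dataset`,
#'   `significant` (logical), `effect_size` (> 0), and optionally
#'   `polymorphic_in_D` (logical filter applied when present).
#' @param exclusive_genes gene ids to exclude from ASE effect summaries
#'   (e.g. from [exclusiveReport()]).
#' @return data.frame with one row per (dataset, category): n, median
#'   and IQR of ASE and eQTL effect sizes.
#' @export
effectSizeCompare <- function(ase_results, eqtl, exclusive_genes = NULL) {
    stopifnot(all(c("gene_id", "dataset", "significant",
                    "effect_size") %in% colnames(eqtl)))
    if (any(eqtl$effect_size <= 0)) stop("effect sizes must be positive")
    if ("polymorphic_in_D" %in% colnames(eqtl))
        eqtl <- eqtl[eqtl$polymorphic_in_D, , drop = FALSE]
    shared <- intersect(ase_results$gene_id, eqtl$gene_id)
    if (!length(shared)) stop("no shared genes between ASE and eQTL tables")
    ia <- match(eqtl$gene_id, ase_results$gene_id)
    keep <- !is.na(ia)
    eqtl <- eqtl[keep, ]; ia <- ia[keep]
    ase_sig <- ase_results$significant[ia]
    ase_eff <- 2^abs(ase_results$log2fc[ia])
    if (!is.null(exclusive_genes))
        ase_eff[eqtl$gene_id %in% exclusive_genes] <- NA_real_
    category <- paste0(ifelse(ase_sig, "+", "-"), "/",
                       ifelse(eqtl$significant, "+", "-"))
    grp <- split(seq_len(nrow(eqtl)), list(eqtl$dataset, category),
                 sep = " ", drop = TRUE)
    out <- lapply(names(grp), function(g) {
        i <- grp[[g]]
        ae <- ase_eff[i][!is.na(ase_eff[i])]
        data.frame(dataset = eqtl$dataset[i][1],
                   category = sub("^\\S+ ", "", g),
                   n = length(i),
                   ase_median = if (length(ae)) median(ae) else NA_real_,
                   ase_iqr = if (length(ae)) stats::IQR(ae) else NA_real_,
                   eqtl_median = median(eqtl$effect_size[i]),
                   eqtl_iqr = stats::IQR(eqtl$effect_size[i]),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    out[order(out$dataset, out$category), ]
}
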
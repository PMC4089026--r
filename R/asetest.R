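#' @include AllClasses.R aggregate.R
#' @importFrom stats p.adjust fisher.test dnbinom dpois pnorm glm Gamma
#'   coef median var cor complete.cases setNames
NULL

#' Median-of-ratios size factors
#'
#' The library-scaling estimator for count columns: for each column j,
#' `s_j = median_i ( k_ij / g_i )` where `g_i` is the geometric mean of
#' unit i across columns, the median running over units with all-positive
#' counts.  Applied to pseudo-sample columns this absorbs both sequencing
#' depth and the global B-over-D reference-mapping bias, since the bias
#' multiplies every B column by a common factor.
#'
#' @param counts integer matrix, units x columns.
#' @param pseudo_reference fall back to a geometric mean over positive
#'   counts only (so units with zeros still contribute) when no unit has
#'   all-positive counts.
#' @return positive numeric vector, one factor per column.
#' @examples
#' m <- cbind(a = c(10L, 20L, 30L), b = c(20L, 40L, 60L))
#' aseSizeFactors(m)  # 1/sqrt(2), sqrt(2)
#' @export
aseSizeFactors <- function(counts, pseudo_reference = FALSE) {
    counts <- as.matrix(counts)
    pos <- rowSums(counts > 0) == ncol(counts)
    if (!any(pos)) {
        if (!pseudo_reference)
            stop("no unit with all-positive counts; ",
                 "retry with pseudo_reference = TRUE")
        lg <- log(counts)
        lg[!is.finite(lg)] <- NA
        geo <- exp(rowMeans(lg, na.rm = TRUE))
        pos <- is.finite(geo) & geo > 0
    } else {
        geo <- exp(rowMeans(log(counts[pos, , drop = FALSE])))
        ratios <- counts[pos, , drop = FALSE] / geo
        return(apply(ratios, 2, median))
    }
    ratios <- counts[pos, , drop = FALSE] / geo[pos]
    apply(ratios, 2, median, na.rm = TRUE)
}

#' Estimate per-unit NB dispersion with a fitted mean trend
#'
#' Method-of-moments dispersion estimation on size-factor-normalized
#' counts, pooled across the two conditions: with pooled within-condition
#' variance `v` and overall mean `m`, the raw estimate is
#' `alpha_hat = max(0, (v - m) / m^2)` (the NB variance law
#' `var = mu + alpha * mu^2` solved for alpha).  A mean-dispersion trend
#' `alpha(mu) = a0 + a1/mu` is fitted by gamma-family regression over
#' units with positive raw estimates, and the working dispersion of each
#' unit is the maximum of its raw estimate and the fitted value -- the
#' conservative sharing choice, so a unit is never assigned less
#' variability than either its own data or the trend supports.
#'
#' @param counts integer matrix, units x columns (pseudo-samples).
#' @param condition factor with two levels over the columns; each level
#'   needs at least 2 replicates.
#' @param sf size factors from [aseSizeFactors()].
#' @return list of class `"DispersionModel"`: `empirical`, `fitted`
#'   (trend values), `working`, `mean` (per-unit normalized mean), and
#'   `trend_coef` (a0, a1).
#' @export
estimateDispersionModel <- function(counts, condition, sf) {
    counts <- as.matrix(counts)
    condition <- droplevels(as.factor(condition))
    stopifnot(nlevels(condition) == 2L, length(sf) == ncol(counts))
    if (any(table(condition) < 2L))
        stop("dispersion estimation needs >= 2 replicates per condition")
    q <- sweep(counts, 2, sf, "/")
    mu <- rowMeans(q)
    lv <- levels(condition)
    n1 <- sum(condition == lv[1]); n2 <- sum(condition == lv[2])
    v1 <- apply(q[, condition == lv[1], drop = FALSE], 1, var)
    v2 <- apply(q[, condition == lv[2], drop = FALSE], 1, var)
    vbar <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    alpha_hat <- ifelse(mu > 0, pmax(0, (vbar - mu) / mu^2), 0)

    use <- alpha_hat > 0 & mu > 0
    a0 <- median(alpha_hat[use])
    a1 <- 0
    if (sum(use) >= 10L) {
        fit <- tryCatch(
            glm(alpha_hat[use] ~ I(1 / mu[use]),
                family = Gamma(link = "identity"),
                start = c(a0, 1)),
            error = function(e) NULL, warning = function(w) NULL)
        if (!is.null(fit) && all(is.finite(coef(fit))) &&
            coef(fit)[1] >= 0) {
            a0 <- unname(coef(fit)[1]); a1 <- max(0, unname(coef(fit)[2]))
        }
    }
    if (!is.finite(a0)) a0 <- 1e-8
    fitted_disp <- ifelse(mu > 0, a0 + a1 / mu, a0)
    structure(list(empirical = alpha_hat,
                   fitted = fitted_disp,
                   working = pmax(alpha_hat, fitted_disp),
                   mean = mu,
                   trend_coef = c(a0 = a0, a1 = a1)),
              class = "DispersionModel")
}

# Conditional NB exact p-value for one unit.
# kA, kB: raw counts per condition; sfA, sfB size factors; alpha working
# dispersion. Models the two condition sums as NB variables with moments
# from the pooled normalized mean, conditions on their total, and sums the
# probabilities of all splits no more likely than the observed one.
.nbExactOne <- function(kA, kB, sfA, sfB, alpha, enum_cap = 10000L) {
    KA <- sum(kA); KB <- sum(kB); KS <- KA + KB
    if (KS == 0L) return(c(pval = 1, zero = 1))
    q0 <- KS / (sum(sfA) + sum(sfB))
    SA <- sum(sfA); SB <- sum(sfB)
    muA <- q0 * SA; muB <- q0 * SB
    vA <- muA + alpha * q0^2 * sum(sfA^2)
    vB <- muB + alpha * q0^2 * sum(sfB^2)
    ldens <- function(x, m, v) {
        if (v - m < 1e-8 * m) dpois(x, m, log = TRUE)
        else dnbinom(x, mu = m, size = m^2 / (v - m), log = TRUE)
    }
    if (KS <= enum_cap) {
        a <- 0:KS
        ll <- ldens(a, muA, vA) + ldens(KS - a, muB, vB)
        lobs <- ll[KA + 1L]
        mx <- max(ll)
        den <- sum(exp(ll - mx))
        num <- sum(exp(ll[ll <= lobs + 1e-7] - mx))
        return(c(pval = min(1, num / den), zero = 0))
    }
    # large totals: normal approximation to the conditional split law
    m <- muA + vA / (vA + vB) * (KS - muA - muB)
    s <- sqrt(vA * vB / (vA + vB))
    p <- 2 * min(pnorm(KA + 0.5, m, s), pnorm(KA - 0.5, m, s,
                                              lower.tail = FALSE))
    c(pval = min(1, p), zero = 0)
}

#' Conditional negative-binomial exact test for one unit
#'
#' Tests whether the counts of one unit differ between two conditions,
#' given replicates: the per-condition sums are modelled as NB variables
#' whose moments derive from the pooled normalized mean and the working
#' dispersion (scaled by the condition size-factor sums), and the reported
#' p-value is the total probability of all splits of the grand total that
#' are no more probable than the observed split, conditioned on that
#' total.  Totals above `enum_cap` switch to a normal approximation of
#' the conditional split distribution.
#'
#' @param kA,kB raw counts of the unit in condition A / B replicates.
#' @param sfA,sfB matching size factors.
#' @param dispersion working dispersion alpha of the unit.
#' @param enum_cap largest grand total enumerated exactly (default 10000).
#' @return list with `pval` (in (0, 1]) and `zero_total` flag.
#' @examples
#' nbExactTest(c(10, 12), c(11, 10), c(1, 1), c(1, 1), dispersion = 0.05)
#' @export
nbExactTest <- function(kA, kB, sfA, sfB, dispersion,
                        enum_cap = 10000L) {
    if (missing(dispersion) || is.na(dispersion))
        stop("a working dispersion is required")
    r <- .nbExactOne(kA, kB, sfA, sfB, dispersion, enum_cap)
    list(pval = unname(r["pval"]), zero_total = r["zero"] == 1)
}

#' Per-SNP Fisher exact test against the library background
#'
#' The classical single-sample ASE baseline: a two-sided Fisher exact test
#' of the 2x2 table `[[b, d], [B_total - b, D_total - d]]`, comparing the
#' SNP's allelic split to the rest of the library.  Using library totals
#' as the reference absorbs the global allelic mapping bias.
#'
#' @param b,d allele counts at the SNP in one sample.
#' @param B_total,D_total library-wide allele counts for that sample.
#' @return list with `pval`, `estimate` (sample odds ratio) and
#'   `degenerate` flag (zero-margin table, p forced to 1).
#' @export
fisherSnpTest <- function(b, d, B_total, D_total) {
    stopifnot(b >= 0, d >= 0, b <= B_total, d <= D_total)
    tab <- matrix(c(b, B_total - b, d, D_total - d), 2L, 2L)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
        return(list(pval = 1, estimate = NA_real_, degenerate = TRUE))
    ft <- fisher.test(tab)
    list(pval = min(1, ft$p.value), estimate = unname(ft$estimate),
         degenerate = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement; adjusted values
#' satisfy `pval <= padj <= 1`.
#'
#' @param pvals numeric vector in \[0, 1\]; `NaN` is rejected.
#' @return numeric vector of adjusted p-values.
#' @export
bhAdjust <- function(pvals) {
    if (any(is.na(pvals)))
        stop("NA/NaN p-values are not allowed")
    stopifnot(all(pvals >= 0 & pvals <= 1))
    p.adjust(pvals, method = "BH")
}

#' Run the replicate-based NB allelic-imbalance contrast
#'
#' The main entry point of the statistical core: given an aggregated
#' [ASEMatrix-class] and a contrast mode, estimates size factors over the
#' pseudo-sample columns, estimates per-unit working dispersions, applies
#' the conditional NB exact test to every unit, and controls FDR by
#' Benjamini-Hochberg.  The log2 fold change is log2(D/B) in strain mode
#' and log2(maternal/paternal) in parent mode, computed from normalized
#' condition means with a pseudocount.
#'
#' @param x an [ASEMatrix-class] object.
#' @param mode,sex_filter contrast, see [makeDesign()].  A sex-restricted
#'   run re-estimates size factors and dispersions from that subset only.
#' @param alpha FDR threshold for the `significant` / `direction` calls.
#' @param pseudocount added to normalized condition means for the fold
#'   change (default 0.5).
#' @param enum_cap see [nbExactTest()].
#' @return data.frame with one row per unit: `unit_id`, `gene_id`,
#'   `base_mean`, `log2fc`, `pval`, `padj`, `significant`, `direction`
#'   (B/D in strain mode, maternal/paternal in parent mode, `none` when
#'   not significant).  The design, size factors and dispersion model are
#'   attached as attributes.
#' @examples
#' cfg <- simConfig(seed = 3, n_genes = 40, fraction_cis = 0.2)
#' ann <- simulateAnnotation(cfg, sequence = FALSE)
#' ac <- simulateCounts(ann, simulateTruth(cfg), cfg)
#' res <- runASE(aggregateCounts(ac))
#' head(res[order(res$padj), ])
#' @export
runASE <- function(x, mode = c("strain", "parent"),
                   sex_filter = c("all", "male", "female"),
                   alpha = 0.05, pseudocount = 0.5, enum_cap = 10000L) {
    stopifnot(is(x, "ASEMatrix"))
    design <- makeDesign(x, mode, sex_filter)
    counts <- assay(x, "counts")[, design$columns, drop = FALSE]
    cond <- design$condition
    sf <- aseSizeFactors(counts, pseudo_reference = TRUE)
    dm <- estimateDispersionModel(counts, cond, sf)
    lv <- levels(cond)
    iA <- which(cond == lv[1]); iB <- which(cond == lv[2])
    n <- nrow(counts)
    pval <- numeric(n)
    for (i in seq_len(n)) {
        pval[i] <- .nbExactOne(counts[i, iA], counts[i, iB],
                               sf[iA], sf[iB], dm$working[i],
                               enum_cap)["pval"]
    }
    q <- sweep(counts, 2, sf, "/")
    mA <- rowMeans(q[, iA, drop = FALSE])
    mB <- rowMeans(q[, iB, drop = FALSE])
    # reference level (B / paternal) is lv[1]; report log2(lv2 / lv1)
    log2fc <- log2((mB + pseudocount) / (mA + pseudocount))
    padj <- bhAdjust(pval)
    sig <- padj < alpha
    dirpos <- lv[2]; dirneg <- lv[1]
    direction <- ifelse(!sig, "none", ifelse(log2fc > 0, dirpos, dirneg))
    res <- data.frame(unit_id = rowData(x)$unit_id,
                      gene_id = rowData(x)$gene_id,
                      base_mean = rowMeans(q),
                      log2fc = log2fc,
                      pval = pval, padj = padj,
                      significant = sig, direction = direction,
                      stringsAsFactors = FALSE)
    attr(res, "mode") <- design$mode
    attr(res, "sex_filter") <- design$sex_filter
    attr(res, "alpha") <- alpha
    attr(res, "size_factors") <- setNames(sf, colnames(counts))
    attr(res, "dispersion") <- dm
    attr(res, "level") <- unitLevel(x)
    res
}

#' The per-sample Fisher-and-intersect baseline
#'
#' The comparator pipeline the NB method is measured against: for every
#' unit and sample, a Fisher exact test of the sample's allelic split
#' against its library totals, BH adjustment within sample, then a unit is
#' called only when significant with a concordant direction in every
#' sample.
#'
#' @param x an [AlleleCounts-class] object.
#' @param alpha within-sample FDR threshold.
#' @param level `"gene"` (aggregate member-SNP counts per sample first,
#'   the default) or `"snp"`.
#' @param exonic_only drop intronic SNPs first.
#' @return data.frame with one row per unit: `unit_id`, `gene_id`,
#'   `called`, `direction` (`B`/`D`/`none`), and `n_sig_samples`.
#' @export
fisherPipeline <- function(x, alpha = 0.05, level = c("gene", "snp"),
                           exonic_only = TRUE) {
    stopifnot(is(x, "AlleleCounts"))
    level <- match.arg(level)
    if (ncol(x) < 2L) stop("the intersection rule needs >= 2 samples")
    v <- rowRanges(x)
    b <- bCounts(x); d <- dCounts(x)
    if (exonic_only) {
        keep <- v$annotation != "intronic"
        v <- v[keep]; b <- b[keep, , drop = FALSE]; d <- d[keep, , drop = FALSE]
    }
    if (level == "gene") {
        keep <- !is.na(v$gene_id)
        f <- factor(v$gene_id[keep], levels = unique(v$gene_id[keep]))
        b <- rowsum(b[keep, , drop = FALSE], f)
        d <- rowsum(d[keep, , drop = FALSE], f)
        unit <- rownames(b); gid <- unit
    } else {
        unit <- sprintf("%s:%d", as.character(seqnames(v)), start(v))
        gid <- v$gene_id
    }
    Btot <- colSums(b); Dtot <- colSums(d)
    nsamp <- ncol(b)
    pm <- matrix(1, nrow(b), nsamp)
    dm <- matrix(0, nrow(b), nsamp)  # signed direction: +1 = D up
    for (j in seq_len(nsamp)) {
        for (i in seq_len(nrow(b))) {
            ft <- fisherSnpTest(b[i, j], d[i, j], Btot[j], Dtot[j])
            pm[i, j] <- ft$pval
        }
        # D up when the SNP's D share exceeds the library's
        expected_d <- Dtot[j] / (Btot[j] + Dtot[j])
        obs_d <- d[, j] / pmax(1, b[, j] + d[, j])
        dm[, j] <- sign(obs_d - expected_d)
    }
    padj <- apply(pm, 2, bhAdjust)
    sig <- padj < alpha
    concord <- rowSums(sig) == nsamp &
        (rowSums(dm == 1) == nsamp | rowSums(dm == -1) == nsamp)
    direction <- ifelse(!concord, "none", ifelse(dm[, 1] == 1, "D", "B"))
    res <- data.frame(unit_id = unit, gene_id = gid,
                      called = concord, direction = direction,
                      n_sig_samples = rowSums(sig),
                      stringsAsFactors = FALSE)
    # per-sample matrices support calling at other thresholds without
    # re-running the tests (e.g. matching a realized FDR)
    attr(res, "padj_matrix") <- padj
    attr(res, "direction_matrix") <- dm
    res
}

#' Significant-call counts as replicates are added
#'
#' Reruns the NB contrast on the first k mouse samples for each k,
#' reporting how the number of significant units grows with replication
#' and how the reduced-replicate calls overlap the full-data calls.
#'
#' @param x an [ASEMatrix-class] object.
#' @param k_values numbers of samples to use (each >= 2).
#' @param mode,alpha,... passed to [runASE()].
#' @return data.frame with columns `k`, `n_significant`,
#'   `overlap_with_full`, `n_full`.
#' @export
replicateTitration <- function(x, k_values, mode = "strain",
                               alpha = 0.05, ...) {
    stopifnot(is(x, "ASEMatrix"))
    samples <- unique(colData(x)$sample_id)
    if (any(k_values < 2L)) stop("dispersion estimation needs k >= 2")
    if (any(k_values > length(samples)))
        stop("k exceeds the number of available samples")
    full <- runASE(x, mode = mode, alpha = alpha, ...)
    full_sig <- full$unit_id[full$significant]
    out <- lapply(k_values, function(k) {
        keep <- colData(x)$sample_id %in% samples[seq_len(k)]
        xs <- x[, keep]
        metadata(xs)$level <- metadata(x)$level
        res <- runASE(xs, mode = mode, alpha = alpha, ...)
        sig <- res$unit_id[res$significant]
        data.frame(k = k, n_significant = length(sig),
                   overlap_with_full = length(intersect(sig, full_sig)),
                   n_full = length(full_sig))
    })
    do.call(rbind, out)
}

#' Concordance of ASE between two result sets (e.g. the two sexes)
#'
#' @param res_a,res_b results from [runASE()] over a shared unit universe
#'   (e.g. male-only and female-only runs).
#' @return list with `r_squared` (of log2 fold changes over shared
#'   units), `n_shared`, `n_sig_a`, `n_sig_b`, `n_both`, `n_either`, and
#'   the specific call lists `only_a`, `only_b`.
#' @export
compareSexes <- function(res_a, res_b) {
    shared <- intersect(res_a$unit_id, res_b$unit_id)
    if (!length(shared)) stop("no shared units between the two result sets")
    ia <- match(shared, res_a$unit_id); ib <- match(shared, res_b$unit_id)
    r2 <- cor(res_a$log2fc[ia], res_b$log2fc[ib])^2
    sa <- res_a$unit_id[res_a$significant]
    sb <- res_b$unit_id[res_b$significant]
    list(r_squared = r2, n_shared = length(shared),
         n_sig_a = length(sa), n_sig_b = length(sb),
         n_both = length(intersect(sa, sb)),
         n_either = length(union(sa, sb)),
         only_a = setdiff(sa, sb), only_b = setdiff(sb, sa))
}
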
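test_that("aggregation sums member SNPs into gene and exon units", {
    # gene g1 has SNPs (3,5) and (7,5); g2 has one intronic SNP
    b <- matrix(c(3L, 7L, 4L), ncol = 1)
    d <- matrix(c(5L, 5L, 6L), ncol = 1)
    ac <- makeCounts(b, d, pos = c(120L, 180L, 320L),
                     gene_id = c("g1", "g1", "g2"),
                     annotation = c("exonic", "exonic", "intronic"),
                     cross = "BxD", sex = "F")
    am <- aggregateCounts(ac, level = "gene", exonic_only = TRUE)
    expect_equal(nrow(am), 1L)  # g2 is intronic-only and drops out
    expect_equal(unname(assay(am, "counts")[1, ]), c(10L, 10L))
    amA <- aggregateCounts(ac, level = "gene", exonic_only = FALSE)
    expect_equal(unname(assay(amA, "counts")["g2", ]), c(4L, 6L))

    # snp level is a pure reshape
    ams <- aggregateCounts(ac, level = "snp", exonic_only = FALSE)
    expect_equal(nrow(ams), 3L)
    expect_equal(unname(assay(ams, "counts")[1, ]), c(3L, 5L))
    expect_equal(unitLevel(ams), "snp")

    # exon level splits g1's SNPs across its two exons
    genes <- makeGenes(c(100L, 150L, 300L), c(140L, 200L, 350L),
                       c("g1", "g1", "g2"))
    ame <- aggregateCounts(ac, genes, level = "exon")
    expect_equal(nrow(ame), 2L)
    expect_equal(unname(assay(ame, "counts")["g1:exon1", ]), c(3L, 5L))
    expect_equal(unname(assay(ame, "counts")["g1:exon2", ]), c(7L, 5L))
})

test_that("a SNP overlapping two genes is counted in both and flagged", {
    b <- matrix(2L, 1, 1); d <- matrix(3L, 1, 1)
    ac <- makeCounts(b, d, pos = 150L, gene_id = "x",
                     cross = "BxD", sex = "F")
    genes <- makeGenes(c(100L, 120L), c(200L, 260L), c("gA", "gB"))
    am <- aggregateCounts(ac, genes, level = "gene")
    expect_equal(nrow(am), 2L)
    expect_true(all(rowData(am)$multi_gene))
    expect_equal(unname(assay(am, "counts")["gA", ]), c(2L, 3L))
    expect_equal(unname(assay(am, "counts")["gB", ]), c(2L, 3L))
})

test_that("exclusive-expression units are removed with a report", {
    b <- rbind(c(5L, 8L, 6L, 7L),   # normal
               c(4L, 6L, 3L, 9L),   # D absent everywhere -> removed
               c(0L, 0L, 2L, 0L))   # D zero in 3 of 4 -> retained
    d <- rbind(c(5L, 4L, 7L, 6L),
               c(0L, 0L, 0L, 0L),
               c(3L, 2L, 2L, 4L))
    ac <- makeCounts(b, d, gene_id = c("g1", "g2", "g3"))
    am <- aggregateCounts(ac, level = "snp", exonic_only = FALSE)
    flt <- filterExclusive(am)
    expect_equal(nrow(flt), 2L)
    rem <- metadata(flt)$removed_exclusive
    expect_equal(rem$gene_id, "g2")
    expect_equal(rem$absent_allele, "D")
    # same semantics on the SNP table itself
    fac <- filterExclusive(ac)
    expect_equal(nrow(fac), 2L)
    expect_equal(metadata(fac)$removed_exclusive$absent_allele, "D")
})

test_that("size factors follow the median-of-ratios closed forms", {
    m <- cbind(c(10L, 20L, 35L), c(10L, 20L, 35L))
    expect_equal(unname(aseSizeFactors(m)), c(1, 1))
    m2 <- cbind(c(10L, 20L, 35L), c(20L, 40L, 70L))
    expect_equal(unname(aseSizeFactors(m2)), c(1 / sqrt(2), sqrt(2)))
    # no unit with all-positive counts
    m3 <- cbind(c(0L, 5L), c(3L, 0L))
    expect_error(aseSizeFactors(m3), "all-positive")
    expect_length(aseSizeFactors(m3, pseudo_reference = TRUE), 2L)
})

test_that("size factors absorb a global allelic mapping bias", {
    cfg <- simConfig(seed = 41, n_genes = 400, fraction_cis = 0,
                     fraction_imprinted = 0, fraction_error_snps = 0,
                     n_stop_gain = 0, n_stop_loss = 0, global_bias = 1.2)
    ann <- simulateAnnotation(cfg, sequence = FALSE)
    am <- aggregateCounts(simulateCounts(ann, simulateTruth(cfg), cfg))
    sf <- aseSizeFactors(assay(am, "counts"))
    isB <- colData(am)$allele == "B"
    expect_equal(mean(sf[isB]) / mean(sf[!isB]), 1.2, tolerance = 0.05)
})

test_that("dispersion estimation: zero-variance and hand-computed cases", {
    cond <- factor(rep(c("A", "B"), each = 2), levels = c("A", "B"))
    # identical replicates within condition: empirical 0, working = trend
    m <- rbind(c(50L, 50L, 70L, 70L),
               c(20L, 20L, 30L, 30L))
    dm <- estimateDispersionModel(m, cond, rep(1, 4))
    expect_equal(dm$empirical, c(0, 0))
    expect_equal(dm$working, dm$fitted)
    # pooled moments: A = (90,110), B = (70,130); mu = 100,
    # vbar = (200 + 1800)/2 = 1000, alpha = (1000-100)/100^2 = 0.09
    m2 <- rbind(c(90L, 110L, 70L, 130L))
    dm2 <- estimateDispersionModel(m2, cond, rep(1, 4))
    expect_equal(dm2$empirical[1], 0.09)
    expect_true(all(dm2$working >= dm2$empirical))
    # a single replicate per condition is refused
    expect_error(
        estimateDispersionModel(m[, c(1, 3)],
                                factor(c("A", "B")), c(1, 1)),
        ">= 2 replicates")
})

test_that("dispersion recovery: median working value near the truth", {
    cfg <- simConfig(seed = 21, n_genes = 2000, fraction_cis = 0,
                     fraction_imprinted = 0, fraction_error_snps = 0,
                     n_stop_gain = 0, n_stop_loss = 0, nb_dispersion = 0.05,
                     mean_coverage_meanlog = log(1000),
                     mean_coverage_sdlog = 0.5, intron_snps_per_gene = 0)
    ann <- simulateAnnotation(cfg, sequence = FALSE)
    am <- aggregateCounts(simulateCounts(ann, simulateTruth(cfg), cfg))
    d <- makeDesign(am, "strain")
    cnt <- assay(am, "counts")
    sf <- aseSizeFactors(cnt)
    dm <- estimateDispersionModel(cnt, d$condition, sf)
    expect_equal(median(dm$working), 0.05, tolerance = 0.25)
})

test_that("the NB exact test behaves at its analytic anchors", {
    # the observed split is the mode -> p = 1
    expect_equal(nbExactTest(c(10, 10), c(10, 10), c(1, 1), c(1, 1),
                             dispersion = 0.05)$pval, 1)
    # zero total -> p = 1 with flag
    r0 <- nbExactTest(c(0, 0), c(0, 0), c(1, 1), c(1, 1),
                      dispersion = 0.05)
    expect_equal(r0$pval, 1)
    expect_true(r0$zero_total)
    expect_error(nbExactTest(c(1), c(2), 1, 1), "dispersion")

    # Poisson/binomial limit: as dispersion -> 0 the conditional law is
    # binomial, so the p-value matches the exact binomial test
    set.seed(71)
    for (i in 1:15) {
        n <- sample(50:400, 1)
        a <- rbinom(1, n, 0.5)
        p_nb <- nbExactTest(a, n - a, 1, 1, dispersion = 1e-9)$pval
        p_bin <- binom.test(a, n, 0.5)$p.value
        expect_equal(p_nb, p_bin, tolerance = 1e-4)
    }
    # unequal size factors shift the conditional success probability
    p_nb <- nbExactTest(c(30, 40), c(10, 15), c(1, 1.2), c(0.9, 1.1),
                        dispersion = 1e-9)$pval
    p_bin <- binom.test(70, 95, 2.2 / 4.2)$p.value
    expect_equal(p_nb, p_bin, tolerance = 1e-4)
})

test_that("the large-total normal approximation matches enumeration", {
    set.seed(72)
    for (i in 1:10) {
        tot <- 12000L
        a <- round(tot * runif(1, 0.46, 0.54)); b <- tot - a
        kA <- c(floor(a / 2), ceiling(a / 2))
        kB <- c(floor(b / 2), ceiling(b / 2))
        p_apx <- nbExactTest(kA, kB, c(1, 1), c(1, 1), 0.02,
                             enum_cap = 10000L)$pval
        p_ex <- nbExactTest(kA, kB, c(1, 1), c(1, 1), 0.02,
                            enum_cap = 20000L)$pval
        expect_equal(log(p_apx), log(p_ex), tolerance = 0.05)
    }
})

test_that("null p-values are calibrated (not anti-conservative)", {
    cfg <- simConfig(seed = 73, n_genes = 800, fraction_cis = 0,
                     fraction_imprinted = 0, fraction_error_snps = 0,
                     n_stop_gain = 0, n_stop_loss = 0, nb_dispersion = 0.05)
    ann <- simulateAnnotation(cfg, sequence = FALSE)
    am <- aggregateCounts(simulateCounts(ann, simulateTruth(cfg), cfg))
    res <- runASE(am)
    # the discrete conditional test is conservative; demand the empirical
    # CDF of p never exceeds uniform by more than a KS-style margin
    expect_lt(mean(res$pval < 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / 800))
    expect_lt(mean(res$pval < 0.01), 0.01 + 2 * sqrt(0.01 * 0.99 / 800))
})

test_that("Fisher SNP test matches hypergeometric enumeration", {
    expect_equal(fisherSnpTest(20, 20, 1000, 1000)$pval, 1.0)
    ft <- fisherSnpTest(30, 10, 1000, 1000)
    expect_equal(ft$pval, enumFisherP(30, 10, 1000, 1000),
                 tolerance = 1e-8)
    z <- fisherSnpTest(0, 0, 0, 0)
    expect_equal(z$pval, 1)
    expect_true(z$degenerate)
    expect_error(fisherSnpTest(5, 1, 3, 10))
})

test_that("BH adjustment follows the step-up formula", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(0.73), 0.73)
    expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
    expect_error(bhAdjust(c(0.1, NaN)), "NA")
    set.seed(74)
    p <- runif(50)
    expect_true(all(bhAdjust(p) >= p))
})

test_that("swapping allele labels negates log2fc and keeps p-values", {
    cfg <- simConfig(seed = 75, n_genes = 100)
    ann <- simulateAnnotation(cfg, sequence = FALSE)
    am <- aggregateCounts(simulateCounts(ann, simulateTruth(cfg), cfg))
    res <- runASE(am)
    swapped <- am
    colData(swapped)$allele <- ifelse(colData(swapped)$allele == "B",
                                      "D", "B")
    metadata(swapped)$level <- metadata(am)$level
    res2 <- runASE(swapped)
    expect_equal(res2$log2fc, -res$log2fc, tolerance = 1e-9)
    expect_equal(res2$pval, res$pval, tolerance = 1e-9)
})

test_that("a strong cis effect is detected with the right direction", {
    cfg <- simConfig(seed = 76, n_genes = 60, fraction_cis = 0,
                     fraction_imprinted = 0, fraction_error_snps = 0,
                     n_stop_gain = 0, n_stop_loss = 0,
                     mean_coverage_meanlog = log(2000),
                     mean_coverage_sdlog = 0)
    ann <- simulateAnnotation(cfg, sequence = FALSE)
    truth <- simulateTruth(cfg)
    truth$ase_log2fc[truth$gene_id == "gene0001"] <- 3
    am <- aggregateCounts(simulateCounts(ann, truth, cfg))
    res <- runASE(am)
    hit <- res[res$gene_id == "gene0001", ]
    expect_true(hit$significant)
    expect_equal(hit$direction, "D")
    expect_equal(hit$log2fc, 3, tolerance = 0.35)
})

test_that("the Fisher pipeline requires significance in every sample", {
    # gene gX: strongly imbalanced in 3 samples, balanced in the 4th;
    # gene gY: imbalanced everywhere; gB anchors the library totals
    b <- rbind(c(200L, 200L, 200L, 100L),
               c(300L, 280L, 310L, 290L),
               rep(20000L, 4))
    d <- rbind(c(20L, 20L, 20L, 100L),
               c(30L, 25L, 35L, 30L),
               rep(20000L, 4))
    ac <- makeCounts(b, d, gene_id = c("gX", "gY", "gB"),
                     pos = c(100L, 5000L, 9000L))
    fp <- fisherPipeline(ac, level = "gene")
    expect_false(fp$called[fp$gene_id == "gX"])
    expect_equal(fp$n_sig_samples[fp$gene_id == "gX"], 3)
    expect_true(fp$called[fp$gene_id == "gY"])
    expect_equal(fp$direction[fp$gene_id == "gY"], "B")
    expect_error(fisherPipeline(ac[, 1]), ">= 2 samples")
})

test_that("replicate titration: full k reproduces the full contrast", {
    cfg <- simConfig(seed = 77, n_genes = 120)
    ann <- simulateAnnotation(cfg, sequence = FALSE)
    am <- aggregateCounts(simulateCounts(ann, simulateTruth(cfg), cfg))
    tt <- replicateTitration(am, k_values = c(2L, 4L))
    full <- runASE(am)
    expect_equal(tt$n_significant[tt$k == 4L], sum(full$significant))
    expect_equal(tt$overlap_with_full[tt$k == 4L], sum(full$significant))
    expect_error(replicateTitration(am, k_values = 1L), "k >= 2")
    expect_error(replicateTitration(am, k_values = 5L), "exceeds")
})

test_that("significant calls do not shrink with more replicates", {
    # power monotonicity in expectation over a few generator seeds
    n2 <- n4 <- numeric(4)
    for (i in 1:4) {
        cfg <- simConfig(seed = 80 + i, n_genes = 150, fraction_cis = 0.2,
                         fraction_imprinted = 0, fraction_error_snps = 0,
                         fraction_sex_specific = 0,
                         n_stop_gain = 0, n_stop_loss = 0)
        ann <- simulateAnnotation(cfg, sequence = FALSE)
        am <- aggregateCounts(simulateCounts(ann, simulateTruth(cfg), cfg))
        tt <- replicateTitration(am, k_values = c(2L, 4L))
        n2[i] <- tt$n_significant[tt$k == 2L]
        n4[i] <- tt$n_significant[tt$k == 4L]
    }
    expect_gte(mean(n4), mean(n2))
})

test_that("sex comparison reports concordance and specific calls", {
    cfg <- simConfig(seed = 85, n_genes = 200, fraction_cis = 0.2)
    ann <- simulateAnnotation(cfg, sequence = FALSE)
    am <- aggregateCounts(simulateCounts(ann, simulateTruth(cfg), cfg))
    resM <- runASE(am, sex_filter = "male")
    resF <- runASE(am, sex_filter = "female")
    self <- compareSexes(resM, resM)
    expect_equal(self$r_squared, 1)
    expect_equal(self$n_both, self$n_sig_a)
    cmp <- compareSexes(resM, resF)
    expect_equal(cmp$n_shared, 200L)
    expect_gte(cmp$n_either, max(cmp$n_sig_a, cmp$n_sig_b))
    expect_error(compareSexes(resM[0, ], resF), "shared")
})
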
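test_that("reference masking replaces exactly the SNP positions", {
    ref <- DNAStringSet(c(chr1 = "ACGT"))
    v <- GRanges("chr1", IRanges(2, width = 1), b_allele = "C",
                 d_allele = "T", kind = "snp", annotation = "exonic",
                 gene_id = "g")
    expect_equal(as.character(maskReference(ref, v)[[1]]), "ANGT")
    # no variants: identity
    expect_equal(as.character(maskReference(ref, v[0])[[1]]), "ACGT")

    set.seed(1)
    seq1k <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE),
                   collapse = "")
    ref2 <- DNAStringSet(c(chr1 = seq1k))
    pos <- sort(sample(1000, 10))
    v2 <- GRanges("chr1", IRanges(pos, width = 1),
                  b_allele = "A", d_allele = "G", kind = "snp",
                  annotation = "exonic", gene_id = "g")
    masked <- maskReference(ref2, v2)
    hitpos <- start(Biostrings::matchPattern("N", masked[[1]]))
    expect_identical(hitpos, pos)
    # idempotence
    twice <- maskReference(masked, v2)
    expect_equal(as.character(twice[[1]]), as.character(masked[[1]]))
    # indels are skipped with a warning
    v3 <- c(v2, GRanges("chr1", IRanges(500, width = 3),
                        b_allele = "ACT", d_allele = "A", kind = "indel",
                        annotation = "exonic", gene_id = "g"))
    expect_warning(maskReference(ref2, v3), "indel")
    expect_error(maskReference(ref,
        GRanges("chr1", IRanges(99, width = 1), b_allele = "A",
                d_allele = "G", kind = "snp", annotation = "exonic",
                gene_id = "g")), "out of range")
})

snpAt <- function(pos, b = "A", d = "G")
    GRanges("chr1", IRanges(pos, width = 1), b_allele = b, d_allele = d,
            kind = "snp", annotation = "exonic", gene_id = "g1")

test_that("single reads are tallied by the base they carry at the SNP", {
    dir <- withr::local_tempdir()
    # SNP at 110; reads of 20 bp starting at 101 -> offset 10
    mkseq <- function(base) paste0(strrep("C", 9), base, strrep("C", 10))
    reads <- data.frame(
        qname = c("r1", "r2", "r3", "r4", "r5", "r6"),
        flag = 0L, pos = 101L, mapq = c(60L, 60L, 60L, 60L, 60L, 0L),
        cigar = "20M",
        seq = c(mkseq("A"), mkseq("G"), mkseq("T"), mkseq("A"),
                mkseq("A"), mkseq("A")),
        qual = c(strrep("I", 20), strrep("I", 20), strrep("I", 20),
                 paste0(strrep("I", 9), "#", strrep("I", 10)),  # Q2 at SNP
                 strrep("I", 20), strrep("I", 20)),
        nm = c(0L, 1L, 1L, 0L, 5L, 0L),   # r5 exceeds the mismatch cap
        nh = c(1L, 1L, 1L, 1L, 1L, 2L))   # r6 is multi-mapped
    sam <- writeSam(reads, file.path(dir, "a.sam"))
    ac <- countAlleles(c(s1 = sam), snpAt(110L))
    expect_equal(unname(bCounts(ac)[1, 1]), 1L)      # r1 only
    expect_equal(unname(dCounts(ac)[1, 1]), 1L)      # r2
    expect_equal(unname(otherCounts(ac)[1, 1]), 1L)  # r3 carries T
    # r4 (low qual), r5 (NM), r6 (NH) all filtered

    # with the mismatch cap raised, r5 is admitted
    ac2 <- countAlleles(c(s1 = sam), snpAt(110L),
                        policy = countingPolicy(max_mismatches = 10L))
    expect_equal(unname(bCounts(ac2)[1, 1]), 2L)
    # without unique filtering, r6 is admitted
    ac3 <- countAlleles(c(s1 = sam), snpAt(110L),
                        policy = countingPolicy(unique_only = FALSE))
    expect_equal(unname(bCounts(ac3)[1, 1]), 2L)
})

test_that("CIGAR operations shift the SNP offset correctly", {
    dir <- withr::local_tempdir()
    # read starts at 101 with 5M2D15M: reference positions 101-105 come
    # from read offsets 1-5, 106-107 are deleted, 108+ resume at offset 6
    reads <- data.frame(
        qname = "r1", flag = 0L, pos = 101L, mapq = 60L,
        cigar = "5M2D15M",
        seq = paste0("CCCCC", "A", strrep("C", 14)),
        qual = strrep("I", 20), nm = 2L, nh = 1L)
    sam <- writeSam(reads, file.path(dir, "c.sam"))
    # SNP at 108 -> the A right after the deletion
    ac <- countAlleles(c(s1 = sam), snpAt(108L))
    expect_equal(unname(bCounts(ac)[1, 1]), 1L)
    # SNP inside the deletion is not counted anywhere
    ac2 <- countAlleles(c(s1 = sam), snpAt(106L))
    expect_equal(unname(bCounts(ac2)[1, 1] + dCounts(ac2)[1, 1] +
                        otherCounts(ac2)[1, 1]), 0L)
})

test_that("fragment_once counts a double-covering pair once", {
    dir <- withr::local_tempdir()
    mkseq <- function(base) paste0(strrep("C", 9), base, strrep("C", 10))
    # two fragments: f1 mates agree (A/A), f2 mates disagree (A/G)
    reads <- data.frame(
        qname = c("f1", "f1", "f2", "f2"),
        flag = c(65L, 129L, 65L, 129L),
        pos = c(101L, 105L, 101L, 105L), mapq = 60L,
        cigar = "20M",
        seq = c(mkseq("A"), paste0(strrep("C", 5), "A", strrep("C", 14)),
                mkseq("A"), paste0(strrep("C", 5), "G", strrep("C", 14))),
        qual = strrep("I", 20), nm = 0L, nh = 1L)
    sam <- writeSam(reads, file.path(dir, "p.sam"))
    frag <- countAlleles(c(s1 = sam), snpAt(110L),
                         policy = countingPolicy(mate_mode = "fragment_once"))
    expect_equal(unname(bCounts(frag)[1, 1]), 1L)      # f1 counted once
    expect_equal(unname(otherCounts(frag)[1, 1]), 1L)  # f2 mates disagree
    indep <- countAlleles(c(s1 = sam), snpAt(110L),
                          policy = countingPolicy(mate_mode = "mates_independent"))
    expect_equal(unname(bCounts(indep)[1, 1]), 3L)
    expect_equal(unname(dCounts(indep)[1, 1]), 1L)
})

test_that("counting equals the brute-force per-read oracle", {
    for (seed in c(31, 32)) {
        cfg <- simConfig(seed = seed, n_genes = 3, n_stop_gain = 0,
                         n_stop_loss = 0, intron_snps_per_gene = 0,
                         close_snp_fraction = 0.5,
                         mean_coverage_meanlog = log(25),
                         multimap_fraction = 0.1,
                         samples = data.frame(cross = "BxD", sex = "F"))
        ann <- simulateAnnotation(cfg)
        rd <- simulateReads(ann, simulateTruth(cfg), cfg)
        ac <- countAlleles(rd$sam, ann$variants)
        v <- ann$variants
        o <- bruteForceSamCounts(rd$sam[1], start(v), v$b_allele,
                                 v$d_allele)
        expect_identical(unname(bCounts(ac)[, 1]), o$b)
        expect_identical(unname(dCounts(ac)[, 1]), o$d)
        expect_identical(unname(otherCounts(ac)[, 1]), o$other)
    }
})

test_that("mates_independent never counts fewer reads than fragment_once", {
    cfg <- simConfig(seed = 33, n_genes = 3, n_stop_gain = 0,
                     n_stop_loss = 0, intron_snps_per_gene = 0,
                     mean_coverage_meanlog = log(20), reads_paired = TRUE,
                     multimap_fraction = 0,
                     samples = data.frame(cross = "BxD", sex = "F"))
    ann <- simulateAnnotation(cfg)
    rd <- simulateReads(ann, simulateTruth(cfg), cfg)
    frag <- countAlleles(rd$sam, ann$variants,
                         policy = countingPolicy(mate_mode = "fragment_once"))
    indep <- countAlleles(rd$sam, ann$variants,
                          policy = countingPolicy(mate_mode = "mates_independent"))
    expect_true(all(bCounts(indep) >= bCounts(frag)))
    expect_true(all(dCounts(indep) >= dCounts(frag)))
})

test_that("a fully multi-mapped library yields zero counts", {
    cfg <- simConfig(seed = 34, n_genes = 2, n_stop_gain = 0,
                     n_stop_loss = 0, intron_snps_per_gene = 0,
                     mean_coverage_meanlog = log(15),
                     multimap_fraction = 1,
                     samples = data.frame(cross = "BxD", sex = "F"))
    ann <- simulateAnnotation(cfg)
    rd <- simulateReads(ann, simulateTruth(cfg), cfg)
    ac <- countAlleles(rd$sam, ann$variants)
    expect_equal(sum(bCounts(ac)) + sum(dCounts(ac)), 0L)
})

test_that("mapping ratio thins close SNPs in independent mode", {
    b <- matrix(c(10L, 10L, 0L), ncol = 1)
    d <- matrix(c(0L, 0L, 10L), ncol = 1)
    ac <- makeCounts(b, d, pos = c(100L, 110L, 5000L),
                     cross = "BxD", sex = "F")
    expect_equal(unname(mappingRatio(ac)), 2.0)
    expect_equal(unname(mappingRatio(ac, independent_only = TRUE,
                                     read_length = 50L)), 1.0)
    # symmetric table: ratio 1 in both modes
    sym <- makeCounts(matrix(5L, 3, 1), matrix(5L, 3, 1),
                      pos = c(100L, 110L, 5000L), cross = "BxD", sex = "F")
    expect_equal(unname(mappingRatio(sym)), 1.0)
    expect_equal(unname(mappingRatio(sym, independent_only = TRUE)), 1.0)
    # zero D counts: undefined, reported as NaN
    zd <- makeCounts(matrix(5L, 1, 1), matrix(0L, 1, 1),
                     cross = "BxD", sex = "F")
    expect_true(is.nan(unname(mappingRatio(zd))))
})

test_that("bias report quantifies the masked-vs-unmasked fold reduction", {
    identicalT <- makeCounts(matrix(10L, 2, 1), matrix(10L, 2, 1),
                             cross = "BxD", sex = "F")
    br <- biasReport(identicalT, identicalT)
    expect_equal(br$fold_reduction, 1.0)
    # unmasked log-ratio ~0.2, masked ~0.1 -> reduction ~2
    masked <- makeCounts(matrix(c(1105L, 1105L), 2, 1),
                         matrix(1000L, 2, 1), cross = "BxD", sex = "F")
    unmasked <- makeCounts(matrix(c(1221L, 1221L), 2, 1),
                           matrix(1000L, 2, 1), cross = "BxD", sex = "F")
    br2 <- biasReport(masked, unmasked)
    expect_equal(br2$fold_reduction, 2.0, tolerance = 0.01)
    # disjoint SNP sets are rejected
    shifted <- makeCounts(matrix(10L, 2, 1), matrix(10L, 2, 1),
                          pos = c(900L, 950L), cross = "BxD", sex = "F")
    expect_error(biasReport(identicalT, shifted), "same SNPs")
})

test_that("alignment-free placement shows no masking-dependent bias", {
    # reads are placed, not aligned: counting against the masked and the
    # unmasked reference must agree (negative control for aligner bias)
    cfg <- simConfig(seed = 35, n_genes = 3, n_stop_gain = 0,
                     n_stop_loss = 0, intron_snps_per_gene = 0,
                     mean_coverage_meanlog = log(20),
                     multimap_fraction = 0,
                     samples = data.frame(cross = "BxD", sex = "F"))
    ann <- simulateAnnotation(cfg)
    rd <- simulateReads(ann, simulateTruth(cfg), cfg)
    ac <- countAlleles(rd$sam, ann$variants)
    br <- biasReport(ac, ac)
    expect_true(all(br$fold_reduction == 1))
})
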
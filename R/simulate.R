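#' @include AllClasses.R
#' @importFrom stats rpois rnbinom rlnorm rnorm rbinom runif
NULL

#' Simulation configuration for synthetic ASE data
#'
#' Builds the validated parameter set consumed by [simulateAnnotation()],
#' [simulateTruth()], [simulateCounts()] and [simulateReads()].  Defaults
#' emulate a 4-pool reciprocal-cross F1 RNA-seq experiment: two crosses
#' (BxD, DxB; maternal strain first) times two sexes, 50 bp reads, a global
#' B-over-D mapping-bias factor of 1.17 (the residual reference bias seen
#' after N-masking in this design), negative-binomial overdispersion 0.05,
#' 10\% of genes carrying a cis effect, a small fraction of imprinted and
#' genotyping-error genes, and 60 stop-gain / 16 stop-loss annotated
#' variants of which 30\% show a marked (4-fold) reduction of the impaired
#' allele.
#'
#' @param seed integer random seed (mandatory; all generators are
#'   deterministic given the config).
#' @param n_genes number of genes.
#' @param snps_per_gene mean exonic SNPs per gene (Poisson; every gene is
#'   guaranteed at least one exonic SNP unless `snps_fixed = TRUE`, in which
#'   case exactly `snps_per_gene` SNPs are placed).
#' @param snps_fixed logical; see `snps_per_gene`.
#' @param exons_per_gene mean exons per gene (Poisson, minimum 1).
#' @param exon_length,intron_length,intergenic_length gene geometry in bp.
#' @param fraction_cis fraction of genes with a strain (cis) effect.
#' @param log2fc_mean,log2fc_sd magnitude distribution of cis effects
#'   (log2 D/B); signs are balanced between B-up and D-up.
#' @param fraction_imprinted fraction of genes with a parent-of-origin
#'   effect (maternal/paternal equally likely) of magnitude
#'   `imprint_magnitude` (log2 maternal/paternal).
#' @param imprint_magnitude see above.
#' @param fraction_sex_specific fraction of cis genes whose effect is
#'   restricted to one sex (male_only/female_only equally likely).
#' @param fraction_error_snps fraction of genes whose SNP calls are
#'   spurious: every SNP of such a gene yields B-only counts (the
#'   genotyping-error artifact responsible for exclusive B expression).
#' @param mean_coverage_meanlog,mean_coverage_sdlog lognormal distribution
#'   of per-gene expected read depth at each exonic SNP, per sample.
#' @param nb_dispersion overdispersion alpha in the NB variance
#'   mu + alpha * mu^2.
#' @param global_bias multiplicative B-over-D reference-mapping bias applied
#'   to B-allele means only.
#' @param samples data.frame with columns `cross` (`"BxD"`/`"DxB"`) and
#'   `sex` (`"M"`/`"F"`), one row per pool.
#' @param read_length read length in bp.
#' @param close_snp_fraction fraction of multi-SNP genes in which a SNP
#'   pair is deliberately placed closer than one read length (exercises the
#'   double-counting concern for reads spanning two SNPs).
#' @param intron_snps_per_gene mean intronic SNPs per gene (Poisson);
#'   intronic SNPs receive `intron_coverage_frac` of the gene's coverage.
#' @param intron_coverage_frac see above.
#' @param n_stop_gain,n_stop_loss numbers of genes given one extra SNP
#'   annotated `stop_gain` / `stop_loss` (D allele carries the stop change).
#' @param fraction_stop_marked fraction of stop variants with a true marked
#'   reduction of the impaired (D) allele.
#' @param stop_marked_ratio true impaired/intact expression ratio of marked
#'   stop variants.
#' @param multimap_fraction fraction of simulated reads flagged as
#'   multi-mapped (NH > 1, MAPQ 0).
#' @param reads_paired emit paired-end mates (two mates per fragment,
#'   shared read name) instead of single-end reads.
#' @return A list of class `"SimConfig"`.
#' @examples
#' cfg <- simConfig(seed = 1, n_genes = 50)
#' truth <- simulateTruth(cfg)
#' table(truth$ase_log2fc != 0)
#' @export
simConfig <- function(seed,
                      n_genes = 2000,
                      snps_per_gene = 3,
                      snps_fixed = FALSE,
                      exons_per_gene = 3,
                      exon_length = 300L,
                      intron_length = 200L,
                      intergenic_length = 500L,
                      fraction_cis = 0.10,
                      log2fc_mean = 1,
                      log2fc_sd = 0.5,
                      fraction_imprinted = 0.02,
                      imprint_magnitude = 2,
                      fraction_sex_specific = 0.02,
                      fraction_error_snps = 0.02,
                      mean_coverage_meanlog = log(200),
                      mean_coverage_sdlog = 1,
                      nb_dispersion = 0.05,
                      global_bias = 1.17,
                      samples = data.frame(
                          cross = c("BxD", "DxB", "BxD", "DxB"),
                          sex = c("F", "F", "M", "M")),
                      read_length = 50L,
                      close_snp_fraction = 0.1,
                      intron_snps_per_gene = 0.5,
                      intron_coverage_frac = 0.05,
                      n_stop_gain = 60L,
                      n_stop_loss = 16L,
                      fraction_stop_marked = 0.30,
                      stop_marked_ratio = 0.25,
                      multimap_fraction = 0.02,
                      reads_paired = FALSE) {
    if (missing(seed)) stop("seed is mandatory")
    seed <- as.integer(seed)
    stopifnot(is.finite(seed), seed >= 0, seed < .Machine$integer.max - 10L)
    if (n_genes < 1) stop("zero genes requested")
    fr <- c(fraction_cis, fraction_imprinted, fraction_error_snps,
            fraction_sex_specific, fraction_stop_marked,
            close_snp_fraction, multimap_fraction)
    if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
    if (fraction_cis + fraction_imprinted + fraction_error_snps > 1)
        stop("effect fractions must sum to at most 1")
    stopifnot(nb_dispersion >= 0, global_bias > 0,
              all(samples$cross %in% .validCrosses),
              all(samples$sex %in% .validSexes),
              read_length >= 20L, exon_length >= read_length)
    cfg <- as.list(environment())
    cfg$n_genes <- as.integer(n_genes)
    cfg$samples <- data.frame(cross = as.character(samples$cross),
                              sex = as.character(samples$sex),
                              stringsAsFactors = FALSE)
    class(cfg) <- "SimConfig"
    cfg
}

.sampleIds <- function(cfg) {
    ids <- paste0(cfg$samples$cross, "_", cfg$samples$sex)
    make.unique(ids, sep = "_")
}

#' Generate a toy annotated genome: reference, gene models, variant sites
#'
#' Lays genes end to end along `chr1`, each with a Poisson number of fixed
#' length exons separated by introns, draws a random reference sequence, and
#' places biallelic SNPs: exonic SNPs (at least one per gene by default),
#' optional intronic SNPs, and one stop-gain/stop-loss annotated SNP in a
#' random subset of genes.  A configurable fraction of multi-SNP genes gets
#' a SNP pair closer than one read length.  Deterministic given
#' `cfg$seed`.
#'
#' @param cfg a [simConfig()] object.
#' @param sequence generate the reference sequence (set `FALSE` to skip the
#'   sequence for count-level simulations; alleles are then drawn at
#'   random).
#' @return A list with elements `reference` (`DNAStringSet` or `NULL`),
#'   `genes` (`GRangesList` of exons with `n_isoforms`), and `variants`
#'   (`GRanges` as from [readVariants()]).
#' @export
simulateAnnotation <- function(cfg, sequence = TRUE) {
    stopifnot(inherits(cfg, "SimConfig"))
    set.seed(cfg$seed)
    n <- cfg$n_genes
    n_ex <- pmax(1L, rpois(n, cfg$exons_per_gene))
    glen <- n_ex * cfg$exon_length + (n_ex - 1L) * cfg$intron_length
    gstart <- cumsum(c(1L, glen[-n] + cfg$intergenic_length))
    gene_id <- sprintf("gene%04d", seq_len(n))

    # vectorized exon geometry: per-gene lists of exon start positions
    gstrand <- sample(c("+", "-"), n, replace = TRUE)
    step <- cfg$exon_length + cfg$intron_length
    ex_starts <- lapply(seq_len(n), function(i)
        gstart[i] + (seq_len(n_ex[i]) - 1L) * step)
    all_ex <- GRanges("chr1",
                      IRanges(unlist(ex_starts), width = cfg$exon_length),
                      strand = rep(gstrand, n_ex))
    genes <- GenomicRanges::split(all_ex,
                                  factor(rep(gene_id, n_ex),
                                         levels = gene_id))
    mcols(genes) <- DataFrame(gene_id = gene_id,
                              n_isoforms = 1L + rpois(n, 0.4))

    chrlen <- gstart[n] + glen[n] + cfg$intergenic_length
    reference <- NULL
    refchars <- NULL
    if (sequence) {
        refchars <- sample(.DNA, chrlen, replace = TRUE)
        reference <- DNAStringSet(paste(refchars, collapse = ""))
        names(reference) <- "chr1"
    }

    # exonic SNP placement, with optional forced close pairs
    n_snps <- if (cfg$snps_fixed) rep(as.integer(cfg$snps_per_gene), n)
              else pmax(1L, rpois(n, cfg$snps_per_gene))
    exon_bases <- function(i)
        sequence(rep(cfg$exon_length, n_ex[i]), from = ex_starts[[i]])
    pos_list <- vector("list", n)
    for (i in seq_len(n)) {
        bases <- exon_bases(i)
        p <- sort(sample(bases, min(n_snps[i], length(bases))))
        if (length(p) >= 2L && runif(1) < cfg$close_snp_fraction) {
            gap <- sample(5:(cfg$read_length - 1L), 1)
            cand <- p[1] + gap
            es <- ex_starts[[i]]
            ee <- es + cfg$exon_length - 1L
            ek <- which(es <= p[1] & ee >= p[1])
            if (cand <= ee[ek] && !cand %in% p) p[2] <- cand
            p <- sort(unique(p))
        }
        pos_list[[i]] <- p
    }
    pos <- unlist(pos_list)
    snp_gene <- rep(gene_id, lengths(pos_list))
    ann <- rep("exonic", length(pos))

    # intronic SNPs
    if (cfg$intron_snps_per_gene > 0) {
        n_int <- rpois(n, cfg$intron_snps_per_gene)
        for (i in which(n_int > 0 & n_ex > 1L)) {
            es <- ex_starts[[i]]
            ee <- es + cfg$exon_length - 1L
            ib <- sequence(rep(cfg$intron_length, n_ex[i] - 1L),
                           from = ee[-n_ex[i]] + 1L)
            p <- sample(ib, min(n_int[i], length(ib)))
            pos <- c(pos, p)
            snp_gene <- c(snp_gene, rep(gene_id[i], length(p)))
            ann <- c(ann, rep("intronic", length(p)))
        }
    }

    # stop-gain / stop-loss annotated SNPs (one per selected gene)
    n_stop <- min(cfg$n_stop_gain + cfg$n_stop_loss, n)
    if (n_stop > 0) {
        sel <- sample(seq_len(n), n_stop)
        lab <- rep(c("stop_gain", "stop_loss"),
                   c(min(cfg$n_stop_gain, n_stop),
                     max(0L, n_stop - cfg$n_stop_gain)))
        for (k in seq_along(sel)) {
            i <- sel[k]
            bases <- setdiff(exon_bases(i), pos[snp_gene == gene_id[i]])
            if (!length(bases)) next
            p <- sample(bases, 1)
            pos <- c(pos, p)
            snp_gene <- c(snp_gene, gene_id[i])
            ann <- c(ann, lab[k])
        }
    }

    o <- order(pos)
    pos <- pos[o]; snp_gene <- snp_gene[o]; ann <- ann[o]
    b <- if (sequence) refchars[pos] else sample(.DNA, length(pos), TRUE)
    d <- vapply(b, function(x) sample(setdiff(.DNA, x), 1), character(1))
    variants <- GRanges("chr1", IRanges(pos, width = 1L),
                        b_allele = unname(b), d_allele = unname(d),
                        kind = "snp", annotation = ann, gene_id = snp_gene)
    GenomeInfoDb::seqlengths(variants) <- c(chr1 = chrlen)
    list(reference = reference, genes = genes, variants = variants)
}

#' Generate the per-gene truth table of simulated effects
#'
#' Assigns each gene to (at most) one of three disjoint classes -- cis
#' effect, imprinted, or genotyping error -- with the configured fractions,
#' draws balanced-sign cis magnitudes, restricts a fraction of cis effects
#' to one sex, and pre-draws the per-gene stop-variant status (whether a
#' stop-annotated SNP in that gene, if any, shows a marked reduction of the
#' impaired allele).
#'
#' @param cfg a [simConfig()] object.
#' @return data.frame with columns `gene_id`, `ase_log2fc` (log2 D/B, 0 =
#'   none), `imprint_mode` (`none`/`maternal`/`paternal`), `imprint_log2`,
#'   `sex_specificity` (`both`/`male_only`/`female_only`),
#'   `is_genotyping_error`, `stop_marked`.
#' @export
simulateTruth <- function(cfg) {
    stopifnot(inherits(cfg, "SimConfig"))
    set.seed(cfg$seed + 1L)
    n <- cfg$n_genes
    cls <- sample(c("cis", "imprinted", "error", "none"), n, replace = TRUE,
                  prob = c(cfg$fraction_cis, cfg$fraction_imprinted,
                           cfg$fraction_error_snps,
                           1 - cfg$fraction_cis - cfg$fraction_imprinted -
                               cfg$fraction_error_snps))
    lfc <- rep(0, n)
    is_cis <- cls == "cis"
    mag <- abs(rnorm(sum(is_cis), cfg$log2fc_mean, cfg$log2fc_sd))
    lfc[is_cis] <- mag * sample(c(-1, 1), sum(is_cis), replace = TRUE)
    imode <- rep("none", n)
    imode[cls == "imprinted"] <- sample(c("maternal", "paternal"),
                                        sum(cls == "imprinted"),
                                        replace = TRUE)
    ilog2 <- ifelse(imode == "none", 0, cfg$imprint_magnitude)
    sexspec <- rep("both", n)
    ss <- is_cis & runif(n) < cfg$fraction_sex_specific
    sexspec[ss] <- sample(c("male_only", "female_only"), sum(ss),
                          replace = TRUE)
    data.frame(gene_id = sprintf("gene%04d", seq_len(n)),
               ase_log2fc = lfc,
               imprint_mode = imode,
               imprint_log2 = ilog2,
               sex_specificity = sexspec,
               is_genotyping_error = cls == "error",
               stop_marked = runif(n) < cfg$fraction_stop_marked,
               stringsAsFactors = FALSE)
}

# per-SNP x per-sample expected counts implied by the truth table.
# Returns list(mu_b, mu_d) matrices. The allelic log2 fold change L (log2
# D/B) is split symmetrically: mu_b ~ 2^(-L/2), mu_d ~ 2^(+L/2), keeping
# total expression invariant under ASE; global bias multiplies B means only.
.expectedMeans <- function(annotation, truth, cfg, coverage) {
    v <- annotation$variants
    ns <- length(v); nsamp <- nrow(cfg$samples)
    ti <- match(v$gene_id, truth$gene_id)
    if (anyNA(ti)) stop("variant gene ids not covered by truth table")
    mu_b <- matrix(0, ns, nsamp)
    mu_d <- matrix(0, ns, nsamp)
    base <- coverage[ti] / 2
    intron <- v$annotation == "intronic"
    base[intron] <- base[intron] * cfg$intron_coverage_frac
    stop_snp <- v$annotation %in% c("stop_gain", "stop_loss")
    stop_fac <- ifelse(stop_snp & truth$stop_marked[ti],
                       cfg$stop_marked_ratio, 1)
    err <- truth$is_genotyping_error[ti]
    for (j in seq_len(nsamp)) {
        cross <- cfg$samples$cross[j]; sex <- cfg$samples$sex[j]
        active <- truth$sex_specificity[ti] == "both" |
            (truth$sex_specificity[ti] == "male_only" & sex == "M") |
            (truth$sex_specificity[ti] == "female_only" & sex == "F")
        L <- ifelse(active, truth$ase_log2fc[ti], 0)
        # maternal allele: B in BxD, D in DxB (maternal strain named first)
        msign <- if (cross == "BxD") -1 else 1
        L <- L + msign * ifelse(truth$imprint_mode[ti] == "maternal",
                                truth$imprint_log2[ti],
                         ifelse(truth$imprint_mode[ti] == "paternal",
                                -truth$imprint_log2[ti], 0))
        mu_b[, j] <- base * cfg$global_bias * 2^(-L / 2)
        mu_d[, j] <- base * 2^(L / 2) * stop_fac
        # spurious SNP: every read carries the B base
        mu_b[err, j] <- 2 * base[err] * cfg$global_bias
        mu_d[err, j] <- 0
    }
    list(mu_b = mu_b, mu_d = mu_d)
}

# NB counts via a gamma replicate factor shared by all SNPs of a gene
# within one (sample x allele) pseudo-sample, with per-SNP Poisson draws:
# marginally each SNP count is NB(mu, alpha), and gene-level sums are
# exactly NB(sum mu, alpha) -- replicate variability acts on the gene,
# so aggregation preserves the dispersion.
.rcounts <- function(mu, alpha, gene_idx) {
    n_genes <- max(gene_idx)
    k <- matrix(0L, nrow(mu), ncol(mu))
    for (j in seq_len(ncol(mu))) {
        g <- if (alpha > 0)
            stats::rgamma(n_genes, shape = 1 / alpha, scale = alpha)
        else rep(1, n_genes)
        k[, j] <- rpois(nrow(mu), mu[, j] * g[gene_idx])
    }
    k[mu == 0] <- 0L
    k
}

#' Generate a per-SNP allele-count table from annotation and truth
#'
#' Draws negative-binomial counts (variance mu + alpha * mu^2) for every
#' SNP x sample x allele.  For a SNP with allelic log2 fold change L
#' (cis effect, gated by sex specificity, plus the parent-of-origin term
#' whose sign depends on the sample's cross direction), the expected counts
#' are `cov/2 * bias * 2^(-L/2)` for B and `cov/2 * 2^(L/2)` for D, where
#' `cov` is the gene's lognormal coverage draw; intronic SNPs receive a
#' small fraction of the gene's coverage; genotyping-error genes emit
#' B-only counts; marked stop variants have the impaired (D) allele mean
#' multiplied by `stop_marked_ratio`.
#'
#' @param annotation output of [simulateAnnotation()].
#' @param truth output of [simulateTruth()].
#' @param cfg the [simConfig()] both were generated from.
#' @return An [AlleleCounts-class] object.
#' @export
simulateCounts <- function(annotation, truth, cfg) {
    stopifnot(inherits(cfg, "SimConfig"))
    set.seed(cfg$seed + 2L)
    coverage <- rlnorm(cfg$n_genes, cfg$mean_coverage_meanlog,
                       cfg$mean_coverage_sdlog)
    mu <- .expectedMeans(annotation, truth, cfg, coverage)
    gi <- match(annotation$variants$gene_id, truth$gene_id)
    b <- .rcounts(mu$mu_b, cfg$nb_dispersion, gi)
    d <- .rcounts(mu$mu_d, cfg$nb_dispersion, gi)
    alleleCounts(annotation$variants, b, d,
                 cross = cfg$samples$cross, sex = cfg$samples$sex,
                 sample_id = .sampleIds(cfg))
}

#' Generate toy aligned reads (SAM) realizing the count model
#'
#' For each sample, draws per-SNP, per-allele read numbers with the same
#' mean structure as [simulateCounts()] and emits pre-placed ungapped
#' alignments (no aligner involved): each read covers its focal SNP, lies
#' entirely within one exon, and carries its haplotype's allele at every
#' SNP it covers.  A configurable fraction of reads is flagged multi-mapped
#' (NH:i:2, MAPQ 0) to exercise unique-read filtering; D reads carry an NM
#' tag equal to their mismatch count against the unmasked reference.  With
#' `cfg$reads_paired`, two mates sharing a read name are emitted per
#' fragment.
#'
#' @param annotation output of [simulateAnnotation()] with
#'   `sequence = TRUE`.
#' @param truth output of [simulateTruth()].
#' @param cfg the [simConfig()] used throughout.
#' @param dir output directory (created if needed).
#' @return list with `fasta` (reference path), `sam` (named vector of SAM
#'   paths, one per sample), and `reads` (data.frame of emitted reads:
#'   sample, qname, pos, allele, focal SNP position).
#' @export
simulateReads <- function(annotation, truth, cfg, dir = tempfile("simreads")) {
    stopifnot(inherits(cfg, "SimConfig"))
    if (is.null(annotation$reference))
        stop("annotation lacks a reference sequence (sequence = FALSE?)")
    set.seed(cfg$seed + 3L)
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    rl <- as.integer(cfg$read_length)
    v <- annotation$variants
    exonic <- which(v$annotation != "intronic")
    genes <- annotation$genes
    refseq <- annotation$reference[[1]]
    chrlen <- length(refseq)
    if (chrlen > 10e6) stop("toy genome exceeds 10 Mb")

    # exon containing each SNP (exonic SNPs only get reads)
    exon_of <- function(i) {
        ex <- genes[[v$gene_id[i]]]
        k <- which(start(ex) <= start(v)[i] & end(ex) >= start(v)[i])
        if (!length(k)) return(NULL)
        c(start(ex)[k], end(ex)[k])
    }

    coverage <- rlnorm(cfg$n_genes, cfg$mean_coverage_meanlog,
                       cfg$mean_coverage_sdlog)
    mu <- .expectedMeans(annotation, truth, cfg, coverage)
    gi <- match(v$gene_id, truth$gene_id)
    nb <- .rcounts(mu$mu_b, cfg$nb_dispersion, gi)[exonic, , drop = FALSE]
    nd <- .rcounts(mu$mu_d, cfg$nb_dispersion, gi)[exonic, , drop = FALSE]

    fasta <- file.path(dir, "reference.fasta")
    writeXStringSet(annotation$reference, fasta)

    ids <- .sampleIds(cfg)
    sams <- setNames(file.path(dir, paste0("reads_", ids, ".sam")), ids)
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                sprintf("@SQ\tSN:chr1\tLN:%d", chrlen))
    recs <- list()
    for (j in seq_along(ids)) {
        lines <- character(0)
        qn <- 0L
        for (k in seq_along(exonic)) {
            i <- exonic[k]
            tot <- nb[k, j] + nd[k, j]
            if (tot == 0L) next
            exk <- exon_of(i)
            if (is.null(exk)) next
            if (exk[2] - exk[1] + 1L < rl)
                stop("read length exceeds exon length at SNP index ", i)
            lo <- max(exk[1], start(v)[i] - rl + 1L)
            hi <- min(start(v)[i], exk[2] - rl + 1L)
            starts <- sample(lo:hi, tot, replace = TRUE)
            alle <- rep(c("B", "D"), c(nb[k, j], nd[k, j]))
            for (r in seq_len(tot)) {
                qn <- qn + 1L
                st <- starts[r]
                sq <- as.character(XVector::subseq(refseq, st, st + rl - 1L))
                nm <- 0L
                if (alle[r] == "D") {
                    cov <- which(start(v) >= st & start(v) <= st + rl - 1L &
                                 v$gene_id == v$gene_id[i])
                    for (ci in cov)
                        substr(sq, start(v)[ci] - st + 1L,
                               start(v)[ci] - st + 1L) <- v$d_allele[ci]
                    nm <- length(cov)
                }
                multi <- runif(1) < cfg$multimap_fraction
                mapq <- if (multi) 0L else 60L
                nh <- if (multi) 2L else 1L
                qname <- sprintf("%s_r%06d", ids[j], qn)
                if (cfg$reads_paired) {
                    st2 <- min(st + rl, exk[2] - rl + 1L)
                    sq2 <- as.character(XVector::subseq(refseq, st2,
                                                        st2 + rl - 1L))
                    if (alle[r] == "D") {
                        cov2 <- which(start(v) >= st2 &
                                      start(v) <= st2 + rl - 1L &
                                      v$gene_id == v$gene_id[i])
                        for (ci in cov2)
                            substr(sq2, start(v)[ci] - st2 + 1L,
                                   start(v)[ci] - st2 + 1L) <- v$d_allele[ci]
                    }
                    lines <- c(lines, sprintf(
                        "%s\t%d\tchr1\t%d\t%d\t%dM\t=\t%d\t0\t%s\t%s\tNM:i:%d\tNH:i:%d",
                        qname, 65L, st, mapq, rl, st2, sq,
                        strrep("I", rl), nm, nh), sprintf(
                        "%s\t%d\tchr1\t%d\t%d\t%dM\t=\t%d\t0\t%s\t%s\tNM:i:%d\tNH:i:%d",
                        qname, 129L, st2, mapq, rl, st, sq2,
                        strrep("I", rl), nm, nh))
                } else {
                    lines <- c(lines, sprintf(
                        "%s\t%d\tchr1\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s\tNM:i:%d\tNH:i:%d",
                        qname, 0L, st, mapq, rl, sq, strrep("I", rl), nm, nh))
                }
                recs[[length(recs) + 1L]] <- data.frame(
                    sample = ids[j], qname = qname, pos = st,
                    allele = alle[r], snp_pos = start(v)[i],
                    multi = multi, stringsAsFactors = FALSE)
            }
        }
        writeLines(c(header, lines), sams[j])
    }
    reads <- if (length(recs)) do.call(rbind, recs)
             else data.frame(sample = character(), qname = character(),
                             pos = integer(), allele = character(),
                             snp_pos = integer(), multi = logical())
    list(fasta = fasta, sam = sams, reads = reads)
}
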
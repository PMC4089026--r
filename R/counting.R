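#' @include AllClasses.R
#' @importFrom Biostrings replaceLetterAt
#' @importFrom Rsamtools asBam ScanBamParam scanBamFlag
#' @importFrom GenomicAlignments readGAlignments sequenceLayer cigar qwidth
NULL

#' Mask variant positions in a reference genome with N
#'
#' Replaces the base at every SNP position with `N`, the standard
#' mitigation for reference-mapping bias: after masking, reads carrying
#' either allele incur the same mismatch count at the variant position.
#' Indels are skipped with a warning (masking is defined for substitutions
#' only).  The operation is idempotent.
#'
#' @param reference `DNAStringSet` (named by chromosome) or path to a FASTA
#'   file.
#' @param variants `GRanges` of variant sites as from [readVariants()].
#' @return `DNAStringSet` with masked positions.
#' @export
maskReference <- function(reference, variants) {
    if (is.character(reference))
        reference <- readDNAStringSet(reference)
    names(reference) <- sub("\\s.*", "", names(reference))
    if (!is.null(variants$kind) && any(variants$kind != "snp")) {
        warning(sum(variants$kind != "snp"),
                " indel(s) skipped: only SNPs are masked")
        variants <- variants[variants$kind == "snp"]
    }
    for (chrom in unique(as.character(seqnames(variants)))) {
        if (!chrom %in% names(reference))
            stop("variant chromosome not in reference: ", chrom)
        pos <- start(variants)[as.character(seqnames(variants)) == chrom]
        bad <- pos < 1L | pos > length(reference[[chrom]])
        if (any(bad))
            stop("variant position out of range on ", chrom, ": ",
                 paste(head(pos[bad], 3), collapse = ", "))
        reference[[chrom]] <- replaceLetterAt(
            reference[[chrom]], pos, rep.int("N", length(pos)))
    }
    reference
}

#' Read-counting policy
#'
#' @param min_base_quality minimum Phred base quality at the SNP position
#'   (default 20).
#' @param mate_mode `"fragment_once"` (default): a properly paired fragment
#'   whose mates both cover a SNP contributes a single count (disagreeing
#'   mates go to `other`); `"mates_independent"`: each mate counts on its
#'   own, as when pairs are treated as two single-end reads.
#' @param unique_only drop multi-mapped reads (NH tag > 1, secondary flag,
#'   or MAPQ 0); default `TRUE`.
#' @param max_mismatches maximum NM tag value (default 3).
#' @return list of class `"CountingPolicy"`.
#' @export
countingPolicy <- function(min_base_quality = 20L,
                           mate_mode = c("fragment_once",
                                         "mates_independent"),
                           unique_only = TRUE,
                           max_mismatches = 3L) {
    mate_mode <- match.arg(mate_mode)
    stopifnot(min_base_quality >= 0L, max_mismatches >= 0L)
    structure(list(min_base_quality = as.integer(min_base_quality),
                   mate_mode = mate_mode,
                   unique_only = isTRUE(unique_only),
                   max_mismatches = as.integer(max_mismatches)),
              class = "CountingPolicy")
}

# read one SAM/BAM into per-read reference-space sequences and qualities
.loadAlignments <- function(path) {
    bam <- if (grepl("\\.bam$", path)) path
           else suppressMessages(asBam(path, tempfile(), overwrite = TRUE,
                                       indexDestination = FALSE))
    param <- ScanBamParam(what = c("qname", "seq", "qual", "mapq", "flag"),
                          tag = c("NM", "NH"),
                          flag = scanBamFlag(isUnmappedQuery = FALSE))
    readGAlignments(bam, param = param)
}

# per-SNP/per-read base + quality lookup via reference-space layering
.basesAtSnps <- function(ga, variants) {
    hits <- findOverlaps(granges(ga), variants)
    if (!length(hits))
        return(data.frame(read = integer(), snp = integer(),
                          base = character(), qual = integer()))
    refseq <- sequenceLayer(mcols(ga)$seq, cigar(ga))
    refqual <- sequenceLayer(mcols(ga)$qual, cigar(ga),
                             D.letter = "!", N.letter = "!")
    ri <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    off <- start(variants)[si] - start(ga)[ri] + 1L
    base <- as.character(XVector::subseq(refseq[ri], off, off))
    qual <- as.integer(charToRaw(paste(
        as.character(XVector::subseq(refqual[ri], off, off)),
        collapse = ""))) - 33L
    data.frame(read = ri, snp = si, base = base, qual = qual,
               stringsAsFactors = FALSE)
}

#' Count allele-specific reads at SNPs from alignments
#'
#' For every read overlapping a SNP position (CIGAR-aware), the base at the
#' SNP is compared to the two known alleles and tallied into `b`, `d` or
#' `other`.  Reads are skipped when multi-mapped (under `unique_only`),
#' when their NM tag exceeds `max_mismatches`, or when the base quality at
#' the SNP is below `min_base_quality`; deletions spanning the SNP do not
#' count.  Under `fragment_once`, the two mates of a fragment that both
#' cover a SNP contribute one count (agreeing mates) or an `other` count
#' (disagreeing mates).
#'
#' @param sam named character vector of SAM/BAM paths, one per sample
#'   (names become sample ids), e.g. the `sam` element of
#'   [simulateReads()].
#' @param variants `GRanges` of SNPs as from [readVariants()]; indels are
#'   ignored.
#' @param policy a [countingPolicy()].
#' @param cross,sex per-sample metadata (recycled defaults `"BxD"`/`"F"`
#'   for anonymous fixtures).
#' @return An [AlleleCounts-class] object (SNPs x samples).
#' @export
countAlleles <- function(sam, variants,
                         policy = countingPolicy(),
                         cross = rep("BxD", length(sam)),
                         sex = rep("F", length(sam))) {
    stopifnot(inherits(policy, "CountingPolicy"))
    if (!is.null(variants$kind)) variants <- variants[variants$kind == "snp"]
    ids <- if (!is.null(names(sam))) names(sam)
           else paste0("sample", seq_along(sam))
    nsnp <- length(variants)
    b <- d <- oth <- matrix(0L, nsnp, length(sam))
    for (j in seq_along(sam)) {
        ga <- .loadAlignments(sam[j])
        if (length(ga)) {
            keep <- rep(TRUE, length(ga))
            flag <- mcols(ga)$flag
            if (policy$unique_only) {
                nh <- mcols(ga)$NH
                multi <- (!is.na(nh) & nh > 1L) |
                    bitwAnd(flag, 256L) > 0L |
                    (!is.na(mcols(ga)$mapq) & mcols(ga)$mapq == 0L)
                keep <- keep & !multi
            }
            nm <- mcols(ga)$NM
            keep <- keep & (is.na(nm) | nm <= policy$max_mismatches)
            ga <- ga[keep]
        }
        if (!length(ga)) next
        hb <- .basesAtSnps(ga, variants)
        hb <- hb[hb$qual >= policy$min_base_quality &
                 hb$base %in% .DNA, , drop = FALSE]
        if (!nrow(hb)) next
        hb$call <- ifelse(hb$base == variants$b_allele[hb$snp], "b",
                   ifelse(hb$base == variants$d_allele[hb$snp], "d",
                          "other"))
        if (policy$mate_mode == "fragment_once") {
            paired <- bitwAnd(mcols(ga)$flag[hb$read], 1L) > 0L
            key <- paste(mcols(ga)$qname[hb$read], hb$snp)
            dupgrp <- paired & (duplicated(key) | duplicated(key,
                                                            fromLast = TRUE))
            if (any(dupgrp)) {
                keep1 <- !dupgrp
                agg <- tapply(hb$call[dupgrp], key[dupgrp], function(calls)
                    if (length(unique(calls)) == 1L) calls[1] else "other")
                extra <- data.frame(
                    snp = as.integer(sub(".* ", "", names(agg))),
                    call = unname(agg), stringsAsFactors = FALSE)
                hb <- rbind(hb[keep1, c("snp", "call")], extra)
            }
        }
        tb <- table(factor(hb$snp, levels = seq_len(nsnp)),
                    factor(hb$call, levels = c("b", "d", "other")))
        b[, j] <- b[, j] + as.integer(tb[, "b"])
        d[, j] <- d[, j] + as.integer(tb[, "d"])
        oth[, j] <- oth[, j] + as.integer(tb[, "other"])
    }
    alleleCounts(variants, b, d, oth, cross = cross, sex = sex,
                 sample_id = ids)
}

#' Per-sample B-to-D mapping ratio
#'
#' The global ratio of B-allele to D-allele read counts, a diagnostic of
#' residual reference-mapping bias.  With `independent_only`, SNPs are
#' greedily thinned so that consecutive retained SNPs are at least one read
#' length apart, removing the double counting of reads spanning two close
#' SNPs.
#'
#' @param x an [AlleleCounts-class] object.
#' @param independent_only thin to SNPs >= `read_length` apart.
#' @param read_length read length in bp used for thinning.
#' @return named numeric vector (one ratio per sample; `NaN` when a sample
#'   has zero D counts).
#' @export
mappingRatio <- function(x, independent_only = FALSE, read_length = 50L) {
    stopifnot(is(x, "AlleleCounts"))
    if (nrow(x) == 0L) stop("empty count table")
    keep <- rep(TRUE, nrow(x))
    if (independent_only) {
        rr <- rowRanges(x)
        o <- order(as.character(seqnames(rr)), start(rr))
        keep <- rep(FALSE, nrow(x))
        last_chrom <- ""; last_pos <- -Inf
        for (i in o) {
            chrom <- as.character(seqnames(rr))[i]
            if (chrom != last_chrom ||
                start(rr)[i] - last_pos >= read_length) {
                keep[i] <- TRUE
                last_chrom <- chrom
                last_pos <- start(rr)[i]
            }
        }
    }
    bs <- colSums(bCounts(x)[keep, , drop = FALSE])
    ds <- colSums(dCounts(x)[keep, , drop = FALSE])
    ratio <- bs / ds
    ratio[ds == 0] <- NaN
    ratio
}

#' Compare reference bias between masked and unmasked counting
#'
#' Quantifies, per sample, the excess of the observed log(B/D) count ratio
#' over the unbiased expectation of 0, for counts produced against an
#' N-masked versus an unmasked reference, and the fold reduction of that
#' excess achieved by masking.
#'
#' @param counts_masked,counts_unmasked [AlleleCounts-class] objects over
#'   the same SNPs and samples.
#' @return data.frame with one row per sample: `log_ratio_masked`,
#'   `log_ratio_unmasked`, `fold_reduction` (|unmasked| / |masked| excess;
#'   `Inf` when masking removes the excess entirely, 1 when the two are
#'   equal).
#' @export
biasReport <- function(counts_masked, counts_unmasked) {
    stopifnot(is(counts_masked, "AlleleCounts"),
              is(counts_unmasked, "AlleleCounts"))
    if (nrow(counts_masked) != nrow(counts_unmasked) ||
        ncol(counts_masked) != ncol(counts_unmasked) ||
        !all(start(rowRanges(counts_masked)) ==
             start(rowRanges(counts_unmasked))))
        stop("masked and unmasked tables must cover the same SNPs and samples")
    lr <- function(x) log(colSums(bCounts(x)) / colSums(dCounts(x)))
    m <- lr(counts_masked); u <- lr(counts_unmasked)
    data.frame(sample = colnames(counts_masked),
               log_ratio_masked = m,
               log_ratio_unmasked = u,
               fold_reduction = ifelse(abs(m) == 0 & abs(u) == 0, 1,
                                       abs(u) / abs(m)),
               row.names = NULL, stringsAsFactors = FALSE)
}
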
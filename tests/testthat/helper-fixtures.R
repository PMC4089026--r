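suppressPackageStartupMessages({
    library(GenomicRanges)
    library(SummarizedExperiment)
    library(Biostrings)
})

# small AlleleCounts straight from matrices
makeCounts <- function(b, d, pos = seq_len(nrow(as.matrix(b))) * 100L,
                       gene_id = rep("g1", nrow(as.matrix(b))),
                       annotation = rep("exonic", nrow(as.matrix(b))),
                       cross = c("BxD", "DxB", "BxD", "DxB"),
                       sex = c("F", "F", "M", "M"),
                       other = NULL) {
    b <- as.matrix(b); d <- as.matrix(d)
    cross <- cross[seq_len(ncol(b))]
    sex <- sex[seq_len(ncol(b))]
    gr <- GRanges(rep("chr1", nrow(b)), IRanges(pos, width = 1L),
                  gene_id = gene_id, annotation = annotation,
                  b_allele = rep("A", nrow(b)), d_allele = rep("G", nrow(b)))
    alleleCounts(gr, b, d, other, cross = cross, sex = sex)
}

# a gene model list laid out to hold the given SNP positions
makeGenes <- function(exon_starts, exon_ends, gene_ids,
                      n_isoforms = NULL) {
    gr <- GRanges("chr1", IRanges(exon_starts, exon_ends), strand = "+")
    gl <- GenomicRanges::split(gr, factor(gene_ids,
                                          levels = unique(gene_ids)))
    mcols(gl) <- S4Vectors::DataFrame(
        gene_id = names(gl),
        n_isoforms = if (is.null(n_isoforms)) rep(1L, length(gl))
                     else n_isoforms)
    gl
}

# write a SAM file from a data.frame of reads (qname, flag, pos, mapq,
# cigar, seq, qual, nm, nh); chromosome chr1, given length
writeSam <- function(reads, path, chrlen = 100000L) {
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                sprintf("@SQ\tSN:chr1\tLN:%d", chrlen))
    body <- sprintf("%s\t%d\tchr1\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tNM:i:%d\tNH:i:%d",
                    reads$qname, reads$flag, reads$pos, reads$mapq,
                    reads$cigar, reads$seq, reads$qual, reads$nm, reads$nh)
    writeLines(c(header, body), path)
    path
}
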
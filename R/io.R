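#' @include AllClasses.R
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#' @importFrom rtracklayer import
#' @importFrom VariantAnnotation readVcf info ref alt
#' @importFrom utils read.table write.table
NULL

.DNA <- c("A", "C", "G", "T")

#' Read biallelic B/D variant sites from a VCF file
#'
#' Reads a VCF 4.x of polymorphisms between the reference strain (B; the REF
#' allele) and the alternate strain (D; the ALT allele).  Positions are
#' returned as a `GRanges` in the usual Bioconductor 1-based convention, so
#' the range start equals the VCF POS; an indel record spans the full REF
#' footprint.  The functional annotation is taken from an INFO key
#' (default `ANN`; one of `intronic`, `exonic`, `utr`, `synonymous`,
#' `nonsynonymous`, `stop_gain`, `stop_loss`) and defaults to `"exonic"`
#' when the key is absent, mirroring the convention of calling every
#' non-intronic site "exonic".  The gene assignment is taken from INFO key
#' `GENE` when present.
#'
#' @param path VCF file (plain or gzipped).
#' @param multiallelic `"error"` (default) to reject records with more than
#'   one ALT allele, or `"split"` to expand them into one site per ALT.
#' @param annotation_key,gene_key INFO keys for the annotation and gene id.
#' @return `GRanges` with metadata columns `b_allele`, `d_allele`, `kind`
#'   (`"snp"`/`"indel"`), `annotation`, `gene_id`.
#' @examples
#' vcf <- system.file("extdata", "toy_variants.vcf", package = "aseF1")
#' readVariants(vcf)
#' @export
readVariants <- function(path, multiallelic = c("error", "split"),
                         annotation_key = "ANN", gene_key = "GENE") {
    multiallelic <- match.arg(multiallelic)
    vcf <- readVcf(path, genome = "toy")
    if (nrow(vcf) == 0L) {
        gr <- GRanges()
        mcols(gr) <- DataFrame(b_allele = character(), d_allele = character(),
                               kind = character(), annotation = character(),
                               gene_id = character())
        return(gr)
    }
    nalt <- lengths(alt(vcf))
    if (any(nalt != 1L)) {
        if (multiallelic == "error")
            stop("multi-allelic record(s) at row(s): ",
                 paste(head(which(nalt != 1L), 5), collapse = ", "),
                 " (use multiallelic = \"split\")")
        vcf <- VariantAnnotation::expand(vcf)
    }
    refs <- as.character(ref(vcf))
    av <- alt(vcf)
    alts <- if (is(av, "XStringSetList") || is(av, "CharacterList"))
        as.character(unlist(av)) else as.character(av)
    if (any(refs == alts))
        stop("REF == ALT at row(s): ",
             paste(head(which(refs == alts), 5), collapse = ", "))
    inf <- info(vcf)
    ann <- if (annotation_key %in% colnames(inf)) {
        a <- as.character(inf[[annotation_key]])
        a[is.na(a)] <- "exonic"
        a
    } else rep("exonic", nrow(vcf))
    bad <- !ann %in% .annotationLevels
    if (any(bad))
        stop("unknown annotation value(s): ",
             paste(unique(ann[bad]), collapse = ", "))
    gid <- if (gene_key %in% colnames(inf))
        as.character(inf[[gene_key]]) else rep(NA_character_, nrow(vcf))
    kind <- ifelse(nchar(refs) == 1L & nchar(alts) == 1L &
                   refs %in% .DNA & alts %in% .DNA, "snp", "indel")
    gr <- granges(SummarizedExperiment::rowRanges(vcf))
    names(gr) <- NULL
    mcols(gr) <- DataFrame(b_allele = refs, d_allele = alts, kind = kind,
                           annotation = ann, gene_id = gid)
    GenomicRanges::strand(gr) <- "*"
    gr
}

# Minimal VCF writer used by the simulator; read back with readVariants().
.writeVariantsVcf <- function(variants, path, contigs = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##INFO=<ID=ANN,Number=1,Type=String,Description=\"Functional annotation\">",
        "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene id\">"), con)
    if (!is.null(contigs))
        writeLines(sprintf("##contig=<ID=%s,length=%d>",
                           names(contigs), unname(contigs)), con)
    writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", con)
    if (length(variants)) {
        gid <- variants$gene_id
        inf <- sprintf("ANN=%s%s", variants$annotation,
                       ifelse(is.na(gid), "", paste0(";GENE=", gid)))
        writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                           as.character(seqnames(variants)), start(variants),
                           variants$b_allele, variants$d_allele, inf), con)
    }
    invisible(path)
}

#' Read gene models from a BED12 file
#'
#' Exons are reconstructed from the block structure of each BED12 row.  The
#' BED score column (column 5) is interpreted as the number of known splice
#' isoforms of the gene (0 is treated as 1); the name column is the gene id.
#'
#' @param path BED12 file (plain or gzipped).
#' @return A `GRangesList` of exons, one element per gene, named by gene id,
#'   with metadata columns `gene_id` and `n_isoforms`.
#' @export
readGeneModels <- function(path) {
    gr <- import(path, format = "bed")
    if (is.null(gr$blocks))
        stop("not a BED12 file (no block structure): ", path)
    exons <- rtracklayer::blocks(gr)
    n <- length(gr)
    for (i in seq_len(n)) {
        ex <- exons[[i]]
        if (length(ex) > 1L) {
            s <- start(ex); e <- end(ex)
            if (is.unsorted(s, strictly = TRUE) || any(s[-1] <= e[-length(e)]))
                stop("overlapping or unsorted exon blocks in gene ", gr$name[i])
        }
        if (max(end(ex)) > end(gr)[i] || min(start(ex)) < start(gr)[i])
            stop("exon block outside gene span in gene ", gr$name[i])
    }
    names(exons) <- gr$name
    niso <- as.integer(gr$score)
    niso[is.na(niso) | niso < 1L] <- 1L
    mcols(exons) <- DataFrame(gene_id = gr$name, n_isoforms = niso)
    exons
}

# BED12 writer for the simulator; round-trips through readGeneModels().
.writeGeneModelsBed <- function(genes, path) {
    lines <- vapply(seq_along(genes), function(i) {
        ex <- genes[[i]]
        chrom <- as.character(seqnames(ex))[1]
        cs <- min(start(ex)) - 1L
        ce <- max(end(ex))
        sizes <- paste0(paste(width(ex), collapse = ","), ",")
        starts <- paste0(paste(start(ex) - 1L - cs, collapse = ","), ",")
        sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%d\t%d\t0\t%d\t%s\t%s",
                chrom, cs, ce, names(genes)[i],
                mcols(genes)$n_isoforms[i],
                as.character(strand(ex))[1], cs, ce, length(ex),
                sizes, starts)
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read ENCODE narrowPeak DNase I hypersensitivity peaks
#'
#' @param path 10-column narrowPeak file (plain or gzipped).
#' @param replicate_id integer label recorded on every peak (the analysis
#'   compares two ENCODE replicates).
#' @return `GRanges` with metadata columns `signal` (column 7, signalValue)
#'   and `replicate_id`.
#' @export
readNarrowPeak <- function(path, replicate_id = 1L) {
    first <- readLines(path, n = 1L)
    if (length(first) && length(strsplit(first, "\t")[[1]]) != 10L)
        stop("narrowPeak requires 10 tab-separated columns: ", path)
    gr <- import(path, format = "BED",
                 extraCols = c(signalValue = "numeric", pValue = "numeric",
                               qValue = "numeric", peak = "integer"))
    if (any(gr$signalValue < 0))
        stop("negative signalValue in ", path)
    mcols(gr) <- DataFrame(signal = gr$signalValue,
                           replicate_id = as.integer(replicate_id))
    gr
}

#' Write / read an allele-count table as TSV
#'
#' The on-disk form of [AlleleCounts-class]: key columns `chrom`, `pos`
#' (1-based SNP position), `gene_id`, `annotation`, `b_allele`, `d_allele`,
#' then three count columns `<sample>.b`, `<sample>.d`, `<sample>.other`
#' per sample.  Sample metadata (cross, sex) are stored in `#sample` header
#' comment lines, so `readCountTable(writeCountTable(x, f))` is the
#' identity.
#'
#' @param x an [AlleleCounts-class] object.
#' @param path output/input TSV path (gzipped input accepted on read).
#' @return `writeCountTable` returns `path` invisibly; `readCountTable`
#'   returns an [AlleleCounts-class] object.
#' @export
writeCountTable <- function(x, path) {
    stopifnot(is(x, "AlleleCounts"))
    con <- file(path, "w")
    on.exit(close(con))
    cd <- colData(x)
    writeLines(sprintf("#sample\t%s\t%s\t%s",
                       rownames(cd), cd$cross, cd$sex), con)
    rr <- rowRanges(x)
    df <- data.frame(chrom = as.character(seqnames(rr)), pos = start(rr),
                     gene_id = rr$gene_id, annotation = rr$annotation,
                     b_allele = rr$b_allele, d_allele = rr$d_allele,
                     check.names = FALSE, stringsAsFactors = FALSE)
    for (j in seq_len(ncol(x))) {
        s <- rownames(cd)[j]
        df[[paste0(s, ".b")]] <- bCounts(x)[, j]
        df[[paste0(s, ".d")]] <- dCounts(x)[, j]
        df[[paste0(s, ".other")]] <- otherCounts(x)[, j]
    }
    suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                                 row.names = FALSE))
    invisible(path)
}

#' @rdname writeCountTable
#' @export
readCountTable <- function(path) {
    all_lines <- readLines(path)
    meta <- all_lines[startsWith(all_lines, "#sample")]
    if (!length(meta))
        stop("no '#sample' header lines in ", path)
    mm <- do.call(rbind, strsplit(meta, "\t"))
    samples <- mm[, 2]
    body <- all_lines[!startsWith(all_lines, "#")]
    df <- read.table(text = body, sep = "\t", header = TRUE,
                     check.names = FALSE, stringsAsFactors = FALSE,
                     colClasses = NA)
    key <- c("chrom", "pos", "gene_id", "annotation", "b_allele", "d_allele")
    if (!all(key %in% colnames(df)))
        stop("missing key column(s): ",
             paste(setdiff(key, colnames(df)), collapse = ", "))
    want <- as.vector(t(outer(samples, c(".b", ".d", ".other"), paste0)))
    if (!all(want %in% colnames(df)))
        stop("count columns do not match '#sample' header: missing ",
             paste(setdiff(want, colnames(df)), collapse = ", "))
    gr <- GRanges(df$chrom, IRanges(df$pos, width = 1L),
                  gene_id = df$gene_id, annotation = df$annotation,
                  b_allele = df$b_allele, d_allele = df$d_allele)
    pick <- function(suffix)
        as.matrix(df[, paste0(samples, suffix), drop = FALSE])
    alleleCounts(gr, pick(".b"), pick(".d"), pick(".other"),
                 cross = mm[, 3], sex = mm[, 4], sample_id = samples)
}
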
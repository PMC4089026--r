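# Independent oracles: deliberately naive implementations that share no
# code path with the package.

# brute-force allele counting by a per-read text scan of a SAM file.
# Handles ungapped (xM) alignments only -- which is all the generator and
# the hand-written fixtures emit. Applies the same policy semantics:
# unique_only via NH tag / MAPQ 0, NM cap, base quality, single-end.
bruteForceSamCounts <- function(sam_path, snp_pos, b_allele, d_allele,
                                min_qual = 20L, max_nm = 3L,
                                unique_only = TRUE) {
    lines <- readLines(sam_path)
    lines <- lines[!startsWith(lines, "@")]
    nb <- nd <- noth <- integer(length(snp_pos))
    for (ln in lines) {
        f <- strsplit(ln, "\t")[[1]]
        flag <- as.integer(f[2])
        if (bitwAnd(flag, 4L) > 0L) next
        pos <- as.integer(f[4]); mapq <- as.integer(f[5])
        cig <- f[6]; seq <- f[10]; qual <- f[11]
        stopifnot(grepl("^[0-9]+M$", cig))
        len <- as.integer(sub("M", "", cig))
        tags <- f[-(1:11)]
        nm <- suppressWarnings(as.integer(
            sub("NM:i:", "", grep("^NM:i:", tags, value = TRUE)[1])))
        nh <- suppressWarnings(as.integer(
            sub("NH:i:", "", grep("^NH:i:", tags, value = TRUE)[1])))
        if (unique_only && ((!is.na(nh) && nh > 1L) || mapq == 0L ||
                            bitwAnd(flag, 256L) > 0L)) next
        if (!is.na(nm) && nm > max_nm) next
        for (k in seq_along(snp_pos)) {
            sp <- snp_pos[k]
            if (sp < pos || sp > pos + len - 1L) next
            off <- sp - pos + 1L
            q <- utf8ToInt(substr(qual, off, off)) - 33L
            if (q < min_qual) next
            base <- substr(seq, off, off)
            if (!base %in% c("A", "C", "G", "T")) next
            if (base == b_allele[k]) nb[k] <- nb[k] + 1L
            else if (base == d_allele[k]) nd[k] <- nd[k] + 1L
            else noth[k] <- noth[k] + 1L
        }
    }
    list(b = nb, d = nd, other = noth)
}

# exhaustive two-sided Fisher p by hypergeometric enumeration
enumFisherP <- function(b, d, B_total, D_total) {
    m <- b + d
    support <- max(0L, m - D_total):min(m, B_total)
    probs <- dhyper(support, B_total, D_total, m)
    p_obs <- dhyper(b, B_total, D_total, m)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# upper-tail hypergeometric overlap p by enumeration
enumOverlapP <- function(k, nA, nB, N) {
    kk <- k:min(nA, nB)
    sum(dhyper(kk, nA, N - nA, nB))
}

# O(n^2) peak-overlap scan (1-based closed intervals)
bruteForceOverlap <- function(s1, e1, s2, e2) {
    out <- logical(length(s1))
    for (i in seq_along(s1))
        for (j in seq_along(s2))
            if (s1[i] <= e2[j] && s2[j] <= e1[i]) out[i] <- TRUE
    out
}
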
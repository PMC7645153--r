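suppressPackageStartupMessages({
    library(GenomicRanges)
    library(SummarizedExperiment)
})

# ---- brute-force oracles (kept independent of the package internals) ----

# naive single-pass merge: positions sorted, new cluster when the gap to
# the previous position exceeds mergeDist; peak = max value, tie 5'-most
# on the strand
oracleClusters <- function(pos, val, strand = "+", mergeDist = 20) {
    o <- order(pos)
    pos <- pos[o]; val <- val[o]
    out <- list()
    cur <- 1L
    for (i in seq_along(pos)) {
        if (i > 1L && pos[i] - pos[i - 1L] > mergeDist) {
            out[[length(out) + 1L]] <- cur:(i - 1L)
            cur <- i
        }
    }
    out[[length(out) + 1L]] <- cur:length(pos)
    do.call(rbind, lapply(out, function(idx) {
        v <- val[idx]; p <- pos[idx]
        best <- p[v == max(v)]
        peak <- if (strand == "-") max(best) else min(best)
        data.frame(start = min(p), end = max(p), peak = peak,
                   total = sum(v))
    }))
}

# per-bp classifier from first principles: plain arithmetic on a list of
# transcripts (each: tss, strand, exons matrix, cds range or NULL)
oracleClassify <- function(txs, pos, strand = "*", halfwidth = 100,
                           proximal = 1000) {
    for (cls in c("promoter", "proximal", "fiveUTR", "threeUTR",
                  "exon", "intron")) {
        for (tx in txs) {
            hit <- switch(cls,
                promoter = abs(pos - tx$tss) <= halfwidth &&
                    (strand == "*" || strand == tx$strand),
                proximal = if (tx$strand == "+")
                    pos >= tx$tss - proximal && pos < tx$tss - halfwidth &&
                        (strand == "*" || strand == "+")
                else pos > tx$tss + halfwidth && pos <= tx$tss + proximal &&
                        (strand == "*" || strand == "-"),
                fiveUTR = !is.null(tx$cds) && any(
                    pos >= tx$exons[, 1] & pos <= tx$exons[, 2]) &&
                    (if (tx$strand == "+") pos < tx$cds[1]
                     else pos > tx$cds[2]),
                threeUTR = !is.null(tx$cds) && any(
                    pos >= tx$exons[, 1] & pos <= tx$exons[, 2]) &&
                    (if (tx$strand == "+") pos > tx$cds[2]
                     else pos < tx$cds[1]),
                exon = any(pos >= tx$exons[, 1] & pos <= tx$exons[, 2]),
                intron = pos >= min(tx$exons) && pos <= max(tx$exons) &&
                    !any(pos >= tx$exons[, 1] & pos <= tx$exons[, 2]))
            if (isTRUE(hit)) return(cls)
        }
    }
    "intergenic"
}

# random toy annotation on one contig + its oracle transcript list
randomToyAnnotation <- function(contigLen = 3000, nTx = 2) {
    txs <- list()
    for (k in seq_len(nTx)) {
        strand <- sample(c("+", "-"), 1)
        a <- sample(200:(contigLen - 1200), 1)
        ex1 <- c(a, a + 150)
        ex2 <- c(a + 400, a + 900)
        cds <- c(a + 60, a + 700)
        tss <- if (strand == "+") a else a + 900
        txs[[k]] <- list(tss = tss, strand = strand,
                         exons = rbind(ex1, ex2), cds = cds,
                         tx_id = sprintf("t%d", k),
                         gene_id = sprintf("g%d", k))
    }
    txs
}

# build a TranscriptModels via a written GFF3 so the reader is exercised
modelsFromToy <- function(txs, contigLen = 3000, contig = "chrT") {
    lines <- c("##gff-version 3")
    for (tx in txs) {
        lo <- min(tx$exons); hi <- max(tx$exons)
        lines <- c(lines,
            sprintf("%s\t.\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                    contig, lo, hi, tx$strand, tx$gene_id),
            sprintf("%s\t.\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                    contig, lo, hi, tx$strand, tx$tx_id, tx$gene_id),
            sprintf("%s\t.\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                    contig, tx$exons[, 1], tx$exons[, 2], tx$strand,
                    tx$tx_id))
        if (!is.null(tx$cds)) {
            seg <- rbind(
                c(max(tx$cds[1], tx$exons[1, 1]),
                  min(tx$cds[2], tx$exons[1, 2])),
                c(max(tx$cds[1], tx$exons[2, 1]),
                  min(tx$cds[2], tx$exons[2, 2])))
            seg <- seg[seg[, 1] <= seg[, 2], , drop = FALSE]
            lines <- c(lines,
                sprintf("%s\t.\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                        contig, seg[, 1], seg[, 2], tx$strand, tx$tx_id))
        }
    }
    gff <- tempfile(fileext = ".gff3")
    writeLines(lines, gff)
    si <- GenomeInfoDb::Seqinfo(contig, contigLen)
    loadAnnotation(gff, si)
}

# O(n^2) Kendall tau-b from concordant/discordant enumeration
oracleKendall <- function(x, y) {
    n <- length(x); C <- 0; D <- 0; tx <- 0; ty <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
        a <- sign(x[i] - x[j]); b <- sign(y[i] - y[j])
        if (a == 0 && b == 0) next
        if (a == 0) tx <- tx + 1
        else if (b == 0) ty <- ty + 1
        else if (a == b) C <- C + 1
        else D <- D + 1
    }
    (C - D) / sqrt((C + D + tx) * (C + D + ty))
}

# textbook Benjamini-Hochberg by explicit step-up rule
oracleBH <- function(p) {
    n <- length(p)
    o <- order(p)
    q <- p[o] * n / seq_len(n)
    for (i in (n - 1):1) q[i] <- min(q[i], q[i + 1])
    out <- numeric(n)
    out[o] <- pmin(q, 1)
    out
}

# small in-memory TagProfile
mkProfile <- function(id, contig, pos, strand, count,
                      contigs = NULL) {
    gr <- if (length(pos))
        GRanges(contig, IRanges(pos, width = 1L), strand = strand)
    else GRanges()
    gr$count <- as.integer(count)
    if (!is.null(contigs)) {
        GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(contigs)
        GenomeInfoDb::seqinfo(gr) <- contigs
    }
    TagProfile(id, gr)
}

# ---- shared simulated panels (generated once per test run) ----
.panelCache <- new.env(parent = emptyenv())

# small panel for fast structural tests
smallPanel <- function() {
    if (is.null(.panelCache$small))
        .panelCache$small <- simulateCagePanel(panelConfig(
            seed = 11, nTissues = 12, nContigs = 1, contigLength = 1e5,
            nGenes = 20, nWgbsTissues = 2, familyBlockSize = 5))
    .panelCache$small
}

# the full default-condition panel used by the recovery criteria
defaultPanel <- function() {
    if (is.null(.panelCache$default))
        .panelCache$default <- simulateCagePanel(panelConfig(seed = 101))
    .panelCache$default
}

defaultPipeline <- function() {
    if (is.null(.panelCache$pipeline))
        .panelCache$pipeline <- runPipeline(defaultPanel(),
                                            verbose = FALSE)
    .panelCache$pipeline
}

# deterministic synthetic CpG track from known HMM parameters
.hmmTrack <- function(nCpG, seed = 1, alpha = c(1, 9), beta = c(9, 1),
                      selfTrans = 0.98, spacing = 50) {
    set.seed(seed)
    states <- integer(nCpG)
    states[1] <- sample(1:2, 1)
    for (i in 2:nCpG)
        states[i] <- if (stats::runif(1) < selfTrans) states[i - 1]
                     else 3L - states[i - 1]
    n <- stats::rpois(nCpG, 20)
    p <- stats::rbeta(nCpG, alpha[states], beta[states])
    m <- stats::rbinom(nCpG, n, p)
    sites <- GRanges("chr1", IRanges(seq_len(nCpG) * spacing, width = 1))
    sites$coverage <- n
    sites$methylated <- m
    list(track = new("CpGTrack", sampleID = "sim", sites = sites,
                     minCoverage = 10),
         states = states)
}
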
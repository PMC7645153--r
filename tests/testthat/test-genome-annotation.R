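test_that("contig tables read as Seqinfo in both dialects", {
    tf <- tempfile()
    writeLines(c("chr1\t50000", "chr2\t30000"), tf)
    si <- readContigs(tf)
    expect_equal(GenomeInfoDb::seqlevels(si), c("chr1", "chr2"))
    expect_equal(unname(GenomeInfoDb::seqlengths(si)), c(50000L, 30000L))
    # .fai dialect: extra columns ignored
    fai <- tempfile()
    writeLines(c("chr1\t50000\t6\t60\t61", "chr2\t30000\t50857\t60\t61"),
               fai)
    expect_equal(GenomeInfoDb::seqlengths(readContigs(fai)),
                 GenomeInfoDb::seqlengths(si))
    bad <- tempfile(); writeLines(c("chr1\t0"), bad)
    expect_error(readContigs(bad), "positive")
    dup <- tempfile(); writeLines(c("chr1\t10", "chr1\t20"), dup)
    expect_error(readContigs(dup), "unique")
})

test_that("TSS is the 5'-most transcribed base on the transcript strand", {
    mkGff <- function(strand) {
        gff <- tempfile(fileext = ".gff3")
        writeLines(c("##gff-version 3",
            sprintf("chr1\t.\tgene\t1001\t1800\t.\t%s\t.\tID=g1", strand),
            sprintf("chr1\t.\tmRNA\t1001\t1800\t.\t%s\t.\tID=t1;Parent=g1",
                    strand),
            sprintf("chr1\t.\texon\t1001\t1200\t.\t%s\t.\tParent=t1",
                    strand),
            sprintf("chr1\t.\texon\t1501\t1800\t.\t%s\t.\tParent=t1",
                    strand)), gff)
        gff
    }
    plus <- loadAnnotation(mkGff("+"))
    expect_equal(transcriptRanges(plus)$tss, 1001L)
    minus <- loadAnnotation(mkGff("-"))
    expect_equal(transcriptRanges(minus)$tss, 1800L)
    # no CDS annotated: UTR lists empty but TSS still defined
    expect_equal(sum(lengths(plus@utr5)), 0L)
})

test_that("malformed input and unknown contigs are rejected", {
    bad <- tempfile(fileext = ".gff3")
    writeLines(c("##gff-version 3", "chr1\tonly\tthree"), bad)
    expect_error(loadAnnotation(bad))
    ok <- tempfile(fileext = ".gff3")
    writeLines(c("##gff-version 3",
        "chrX\t.\tmRNA\t100\t200\t.\t+\t.\tID=t1",
        "chrX\t.\texon\t100\t200\t.\t+\t.\tParent=t1"), ok)
    si <- GenomeInfoDb::Seqinfo("chr1", 1000)
    expect_error(loadAnnotation(ok, si), "unknown contig")
})

test_that("generator GFF3 round-trips to the planted gene models", {
    p <- smallPanel()
    dir <- tempfile(); dir.create(dir)
    simulateCagePanel(p$config, outdir = dir)
    reread <- loadAnnotation(file.path(dir, "annotation.gff3"),
                             readContigs(file.path(dir, "contigs.tsv")))
    truthAnnot <- p$truth@tss[p$truth@tss$class == "annotated", ]
    tx <- transcriptRanges(reread)
    expect_setequal(tx$tx_id, truthAnnot$tx_id)
    m <- match(truthAnnot$tx_id, tx$tx_id)
    expect_equal(tx$tss[m], as.integer(truthAnnot$position))
    expect_equal(as.character(GenomicRanges::strand(tx))[m],
                 truthAnnot$strand)
})

test_that("positions classify by the documented precedence", {
    txs <- list(list(tss = 1500, strand = "+",
                     exons = rbind(c(1500, 1650), c(1900, 2400)),
                     cds = c(1630, 2200), tx_id = "t1", gene_id = "g1"))
    models <- modelsFromToy(txs)
    idx <- buildRegionIndex(models)
    at <- function(pos, strand = "+")
        as.character(classifyPositions(idx,
            GRanges("chrT", IRanges(pos, width = 1), strand = strand)))
    expect_equal(at(1550), "promoter")     # tss + 50, inside +/-100
    expect_equal(at(1000), "proximal")     # tss - 500, upstream
    expect_equal(at(200), "intergenic")    # far upstream of everything
    # promoter is strand-aware; an antisense tag falls through to the
    # strand-agnostic exonic classes
    expect_equal(at(1550, "-"), "fiveUTR")
    expect_equal(at(1620), "fiveUTR")      # exonic, 5' of the CDS
    expect_equal(at(1750), "intron")
    expect_equal(at(2100), "exon")
    expect_equal(at(2300), "threeUTR")
})

test_that("interval classification follows the peak and reports genes", {
    txs <- list(list(tss = 1500, strand = "+",
                     exons = rbind(c(1500, 1650), c(1900, 2400)),
                     cds = c(1630, 2200), tx_id = "t1", gene_id = "g1"))
    idx <- buildRegionIndex(modelsFromToy(txs))
    cl <- GRanges("chrT", IRanges(c(1480, 1580), c(1550, 1680)),
                  strand = "+", peak = c(1500, 1610))
    res <- classifyClusters(idx, cl)
    expect_equal(as.character(res$class), c("promoter", "fiveUTR"))
    expect_equal(unlist(res$geneIDs[1]), "g1", ignore_attr = TRUE)
    # spanning promoter + 5'UTR but peaking in the UTR -> fiveUTR
    expect_true("g1" %in% unlist(res$geneIDs[2]))
    # out-of-bounds interval errors
    bad <- GRanges("chrT", IRanges(2900, 3200), peak = 3000)
    expect_error(classifyClusters(idx, bad), "bounds")
})

test_that("classification agrees with a per-bp brute-force oracle", {
    set.seed(42)
    for (rep in 1:12) {
        txs <- randomToyAnnotation()
        idx <- buildRegionIndex(modelsFromToy(txs))
        pos <- sample(3000, 150)
        got <- as.character(classifyPositions(idx,
            GRanges("chrT", IRanges(pos, width = 1), strand = "*")))
        want <- vapply(pos, function(p) oracleClassify(txs, p),
                       character(1))
        expect_equal(got, want, info = sprintf("replicate %d", rep))
    }
})

test_that("per-class bp totals partition the contig", {
    set.seed(7)
    for (rep in 1:5) {
        txs <- randomToyAnnotation(nTx = 3)
        idx <- buildRegionIndex(modelsFromToy(txs))
        tot <- regionBpTotals(idx)
        expect_equal(sum(tot), 3000)
        expect_true(all(tot >= 0))
    }
})

test_that("classification is symmetric under strand reflection", {
    contigLen <- 3000
    txs <- randomToyAnnotation()
    reflect <- function(tx) {
        ex <- contigLen + 1 - tx$exons[, 2:1, drop = FALSE]
        list(tss = contigLen + 1 - tx$tss,
             strand = if (tx$strand == "+") "-" else "+",
             exons = ex[order(ex[, 1]), , drop = FALSE],
             cds = contigLen + 1 - rev(tx$cds),
             tx_id = tx$tx_id, gene_id = tx$gene_id)
    }
    idx1 <- buildRegionIndex(modelsFromToy(txs))
    idx2 <- buildRegionIndex(modelsFromToy(lapply(txs, reflect)))
    pos <- seq(10, 2990, by = 7)
    c1 <- classifyPositions(idx1, GRanges("chrT",
        IRanges(pos, width = 1), strand = "*"))
    c2 <- classifyPositions(idx2, GRanges("chrT",
        IRanges(contigLen + 1 - pos, width = 1), strand = "*"))
    expect_equal(as.character(c1), as.character(c2))
})
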
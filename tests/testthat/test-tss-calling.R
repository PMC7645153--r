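test_that("representation threshold reproduces the printed cutoffs", {
    expect_identical(representationThreshold(56, 2/3), 37L)
    expect_identical(representationThreshold(56, 2/3, "ceil"), 38L)
    expect_identical(representationThreshold(56, 1), 56L)
    expect_identical(representationThreshold(3, 2/3), 2L)
    expect_identical(representationThreshold(1, 1/2), 1L)  # floor >= 1
})

.mkPooled <- function(pos, val, strand = "+", contig = "chr1") {
    gr <- GRanges(contig, IRanges(pos, width = 1), strand = strand)
    gr$score <- val
    gr
}

test_that("uni-directional clustering merges by gap and picks peaks", {
    pooled <- .mkPooled(c(100, 101, 102, 150), c(12, 30, 8, 9))
    cl <- callUnidirectionalClusters(pooled, mergeDist = 20)
    expect_equal(GenomicRanges::start(cl), c(100, 150))
    expect_equal(GenomicRanges::end(cl), c(102, 150))
    expect_equal(cl$peak, c(101, 150))
    expect_equal(cl$pooledSignal, c(50, 9))
    # single position
    one <- callUnidirectionalClusters(.mkPooled(500, 4))
    expect_equal(one$peak, 500)
    expect_equal(GenomicRanges::width(one), 1)
    # merge boundary: 20 apart merges, 21 apart splits
    expect_length(callUnidirectionalClusters(
        .mkPooled(c(100, 120), c(1, 1)), 20), 1)
    expect_length(callUnidirectionalClusters(
        .mkPooled(c(100, 121), c(1, 1)), 20), 2)
    # peak ties resolve 5'-most on the cluster strand
    tiePlus <- callUnidirectionalClusters(.mkPooled(c(10, 12), c(5, 5)))
    expect_equal(tiePlus$peak, 10)
    tieMinus <- callUnidirectionalClusters(
        .mkPooled(c(10, 12), c(5, 5), strand = "-"))
    expect_equal(tieMinus$peak, 12)
    # empty signal -> empty set
    expect_length(callUnidirectionalClusters(GRanges(score = numeric(0))),
                  0)
})

test_that("clustering matches the brute-force oracle on random signals", {
    set.seed(99)
    for (i in 1:300) {
        n <- sample(1:25, 1)
        pos <- sort(sample(1:400, n))
        val <- sample(1:50, n, replace = TRUE)
        strand <- sample(c("+", "-"), 1)
        md <- sample(c(0, 1, 5, 20), 1)
        got <- callUnidirectionalClusters(
            .mkPooled(pos, val, strand), mergeDist = md)
        want <- oracleClusters(pos, val, strand, mergeDist = md)
        expect_equal(GenomicRanges::start(got), want$start)
        expect_equal(GenomicRanges::end(got), want$end)
        expect_equal(got$peak, want$peak)
        expect_equal(got$pooledSignal, want$total)
    }
})

test_that("clustering is order-invariant and monotone in mergeDist", {
    set.seed(5)
    pos <- sample(1:2000, 60)
    val <- sample(1:20, 60, replace = TRUE)
    perm <- sample(60)
    a <- callUnidirectionalClusters(.mkPooled(pos, val))
    b <- callUnidirectionalClusters(.mkPooled(pos[perm], val[perm]))
    expect_equal(a, b)
    sizes <- vapply(c(0, 1, 2, 5, 10, 50, 200), function(md)
        length(callUnidirectionalClusters(.mkPooled(pos, val), md)),
        numeric(1))
    expect_true(all(diff(sizes) <= 0))
})

.mkSet <- function(countMat, contig = "chr1", strand = "+") {
    n <- nrow(countMat)
    cl <- GRanges(contig, IRanges(seq_len(n) * 1000,
                                  seq_len(n) * 1000 + 4),
                  strand = strand)
    cl$cluster_id <- sprintf("c%d", seq_len(n))
    cl$peak <- GenomicRanges::start(cl)
    cl$pooledSignal <- rowSums(countMat)
    profs <- lapply(seq_len(ncol(countMat)), function(j) {
        keep <- countMat[, j] > 0
        mkProfile(sprintf("t%02d", j), contig,
                  GenomicRanges::start(cl)[keep], strand,
                  countMat[keep, j])
    })
    quantifyClusters(cl, profs)
}

test_that("two-stage filter drops low-count then under-represented clusters", {
    # 3 clusters x 6 tissues: present in 6, 4, and 1 tissues
    m <- rbind(rep(20, 6), c(15, 15, 15, 15, 0, 0),
               c(12, 0, 0, 0, 0, 0))
    tcs <- .mkSet(m)
    f <- filterClusters(tcs, minClusterCount = 10, minTissues = 4)
    expect_equal(nrow(f), 2)
    # pooled count 9 dropped regardless of spread
    m2 <- rbind(matrix(1.5, 1, 6))
    m2 <- rbind(c(2, 2, 1, 1, 2, 1))
    tcs2 <- .mkSet(m2)
    expect_equal(nrow(filterClusters(tcs2, minClusterCount = 10,
                                     minTissues = 1)), 0)
    # threshold larger than the panel errors
    expect_error(filterClusters(tcs, minTissues = 7), "exceeds")
    # monotone: raising the threshold never adds clusters
    ns <- vapply(1:6, function(k)
        nrow(filterClusters(tcs, minTissues = k)), numeric(1))
    expect_true(all(diff(ns) <= 0))
})

test_that("presence rules distinguish raw counts from CTPM", {
    m <- rbind(c(10, 10, 9, 0))
    tcs <- .mkSet(m)
    expect_equal(sum(presenceMatrix(tcs, "count_ge_10", 10)), 2)
    # ctpm rule is strict: a cluster holding the whole library is 1e6 CTPM
    expect_equal(sum(presenceMatrix(tcs, "ctpm_gt_10", 10)), 3)
})

test_that("tissue-specific clusters are grouped by their single tissue", {
    m <- rbind(c(12, 0, 0, 0, 0, 0),   # specific to t01
               c(12, 12, 0, 0, 0, 0),  # two tissues: excluded
               c(10, 0, 0, 0, 0, 0),   # not > 10: excluded
               c(0, 0, 0, 30, 0, 0))   # specific to t04
    ts <- tissueSpecificClusters(.mkSet(m), minCount = 10)
    expect_setequal(names(ts), c("t01", "t04"))
    expect_equal(nrow(ts[["t01"]]), 1)
    expect_equal(rownames(ts[["t01"]]), "c1")
})

test_that("planted tissue-restricted clusters are recovered per tissue", {
    p <- smallPanel()
    pooled <- poolProfiles(p$profiles)
    tcs <- quantifyClusters(callUnidirectionalClusters(pooled),
                            p$profiles)
    ts <- tissueSpecificClusters(tcs)
    truthTS <- p$truth@tss[p$truth@tss$class == "tissue_specific", ]
    found <- unlist(lapply(names(ts), function(nm) {
        pk <- SummarizedExperiment::rowRanges(ts[[nm]])$peak
        vapply(seq_len(nrow(truthTS)), function(i)
            truthTS$tissues[i] == nm &&
                any(abs(pk - truthTS$position[i]) <= 10), logical(1))
    }))
    expect_equal(sum(found), nrow(truthTS))
})

test_that("clusters per gene counts promoter-window assignments", {
    txs <- list(list(tss = 1500, strand = "+",
                     exons = rbind(c(1500, 1650), c(1900, 2400)),
                     cds = c(1630, 2200), tx_id = "t1", gene_id = "g1"))
    idx <- buildRegionIndex(modelsFromToy(txs))
    m <- rbind(c(40, 40), c(40, 40))
    tcs <- .mkSet(m, contig = "chrT")
    # move both clusters inside g1's promoter window
    rr <- SummarizedExperiment::rowRanges(tcs)
    GenomicRanges::ranges(rr) <- IRanges(c(1450, 1560), c(1460, 1570))
    rr$peak <- GenomicRanges::start(rr)
    SummarizedExperiment::rowRanges(tcs) <- rr
    res <- clustersPerGene(tcs, idx)
    expect_equal(res$perGene$nClusters[res$perGene$gene_id == "g1"], 2L)
    expect_equal(res$meanPerGene, 2)
    expect_equal(res$nGenesNotCaptured, 0)
})

test_that("second TSS in a fraction of genes lifts the per-gene mean", {
    p <- smallPanel()
    res <- runPipeline(p, verbose = FALSE)
    pg <- res$perGene
    fracMulti <- p$config$fracMultiTss
    expect_equal(pg$medianPerGene, 1)
    expect_lt(abs(pg$meanPerGene - (1 + fracMulti)), 0.15)
})
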
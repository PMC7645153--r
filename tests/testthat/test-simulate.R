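.tinyCfg <- function(seed = 3)
    panelConfig(seed = seed, nTissues = 6, nContigs = 1,
                contigLength = 6e4, nGenes = 10, nWgbsTissues = 1,
                familyBlockSize = 2, nTissueFamilies = 2)

test_that("a fixed seed reproduces byte-identical panel files", {
    d1 <- tempfile(); d2 <- tempfile()
    simulateCagePanel(.tinyCfg(), outdir = d1)
    simulateCagePanel(.tinyCfg(), outdir = d2)
    f1 <- list.files(d1, recursive = TRUE)
    f2 <- list.files(d2, recursive = TRUE)
    expect_setequal(f1, f2)
    for (f in f1)
        expect_identical(unname(tools::md5sum(file.path(d1, f))),
                         unname(tools::md5sum(file.path(d2, f))),
                         label = f)
    d3 <- tempfile()
    simulateCagePanel(.tinyCfg(seed = 4), outdir = d3)
    sums <- function(d) unname(tools::md5sum(
        file.path(d, list.files(d, recursive = TRUE))))
    expect_false(identical(sums(d1), sums(d3)))
})

test_that("emitted files parse back through the pipeline readers", {
    d <- tempfile()
    p <- simulateCagePanel(.tinyCfg(), outdir = d)
    si <- readContigs(file.path(d, "contigs.tsv"))
    expect_equal(GenomeInfoDb::seqlengths(si),
                 GenomeInfoDb::seqlengths(p$contigs))
    models <- loadAnnotation(file.path(d, "annotation.gff3"), si)
    expect_equal(sort(transcriptRanges(models)$tx_id),
                 sort(transcriptRanges(p$models)$tx_id))
    beds <- list.files(file.path(d, "cage"), full.names = TRUE)
    expect_length(beds, 6)
    prof <- readTagProfile(beds[1], contigs = si)
    inMem <- p$profiles[[sub("\\.bed$", "", basename(beds[1]))]]
    expect_equal(totalMapped(prof), totalMapped(inMem))
    cg <- list.files(file.path(d, "wgbs"), full.names = TRUE)
    tr <- suppressMessages(mergeSymmetricCpGs(readCGmap(cg[1])))
    inMemTrack <- p$cpgTracks[[1]]
    expect_equal(sum(cpgSites(tr)$coverage),
                 sum(cpgSites(inMemTrack)$coverage))
    ab <- readKallistoAbundance(
        list.files(file.path(d, "tpm"), full.names = TRUE)[1])
    expect_true(all(c("target_id", "tpm") %in% names(ab)))
    tj <- jsonlite::read_json(file.path(d, "truth.json"),
                              simplifyVector = TRUE)
    expect_equal(nrow(tj$tss), nrow(p$truth@tss))
})

test_that("planted coordinates respect their construction rules", {
    p <- smallPanel()
    truth <- p$truth
    tssAn <- tssAnchors(p$models)
    anchors <- GenomicRanges::start(tssAn)
    byContig <- split(anchors,
                      as.character(GenomicRanges::seqnames(tssAn)))
    minDistToPromoter <- function(contig, pos)
        min(abs(byContig[[contig]] - pos))
    # annotated TSS sit exactly at a transcript TSS
    an <- truth@tss[truth@tss$class == "annotated", ]
    expect_true(all(vapply(seq_len(nrow(an)), function(i)
        minDistToPromoter(an$contig[i], an$position[i]) == 0,
        logical(1))))
    # novel TSS lie at least 400 bp from every promoter
    nv <- truth@tss[truth@tss$class == "novel", ]
    expect_true(all(vapply(seq_len(nrow(nv)), function(i)
        minDistToPromoter(nv$contig[i], nv$position[i]) >= 400,
        logical(1))))
    # in-range enhancers are 400-1000 bp from their nearest promoter,
    # decoys farther than 1000 bp
    for (i in seq_len(nrow(truth@enhancers))) {
        d <- minDistToPromoter(truth@enhancers$contig[i],
                               truth@enhancers$midpoint[i])
        if (truth@enhancers$inRange[i])
            expect_true(d >= 400 && d <= 1000)
        else expect_gt(d, 1000)
    }
    # planted islands cover the TSS they were assigned to
    hm <- truth@hmrs
    flagged <- truth@tss[truth@tss$hmr, ]
    expect_true(all(flagged$position >= 0))
    expect_equal(nrow(hm), nrow(flagged))
})

test_that("library sizes match the count-model expectation", {
    p <- smallPanel()
    cfg <- p$config
    truth <- p$truth@tss
    nShared <- sum(truth$class %in% c("annotated", "novel"))
    nArms <- 2 * sum(p$truth@enhancers$inRange)
    mu <- cfg$tssCountMean
    expPerTissue <- (nShared + nArms) * mu
    # negative binomial variance mu + mu^2/size per locus
    varPerTissue <- (nShared + nArms) *
        (mu + mu^2 * cfg$tssCountDispersion)
    totals <- vapply(p$profiles, totalMapped, numeric(1))
    # every tissue total within 4 sd of the expectation (family,
    # tissue-specific and noise tags add a small positive excess)
    slack <- 4 * sqrt(varPerTissue)
    excess <- cfg$familyBlockSize * mu + 50
    expect_true(all(totals > expPerTissue - slack))
    expect_true(all(totals < expPerTissue + slack + excess * 3))
})

test_that("recovery scoring matches brute-force matching and edge cases", {
    truth <- data.frame(contig = "c", position = c(100, 200, 300))
    calls <- GRanges("c", IRanges(c(102, 205, 290), width = 1))
    calls$peak <- GenomicRanges::start(calls)
    perfect <- scoreRecovery(truth, calls, toleranceBp = 10)
    expect_equal(perfect$precision, 1)
    expect_equal(perfect$recall, 1)
    empty <- scoreRecovery(truth, GRanges())
    expect_equal(empty$recall, 0)
    # one-to-one: two calls cannot consume the same truth position
    dup <- GRanges("c", IRanges(c(101, 99), width = 1))
    dup$peak <- GenomicRanges::start(dup)
    one <- scoreRecovery(data.frame(contig = "c", position = 100), dup,
                         toleranceBp = 10)
    expect_equal(one$nMatched, 1L)
    expect_equal(one$precision, 0.5)
    # greedy closest-first assignment agrees with an exhaustive search
    set.seed(31)
    for (rep in 1:5) {
        tpos <- sort(sample(1:2000, 20))
        cpos <- tpos + sample(-15:15, 20, replace = TRUE)
        got <- scoreRecovery(data.frame(contig = "c", position = tpos),
                             {
                                 g <- GRanges("c", IRanges(cpos, width = 1))
                                 g$peak <- cpos
                                 g
                             }, toleranceBp = 10)
        # brute-force greedy: repeatedly take the globally closest pair
        pairs <- expand.grid(t = 1:20, c = 1:20)
        pairs$d <- abs(tpos[pairs$t] - cpos[pairs$c])
        pairs <- pairs[pairs$d <= 10, ]
        pairs <- pairs[order(pairs$d, pairs$t, pairs$c), ]
        tU <- cU <- logical(20); nM <- 0
        for (k in seq_len(nrow(pairs))) {
            if (!tU[pairs$t[k]] && !cU[pairs$c[k]]) {
                tU[pairs$t[k]] <- cU[pairs$c[k]] <- TRUE
                nM <- nM + 1
            }
        }
        expect_equal(got$nMatched, nM)
    }
    # interval mode: identical sets give Jaccard 1
    iv <- data.frame(contig = "c", start = c(10, 50), end = c(20, 70))
    ivGR <- GRanges("c", IRanges(c(10, 50), c(20, 70)))
    self <- scoreRecovery(iv, ivGR, mode = "intervals")
    expect_equal(self$jaccard, 1)
})
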
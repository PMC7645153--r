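test_that("symmetric CpG pairs merge additively; orphans are kept", {
    recs <- data.frame(
        contig = c("chr1", "chr1", "chr1"),
        strand = c("+", "-", "+"),
        position = c(100L, 101L, 500L),
        methylated = c(3L, 2L, 0L),
        coverage = c(6L, 4L, 12L))
    expect_message(mergeSymmetricCpGs(recs, "s"), "partner")
    tr <- suppressMessages(mergeSymmetricCpGs(recs, "s"))
    st <- cpgSites(tr)
    expect_equal(GenomicRanges::start(st), c(100L, 500L))
    expect_equal(st$coverage, c(10L, 12L))
    expect_equal(st$methylated, c(5L, 0L))
    # a lone minus-strand C reports at the dinucleotide anchor
    lone <- data.frame(contig = "chr1", strand = "-", position = 201L,
                       methylated = 1L, coverage = 5L)
    expect_equal(GenomicRanges::start(
        cpgSites(suppressMessages(mergeSymmetricCpGs(lone, "s")))), 200L)
})

test_that("CGmap reading keeps CpG context and infers strand", {
    f <- tempfile()
    writeLines(c("chr1\tC\t100\tCG\tCG\t0.5\t3\t6",
                 "chr1\tG\t101\tCG\tCG\t0.5\t2\t4",
                 "chr1\tC\t150\tCHH\tCA\t0.0\t0\t9"), f)
    rec <- readCGmap(f, "x")
    expect_equal(nrow(rec), 2)   # CHH dropped
    expect_equal(rec$strand, c("+", "-"))
    tr <- mergeSymmetricCpGs(rec)
    expect_equal(cpgSites(tr)$coverage, 10L)
})

test_that("Beta-Binomial log-pmf matches closed forms and quadrature", {
    # alpha = beta = 1 is uniform on 0..n
    expect_equal(betaBinomLogPmf(5, 10, 1, 1), log(1 / 11),
                 tolerance = 1e-10)
    expect_equal(betaBinomLogPmf(0, 0, 3, 7), 0, tolerance = 1e-12)
    # numerical integration over the Beta prior
    quad <- function(m, n, a, b)
        log(stats::integrate(function(p)
            choose(n, m) * p^m * (1 - p)^(n - m) * stats::dbeta(p, a, b),
            0, 1, rel.tol = 1e-12)$value)
    for (cse in list(c(3, 8, 2, 5), c(0, 15, 1, 9), c(12, 12, 9, 1))) {
        expect_equal(betaBinomLogPmf(cse[1], cse[2], cse[3], cse[4]),
                     quad(cse[1], cse[2], cse[3], cse[4]),
                     tolerance = 1e-8)
    }
    # pmf sums to 1
    expect_equal(sum(exp(betaBinomLogPmf(0:20, 20, 2.5, 0.7))), 1,
                 tolerance = 1e-10)
    expect_error(betaBinomLogPmf(5, 3, 1, 1))
    expect_error(betaBinomLogPmf(1, 3, -1, 1))
})

test_that("EM log-likelihood is non-decreasing and posteriors normalize", {
    tt <- .hmmTrack(400, seed = 21)
    fit <- fitMethHMM(tt$track)
    expect_true(all(diff(fit$logLik) > -1e-6))
    expect_equal(fit$posteriorHypo + fit$posteriorHyper,
                 rep(1, length(fit$posteriorHypo)), tolerance = 1e-10)
    expect_true(all(fit$posteriorHypo >= 0 & fit$posteriorHypo <= 1))
    expect_lt(fit$stateMeans[1], fit$stateMeans[2])
    # forward and backward recursions agree on the total log-likelihood
    expect_equal(fit$logLik[length(fit$logLik)], fit$logLikBackward,
                 tolerance = 1e-8)
})

test_that("EM recovers the generating state means", {
    tt <- .hmmTrack(10000, seed = 33)
    fit <- fitMethHMM(tt$track)
    expect_lt(abs(fit$stateMeans[1] - 0.1), 0.05)
    expect_lt(abs(fit$stateMeans[2] - 0.9), 0.05)
    # decoded states agree with the simulation overwhelmingly
    cov10 <- cpgSites(tt$track)$coverage >= 10
    agree <- mean(fit$states == tt$states[cov10])
    expect_gt(max(agree, 1 - agree), 0.95)
})

test_that("degenerate tracks yield no hypomethylated regions", {
    sites <- GRanges("chr1", IRanges(seq_len(200) * 40, width = 1))
    sites$coverage <- rep(20L, 200)
    sites$methylated <- rep(20L, 200)   # fully methylated everywhere
    tr <- new("CpGTrack", sampleID = "flat", sites = sites,
              minCoverage = 10)
    h <- suppressWarnings(callHMRs(tr))
    expect_length(hmrRegions(h), 0)
})

test_that("segmentation ignores CpGs below the coverage filter", {
    tt <- .hmmTrack(500, seed = 55)
    h1 <- callHMRs(tt$track)
    # interleave low-coverage CpGs; segmentation must not change
    st <- cpgSites(tt$track)
    extra <- GRanges("chr1",
                     IRanges(GenomicRanges::start(st) + 7, width = 1))
    extra$coverage <- 5L
    extra$methylated <- 2L
    both <- sort(c(st, extra))
    tr2 <- new("CpGTrack", sampleID = "sim", sites = both,
               minCoverage = 10)
    h2 <- callHMRs(tr2)
    expect_equal(hmrRegions(h1), hmrRegions(h2))
})

test_that("planted hypomethylated islands are recovered (Jaccard)", {
    p <- smallPanel()
    h <- callHMRs(p$cpgTracks[[1]])
    sc <- scoreRecovery(p$truth@hmrs, h, mode = "intervals")
    expect_gte(sc$jaccard, 0.85)
    expect_gte(sc$recall, 0.95)
})

test_that("TSS validation crosses novelty with HMR overlap", {
    cl <- GRanges("chr1", IRanges(c(100, 300, 500, 700), width = 10))
    hmr <- GRanges("chr1", IRanges(c(95, 505), width = 20))
    res <- validateTSS(cl, novel = c(FALSE, FALSE, TRUE, TRUE), hmr)
    expect_equal(as.character(res$category),
                 c("annotated+HypoCpG", "annotated w/o",
                   "novel+HypoCpG", "novel w/o"))
    expect_equal(res$table$percent, rep(25, 4))
})
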
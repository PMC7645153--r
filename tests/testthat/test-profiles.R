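test_that("equal-width binning spans the range and handles constants", {
    expect_equal(binProfile(0:9, 10), 0:9)
    expect_equal(binProfile(rep(3.5, 20), 10), rep(0L, 20))
    b <- binProfile(stats::runif(100, 5, 9), 10)
    expect_true(all(b >= 0 & b <= 9))
    # the maximum lands in the top bin
    expect_equal(binProfile(c(0, 10), 10), c(0L, 9L))
    # equal-frequency alternative
    bf <- binProfile(stats::rexp(1000), 4, scheme = "frequency")
    expect_true(max(table(bf)) / min(table(bf)) < 1.2)
})

test_that("mutual information matches hand-computed identities", {
    # independent patterns with uniform marginals
    x <- rep(c(0L, 1L), 50)
    y <- rep(c(0L, 0L, 1L, 1L), 25)
    expect_equal(mutualInformation(x, y), 0, tolerance = 1e-12)
    # identical vectors: MI = entropy of the bin distribution
    v <- rep(0:9, 10)
    expect_equal(mutualInformation(v, v), log(10), tolerance = 1e-12)
    expect_equal(mutualInformation(v, v),
                 mutualInformation(binProfile(as.numeric(v), 10),
                                   binProfile(as.numeric(v), 10)))
    # 3x3 joint table vs direct plug-in sum
    x3 <- c(rep(0L, 4), rep(1L, 3), rep(2L, 2), 0L, 1L, 2L)
    y3 <- c(0L, 0L, 1L, 2L, 1L, 1L, 0L, 2L, 2L, 2L, 0L, 1L)
    j <- table(x3, y3) / length(x3)
    px <- rowSums(j); py <- colSums(j)
    hand <- 0
    for (i in 1:3) for (k in 1:3)
        if (j[i, k] > 0)
            hand <- hand + j[i, k] * log(j[i, k] / (px[i] * py[k]))
    expect_equal(mutualInformation(x3, y3), as.numeric(hand),
                 tolerance = 1e-12)
    # symmetry
    expect_equal(mutualInformation(x3, y3), mutualInformation(y3, x3),
                 tolerance = 1e-12)
    expect_error(mutualInformation(0:3, 0:4), "equal length")
})

test_that("MI distance follows its closed form and is monotone", {
    expect_equal(miDistance(0), 1)
    expect_equal(miDistance(log(10)), 1 - sqrt(1 - 0.01),
                 tolerance = 1e-12)
    expect_lt(miDistance(50), 1e-12)
    mis <- seq(0, 5, by = 0.01)
    expect_true(all(diff(miDistance(mis)) < 0))
    expect_true(all(miDistance(mis) >= 0 & miDistance(mis) <= 1))
    expect_error(miDistance(-0.1), "non-negative")
})

test_that("the Gaussian identity delta = |rho| holds asymptotically", {
    # for bivariate normal data, sqrt(1 - exp(-2 MI)) estimates |rho|
    set.seed(17)
    n <- 20000
    for (rho in c(0.5, 0.8)) {
        x <- stats::rnorm(n)
        y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
        mi <- mutualInformation(binProfile(x, 12), binProfile(y, 12))
        delta <- sqrt(1 - exp(-2 * mi))
        expect_lt(abs(delta - rho), 0.08)
    }
})

test_that("tissues with identical profiles join first in the dendrogram", {
    set.seed(4)
    base <- stats::rnbinom(200, mu = 50, size = 2)
    m <- cbind(A = base, B = base,
               C = stats::rnbinom(200, mu = 50, size = 2),
               D = stats::rnbinom(200, mu = 50, size = 2))
    ct <- clusterTissues(m)
    first <- ct$hclust$merge[1, ]
    expect_setequal(ct$hclust$labels[-first], c("A", "B"))
    # Newick round-trips through a standard parser
    tr <- ape::read.tree(text = ct$newick)
    expect_s3_class(tr, "phylo")
    expect_setequal(tr$tip.label, colnames(m))
    # distance matrix is symmetric with values in [0, 1]
    expect_equal(ct$distance, t(ct$distance))
    expect_true(all(ct$distance >= 0 & ct$distance <= 1))
})

test_that("sharing matrix equals brute-force pairwise intersection", {
    m <- rbind(c(20, 20, 20, 20, 20),
               c(20, 20, 0, 0, 0),
               c(0, 20, 20, 0, 0),
               c(0, 0, 0, 0, 20))
    cl <- GRanges("chr1", IRanges(1:4 * 1000, width = 5), strand = "+")
    cl$cluster_id <- sprintf("c%d", 1:4)
    cl$peak <- GenomicRanges::start(cl)
    cl$pooledSignal <- rowSums(m)
    profs <- lapply(1:5, function(j) {
        keep <- m[, j] > 0
        mkProfile(sprintf("t%d", j), "chr1",
                  GenomicRanges::start(cl)[keep], "+", m[keep, j])
    })
    tcs <- quantifyClusters(cl, profs)
    S <- sharingMatrix(tcs)
    pres <- m >= 10
    want <- matrix(0L, 5, 5)
    for (t in 1:5) for (u in 1:5)
        want[t, u] <- sum(pres[, t] & pres[, u])
    dimnames(want) <- dimnames(S)
    expect_equal(S, want)
    expect_equal(S, t(S))
    expect_equal(diag(S), colSums(pres), ignore_attr = TRUE)
})

test_that("planted tissue families are recovered from expression", {
    skip_if_not_installed("mclust")
    p <- smallPanel()
    pooled <- poolProfiles(p$profiles)
    tcs <- quantifyClusters(callUnidirectionalClusters(pooled),
                            p$profiles)
    keep <- rowSums(SummarizedExperiment::assay(tcs, "counts")) >= 10
    ct <- clusterTissues(tcs[keep, ])
    k <- p$config$nTissueFamilies
    cl <- stats::cutree(ct$hclust, k = k)
    fam <- p$truth@families$family[match(names(cl),
                                         p$truth@families$tissue)]
    ari <- mclust::adjustedRandIndex(cl, fam)
    expect_gte(ari, 0.9)
})

test_that("CAGE-mRNA correlation matches the textbook formula", {
    set.seed(9)
    ct <- matrix(stats::rexp(50, 0.01), 5, 10,
                 dimnames = list(sprintf("c%d", 1:5),
                                 sprintf("t%d", 1:10)))
    tp <- ct * 2
    rownames(tp) <- sprintf("x%d", 1:5)
    pairs <- data.frame(cluster_id = rownames(ct), tx_id = rownames(tp))
    r <- correlateCageMrna(ct, tp, pairs, logScale = FALSE)
    expect_equal(r$r, 1, tolerance = 1e-12)
    tpNeg <- max(ct) - ct
    rownames(tpNeg) <- rownames(tp)
    expect_equal(correlateCageMrna(ct, tpNeg, pairs,
                                   logScale = FALSE)$r, -1,
                 tolerance = 1e-12)
    # direct formula on the flattened pairs
    noisy <- ct + matrix(stats::rexp(50, 0.01), 5, 10)
    rownames(noisy) <- rownames(tp)
    got <- correlateCageMrna(ct, noisy, pairs, logScale = FALSE)
    x <- as.vector(ct); y <- as.vector(noisy)
    want <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(got$r, want, tolerance = 1e-12)
})
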
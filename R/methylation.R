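#' Read a CGmap-style per-cytosine methylation table
#'
#' CGmap columns: contig, nucleotide on the Watson strand (`C` = plus
#' strand cytosine, `G` = minus strand cytosine), 1-based position,
#' context (`CG`/`CHG`/`CHH`), dinucleotide context, methylation level,
#' methylated read count, total coverage. Only CpG-context records are
#' retained.
#'
#' @param path path to the (optionally headerless) tab-separated file.
#' @param sampleID library identifier; defaults to the file base name.
#' @return data.frame with `contig`, `strand`, `position`, `methylated`,
#'   `coverage` for CpG-context cytosines, suitable for
#'   [mergeSymmetricCpGs()].
#' @export
readCGmap <- function(path, sampleID = NULL) {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE,
                             col.names = c("contig", "nucleotide",
                                           "position", "context",
                                           "dinucleotide", "level",
                                           "methylated", "coverage"))
    if (is.null(sampleID))
        sampleID <- sub("\\.(cgmap|CGmap)(\\.tsv)?$", "", basename(path))
    tab <- tab[tab$context == "CG", , drop = FALSE]
    out <- data.frame(contig = tab$contig,
                      strand = ifelse(tab$nucleotide == "C", "+", "-"),
                      position = as.integer(tab$position),
                      methylated = as.integer(tab$methylated),
                      coverage = as.integer(tab$coverage))
    attr(out, "sampleID") <- sampleID
    out
}

#' Merge methylation counts at symmetric CpG pairs
#'
#' The two cytosines of one CpG dinucleotide (plus-strand C at `p`,
#' minus-strand C at `p + 1`) report the same methylation state; their
#' counts are summed and recorded at `p`, the plus-strand C. A cytosine
#' whose partner was not observed is kept as-is (reported at the
#' dinucleotide's plus-strand coordinate) with a notice.
#'
#' @param records data.frame from [readCGmap()] (or with the same
#'   columns).
#' @param sampleID library identifier; defaults to the `sampleID`
#'   attribute of `records`.
#' @param minCoverage coverage cut-off stored with the track (default 10);
#'   sites below it are excluded from HMM fitting, not from the track.
#' @return a [CpGTrack-class].
#' @export
mergeSymmetricCpGs <- function(records, sampleID = NULL,
                               minCoverage = 10) {
    if (is.null(sampleID)) {
        sampleID <- attr(records, "sampleID")
        if (is.null(sampleID)) sampleID <- "sample"
    }
    plus <- records[records$strand == "+", , drop = FALSE]
    minus <- records[records$strand == "-", , drop = FALSE]
    # a minus-strand C at p belongs to the dinucleotide anchored at p - 1
    minusKey <- paste(minus$contig, minus$position - 1L)
    plusKey <- paste(plus$contig, plus$position)
    mIdx <- match(plusKey, minusKey)
    paired <- !is.na(mIdx)
    mergedPlus <- data.frame(
        contig = plus$contig, position = plus$position,
        methylated = plus$methylated +
            ifelse(paired, minus$methylated[mIdx], 0L),
        coverage = plus$coverage +
            ifelse(paired, minus$coverage[mIdx], 0L))
    lonely <- minus[!(minusKey %in% plusKey), , drop = FALSE]
    nLone <- sum(!paired) + nrow(lonely)
    if (nLone > 0L)
        message(nLone, " CpG record(s) had no symmetric partner; ",
                "kept single-stranded")
    merged <- rbind(mergedPlus,
                    data.frame(contig = lonely$contig,
                               position = lonely$position - 1L,
                               methylated = lonely$methylated,
                               coverage = lonely$coverage))
    merged <- merged[order(merged$contig, merged$position), , drop = FALSE]
    sites <- GRanges(merged$contig, IRanges(merged$position, width = 1L),
                     coverage = merged$coverage,
                     methylated = merged$methylated)
    new("CpGTrack", sampleID = sampleID, sites = sites,
        minCoverage = minCoverage)
}

#' Beta-Binomial log probability mass
#'
#' `log P(m | n, alpha, beta)` for the Beta-Binomial distribution:
#' `lchoose(n, m) + lbeta(m + alpha, n - m + beta) - lbeta(alpha, beta)`.
#' With `alpha = beta = 1` the distribution is uniform on `0..n`; an empty
#' trial (`n = 0`) has probability 1.
#'
#' @param m methylated count(s), `0 <= m <= n`.
#' @param n coverage(s).
#' @param alpha,beta positive shape parameters.
#' @return numeric log-probabilities (vectorized).
#' @export
betaBinomLogPmf <- function(m, n, alpha, beta) {
    if (any(alpha <= 0) || any(beta <= 0))
        stop("alpha and beta must be positive")
    if (any(m < 0) || any(m > n))
        stop("need 0 <= m <= n")
    lchoose(n, m) + lbeta(m + alpha, n - m + beta) - lbeta(alpha, beta)
}

#' @noRd
.splitChains <- function(track, minCoverage, desertSize) {
    st <- cpgSites(track)
    st <- st[st$coverage >= minCoverage]
    if (length(st) == 0L) return(list(sites = st, chain = integer(0)))
    ctg <- as.character(seqnames(st))
    pos <- start(st)
    brk <- c(TRUE, ctg[-1L] != ctg[-length(ctg)] |
                   (pos[-1L] - pos[-length(pos)]) > desertSize)
    list(sites = st, chain = cumsum(brk))
}

#' Fit a two-state Beta-Binomial HMM to a CpG methylation track
#'
#' Models per-CpG methylated counts `m_i ~ BetaBinomial(n_i, alpha_s,
#' beta_s)` given a hidden hypo-/hypermethylated state following a
#' first-order Markov chain. Fitting is Baum-Welch EM: the initial
#' distribution and transition matrix have closed-form updates; the state
#' emission shapes are re-estimated each iteration by numerical
#' maximization of the expected emission log-likelihood (BFGS on log
#' shapes, warm-started). States are relabelled so state 1 ("hypo") has
#' the smaller mean `alpha / (alpha + beta)`. CpGs below the coverage
#' cut-off are ignored; chains are broken at inter-CpG gaps larger than
#' `desertSize` bp and share one parameter set.
#'
#' @param track a [CpGTrack-class].
#' @param hypoMeanInit,hyperMeanInit initial state means (defaults 0.2 /
#'   0.8).
#' @param concInit initial concentration `alpha + beta` per state
#'   (default 10).
#' @param selfTransInit initial self-transition probability (default
#'   0.99).
#' @param emTol EM stops when the log-likelihood improves by less than
#'   this (default 1e-4).
#' @param maxIter maximum EM iterations (default 100).
#' @param minCoverage coverage filter (default from the track).
#' @param desertSize chain-breaking gap in bp (default 1000).
#' @return list: `alpha`, `beta` (length-2, hypo first), `stateMeans`,
#'   `A` (transition matrix), `pi`, `logLik` (trace), `converged`,
#'   `posteriorHypo`, `states` (Viterbi path, 1 = hypo), `sites` (the
#'   filtered `GRanges`), `chain` (chain id per site).
#' @export
fitMethHMM <- function(track, hypoMeanInit = 0.2, hyperMeanInit = 0.8,
                       concInit = 10, selfTransInit = 0.99,
                       emTol = 1e-4, maxIter = 100,
                       minCoverage = NULL, desertSize = 1000) {
    stopifnot(is(track, "CpGTrack"))
    if (is.null(minCoverage)) minCoverage <- track@minCoverage
    sp <- .splitChains(track, minCoverage, desertSize)
    st <- sp$sites
    if (length(st) < 50L)
        stop("need at least 50 CpGs above the coverage cut-off")
    m <- st$methylated; n <- st$coverage
    chains <- split(seq_along(m), sp$chain)

    a <- c(hypoMeanInit, hyperMeanInit) * concInit
    b <- (1 - c(hypoMeanInit, hyperMeanInit)) * concInit
    A <- matrix(c(selfTransInit, 1 - selfTransInit,
                  1 - selfTransInit, selfTransInit), 2L, 2L, byrow = TRUE)
    piv <- c(0.5, 0.5)
    llTrace <- numeric(0)
    converged <- FALSE
    gamma <- matrix(0, length(m), 2L)

    for (iter in seq_len(maxIter)) {
        le <- cbind(betaBinomLogPmf(m, n, a[1L], b[1L]),
                    betaBinomLogPmf(m, n, a[2L], b[2L]))
        ll <- 0
        xiSum <- matrix(0, 2L, 2L)
        pi1 <- c(0, 0)
        for (idx in chains) {
            e <- exp(le[idx, , drop = FALSE] -
                     apply(le[idx, , drop = FALSE], 1L, max))
            off <- apply(le[idx, , drop = FALSE], 1L, max)
            Tn <- length(idx)
            al <- matrix(0, Tn, 2L); cs <- numeric(Tn)
            al[1L, ] <- piv * e[1L, ]
            cs[1L] <- sum(al[1L, ]); al[1L, ] <- al[1L, ] / cs[1L]
            if (Tn > 1L) for (t in 2:Tn) {
                al[t, ] <- (al[t - 1L, ] %*% A) * e[t, ]
                cs[t] <- sum(al[t, ]); al[t, ] <- al[t, ] / cs[t]
            }
            be <- matrix(0, Tn, 2L)
            be[Tn, ] <- 1
            if (Tn > 1L) for (t in (Tn - 1L):1L) {
                be[t, ] <- A %*% (e[t + 1L, ] * be[t + 1L, ]) / cs[t + 1L]
            }
            g <- al * be
            g <- g / rowSums(g)
            gamma[idx, ] <- g
            if (Tn > 1L) for (t in 1:(Tn - 1L)) {
                xi <- (al[t, ] %o% (e[t + 1L, ] * be[t + 1L, ])) * A /
                      cs[t + 1L]
                xiSum <- xiSum + xi
            }
            pi1 <- pi1 + g[1L, ]
            ll <- ll + sum(log(cs)) + sum(off)
        }
        llTrace <- c(llTrace, ll)
        if (iter > 1L && abs(ll - llTrace[iter - 1L]) < emTol) {
            converged <- TRUE
            break
        }
        # M-step
        piv <- pi1 / length(chains)
        piv <- piv / sum(piv)
        if (sum(xiSum) > 0) {
            A <- xiSum / rowSums(xiSum)
            A[A < 1e-12] <- 1e-12
            A <- A / rowSums(A)
        }
        for (s in 1:2) {
            w <- gamma[, s]
            obj <- function(par) {
                # log-shape parametrization, clamped to keep lbeta finite
                par <- pmin(pmax(par, -10), 12)
                v <- -sum(w * betaBinomLogPmf(m, n, exp(par[1L]),
                                              exp(par[2L])))
                if (!is.finite(v)) 1e300 else v
            }
            opt <- stats::optim(log(c(a[s], b[s])), obj, method = "BFGS",
                                control = list(maxit = 50))
            par <- pmin(pmax(opt$par, -10), 12)
            a[s] <- exp(par[1L]); b[s] <- exp(par[2L])
        }
        if (a[1L] / (a[1L] + b[1L]) > a[2L] / (a[2L] + b[2L])) {
            a <- rev(a); b <- rev(b)
            A <- A[2:1, 2:1]; piv <- rev(piv)
        }
    }
    if (!converged)
        warning("EM did not converge in ", maxIter, " iterations; ",
                "returning best-so-far parameters")
    if (a[1L] / (a[1L] + b[1L]) > a[2L] / (a[2L] + b[2L])) {
        a <- rev(a); b <- rev(b)
        A <- A[2:1, 2:1]; piv <- rev(piv)
        gamma <- gamma[, 2:1, drop = FALSE]
    }
    # final posteriors + Viterbi under the returned parameters
    le <- cbind(betaBinomLogPmf(m, n, a[1L], b[1L]),
                betaBinomLogPmf(m, n, a[2L], b[2L]))
    # independent log-space backward recursion as a numerical cross-check
    lse <- function(x) { mx <- max(x); mx + log(sum(exp(x - mx))) }
    lA <- log(A)
    llBackward <- 0
    for (idx in chains) {
        Tn <- length(idx)
        lb <- c(0, 0)
        if (Tn > 1L) for (t in (Tn - 1L):1L) {
            lb <- c(lse(lA[1L, ] + le[idx[t + 1L], ] + lb),
                    lse(lA[2L, ] + le[idx[t + 1L], ] + lb))
        }
        llBackward <- llBackward + lse(log(piv) + le[idx[1L], ] + lb)
    }
    states <- integer(length(m))
    for (idx in chains) {
        Tn <- length(idx)
        d <- matrix(-Inf, Tn, 2L)
        ptr <- matrix(0L, Tn, 2L)
        d[1L, ] <- log(piv) + le[idx[1L], ]
        if (Tn > 1L) for (t in 2:Tn) {
            for (s in 1:2) {
                v <- d[t - 1L, ] + lA[, s]
                ptr[t, s] <- which.max(v)
                d[t, s] <- max(v) + le[idx[t], s]
            }
        }
        path <- integer(Tn)
        path[Tn] <- which.max(d[Tn, ])
        if (Tn > 1L) for (t in (Tn - 1L):1L)
            path[t] <- ptr[t + 1L, path[t + 1L]]
        states[idx] <- path
    }
    list(alpha = a, beta = b,
         stateMeans = a / (a + b), A = A, pi = piv,
         logLik = llTrace, logLikBackward = llBackward,
         converged = converged,
         posteriorHypo = gamma[, 1L], posteriorHyper = gamma[, 2L],
         states = states, sites = st, chain = sp$chain)
}

#' Call hypomethylated regions (HMRs)
#'
#' Fits the Beta-Binomial HMM ([fitMethHMM()]) and reports maximal runs of
#' Viterbi hypomethylated CpGs as regions spanning from the first member
#' CpG to one base past the last (covering the full CpG dinucleotide).
#' Runs with fewer than `minCpGs` CpGs are dropped. A track decoded
#' entirely into one state yields an empty set.
#'
#' @param track a [CpGTrack-class].
#' @param minCpGs minimum CpGs per region (default 3).
#' @param ... passed to [fitMethHMM()].
#' @return an [HMRSet-class]; the HMM fit is kept in the `fit` slot.
#' @export
callHMRs <- function(track, minCpGs = 3, ...) {
    fit <- fitMethHMM(track, ...)
    st <- fit$sites
    hypo <- fit$states == 1L
    r <- S4Vectors::Rle(paste0(fit$chain, "_", hypo))
    runIdx <- rep(seq_along(S4Vectors::runLength(r)),
                  S4Vectors::runLength(r))
    regions <- GRanges()
    pieces <- split(seq_along(hypo), runIdx)
    sel <- pieces[vapply(pieces, function(i) hypo[i[1L]], logical(1))]
    sel <- sel[vapply(sel, length, integer(1)) >= minCpGs]
    if (length(sel)) {
        firsts <- vapply(sel, function(i) start(st)[i[1L]], numeric(1))
        lasts <- vapply(sel, function(i) start(st)[i[length(i)]],
                        numeric(1))
        ctgs <- vapply(sel, function(i)
            as.character(seqnames(st))[i[1L]], character(1))
        regions <- GRanges(ctgs, IRanges(firsts, lasts + 1L),
                           seqinfo = seqinfo(st))
        regions$nCpGs <- vapply(sel, length, integer(1))
        regions$score <- vapply(sel, function(i)
            sum(fit$posteriorHypo[i]), numeric(1))
        regions$meanMethylation <- vapply(sel, function(i)
            sum(st$methylated[i]) / sum(st$coverage[i]), numeric(1))
        regions <- sort(regions, ignore.strand = TRUE)
    } else {
        regions$nCpGs <- integer(0)
        regions$score <- numeric(0)
        regions$meanMethylation <- numeric(0)
    }
    new("HMRSet", regions = regions,
        fit = fit[c("alpha", "beta", "stateMeans", "A", "pi", "logLik",
                    "converged")])
}

#' Validate TSS clusters against hypomethylated regions
#'
#' Crosses each cluster's annotated/novel label with whether its interval
#' overlaps (by at least 1 bp) any hypomethylated region, yielding the
#' four categories `annotated+HypoCpG`, `annotated w/o`, `novel+HypoCpG`,
#' `novel w/o`.
#'
#' @param clusters cluster `GRanges` or a [TagClusterSet-class].
#' @param novel logical vector: is each cluster novel?
#' @param hmrs an [HMRSet-class] (or `GRanges` of hypomethylated
#'   intervals).
#' @return list with `category` (factor per cluster) and `table`
#'   (data.frame category, n, percent).
#' @export
validateTSS <- function(clusters, novel, hmrs) {
    if (is(clusters, "SummarizedExperiment"))
        clusters <- rowRanges(clusters)
    rg <- if (is(hmrs, "HMRSet")) hmrRegions(hmrs) else hmrs
    stopifnot(length(novel) == length(clusters))
    hypo <- overlapsAny(clusters, rg, ignore.strand = TRUE)
    lv <- c("annotated+HypoCpG", "annotated w/o", "novel+HypoCpG",
            "novel w/o")
    cat <- ifelse(novel,
                  ifelse(hypo, "novel+HypoCpG", "novel w/o"),
                  ifelse(hypo, "annotated+HypoCpG", "annotated w/o"))
    cat <- factor(cat, levels = lv)
    tab <- as.data.frame(table(category = cat))
    names(tab)[2L] <- "n"
    tab$percent <- if (length(cat)) 100 * tab$n / length(cat) else 0
    list(category = cat, table = tab)
}

#' Write hypomethylated regions as BED
#'
#' @param hmrs an [HMRSet-class].
#' @param path output BED path.
#' @return the path, invisibly.
#' @export
writeHMRBed <- function(hmrs, path) {
    gr <- hmrRegions(hmrs)
    out <- granges(gr)
    out$name <- sprintf("HMR_%d", seq_along(gr))
    out$score <- pmin(1000L, as.integer(round(gr$score)))
    rtracklayer::export(out, path, format = "BED")
    invisible(path)
}

#' Write per-CpG posterior hypomethylation probability as bedGraph
#'
#' @param fit result of [fitMethHMM()] (or the `fit` slot contents plus
#'   sites; pass the full fit list).
#' @param path output bedGraph path.
#' @return the path, invisibly.
#' @export
writePosteriorBedGraph <- function(fit, path) {
    gr <- granges(fit$sites)
    gr$score <- fit$posteriorHypo
    rtracklayer::export(gr, path, format = "bedGraph")
    invisible(path)
}
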
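#' Bhattacharyya balance score for divergent transcription
#'
#' Measures how closely the 4-way tag tally around a candidate midpoint
#' (minus-strand upstream, plus-strand downstream, plus-strand upstream,
#' minus-strand downstream) matches the ideal divergent profile
#' (0.5, 0.5, 0, 0): `B = sqrt(0.5 p_um) + sqrt(0.5 p_dp)` where the `p`
#' are the normalized tallies. `B = 1` is perfectly bidirectional;
#' single-strand signal gives `sqrt(0.5) ~ 0.707`. The score is invariant
#' to uniform scaling of the four tallies.
#'
#' @param upstreamMinus,downstreamPlus,upstreamPlus,downstreamMinus
#'   non-negative tallies (vectorized).
#' @return numeric balance score(s) in \[0, 1\].
#' @examples
#' balanceScore(50, 50, 0, 0)   # 1
#' balanceScore(100, 0, 0, 0)   # sqrt(0.5)
#' @export
balanceScore <- function(upstreamMinus, downstreamPlus, upstreamPlus,
                         downstreamMinus) {
    tot <- upstreamMinus + downstreamPlus + upstreamPlus + downstreamMinus
    if (any(c(upstreamMinus, downstreamPlus, upstreamPlus,
              downstreamMinus) < 0))
        stop("tallies must be non-negative")
    if (any(tot == 0))
        stop("balance undefined for all-zero tallies")
    sqrt(0.5 * upstreamMinus / tot) + sqrt(0.5 * downstreamPlus / tot)
}

#' @noRd
.windowSums <- function(pos, val, lo, hi) {
    # sum of val at positions in [lo, hi] for each (lo, hi) pair
    if (length(pos) == 0L) return(numeric(length(lo)))
    cs <- c(0, cumsum(val))
    iHi <- findInterval(hi, pos)
    iLo <- findInterval(lo - 1L, pos)
    cs[iHi + 1L] - cs[iLo + 1L]
}

#' Call bi-directional (TSS-Enhancer) clusters
#'
#' Scans every position carrying signal on either strand as a candidate
#' midpoint, tallies the four arm sums over `[mid - w, mid)` and
#' `(mid, mid + w]`, computes the [balanceScore()], and keeps balance local
#' maxima with score at least `balanceThreshold` and signal on both
#' divergent arms. Surviving candidates are then restricted to those whose
#' midpoint lies within `promoterDistanceRange` bp (inclusive) of the
#' nearest promoter centre (transcript TSS); everything outside that range
#' is excluded.
#'
#' @param pooled width-1 stranded `GRanges` with `score` (both strands
#'   present; see [poolProfiles()]).
#' @param tss promoter centres: width-1 `GRanges` (e.g. [tssAnchors()]) or
#'   a [RegionIndex-class]/[TranscriptModels-class].
#' @param windowHalfwidth arm length `w` in bp (default 200).
#' @param balanceThreshold minimum balance score (default 0.95).
#' @param promoterDistanceRange inclusive \[min, max\] midpoint-to-promoter
#'   distance in bp (default `c(400, 1000)`).
#' @param nmsRadius minimum distance between two retained midpoints
#'   (default `2 * windowHalfwidth`).
#' @return unstranded `GRanges` of windows `[mid - w, mid + w]` with
#'   `cluster_id`, `midpoint`, `balance`, `minusArm`, `plusArm`,
#'   `promoterDistance` columns.
#' @export
callBidirectionalClusters <- function(pooled, tss, windowHalfwidth = 200,
                                      balanceThreshold = 0.95,
                                      promoterDistanceRange = c(400, 1000),
                                      nmsRadius = 2 * windowHalfwidth) {
    if (is(tss, "TranscriptModels")) tss <- tssAnchors(tss)
    if (is(tss, "RegionIndex")) {
        pr <- tss@promoters
        tss <- GRanges(seqnames(pr),
                       IRanges(start(pr) + tss@params$promoterHalfwidth,
                               width = 1L), strand = strand(pr))
    }
    if (!is(tss, "GRanges") || length(tss) == 0L)
        stop("no promoter centres supplied; the distance filter cannot run")
    stopifnot(is(pooled, "GRanges"))
    w <- windowHalfwidth
    res <- list()
    for (ctg in unique(as.character(seqnames(pooled)))) {
        sub <- pooled[seqnames(pooled) == ctg]
        pl <- sub[strand(sub) == "+"]
        mn <- sub[strand(sub) == "-"]
        if (length(pl) == 0L || length(mn) == 0L) next
        pPos <- start(pl); pVal <- pl$score
        mPos <- start(mn); mVal <- mn$score
        # every position within w of any signal is a candidate midpoint
        lo <- max(1L, min(pPos, mPos) - w)
        hi <- max(pPos, mPos) + w
        mids <- lo:hi
        um <- .windowSums(mPos, mVal, mids - w, mids - 1L)
        dp <- .windowSums(pPos, pVal, mids + 1L, mids + w)
        up <- .windowSums(pPos, pVal, mids - w, mids - 1L)
        dm <- .windowSums(mPos, mVal, mids + 1L, mids + w)
        tot <- um + dp + up + dm
        ok <- tot > 0 & um > 0 & dp > 0
        if (!any(ok)) next
        B <- rep(NA_real_, length(mids))
        B[ok] <- balanceScore(um[ok], dp[ok], up[ok], dm[ok])
        cand <- which(ok & B >= balanceThreshold)
        if (length(cand) == 0L) next
        # one cluster per balance local maximum: group candidates
        # separated by more than nmsRadius, then take the centre of each
        # group's maximum-balance plateau as the midpoint
        gap <- c(TRUE, diff(mids[cand]) > nmsRadius)
        grpId <- cumsum(gap)
        groups <- split(cand, grpId)
        midKeep <- vapply(groups, function(g) {
            # centre of the candidate run, refined to the midpoint of the
            # two arm signal centroids
            c0 <- as.integer(round(stats::median(mids[g])))
            mSel <- mPos >= c0 - w & mPos <= c0
            pSel <- pPos >= c0 & pPos <= c0 + w
            if (!any(mSel) || !any(pSel)) return(c0)
            muM <- sum(mPos[mSel] * mVal[mSel]) / sum(mVal[mSel])
            muP <- sum(pPos[pSel] * pVal[pSel]) / sum(pVal[pSel])
            m1 <- as.integer(round((muM + muP) / 2))
            max(min(m1, max(mids[g])), min(mids[g]))
        }, integer(1))
        midKeep <- unname(midKeep)
        keepIdx <- midKeep - lo + 1L
        tssHere <- start(tss)[as.character(seqnames(tss)) == ctg]
        dist <- if (length(tssHere))
            vapply(midKeep, function(m) min(abs(tssHere - m)), numeric(1))
        else rep(Inf, length(midKeep))
        inRange <- dist >= promoterDistanceRange[1L] &
                   dist <= promoterDistanceRange[2L]
        keepIdx <- keepIdx[inRange]; dist <- dist[inRange]
        midKeep <- midKeep[inRange]
        if (length(keepIdx) == 0L) next
        gr <- GRanges(ctg, IRanges(pmax(1L, midKeep - w), midKeep + w),
                      strand = "*", seqinfo = seqinfo(pooled))
        gr$cluster_id <- sprintf("BC_%s_%d", ctg, midKeep)
        gr$midpoint <- midKeep
        gr$balance <- B[keepIdx]
        gr$minusArm <- um[keepIdx]
        gr$plusArm <- dp[keepIdx]
        gr$promoterDistance <- dist
        res[[ctg]] <- gr
    }
    if (length(res) == 0L) {
        out <- GRanges()
        for (nm in c("cluster_id", "midpoint", "balance", "minusArm",
                     "plusArm", "promoterDistance"))
            mcols(out)[[nm]] <- if (nm == "cluster_id") character(0)
                                else numeric(0)
        return(out)
    }
    sort(unlist(GRangesList(res), use.names = FALSE), ignore.strand = TRUE)
}

#' Quantify bi-directional clusters per sample
#'
#' Sums each library's tag counts over the full (both-strand) cluster
#' window and assembles a [BidirClusterSet-class].
#'
#' @param bidir `GRanges` from [callBidirectionalClusters()].
#' @param profiles list of [TagProfile-class] objects.
#' @return a [BidirClusterSet-class] with `counts` and `ctpm` assays.
#' @export
quantifyBidirClusters <- function(bidir, profiles) {
    stopifnot(is(bidir, "GRanges"), length(profiles) >= 1L)
    n <- length(bidir)
    ids <- vapply(profiles, sampleID, character(1))
    counts <- matrix(0, nrow = n, ncol = length(profiles),
                     dimnames = list(bidir$cluster_id, ids))
    ctpm <- counts
    for (j in seq_along(profiles)) {
        p <- profiles[[j]]
        tg <- tagPositions(p)
        hits <- findOverlaps(tg, bidir, ignore.strand = TRUE)
        if (length(hits)) {
            s <- rowsum(as.numeric(tg$count[queryHits(hits)]),
                        subjectHits(hits))
            counts[as.integer(rownames(s)), j] <- s[, 1L]
        }
        if (p@totalMapped > 0)
            ctpm[, j] <- counts[, j] / p@totalMapped * 1e6
    }
    new("BidirClusterSet",
        SummarizedExperiment(assays = list(counts = counts, ctpm = ctpm),
                             rowRanges = bidir))
}

#' Co-expression links between bi- and uni-directional clusters
#'
#' For every bidirectional-unidirectional cluster pair on the same contig
#' within `maxLinkDistance` bp, computes Kendall's tau-b between the two
#' per-sample CTPM vectors ([stats::cor.test()], exact p for small
#' tie-free samples, normal approximation otherwise), adjusts p-values
#' with Benjamini-Hochberg across all tested pairs, and returns links with
#' `q <= alpha`. Pairs where either vector is constant are skipped with a
#' notice.
#'
#' @param bidir a [BidirClusterSet-class].
#' @param uni a [TagClusterSet-class] quantified over the same samples.
#' @param maxLinkDistance maximum midpoint-to-peak distance in bp
#'   (default 10000).
#' @param alpha BH-adjusted significance cut-off (default 0.05).
#' @return data.frame: `bidir_id`, `uni_id`, `tau`, `p`, `q`, `distance`.
#' @export
findLinks <- function(bidir, uni, maxLinkDistance = 10000, alpha = 0.05) {
    stopifnot(is(bidir, "BidirClusterSet"), is(uni, "TagClusterSet"))
    if (!identical(colnames(bidir), colnames(uni)))
        stop("bidir and uni sets must be quantified over the same samples")
    if (ncol(uni) < 8L)
        stop("need at least 8 samples for co-expression testing")
    hits <- findOverlaps(rowRanges(bidir), rowRanges(uni),
                         maxgap = maxLinkDistance, ignore.strand = TRUE)
    empty <- data.frame(bidir_id = character(0), uni_id = character(0),
                        tau = numeric(0), p = numeric(0), q = numeric(0),
                        distance = numeric(0))
    if (length(hits) == 0L) return(empty)
    bC <- assay(bidir, "ctpm"); uC <- assay(uni, "ctpm")
    bMid <- rowRanges(bidir)$midpoint
    uPeak <- rowRanges(uni)$peak
    nSkipped <- 0L
    rows <- vector("list", length(hits))
    for (k in seq_along(hits)) {
        i <- queryHits(hits)[k]; j <- subjectHits(hits)[k]
        x <- bC[i, ]; y <- uC[j, ]
        if (stats::sd(x) == 0 || stats::sd(y) == 0) {
            nSkipped <- nSkipped + 1L
            next
        }
        ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
        rows[[k]] <- data.frame(
            bidir_id = rownames(bC)[i], uni_id = rownames(uC)[j],
            tau = unname(ct$estimate), p = ct$p.value,
            distance = abs(bMid[i] - uPeak[j]))
    }
    if (nSkipped > 0L)
        message(nSkipped, " pair(s) skipped: constant expression vector")
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) == 0L) return(empty)
    df <- do.call(rbind, rows)
    df$q <- stats::p.adjust(df$p, method = "BH")
    df <- df[df$q <= alpha, c("bidir_id", "uni_id", "tau", "p", "q",
                              "distance")]
    rownames(df) <- NULL
    df
}

#' Write bi-directional clusters as BED (score = 1000 * balance)
#'
#' @param bidir a [BidirClusterSet-class] or its `GRanges`.
#' @param path output BED path.
#' @return the path, invisibly.
#' @export
writeEnhancerBED <- function(bidir, path) {
    gr <- if (is(bidir, "SummarizedExperiment")) rowRanges(bidir) else bidir
    out <- granges(gr)
    out$name <- gr$cluster_id
    out$score <- as.integer(round(1000 * gr$balance))
    rtracklayer::export(out, path, format = "BED")
    invisible(path)
}

#' Write co-expression links as BEDPE-like TSV
#'
#' @param links data.frame from [findLinks()].
#' @param bidir,uni the cluster sets the links refer to.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeLinksTSV <- function(links, bidir, uni, path) {
    bRR <- rowRanges(bidir); uRR <- rowRanges(uni)
    bi <- match(links$bidir_id, bRR$cluster_id)
    ui <- match(links$uni_id, uRR$cluster_id)
    out <- data.frame(
        chrom1 = as.character(seqnames(bRR))[bi],
        start1 = start(bRR)[bi] - 1L, end1 = end(bRR)[bi],
        chrom2 = as.character(seqnames(uRR))[ui],
        start2 = start(uRR)[ui] - 1L, end2 = end(uRR)[ui],
        bidir_id = links$bidir_id, uni_id = links$uni_id,
        tau = links$tau, p = links$p, q = links$q,
        distance = links$distance)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
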
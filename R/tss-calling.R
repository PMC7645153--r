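#' Tissue-representation threshold
#'
#' Number of tissues a cluster must be present in to count as reproducible:
#' a fixed fraction of the panel size, rounded down by default. With 56
#' tissues and a two-thirds fraction this gives 37.
#'
#' @param nTissues panel size (>= 1).
#' @param fraction required fraction in (0, 1].
#' @param rounding `"floor"` (default) or `"ceil"`.
#' @return integer threshold.
#' @examples
#' representationThreshold(56, 2/3)  # 37
#' @export
representationThreshold <- function(nTissues, fraction = 2/3,
                                    rounding = c("floor", "ceil")) {
    rounding <- match.arg(rounding)
    stopifnot(nTissues >= 1, fraction > 0, fraction <= 1)
    f <- if (rounding == "floor") floor else ceiling
    max(1L, as.integer(f(nTissues * fraction)))
}

#' Clustering and filtering parameters for uni-directional TSS calling
#'
#' @param mergeDist maximum gap (bp) between consecutive signal positions
#'   merged into one cluster (default 20).
#' @param minClusterCount minimum pooled raw tag count a cluster needs
#'   (default 10).
#' @param representationFraction fraction of tissues a cluster must be
#'   present in (default 2/3).
#' @param presenceRule how presence in a tissue is decided:
#'   `"count_ge_10"` (raw count >= `presenceMin`, default) or
#'   `"ctpm_gt_10"` (CTPM strictly > `presenceMin`).
#' @param presenceMin presence cut-off (default 10).
#' @param poolMode pooled-signal scale used for clustering: `"ctpm"`
#'   (default) or `"raw"`.
#' @return validated parameter list of class `ClusteringParams`.
#' @export
clusteringParams <- function(mergeDist = 20, minClusterCount = 10,
                             representationFraction = 2/3,
                             presenceRule = c("count_ge_10", "ctpm_gt_10"),
                             presenceMin = 10,
                             poolMode = c("ctpm", "raw")) {
    presenceRule <- match.arg(presenceRule)
    poolMode <- match.arg(poolMode)
    stopifnot(mergeDist >= 0, minClusterCount >= 0, presenceMin >= 0,
              representationFraction > 0, representationFraction <= 1)
    structure(list(mergeDist = mergeDist,
                   minClusterCount = minClusterCount,
                   representationFraction = representationFraction,
                   presenceRule = presenceRule, presenceMin = presenceMin,
                   poolMode = poolMode),
              class = "ClusteringParams")
}

#' Call uni-directional TSS clusters from pooled signal
#'
#' Per contig and strand, maximal runs of signal positions in which
#' consecutive positions are at most `mergeDist` bp apart are merged into
#' one cluster (two positions exactly `mergeDist` apart share a cluster;
#' `mergeDist + 1` apart they do not). The cluster peak is the position of
#' maximum pooled signal, ties resolved to the 5'-most position on the
#' cluster strand.
#'
#' @param pooled width-1 stranded `GRanges` with a `score` column (see
#'   [poolProfiles()]).
#' @param mergeDist merge distance in bp (default 20).
#' @return `GRanges` of clusters with `cluster_id`, `peak` and
#'   `pooledSignal` columns, sorted, non-overlapping per contig+strand.
#' @export
callUnidirectionalClusters <- function(pooled, mergeDist = 20) {
    stopifnot(is(pooled, "GRanges"))
    if (length(pooled) == 0L) {
        out <- GRanges()
        out$cluster_id <- character(0)
        out$peak <- integer(0)
        out$pooledSignal <- numeric(0)
        return(out)
    }
    if (any(width(pooled) != 1L))
        stop("pooled signal must be per-bp (width-1) positions")
    o <- order(as.factor(seqnames(pooled)), as.factor(strand(pooled)),
               start(pooled))
    sq <- as.character(seqnames(pooled))[o]
    st <- as.character(strand(pooled))[o]
    pos <- start(pooled)[o]
    val <- pooled$score[o]
    newGrp <- c(TRUE, sq[-1L] != sq[-length(sq)] |
                      st[-1L] != st[-length(st)] |
                      (pos[-1L] - pos[-length(pos)]) > mergeDist)
    grp <- cumsum(newGrp)
    startV <- tapply(pos, grp, min)
    endV <- tapply(pos, grp, max)
    sumV <- tapply(val, grp, sum)
    sqV <- sq[newGrp]
    stV <- st[newGrp]
    # peak: max signal, tie -> 5'-most on the cluster strand
    peakV <- vapply(split(seq_along(grp), grp), function(i) {
        v <- val[i]; p <- pos[i]
        cand <- p[v == max(v)]
        if (st[i[1L]] == "-") max(cand) else min(cand)
    }, numeric(1))
    gr <- GRanges(sqV, IRanges(as.integer(startV), as.integer(endV)),
                  strand = stV, seqinfo = seqinfo(pooled))
    gr$cluster_id <- sprintf("TC_%s_%s_%d", sqV,
                             ifelse(stV == "+", "p", "m"),
                             as.integer(startV))
    gr$peak <- as.integer(peakV)
    gr$pooledSignal <- as.numeric(sumV)
    sort(gr, ignore.strand = TRUE)
}

#' Quantify clusters per sample
#'
#' Sums each library's raw tag counts (and CTPM) over every cluster
#' interval, strand-matched, and assembles a [TagClusterSet-class].
#'
#' @param clusters cluster `GRanges` from [callUnidirectionalClusters()].
#' @param profiles list of [TagProfile-class] objects (the tissue panel).
#' @param params a [clusteringParams()] list stored with the result.
#' @return a [TagClusterSet-class] with `counts` and `ctpm` assays.
#' @export
quantifyClusters <- function(clusters, profiles,
                             params = clusteringParams()) {
    stopifnot(is(clusters, "GRanges"), length(profiles) >= 1L)
    n <- length(clusters)
    ids <- vapply(profiles, sampleID, character(1))
    counts <- matrix(0, nrow = n, ncol = length(profiles),
                     dimnames = list(clusters$cluster_id, ids))
    ctpm <- counts
    for (j in seq_along(profiles)) {
        p <- profiles[[j]]
        tg <- tagPositions(p)
        hits <- findOverlaps(tg, clusters, ignore.strand = FALSE)
        if (length(hits)) {
            s <- rowsum(as.numeric(tg$count[queryHits(hits)]),
                        subjectHits(hits))
            counts[as.integer(rownames(s)), j] <- s[, 1L]
        }
        if (p@totalMapped > 0)
            ctpm[, j] <- counts[, j] / p@totalMapped * 1e6
    }
    se <- SummarizedExperiment(
        assays = list(counts = counts, ctpm = ctpm),
        rowRanges = clusters,
        metadata = list(params = params,
                        attrition = list(called = n)))
    new("TagClusterSet", se)
}

#' Presence matrix of a cluster set
#'
#' @param tcs a [TagClusterSet-class].
#' @param presenceRule,presenceMin see [clusteringParams()]; defaults come
#'   from the parameters stored in the object.
#' @return logical matrix clusters x samples.
#' @export
presenceMatrix <- function(tcs, presenceRule = NULL, presenceMin = NULL) {
    p <- S4Vectors::metadata(tcs)$params
    if (is.null(presenceRule))
        presenceRule <- if (!is.null(p)) p$presenceRule else "count_ge_10"
    if (is.null(presenceMin))
        presenceMin <- if (!is.null(p)) p$presenceMin else 10
    if (presenceRule == "count_ge_10")
        assay(tcs, "counts") >= presenceMin
    else
        assay(tcs, "ctpm") > presenceMin
}

#' Apply the count and tissue-representation filters
#'
#' Two-stage filter: (1) clusters whose pooled raw count (sum over all
#' samples) is below `minClusterCount` are removed; (2) of the remainder,
#' only clusters present (per the presence rule) in at least
#' `minTissues` tissues are kept. Attrition counts are recorded in
#' `metadata()$attrition`.
#'
#' @param tcs a [TagClusterSet-class].
#' @param minClusterCount stage-1 pooled count cut-off (default from the
#'   stored parameters).
#' @param minTissues representation threshold; default
#'   `representationThreshold(ncol(tcs), fraction)` with the stored
#'   fraction.
#' @return the filtered [TagClusterSet-class].
#' @export
filterClusters <- function(tcs, minClusterCount = NULL, minTissues = NULL) {
    stopifnot(is(tcs, "TagClusterSet"))
    p <- S4Vectors::metadata(tcs)$params
    if (is.null(minClusterCount))
        minClusterCount <- if (!is.null(p)) p$minClusterCount else 10
    if (is.null(minTissues))
        minTissues <- representationThreshold(
            ncol(tcs),
            if (!is.null(p)) p$representationFraction else 2/3)
    if (minTissues > ncol(tcs))
        stop("representation threshold (", minTissues,
             ") exceeds the number of samples (", ncol(tcs), ")")
    pre <- nrow(tcs)
    pooled <- rowSums(assay(tcs, "counts"))
    tcs1 <- tcs[pooled >= minClusterCount, ]
    pres <- presenceMatrix(tcs1)
    keep <- rowSums(pres) >= minTissues
    out <- tcs1[keep, ]
    md <- S4Vectors::metadata(out)
    md$attrition <- list(called = pre, afterCountFilter = nrow(tcs1),
                         afterRepresentationFilter = nrow(out))
    md$minTissues <- minTissues
    S4Vectors::metadata(out) <- md
    out
}

#' Tissue-specific clusters
#'
#' Clusters expressed (count strictly greater than `minCount`) in exactly
#' one tissue, grouped by that tissue. Run this on the unfiltered set: the
#' representation filter removes tissue-restricted clusters by design.
#'
#' @param tcs a [TagClusterSet-class] (unfiltered).
#' @param minCount expression cut-off (default 10, exclusive).
#' @return named list (one element per tissue with at least one specific
#'   cluster) of [TagClusterSet-class] subsets.
#' @export
tissueSpecificClusters <- function(tcs, minCount = 10) {
    stopifnot(is(tcs, "TagClusterSet"))
    expressed <- assay(tcs, "counts") > minCount
    nExpr <- rowSums(expressed)
    sel <- which(nExpr == 1L)
    if (length(sel) == 0L) return(list())
    tissue <- colnames(tcs)[apply(expressed[sel, , drop = FALSE], 1L,
                                  which)]
    lapply(split(sel, tissue), function(i) tcs[i, ])
}

#' Clusters per gene via promoter-window assignment
#'
#' Counts, for every gene, the clusters whose interval overlaps one of the
#' gene's promoter windows, and summarizes the distribution over genes
#' that captured at least one cluster. Genes with none are reported as not
#' captured.
#'
#' @param tcs a [TagClusterSet-class] (typically filtered).
#' @param index a [RegionIndex-class].
#' @return list with `perGene` (data.frame gene_id, nClusters),
#'   `meanPerGene`, `medianPerGene`, `nGenesCaptured`, `nGenesNotCaptured`.
#' @export
clustersPerGene <- function(tcs, index) {
    stopifnot(is(tcs, "TagClusterSet"), is(index, "RegionIndex"))
    rr <- rowRanges(tcs)
    hits <- findOverlaps(rr, index@promoters, ignore.strand = TRUE)
    df <- unique(data.frame(cluster = queryHits(hits),
                            gene = index@promoters$gene_id[subjectHits(hits)]))
    allGenes <- unique(index@promoters$gene_id)
    cnt <- table(factor(df$gene, levels = allGenes))
    perGene <- data.frame(gene_id = names(cnt),
                          nClusters = as.integer(cnt))
    captured <- perGene$nClusters[perGene$nClusters > 0L]
    list(perGene = perGene,
         meanPerGene = if (length(captured)) mean(captured) else NA_real_,
         medianPerGene = if (length(captured))
             stats::median(captured) else NA_real_,
         nGenesCaptured = length(captured),
         nGenesNotCaptured = length(allGenes) - length(captured))
}

#' Write clusters as BED (thickStart marks the peak)
#'
#' @param tcs a [TagClusterSet-class] or cluster `GRanges`.
#' @param path output BED path.
#' @return the path, invisibly.
#' @export
writeClusterBED <- function(tcs, path) {
    gr <- if (is(tcs, "SummarizedExperiment")) rowRanges(tcs) else tcs
    out <- granges(gr)
    out$name <- gr$cluster_id
    out$score <- pmin(1000L, as.integer(round(gr$pooledSignal)))
    out$thick <- IRanges(gr$peak, width = 1L)
    rtracklayer::export(out, path, format = "BED")
    invisible(path)
}

#' Write the cluster x tissue count matrix as TSV
#'
#' @param tcs a [TagClusterSet-class].
#' @param path output TSV path.
#' @param assayName `"counts"` (default) or `"ctpm"`.
#' @return the path, invisibly.
#' @export
writeCountMatrix <- function(tcs, path, assayName = "counts") {
    m <- assay(tcs, assayName)
    utils::write.table(data.frame(cluster_id = rownames(m), m,
                                  check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
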
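#' Classify clusters as annotated or novel relative to known promoters
#'
#' A cluster is "annotated" at range `w` when its interval comes within
#' `w` bp (inclusive: a gap of exactly `w` still counts) of a promoter
#' anchor, i.e. it overlaps `[tss - w, tss + w]`. Both the short-range
#' (default 50 bp) and long-range (default 400 bp) rules are evaluated;
#' short-range annotated implies long-range annotated. Matching is
#' strand-agnostic by default. Clusters annotated at neither range are
#' "novel".
#'
#' @param clusters cluster `GRanges` or a [TagClusterSet-class].
#' @param models a [TranscriptModels-class] (or width-1 anchor `GRanges`
#'   with `tx_id`/`gene_id`).
#' @param shortWindow,longWindow window half-widths in bp (defaults
#'   50 / 400).
#' @param strandAware require the cluster strand to match the transcript
#'   strand (default `FALSE`).
#' @param usePeak classify by the cluster peak position instead of the
#'   full interval (default `FALSE`).
#' @return data.frame: `cluster_id`, `shortRangeAnnotated`,
#'   `longRangeAnnotated`, `novel` (complement of the short-range rule),
#'   `matchedTx`, `matchedGenes` (comma-separated, long-range matches),
#'   `distanceToNearestPromoter` (signed bp; negative = cluster lies 5' of
#'   the anchor on the anchor strand; 0 = anchor inside the interval).
#' @export
callNovelty <- function(clusters, models, shortWindow = 50,
                        longWindow = 400, strandAware = FALSE,
                        usePeak = FALSE) {
    if (is(clusters, "SummarizedExperiment"))
        clusters <- rowRanges(clusters)
    anchors <- if (is(models, "TranscriptModels")) tssAnchors(models)
               else models
    stopifnot(is(anchors, "GRanges"))
    if (any(width(anchors) != 1L))
        stop("promoter anchors must be width-1 TSS positions")
    if (usePeak && !is.null(clusters$peak))
        clusters <- GRanges(seqnames(clusters),
                            IRanges(clusters$peak, width = 1L),
                            strand = strand(clusters),
                            cluster_id = clusters$cluster_id)
    ig <- !strandAware
    annotAt <- function(w) {
        win <- suppressWarnings(
            GRanges(seqnames(anchors),
                    IRanges(pmax(1L, start(anchors) - w),
                            start(anchors) + w),
                    strand = strand(anchors)))
        overlapsAny(clusters, win, ignore.strand = ig)
    }
    shortA <- annotAt(shortWindow)
    longA <- annotAt(longWindow)
    winL <- GRanges(seqnames(anchors),
                    IRanges(pmax(1L, start(anchors) - longWindow),
                            start(anchors) + longWindow),
                    strand = strand(anchors))
    hits <- findOverlaps(clusters, winL, ignore.strand = ig)
    grp <- split(subjectHits(hits),
                 factor(queryHits(hits), levels = seq_along(clusters)))
    matchedTx <- vapply(grp, function(i)
        paste(unique(anchors$tx_id[i]), collapse = ","), character(1))
    matchedGenes <- vapply(grp, function(i)
        paste(unique(anchors$gene_id[i]), collapse = ","), character(1))
    # signed distance to nearest anchor: 0 if inside the interval,
    # negative when the cluster lies 5' of the anchor on its strand
    nn <- nearest(clusters, anchors, ignore.strand = ig)
    dist <- rep(NA_real_, length(clusters))
    ok <- !is.na(nn)
    if (any(ok)) {
        ap <- start(anchors)[nn[ok]]
        astr <- as.character(strand(anchors))[nn[ok]]
        s <- start(clusters)[ok]; e <- end(clusters)[ok]
        raw <- ifelse(ap < s, ap - s, ifelse(ap > e, ap - e, 0))
        # raw > 0: cluster upstream of anchor in genome coords
        dist[ok] <- ifelse(astr == "-", raw, -raw)
    }
    ids <- clusters$cluster_id
    if (is.null(ids)) ids <- sprintf("cluster_%d", seq_along(clusters))
    data.frame(cluster_id = ids,
               shortRangeAnnotated = shortA,
               longRangeAnnotated = longA,
               novel = !shortA,
               matchedTx = matchedTx,
               matchedGenes = matchedGenes,
               distanceToNearestPromoter = dist,
               row.names = NULL)
}

#' Per-tissue novelty summary table
#'
#' One row per tissue with the total cluster count, the counts annotated
#' within the short and long windows, and the percentage novel (clusters
#' not short-range annotated), plus an overall averages row.
#'
#' @param callsPerTissue named list of data.frames from [callNovelty()],
#'   one per tissue.
#' @return data.frame: tissue, pctNovel, nWithin50, nWithin400, total;
#'   last row holds the column means/sums labelled "overall".
#' @export
noveltyReport <- function(callsPerTissue) {
    stopifnot(length(callsPerTissue) >= 1L)
    rows <- lapply(names(callsPerTissue), function(ts) {
        cl <- callsPerTissue[[ts]]
        tot <- nrow(cl)
        data.frame(tissue = ts,
                   pctNovel = if (tot) 100 * sum(!cl$shortRangeAnnotated) /
                                  tot else NA_real_,
                   nWithin50 = sum(cl$shortRangeAnnotated),
                   nWithin400 = sum(cl$longRangeAnnotated),
                   total = tot)
    })
    out <- do.call(rbind, rows)
    overall <- data.frame(tissue = "overall",
                          pctNovel = mean(out$pctNovel, na.rm = TRUE),
                          nWithin50 = sum(out$nWithin50),
                          nWithin400 = sum(out$nWithin400),
                          total = sum(out$total))
    rbind(out, overall)
}
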
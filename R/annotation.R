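#' Load transcript models from a GFF3 annotation
#'
#' Parses gene/transcript/exon/CDS features with the rtracklayer GFF3
#' reader and
#' assembles one transcript model per `mRNA`/`transcript` feature. The TSS
#' of a transcript is the 5'-most transcribed base on its strand (the exon
#' union start on `+`, end on `-`). When CDS features are present, 5' and 3'
#' UTRs are derived as the exonic sequence up-/downstream of the CDS span;
#' without CDS the UTR lists are left empty and the TSS is still defined
#' from the transcript 5' end.
#'
#' @param path path to a GFF3 file. GTF-style attribute dialects are
#'   accepted as long as `type`, `ID` and `Parent` resolve.
#' @param contigs optional [GenomeInfoDb::Seqinfo]; when supplied, a
#'   transcript on an unknown contig is an error and the returned ranges
#'   carry the seqinfo.
#' @param txTypes feature types treated as transcripts.
#' @return a [TranscriptModels-class] object.
#' @examples
#' gff <- tempfile(fileext = ".gff3")
#' writeLines(c("##gff-version 3",
#'   "chr1\t.\tgene\t1001\t1800\t.\t+\t.\tID=g1",
#'   "chr1\t.\tmRNA\t1001\t1800\t.\t+\t.\tID=t1;Parent=g1",
#'   "chr1\t.\texon\t1001\t1200\t.\t+\t.\tParent=t1",
#'   "chr1\t.\texon\t1501\t1800\t.\t+\t.\tParent=t1"), gff)
#' loadAnnotation(gff)
#' @export
loadAnnotation <- function(path, contigs = NULL,
                           txTypes = c("mRNA", "transcript")) {
    gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                   error = function(e)
                       stop("malformed GFF3 '", path, "': ",
                            conditionMessage(e), call. = FALSE))
    type <- as.character(gr$type)
    tx <- gr[type %in% txTypes]
    if (length(tx) == 0L)
        stop("no transcript features (", paste(txTypes, collapse = "/"),
             ") found in ", path)
    txID <- as.character(tx$ID)
    if (anyNA(txID) || any(txID == ""))
        stop("transcript features must carry an ID attribute")
    parent1 <- function(x) {
        p <- as(x$Parent, "CharacterList")
        vapply(p, function(v) if (length(v)) v[[1L]] else NA_character_,
               character(1))
    }
    geneID <- parent1(tx)
    geneID[is.na(geneID)] <- txID[is.na(geneID)]

    if (!is.null(contigs)) {
        bad <- setdiff(unique(as.character(seqnames(tx))),
                       seqlevels(contigs))
        if (length(bad))
            stop("transcript(s) reference unknown contig(s): ",
                 paste(bad, collapse = ", "))
    }

    .byTx <- function(feat) {
        f <- gr[type == feat]
        if (length(f) == 0L)
            return(setNames(GRangesList(), character(0)))
        split(granges(f), parent1(f))
    }
    exonsByTx <- .byTx("exon")
    cdsByTx <- .byTx("CDS")
    missingEx <- setdiff(txID, names(exonsByTx))
    if (length(missingEx)) {
        # transcripts without exon children span their own range
        own <- setNames(as(granges(tx[match(missingEx, txID)]),
                           "GRangesList"), missingEx)
        exonsByTx <- c(exonsByTx, own)
    }
    exonsByTx <- exonsByTx[txID]
    exonsByTx <- sort(exonsByTx)
    red <- reduce(exonsByTx)
    if (any(lengths(red) != lengths(exonsByTx)))
        stop("overlapping exons within a transcript: ",
             paste(txID[lengths(red) != lengths(exonsByTx)], collapse = ", "))

    rng <- unlist(range(exonsByTx), use.names = FALSE)
    strand(rng) <- strand(tx)[match(names(exonsByTx), txID)]
    txStrand <- as.character(strand(rng))
    if (any(txStrand == "*"))
        stop("transcripts must be stranded (+/-)")
    tss <- ifelse(txStrand == "+", start(rng), end(rng))

    utr5 <- utr3 <- vector("list", length(txID))
    names(utr5) <- names(utr3) <- txID
    cdsOut <- vector("list", length(txID))
    names(cdsOut) <- txID
    for (i in seq_along(txID)) {
        id <- txID[i]
        ex <- exonsByTx[[id]]
        if (!is.null(cdsByTx[[id]]) && id %in% names(cdsByTx)) {
            cd <- sort(granges(cdsByTx[[id]]))
            cdsOut[[i]] <- cd
            cs <- min(start(cd)); ce <- max(end(cd))
            ts <- min(start(ex)); te <- max(end(ex))
            left <- if (cs > ts)
                intersect(ex, GRanges(seqnames(ex)[1L],
                                      IRanges(ts, cs - 1L)),
                          ignore.strand = TRUE) else GRanges()
            right <- if (ce < te)
                intersect(ex, GRanges(seqnames(ex)[1L],
                                      IRanges(ce + 1L, te)),
                          ignore.strand = TRUE) else GRanges()
            if (txStrand[i] == "+") {
                utr5[[i]] <- left; utr3[[i]] <- right
            } else {
                utr5[[i]] <- right; utr3[[i]] <- left
            }
        } else {
            cdsOut[[i]] <- GRanges()
            utr5[[i]] <- GRanges(); utr3[[i]] <- GRanges()
        }
    }

    transcripts <- rng
    mcols(transcripts) <- DataFrame(tx_id = txID, gene_id = geneID,
                                    tss = as.integer(tss))
    if (!is.null(contigs)) {
        seqlevels(transcripts) <- seqlevels(contigs)
        seqinfo(transcripts) <- contigs
    }
    new("TranscriptModels",
        transcripts = transcripts,
        exons = exonsByTx,
        cds = as(cdsOut, "CompressedGRangesList"),
        utr5 = as(utr5, "CompressedGRangesList"),
        utr3 = as(utr3, "CompressedGRangesList"))
}

#' Region classes in precedence order
#' @keywords internal
.REGION_CLASSES <- c("promoter", "proximal", "fiveUTR", "threeUTR",
                     "exon", "intron", "intergenic")

#' Build a genomic-region classifier from transcript models
#'
#' Derives, per transcript, the promoter window (TSS +/-
#' `promoterHalfwidth`), the proximal region (up to `proximalLength` bp
#' upstream of the TSS, excluding the promoter window), UTRs, exons and
#' introns, and packs them into a [RegionIndex-class]. A genomic position is
#' classified by the first class that covers it, in the fixed precedence
#' promoter > proximal > fiveUTR > threeUTR > exon > intron; anything left
#' is intergenic. Promoter and proximal matching is strand-aware (an
#' unstranded query matches either strand); the remaining gene-body classes
#' are matched regardless of strand.
#'
#' @param models a [TranscriptModels-class] object.
#' @param contigs optional `Seqinfo` used to clip windows at contig ends.
#' @param promoterHalfwidth half-width of the promoter window in bp
#'   (default 100, i.e. a 201-bp window centred on the TSS).
#' @param proximalLength upstream reach of the proximal class in bp from
#'   the TSS (default 1000).
#' @param intergenicMargin bp beyond which a position up-/downstream of a
#'   gene is called intergenic (default 1000; upstream this coincides with
#'   `proximalLength`, and no separate downstream class is defined, so the
#'   complement of all other classes is intergenic).
#' @return a [RegionIndex-class].
#' @export
buildRegionIndex <- function(models, contigs = NULL,
                             promoterHalfwidth = 100,
                             proximalLength = 1000,
                             intergenicMargin = 1000) {
    stopifnot(is(models, "TranscriptModels"))
    if (proximalLength <= promoterHalfwidth)
        stop("'proximalLength' must exceed 'promoterHalfwidth'")
    tx <- models@transcripts
    if (length(tx) == 0L) stop("no transcript models supplied")
    if (is.null(contigs)) {
        sl <- seqlengths(seqinfo(tx))
        contigs <- if (!anyNA(sl)) seqinfo(tx) else
            Seqinfo(seqnames = seqlevels(tx),
                    seqlengths = rep(536870912L, length(seqlevels(tx))))
    }
    ids <- DataFrame(tx_id = tx$tx_id, gene_id = tx$gene_id)
    str <- as.character(strand(tx))
    tssPos <- tx$tss

    clip <- function(gr) {
        seqlevels(gr) <- seqlevels(contigs)
        # windows reaching past a contig end are clipped on purpose
        suppressWarnings({
            seqinfo(gr) <- contigs
            gr <- trim(gr)
        })
        gr
    }
    promoters <- GRanges(seqnames(tx),
                         IRanges(pmax(1L, tssPos - promoterHalfwidth),
                                 tssPos + promoterHalfwidth),
                         strand = strand(tx))
    mcols(promoters) <- ids
    proxStart <- ifelse(str == "+", tssPos - proximalLength,
                        tssPos + promoterHalfwidth + 1L)
    proxEnd <- ifelse(str == "+", tssPos - promoterHalfwidth - 1L,
                      tssPos + proximalLength)
    proximal <- GRanges(seqnames(tx),
                        IRanges(pmax(1L, proxStart), pmax(0L, proxEnd)),
                        strand = strand(tx))
    keep <- width(proximal) > 0L
    proximal <- proximal[keep]
    mcols(proximal) <- ids[keep, , drop = FALSE]

    unlistTrack <- function(grl) {
        u <- unlist(grl, use.names = TRUE)
        if (length(u) == 0L) {
            mcols(u) <- DataFrame(tx_id = character(0),
                                  gene_id = character(0))
            return(u)
        }
        idx <- match(names(u), tx$tx_id)
        mcols(u) <- DataFrame(tx_id = tx$tx_id[idx],
                              gene_id = tx$gene_id[idx])
        names(u) <- NULL
        u
    }
    exonTrack <- unlistTrack(models@exons)
    utr5Track <- unlistTrack(models@utr5)
    utr3Track <- unlistTrack(models@utr3)
    intronsByTx <- psetdiff(unlist(range(models@exons)), models@exons)
    intronTrack <- unlistTrack(intronsByTx)

    new("RegionIndex",
        promoters = clip(promoters), proximal = clip(proximal),
        utr5 = clip(utr5Track), utr3 = clip(utr3Track),
        exons = clip(exonTrack), introns = clip(intronTrack),
        params = list(promoterHalfwidth = promoterHalfwidth,
                      proximalLength = proximalLength,
                      intergenicMargin = intergenicMargin),
        seqinfo = contigs)
}

#' Classify genomic positions into region classes
#'
#' Applies the precedence rule of a [RegionIndex-class] to width-1 query
#' positions. Promoter and proximal tracks are matched on the query strand
#' when `strandAware = TRUE` (a `*` query matches both strands); UTR, exon
#' and intron classes are always matched regardless of strand.
#'
#' @param index a [RegionIndex-class].
#' @param positions width-1 `GRanges` of query positions (strand optional).
#' @param strandAware match promoter/proximal on the query strand
#'   (default `TRUE`).
#' @return factor of region classes, levels in precedence order.
#' @export
classifyPositions <- function(index, positions, strandAware = TRUE) {
    stopifnot(is(index, "RegionIndex"), is(positions, "GRanges"))
    cls <- rep("intergenic", length(positions))
    assigned <- logical(length(positions))
    tracks <- list(promoter = index@promoters, proximal = index@proximal,
                   fiveUTR = index@utr5, threeUTR = index@utr3,
                   exon = index@exons, intron = index@introns)
    strandedCls <- c("promoter", "proximal")
    for (nm in names(tracks)) {
        if (all(assigned)) break
        ig <- if (nm %in% strandedCls) !strandAware else TRUE
        hit <- overlapsAny(positions, tracks[[nm]], ignore.strand = ig)
        take <- hit & !assigned
        cls[take] <- nm
        assigned <- assigned | hit
    }
    factor(cls, levels = .REGION_CLASSES)
}

#' Classify clusters by their peak position
#'
#' A cluster is assigned the region class of its peak (the position of
#' maximum pooled signal; for bi-directional clusters, the midpoint). All
#' transcripts whose promoter window overlaps the full cluster interval are
#' reported as associated genes/transcripts.
#'
#' @param index a [RegionIndex-class].
#' @param clusters `GRanges` with a `peak` (or `midpoint`) metadata column,
#'   or a [TagClusterSet-class]/[BidirClusterSet-class].
#' @param strandAware passed to [classifyPositions()].
#' @return a [S4Vectors::DataFrame] with `class`, `geneIDs` and `txIDs`
#'   (CharacterList) columns, one row per cluster.
#' @export
classifyClusters <- function(index, clusters, strandAware = TRUE) {
    if (is(clusters, "SummarizedExperiment"))
        clusters <- rowRanges(clusters)
    stopifnot(is(index, "RegionIndex"), is(clusters, "GRanges"))
    peak <- clusters$peak
    if (is.null(peak)) peak <- clusters$midpoint
    if (is.null(peak))
        stop("'clusters' must carry a 'peak' or 'midpoint' column")
    sl <- seqlengths(index@seqinfo)[as.character(seqnames(clusters))]
    if (any(start(clusters) < 1L) ||
        any(!is.na(sl) & end(clusters) > sl))
        stop("cluster interval outside contig bounds")
    pts <- GRanges(seqnames(clusters), IRanges(peak, width = 1L),
                   strand = strand(clusters))
    cls <- classifyPositions(index, pts, strandAware = strandAware)
    hits <- findOverlaps(clusters, index@promoters, ignore.strand = TRUE)
    grp <- split(subjectHits(hits), factor(queryHits(hits),
                                           levels = seq_along(clusters)))
    geneIDs <- CharacterList(lapply(grp, function(i)
        unique(index@promoters$gene_id[i])))
    txIDs <- CharacterList(lapply(grp, function(i)
        unique(index@promoters$tx_id[i])))
    DataFrame(class = cls, geneIDs = geneIDs, txIDs = txIDs)
}

#' Per-class base-pair totals over the contig set
#'
#' Computes, strand-agnostically, how many bases of the genome fall in each
#' region class under the precedence rule. The totals partition the genome:
#' they sum to the total contig length.
#'
#' @param index a [RegionIndex-class] built with a bounded `Seqinfo`.
#' @return named numeric vector over the seven region classes.
#' @export
regionBpTotals <- function(index) {
    sl <- seqlengths(index@seqinfo)
    if (anyNA(sl)) stop("regionBpTotals needs contig lengths")
    tracks <- list(promoter = index@promoters, proximal = index@proximal,
                   fiveUTR = index@utr5, threeUTR = index@utr3,
                   exon = index@exons, intron = index@introns)
    covered <- GRanges()
    out <- setNames(numeric(length(.REGION_CLASSES)), .REGION_CLASSES)
    for (nm in names(tracks)) {
        r <- reduce(granges(tracks[[nm]]), ignore.strand = TRUE)
        r <- setdiff(r, covered, ignore.strand = TRUE)
        out[nm] <- sum(as.numeric(width(r)))
        covered <- reduce(union(covered, r, ignore.strand = TRUE))
    }
    out["intergenic"] <- sum(as.numeric(sl)) - sum(out)
    out
}

#' TSS anchor points of all transcripts
#'
#' @param models a [TranscriptModels-class].
#' @return width-1 `GRanges` at each transcript TSS with `tx_id`/`gene_id`.
#' @export
tssAnchors <- function(models) {
    tx <- models@transcripts
    GRanges(seqnames(tx), IRanges(tx$tss, width = 1L), strand = strand(tx),
            tx_id = tx$tx_id, gene_id = tx$gene_id,
            seqinfo = seqinfo(tx))
}

#' Write promoter windows as BED6
#'
#' @param index a [RegionIndex-class].
#' @param path output BED path.
#' @return the path, invisibly.
#' @export
writePromoterBED <- function(index, path) {
    gr <- index@promoters
    gr$name <- gr$tx_id
    gr$score <- 0L
    gr$tx_id <- gr$gene_id <- NULL
    rtracklayer::export(gr, path, format = "BED")
    invisible(path)
}
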
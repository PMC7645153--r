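#' @import methods
#' @import GenomicRanges
#' @import IRanges
#' @import S4Vectors
#' @import GenomeInfoDb
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges colData
NULL

#' TagProfile: strand-specific per-bp CAGE 5' tag counts for one sample
#'
#' A `TagProfile` stores the 5'-end positions of mapped CAGE tags for a
#' single library at base-pair resolution, as width-1 [GenomicRanges::GRanges]
#' on an explicit strand, with an integer `count` metadata column. The total
#' library size (`totalMapped`) is the denominator used for CTPM
#' normalization.
#'
#' @slot sampleID single character, library/tissue identifier.
#' @slot tags width-1 `GRanges` with strand `+`/`-` and integer `count`
#'   metadata column (every stored position has count >= 1).
#' @slot totalMapped numeric(1), sum of all counts.
#'
#' @seealso [readTagProfile()], [toCTPM()], [poolProfiles()]
#' @export
setClass("TagProfile",
    representation(sampleID = "character", tags = "GRanges",
                   totalMapped = "numeric"))

setValidity("TagProfile", function(object) {
    msg <- NULL
    if (length(object@sampleID) != 1L)
        msg <- c(msg, "'sampleID' must be a single string")
    tg <- object@tags
    if (length(tg)) {
        if (is.null(tg$count))
            return("'tags' must carry a 'count' metadata column")
        if (any(width(tg) != 1L))
            msg <- c(msg, "all tag positions must have width 1")
        if (any(tg$count < 1) || any(tg$count != round(tg$count)))
            msg <- c(msg, "tag counts must be integers >= 1")
        if (any(strand(tg) == "*"))
            msg <- c(msg, "tag positions must be stranded (+/-)")
    }
    tot <- if (length(tg)) sum(as.numeric(tg$count)) else 0
    if (!isTRUE(all.equal(object@totalMapped, tot)))
        msg <- c(msg, "'totalMapped' must equal the sum of counts")
    if (is.null(msg)) TRUE else msg
})

#' CTPMProfile: CTPM-normalized per-bp CAGE signal for one sample
#'
#' Same shape as [TagProfile-class] but with a numeric `ctpm` metadata column:
#' `ctpm = count / totalMapped * 1e6`. The CTPM values of one sample sum to
#' 1e6 by construction.
#'
#' @slot sampleID single character.
#' @slot tags width-1 `GRanges` with a numeric `ctpm` metadata column.
#' @slot totalMapped numeric(1), the raw library size used as denominator.
#' @export
setClass("CTPMProfile",
    representation(sampleID = "character", tags = "GRanges",
                   totalMapped = "numeric"))

setValidity("CTPMProfile", function(object) {
    msg <- NULL
    tg <- object@tags
    if (length(tg)) {
        if (is.null(tg$ctpm))
            return("'tags' must carry a 'ctpm' metadata column")
        if (any(tg$ctpm < 0)) msg <- c(msg, "ctpm values must be >= 0")
        s <- sum(tg$ctpm)
        if (abs(s - 1e6) > 1e-3)
            msg <- c(msg, sprintf("ctpm values must sum to 1e6 (got %.6f)", s))
    }
    if (is.null(msg)) TRUE else msg
})

#' TranscriptModels: gene models parsed from GFF3
#'
#' Transcript-level gene models with derived TSS positions and UTRs. The
#' `transcripts` ranges span each transcript; metadata columns `tx_id`,
#' `gene_id` and `tss` (the 1-based position of the 5'-most transcribed base
#' on the transcript strand). Exon, CDS and UTR structure is held in
#' [GenomicRanges::GRangesList] objects named by `tx_id`.
#'
#' @slot transcripts `GRanges` with `tx_id`, `gene_id`, `tss` columns.
#' @slot exons,cds,utr5,utr3 `GRangesList` keyed by `tx_id` (possibly empty
#'   elements for cds/utr when no CDS is annotated).
#' @seealso [loadAnnotation()]
#' @export
setClass("TranscriptModels",
    representation(transcripts = "GRanges", exons = "GRangesList",
                   cds = "GRangesList", utr5 = "GRangesList",
                   utr3 = "GRangesList"))

setValidity("TranscriptModels", function(object) {
    tx <- object@transcripts
    need <- c("tx_id", "gene_id", "tss")
    if (!all(need %in% names(mcols(tx))))
        return("'transcripts' must carry tx_id, gene_id and tss columns")
    if (anyDuplicated(tx$tx_id)) return("tx_id values must be unique")
    if (!all(tx$tx_id %in% names(object@exons)))
        return("every transcript needs an exons entry")
    ok <- ifelse(strand(tx) == "+", tx$tss == start(tx), tx$tss == end(tx))
    if (!all(ok))
        return("tss must be the 5'-most transcribed base on the strand")
    TRUE
})

#' RegionIndex: genomic-region classifier built from gene models
#'
#' Pre-computed, precedence-ordered region tracks used to classify genomic
#' positions into one of `promoter`, `proximal`, `fiveUTR`, `threeUTR`,
#' `exon`, `intron` or `intergenic`. Promoter windows are centred on the
#' transcript TSS (+/- `promoterHalfwidth`); proximal regions extend
#' `proximalLength` bp upstream of the promoter window on the transcript
#' strand. Positions hitting nothing are intergenic.
#'
#' @slot promoters,proximal,utr5,utr3,exons,introns `GRanges` tracks, each
#'   carrying `tx_id` and `gene_id`.
#' @slot params list with `promoterHalfwidth`, `proximalLength`,
#'   `intergenicMargin`.
#' @slot seqinfo `Seqinfo` of the contig set.
#' @seealso [buildRegionIndex()], [classifyPositions()], [classifyClusters()]
#' @export
setClass("RegionIndex",
    representation(promoters = "GRanges", proximal = "GRanges",
                   utr5 = "GRanges", utr3 = "GRanges", exons = "GRanges",
                   introns = "GRanges", params = "list",
                   seqinfo = "Seqinfo"))

#' TagClusterSet: uni-directional TSS clusters with per-tissue quantification
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] whose rows are
#' strand-specific uni-directional CAGE tag clusters and whose columns are
#' samples (tissues). Row ranges carry `peak` (position of maximum pooled
#' signal; ties resolved 5'-most on the cluster strand) and `pooledSignal`.
#' Assays: `counts` (raw tags per cluster per sample) and `ctpm`.
#' Clustering/filter parameters and attrition counts live in `metadata()`.
#'
#' @seealso [callUnidirectionalClusters()], [filterClusters()]
#' @export
setClass("TagClusterSet", contains = "RangedSummarizedExperiment")

setValidity("TagClusterSet", function(object) {
    rr <- rowRanges(object)
    if (length(rr) == 0L) return(TRUE)
    msg <- NULL
    if (is.null(rr$peak)) return("row ranges must carry a 'peak' column")
    if (!all(start(rr) <= rr$peak & rr$peak <= end(rr)))
        msg <- c(msg, "peak must lie inside [start, end]")
    if (!all(c("counts", "ctpm") %in% names(assays(object))))
        msg <- c(msg, "assays 'counts' and 'ctpm' are required")
    else if (any(assay(object, "counts") < 0))
        msg <- c(msg, "counts must be non-negative")
    key <- paste(seqnames(rr), strand(rr))
    for (k in unique(key)) {
        g <- rr[key == k]
        if (length(g) > 1L) {
            o <- order(start(g))
            if (any(start(g)[o][-1L] <= end(g)[o][-length(g)]))
                msg <- c(msg, "clusters on one contig+strand must not overlap")
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' BidirClusterSet: divergent (bi-directional) TSS-Enhancer clusters
#'
#' A `RangedSummarizedExperiment` of bi-directional CAGE clusters. Row
#' ranges are unstranded windows `[midpoint - w, midpoint + w]` carrying
#' `midpoint`, `balance` (Bhattacharyya score in \[0, 1\]), `minusArm` and
#' `plusArm` pooled tallies and `promoterDistance` (bp from midpoint to the
#' nearest promoter centre). Retained clusters satisfy the promoter
#' proximity constraint (default 400-1000 bp).
#'
#' @seealso [callBidirectionalClusters()], [balanceScore()], [findLinks()]
#' @export
setClass("BidirClusterSet", contains = "RangedSummarizedExperiment")

setValidity("BidirClusterSet", function(object) {
    rr <- rowRanges(object)
    if (length(rr) == 0L) return(TRUE)
    need <- c("midpoint", "balance", "minusArm", "plusArm",
              "promoterDistance")
    if (!all(need %in% names(mcols(rr))))
        return(paste("row ranges must carry:", paste(need, collapse = ", ")))
    if (any(rr$balance < 0 | rr$balance > 1))
        return("balance must lie in [0, 1]")
    TRUE
})

#' CpGTrack: symmetric-merged per-CpG methylation counts for one sample
#'
#' Width-1 unstranded positions (the C of the CpG dinucleotide on the plus
#' strand after symmetric merging) with `coverage` and `methylated` counts.
#'
#' @slot sampleID single character.
#' @slot sites width-1 `GRanges`, sorted, with integer `coverage` and
#'   `methylated` columns (0 <= methylated <= coverage).
#' @slot minCoverage minimum read coverage a CpG needs to enter the HMM
#'   (default 10).
#' @seealso [readCGmap()], [mergeSymmetricCpGs()], [callHMRs()]
#' @export
setClass("CpGTrack",
    representation(sampleID = "character", sites = "GRanges",
                   minCoverage = "numeric"))

setValidity("CpGTrack", function(object) {
    st <- object@sites
    if (length(st) == 0L) return(TRUE)
    if (!all(c("coverage", "methylated") %in% names(mcols(st))))
        return("'sites' must carry coverage and methylated columns")
    if (any(st$methylated < 0 | st$methylated > st$coverage))
        return("need 0 <= methylated <= coverage")
    key <- as.character(seqnames(st))
    for (k in unique(key)) {
        p <- start(st)[key == k]
        if (is.unsorted(p, strictly = TRUE))
            return("positions must be strictly increasing per contig")
    }
    TRUE
})

#' HMRSet: hypomethylated regions segmented by the Beta-Binomial HMM
#'
#' @slot regions sorted, non-overlapping `GRanges` with `nCpGs` (member CpG
#'   count), `score` (summed posterior hypomethylation probability) and
#'   `meanMethylation` columns. Region ends extend one base past the last
#'   member CpG so the full CpG dinucleotide is covered.
#' @slot fit list with fitted HMM parameters and diagnostics (see
#'   [fitMethHMM()]).
#' @seealso [callHMRs()], [validateTSS()]
#' @export
setClass("HMRSet", representation(regions = "GRanges", fit = "list"))

setValidity("HMRSet", function(object) {
    rg <- object@regions
    if (length(rg) == 0L) return(TRUE)
    if (!all(c("nCpGs", "score") %in% names(mcols(rg))))
        return("'regions' must carry nCpGs and score columns")
    if (length(reduce(rg, ignore.strand = TRUE)) != length(rg))
        return("regions must be non-overlapping")
    TRUE
})

#' TruthTable: planted coordinates emitted by the synthetic panel generator
#'
#' Machine-readable ground truth for a simulated tissue panel: every planted
#' TSS (with its expressing tissues and novelty flag), divergent enhancer
#' locus (with in-range flag), hypomethylated island, and the tissue family
#' labels.
#'
#' @slot tss data.frame: contig, position, strand, class
#'   (annotated/novel/tissue_specific/family), gene_id, tx_id, nTissues,
#'   tissues (comma-separated), hmr flag.
#' @slot enhancers data.frame: contig, midpoint, distance, inRange, gene_id,
#'   nTissues.
#' @slot hmrs data.frame: contig, start, end, category.
#' @slot families data.frame: tissue, family.
#' @slot config the [panelConfig()] list used for generation.
#' @seealso [simulateCagePanel()], [scoreRecovery()]
#' @export
setClass("TruthTable",
    representation(tss = "data.frame", enhancers = "data.frame",
                   hmrs = "data.frame", families = "data.frame",
                   config = "list"))
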
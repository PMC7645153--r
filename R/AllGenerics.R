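#' Accessors for cageAtlas classes
#'
#' `sampleID()` returns the library identifier of a profile or track;
#' `tagPositions()` the width-1 tag `GRanges`; `totalMapped()` the library
#' size; `cpgSites()` the per-CpG `GRanges` of a [CpGTrack-class];
#' `hmrRegions()` the region `GRanges` of an [HMRSet-class];
#' `transcriptRanges()` the transcript-level `GRanges` of a
#' [TranscriptModels-class]; `promoterRanges()` the promoter windows of a
#' [RegionIndex-class].
#'
#' @param x the object.
#' @return the slot contents described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleID", function(x) standardGeneric("sampleID"))
#' @rdname accessors
#' @export
setGeneric("tagPositions", function(x) standardGeneric("tagPositions"))
#' @rdname accessors
#' @export
setGeneric("totalMapped", function(x) standardGeneric("totalMapped"))
#' @rdname accessors
#' @export
setGeneric("cpgSites", function(x) standardGeneric("cpgSites"))
#' @rdname accessors
#' @export
setGeneric("hmrRegions", function(x) standardGeneric("hmrRegions"))
#' @rdname accessors
#' @export
setGeneric("transcriptRanges", function(x) standardGeneric("transcriptRanges"))
#' @rdname accessors
#' @export
setGeneric("promoterRanges", function(x) standardGeneric("promoterRanges"))

#' @rdname accessors
setMethod("sampleID", "TagProfile", function(x) x@sampleID)
#' @rdname accessors
setMethod("sampleID", "CTPMProfile", function(x) x@sampleID)
#' @rdname accessors
setMethod("sampleID", "CpGTrack", function(x) x@sampleID)
#' @rdname accessors
setMethod("tagPositions", "TagProfile", function(x) x@tags)
#' @rdname accessors
setMethod("tagPositions", "CTPMProfile", function(x) x@tags)
#' @rdname accessors
setMethod("totalMapped", "TagProfile", function(x) x@totalMapped)
#' @rdname accessors
setMethod("totalMapped", "CTPMProfile", function(x) x@totalMapped)
#' @rdname accessors
setMethod("cpgSites", "CpGTrack", function(x) x@sites)
#' @rdname accessors
setMethod("hmrRegions", "HMRSet", function(x) x@regions)
#' @rdname accessors
setMethod("transcriptRanges", "TranscriptModels", function(x) x@transcripts)
#' @rdname accessors
setMethod("promoterRanges", "RegionIndex", function(x) x@promoters)

setMethod("show", "TagProfile", function(object) {
    cat("TagProfile '", object@sampleID, "': ", length(object@tags),
        " positions, ", format(object@totalMapped, big.mark = ","),
        " mapped tags\n", sep = "")
})

setMethod("show", "CTPMProfile", function(object) {
    cat("CTPMProfile '", object@sampleID, "': ", length(object@tags),
        " positions (library size ",
        format(object@totalMapped, big.mark = ","), ")\n", sep = "")
})

setMethod("show", "TranscriptModels", function(object) {
    tx <- object@transcripts
    cat("TranscriptModels: ", length(tx), " transcripts, ",
        length(unique(tx$gene_id)), " genes on ",
        length(unique(as.character(seqnames(tx)))), " contig(s)\n", sep = "")
})

setMethod("show", "RegionIndex", function(object) {
    cat("RegionIndex: ", length(object@promoters), " promoter windows ",
        "(halfwidth ", object@params$promoterHalfwidth, " bp, proximal ",
        object@params$proximalLength, " bp)\n", sep = "")
})

setMethod("show", "TagClusterSet", function(object) {
    cat("TagClusterSet: ", nrow(object), " uni-directional clusters x ",
        ncol(object), " samples\n", sep = "")
    att <- S4Vectors::metadata(object)$attrition
    if (!is.null(att))
        cat("  attrition: ", paste(names(att), unlist(att), sep = "=",
            collapse = ", "), "\n", sep = "")
})

setMethod("show", "BidirClusterSet", function(object) {
    cat("BidirClusterSet: ", nrow(object),
        " bi-directional (TSS-Enhancer) clusters x ", ncol(object),
        " samples\n", sep = "")
})

setMethod("show", "CpGTrack", function(object) {
    cat("CpGTrack '", object@sampleID, "': ", length(object@sites),
        " CpG sites (min coverage for HMM: ", object@minCoverage, ")\n",
        sep = "")
})

setMethod("show", "HMRSet", function(object) {
    cat("HMRSet: ", length(object@regions), " hypomethylated regions",
        sep = "")
    if (length(object@regions))
        cat(", median width ",
            stats::median(width(object@regions)), " bp", sep = "")
    cat("\n")
})

setMethod("show", "TruthTable", function(object) {
    cat("TruthTable: ", nrow(object@tss), " planted TSS (",
        sum(object@tss$class == "novel"), " novel), ",
        nrow(object@enhancers), " enhancer loci, ",
        nrow(object@hmrs), " hypomethylated islands, ",
        nrow(object@families), " tissues\n", sep = "")
})
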
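#' Read a pipeline run configuration
#'
#' YAML with input paths (`contigs`, `annotation`, `cageDir`, `wgbsDir`,
#' `tpmDir`) and optional stage parameters (any argument of
#' [clusteringParams()], plus `shortWindow`, `longWindow`,
#' `windowHalfwidth`, `balanceThreshold`, `promoterDistanceRange`,
#' `maxLinkDistance`, `alpha`, `minCpGs`, `thresholds`).
#'
#' @param path YAML file.
#' @return named list.
#' @export
readRunConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg$cageDir))
        stop("run config must name 'cageDir' with per-tissue tag files")
    cfg
}

#' @noRd
.loadPanelInputs <- function(config) {
    if (inherits(config, "CagePanel"))
        return(list(contigs = config$contigs, models = config$models,
                    profiles = config$profiles,
                    cpgTracks = config$cpgTracks, tpm = config$tpm))
    contigs <- readContigs(config$contigs)
    models <- loadAnnotation(config$annotation, contigs)
    files <- list.files(config$cageDir, pattern = "\\.bed$",
                        full.names = TRUE)
    if (length(files) == 0L)
        files <- unique(sub("\\.(plus|minus)\\.bedGraph$", "",
                            list.files(config$cageDir,
                                       pattern = "\\.bedGraph$",
                                       full.names = TRUE)))
    profiles <- lapply(files, readTagProfile, contigs = contigs)
    cpgTracks <- list()
    if (!is.null(config$wgbsDir)) {
        wf <- list.files(config$wgbsDir, pattern = "cgmap",
                         full.names = TRUE)
        cpgTracks <- lapply(wf, function(f)
            mergeSymmetricCpGs(readCGmap(f)))
        names(cpgTracks) <- vapply(cpgTracks, sampleID, character(1))
    }
    tpm <- NULL
    if (!is.null(config$tpmDir)) {
        tf <- list.files(config$tpmDir, pattern = "abundance",
                         full.names = TRUE)
        if (length(tf)) {
            tabs <- lapply(tf, readKallistoAbundance)
            ids <- sub("_abundance\\.tsv$", "", basename(tf))
            tpm <- do.call(cbind, lapply(tabs, function(x) x$tpm))
            rownames(tpm) <- tabs[[1L]]$target_id
            colnames(tpm) <- ids
        }
    }
    list(contigs = contigs, models = models, profiles = profiles,
         cpgTracks = cpgTracks, tpm = tpm)
}

#' Run the full TSS/enhancer/methylation pipeline
#'
#' Orchestrates every stage over a tissue panel: pooled uni-directional
#' TSS clustering, per-sample quantification, count and representation
#' filtering, genomic-region classification, bi-directional TSS-Enhancer
#' calling with the promoter-distance constraint, co-expression links,
#' per-tissue novelty annotation, hypomethylated-region calling on the
#' WGBS subset, validation of annotated/novel TSS against HMRs, the
#' tissue-sharing matrix and the MI-distance tissue dendrogram.
#' Uni-directional clusters overlapping a retained bi-directional cluster
#' window are treated as enhancer-associated and set aside from the
#' novelty/methylation tables.
#'
#' @param config a `CagePanel` from [simulateCagePanel()], a run-config
#'   list (see [readRunConfig()]) or a YAML path.
#' @param outdir optional output directory for track/table exports and the
#'   JSON summary.
#' @param params a [clusteringParams()] list.
#' @param shortWindow,longWindow novelty windows in bp (50 / 400).
#' @param windowHalfwidth,balanceThreshold,promoterDistanceRange
#'   bi-directional calling parameters (see
#'   [callBidirectionalClusters()]).
#' @param maxLinkDistance,alpha co-expression link parameters (see
#'   [findLinks()]).
#' @param minCpGs minimum CpGs per hypomethylated region.
#' @param verbose log stage progress to stderr (default `TRUE`).
#' @return list of stage results: `clusters` (filtered
#'   [TagClusterSet-class]), `unfiltered`, `bidir`, `links`, `regionClass`
#'   (classification of filtered clusters), `regionClassProportions`,
#'   `novelty` (per-tissue calls), `noveltyTable`, `hmrs` (per WGBS
#'   tissue), `validation` (per WGBS tissue), `validationSummary`,
#'   `sharing`, `tissueTree`, `perGene`, `attrition`, `summary` (the
#'   JSON-ready summary list).
#' @export
runPipeline <- function(config, outdir = NULL,
                        params = clusteringParams(),
                        shortWindow = 50, longWindow = 400,
                        windowHalfwidth = 200, balanceThreshold = 0.95,
                        promoterDistanceRange = c(400, 1000),
                        maxLinkDistance = 10000, alpha = 0.05,
                        minCpGs = 3, verbose = TRUE) {
    log <- function(...) if (verbose) message("[cageAtlas] ", ...)
    if (is.character(config)) config <- readRunConfig(config)
    inp <- .loadPanelInputs(config)
    nT <- length(inp$profiles)
    log("loaded ", nT, " tissue profiles")

    log("pooling and uni-directional clustering")
    pooled <- poolProfiles(inp$profiles, mode = params$poolMode)
    uniGR <- callUnidirectionalClusters(pooled,
                                        mergeDist = params$mergeDist)
    unfiltered <- quantifyClusters(uniGR, inp$profiles, params)
    clusters <- filterClusters(unfiltered)
    attrition <- S4Vectors::metadata(clusters)$attrition
    log("clusters: ", paste(names(attrition), unlist(attrition),
                            sep = "=", collapse = ", "))

    log("region classification")
    index <- buildRegionIndex(inp$models, inp$contigs)
    regionClass <- classifyClusters(index, clusters)
    regionProp <- 100 * prop.table(table(regionClass$class))
    perGene <- clustersPerGene(clusters, index)

    log("bi-directional TSS-Enhancer calling")
    bidirGR <- callBidirectionalClusters(
        pooled, inp$models, windowHalfwidth = windowHalfwidth,
        balanceThreshold = balanceThreshold,
        promoterDistanceRange = promoterDistanceRange)
    bidir <- quantifyBidirClusters(bidirGR, inp$profiles)
    # the low-count rule applies to bi-directional clusters as well
    bidir <- bidir[rowSums(assay(bidir, "counts")) >=
                       params$minClusterCount, ]
    bidirGR <- rowRanges(bidir)
    links <- if (nrow(bidir) > 0L && ncol(bidir) >= 8L)
        findLinks(bidir, clusters, maxLinkDistance = maxLinkDistance,
                  alpha = alpha)
    else data.frame()

    # enhancer-associated unidirectional clusters are reported separately
    enhAssoc <- overlapsAny(rowRanges(clusters), bidirGR,
                            ignore.strand = TRUE)
    tssOnly <- clusters[!enhAssoc, ]

    log("per-tissue novelty annotation")
    pres <- presenceMatrix(tssOnly)
    novelty <- lapply(seq_len(ncol(tssOnly)), function(t)
        callNovelty(tssOnly[pres[, t], ], inp$models,
                    shortWindow = shortWindow, longWindow = longWindow))
    names(novelty) <- colnames(tssOnly)
    noveltyTable <- noveltyReport(novelty)

    hmrs <- list(); validation <- list()
    if (length(inp$cpgTracks)) {
        log("hypomethylated-region calling on ", length(inp$cpgTracks),
            " WGBS tissue(s)")
        allNovel <- callNovelty(tssOnly, inp$models,
                                shortWindow = shortWindow,
                                longWindow = longWindow)
        for (ts in names(inp$cpgTracks)) {
            hmrs[[ts]] <- callHMRs(inp$cpgTracks[[ts]],
                                   minCpGs = minCpGs)
            keep <- if (ts %in% colnames(tssOnly)) pres[, ts]
                    else rep(TRUE, nrow(tssOnly))
            validation[[ts]] <- validateTSS(
                rowRanges(tssOnly)[keep], allNovel$novel[keep],
                hmrs[[ts]])
        }
    }
    validationSummary <- if (length(validation)) {
        tabs <- lapply(validation, function(v) v$table)
        agg <- tabs[[1L]][, "category", drop = FALSE]
        agg$n <- Reduce(`+`, lapply(tabs, function(x) x$n))
        pctAnnotHypo <- mean(vapply(tabs, function(x) {
            a <- x$n[grepl("annotated", x$category)]
            if (sum(a)) 100 * a[1L] / sum(a) else NA_real_
        }, numeric(1)), na.rm = TRUE)
        pctNovelHypo <- mean(vapply(tabs, function(x) {
            a <- x$n[grepl("novel", x$category)]
            if (sum(a)) 100 * a[1L] / sum(a) else NA_real_
        }, numeric(1)), na.rm = TRUE)
        list(counts = agg, pctAnnotatedHypo = pctAnnotHypo,
             pctNovelHypo = pctNovelHypo)
    } else NULL

    log("tissue profiles: sharing matrix and MI dendrogram")
    sharing <- sharingMatrix(clusters)
    tissueTree <- if (ncol(unfiltered) >= 3L) {
        m <- assay(unfiltered, "ctpm")
        pooledCount <- rowSums(assay(unfiltered, "counts"))
        clusterTissues(m[pooledCount >= params$minClusterCount, ,
                         drop = FALSE])
    } else NULL

    summary <- list(
        nTissues = nT,
        attrition = attrition,
        nUnidirectional = nrow(clusters),
        nBidirectional = nrow(bidir),
        nLinks = nrow(links),
        regionClassProportions = as.list(regionProp),
        meanClustersPerGene = perGene$meanPerGene,
        medianClustersPerGene = perGene$medianPerGene,
        pctNovelShortRange =
            noveltyTable$pctNovel[noveltyTable$tissue == "overall"],
        pctAnnotatedHypomethylated =
            if (!is.null(validationSummary))
                validationSummary$pctAnnotatedHypo else NA,
        pctNovelHypomethylated =
            if (!is.null(validationSummary))
                validationSummary$pctNovelHypo else NA)

    res <- list(clusters = clusters, unfiltered = unfiltered,
                bidir = bidir, links = links,
                regionClass = regionClass,
                regionClassProportions = regionProp,
                novelty = novelty, noveltyTable = noveltyTable,
                hmrs = hmrs, validation = validation,
                validationSummary = validationSummary,
                sharing = sharing, tissueTree = tissueTree,
                perGene = perGene, attrition = attrition,
                summary = summary)
    if (!is.null(outdir)) .writePipelineOutputs(res, outdir, params)
    invisible(res)
}

#' @noRd
.writePipelineOutputs <- function(res, outdir, params) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    writeClusterBED(res$clusters, file.path(outdir, "tss_clusters.bed"))
    writeCountMatrix(res$clusters, file.path(outdir,
                                             "cluster_counts.tsv"))
    if (nrow(res$bidir) > 0L)
        writeEnhancerBED(res$bidir, file.path(outdir, "enhancers.bed"))
    if (nrow(res$links) > 0L)
        writeLinksTSV(res$links, res$bidir, res$clusters,
                      file.path(outdir, "links.tsv"))
    utils::write.table(res$noveltyTable,
                       file.path(outdir, "novelty_by_tissue.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (ts in names(res$hmrs))
        writeHMRBed(res$hmrs[[ts]],
                    file.path(outdir, paste0("hmr_", ts, ".bed")))
    if (!is.null(res$tissueTree))
        writeLines(res$tissueTree$newick,
                   file.path(outdir, "tissue_dendrogram.nwk"))
    if (!is.null(res$tissueTree))
        writePhylipMatrix(res$tissueTree$distance,
                          file.path(outdir, "tissue_distance.phylip"))
    utils::write.table(res$sharing,
                       file.path(outdir, "sharing_matrix.tsv"),
                       sep = "\t", quote = FALSE)
    jsonlite::write_json(res$summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    yaml::write_yaml(c(params, list()),
                     file.path(outdir, "params_used.yaml"))
    invisible(outdir)
}

#' Compare tissue-representation thresholds
#'
#' Re-applies the representation filter at several thresholds and
#' reports, per threshold, the retained cluster count, the number of
#' genes tagged by at least one promoter-class cluster, and the
#' percentage of retained clusters not overlapping any promoter window
#' ("untagged"). Retained counts are non-increasing in the threshold.
#'
#' @param tcs an unfiltered [TagClusterSet-class].
#' @param index a [RegionIndex-class].
#' @param thresholds integer vector of minimum tissue counts; default
#'   `c(1, 5, n/3, n/2, 2n/3, n)` (rounded down, deduplicated).
#' @return data.frame: threshold, retained, genesTagged, pctUntagged.
#' @export
compareThresholds <- function(tcs, index, thresholds = NULL) {
    stopifnot(is(tcs, "TagClusterSet"))
    n <- ncol(tcs)
    if (is.null(thresholds))
        thresholds <- unique(pmax(1L, floor(c(1, 5, n / 3, n / 2,
                                              2 * n / 3, n))))
    thresholds <- sort(unique(as.integer(thresholds)))
    rows <- lapply(thresholds, function(th) {
        f <- filterClusters(tcs, minTissues = th)
        tagged <- overlapsAny(rowRanges(f), index@promoters,
                              ignore.strand = TRUE)
        hits <- findOverlaps(rowRanges(f), index@promoters,
                             ignore.strand = TRUE)
        data.frame(threshold = th, retained = nrow(f),
                   genesTagged = length(unique(
                       index@promoters$gene_id[subjectHits(hits)])),
                   pctUntagged = if (nrow(f))
                       100 * sum(!tagged) / nrow(f) else NA_real_)
    })
    do.call(rbind, rows)
}
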
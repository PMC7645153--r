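#' Configuration for the synthetic tissue-panel generator
#'
#' Defines the study conditions the generator emulates: a panel of many
#' tissues sharing a core set of promoter-focal TSS, a minority of
#' tissue-restricted TSS, divergent enhancer loci 400-1,000 bp from
#' promoters (plus out-of-range decoys), background noise tags, and CpG
#' methylation tracks with hypomethylated islands over true (but not
#' spurious) TSS.
#'
#' @param seed RNG seed; a fixed seed yields byte-identical output files.
#' @param nTissues number of tissues in the panel (default 56).
#' @param nContigs,contigLength genome shape (default 2 x 500,000 bp).
#' @param nGenes number of annotated genes (default 200).
#' @param fracMultiTss fraction of genes with a second transcript and
#'   alternative TSS (default 0.1).
#' @param fracNovelTss fraction of all planted widely-shared TSS that are
#'   novel, i.e. placed at least 400 bp from any promoter (default 0.4).
#' @param fracTissueSpecific tissue-specific TSS as a fraction of all
#'   planted TSS; each is expressed (>10 tags) in exactly one tissue
#'   (default 0.05).
#' @param fracWithEnhancer fraction of genes with a divergent enhancer
#'   400-1,000 bp upstream of the promoter centre (default 0.2).
#' @param enhancerDecoyFrac fraction of genes with an out-of-range
#'   divergent decoy locus (default 0.05).
#' @param tssCountMean,tssCountDispersion negative-binomial tag count per
#'   expressed locus per tissue (mean 50, dispersion 0.5, i.e.
#'   `size = 1 / dispersion`).
#' @param jitterBp positional jitter: counts are spread multinomially over
#'   `peak +/- jitterBp` (default 2).
#' @param noiseRate background noise tags per bp per tissue (default
#'   1e-5).
#' @param fracNovelWithHmr fraction of novel TSS covered by a planted
#'   hypomethylated island (default 0.3).
#' @param fracAnnotatedWithHmr fraction of annotated TSS covered by a
#'   planted island (default 0.9).
#' @param islandMeth,backgroundMeth Beta shape pairs for per-CpG
#'   methylation levels inside islands (default Beta(1, 9)) and in the
#'   background (default Beta(9, 1)).
#' @param coverageMean per-CpG coverage is Poisson with this mean
#'   (default 20; split evenly between the two strands).
#' @param nWgbsTissues tissues with a WGBS track (default 8).
#' @param nTissueFamilies,familyBlockSize tissue families (default 4) and
#'   family-specific TSS per family (default 25), expressed only in that
#'   family's tissues.
#' @param decoyTissues tissues expressing each decoy locus (default 20;
#'   below the two-thirds representation threshold, as befits
#'   non-reproducible loci).
#' @param tpmNoiseSd lognormal noise (sd on the log scale) linking
#'   transcript TPM to its TSS tag count (default 1.5).
#' @return validated config list of class `PanelConfig`.
#' @export
panelConfig <- function(seed = 1L, nTissues = 56, nContigs = 2,
                        contigLength = 500000, nGenes = 200,
                        fracMultiTss = 0.1, fracNovelTss = 0.4,
                        fracTissueSpecific = 0.05,
                        fracWithEnhancer = 0.2, enhancerDecoyFrac = 0.05,
                        tssCountMean = 50, tssCountDispersion = 0.5,
                        jitterBp = 2, noiseRate = 1e-5,
                        fracNovelWithHmr = 0.3,
                        fracAnnotatedWithHmr = 0.9,
                        islandMeth = c(1, 9), backgroundMeth = c(9, 1),
                        coverageMean = 20, nWgbsTissues = 8,
                        nTissueFamilies = 4, familyBlockSize = 25,
                        decoyTissues = 20, tpmNoiseSd = 1.5) {
    cfg <- as.list(environment())
    fr <- c(fracMultiTss, fracNovelTss, fracTissueSpecific,
            fracWithEnhancer, enhancerDecoyFrac, fracNovelWithHmr,
            fracAnnotatedWithHmr)
    stopifnot(all(fr >= 0), all(fr <= 1), fracNovelTss < 1,
              nTissues >= 1, nGenes >= 1, contigLength >= 20000,
              nWgbsTissues <= nTissues, tssCountMean > 0,
              tssCountDispersion > 0)
    slotLen <- 4000L
    nSlots <- nContigs * (contigLength %/% slotLen)
    nAnnot <- nGenes + round(fracMultiTss * nGenes)
    nNovel <- round(fracNovelTss / (1 - fracNovelTss) * nAnnot)
    nAux <- nNovel + round(fracTissueSpecific * (nAnnot + nNovel)) +
        nTissueFamilies * familyBlockSize + round(enhancerDecoyFrac * nGenes)
    if (nGenes > nSlots)
        stop("genome too small: ", nGenes, " genes need ", nGenes,
             " slots of ", slotLen, " bp, have ", nSlots)
    if (nAux > 2L * nSlots)
        stop("genome too small for ", nAux, " auxiliary loci")
    structure(cfg, class = "PanelConfig")
}

#' @noRd
.jitterSpread <- function(counts, peaks, jitterBp) {
    # multinomial spread of each locus count over peak +/- jitterBp,
    # vectorized across loci by sequential binomial splitting
    idxAll <- which(counts > 0L)
    counts <- counts[idxAll]; peaks <- peaks[idxAll]
    if (length(idxAll) == 0L)
        return(data.frame(idx = integer(0), pos = integer(0),
                          count = integer(0)))
    if (jitterBp == 0L)
        return(data.frame(idx = idxAll, pos = peaks, count = counts))
    offs <- -jitterBp:jitterBp
    w <- stats::dbinom(0:(2 * jitterBp), 2 * jitterBp, 0.5)
    cols <- matrix(0L, length(counts), length(offs))
    rem <- counts; remW <- 1
    for (k in seq_along(offs)) {
        p <- if (remW > 0) min(1, w[k] / remW) else 1
        if (k == length(offs)) p <- 1
        draw <- stats::rbinom(length(rem), rem, p)
        cols[, k] <- draw
        rem <- rem - draw
        remW <- remW - w[k]
    }
    posM <- outer(peaks, offs, `+`)
    keep <- as.vector(cols) > 0L
    data.frame(idx = rep(idxAll, length(offs))[keep],
               pos = as.vector(posM)[keep],
               count = as.vector(cols)[keep])
}

#' Generate a synthetic multi-tissue CAGE/WGBS/mRNA panel
#'
#' Lays out genes on a fixed slot grid across the contigs, plants
#' annotated, novel, tissue-specific and tissue-family TSS plus in-range
#' divergent enhancers and out-of-range decoys, draws per-tissue tag
#' counts, and emits per-tissue CAGE tag profiles, CpG methylation tracks
#' (for a WGBS subset of tissues) with hypomethylated islands over true
#' TSS, and transcript TPM tables - together with a [TruthTable-class] of
#' every planted coordinate. All randomness comes from `config$seed`;
#' repeated runs are identical.
#'
#' @param config a [panelConfig()] list.
#' @param outdir optional directory; when given, all panel files are
#'   written there (`contigs.tsv`, `annotation.gff3`, `truth.json`,
#'   `cage/<tissue>.bed`, `wgbs/<tissue>.cgmap.tsv`,
#'   `tpm/<tissue>_abundance.tsv`).
#' @return list of class `CagePanel`: `truth` ([TruthTable-class]),
#'   `contigs` (`Seqinfo`), `models` ([TranscriptModels-class]),
#'   `profiles` (list of [TagProfile-class]), `cpgTracks` (list of
#'   [CpGTrack-class]), `tpm` (transcript x tissue matrix), `config`,
#'   `dir`.
#' @export
simulateCagePanel <- function(config = panelConfig(), outdir = NULL) {
    stopifnot(inherits(config, "PanelConfig"))
    if (exists(".Random.seed", envir = globalenv())) {
        oldSeed <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
    }
    set.seed(config$seed)
    cfg <- config
    slotLen <- 4000L
    perContig <- cfg$contigLength %/% slotLen
    contigs <- Seqinfo(sprintf("ctg%d", seq_len(cfg$nContigs)),
                       rep(as.integer(cfg$contigLength), cfg$nContigs))
    slots <- data.frame(
        contig = rep(seqlevels(contigs), each = perContig),
        off0 = rep((seq_len(perContig) - 1L) * slotLen,
                   cfg$nContigs))
    nSlots <- nrow(slots)
    slotOrder <- sample(nSlots)
    geneSlots <- slotOrder[seq_len(cfg$nGenes)]
    slots$gene <- FALSE
    slots$gene[geneSlots] <- TRUE
    slots$strand <- sample(c("+", "-"), nSlots, replace = TRUE)

    tissues <- sprintf("tissue%02d", seq_len(cfg$nTissues))
    family <- sort(rep(seq_len(cfg$nTissueFamilies),
                       length.out = cfg$nTissues))
    famDf <- data.frame(tissue = tissues, family = family)

    rel <- function(strand, x) if (strand == "+") x else slotLen - x

    ## ---- gene models -------------------------------------------------
    gs <- slots[geneSlots, ]
    gs$gene_id <- sprintf("gene%03d", seq_len(cfg$nGenes))
    nMulti <- round(cfg$fracMultiTss * cfg$nGenes)
    multiIdx <- sort(sample(cfg$nGenes, nMulti))
    txRows <- list()
    mkTx <- function(contig, off0, strand, gene_id, tx_id, relTss) {
        # primary transcript geometry (rel offsets from the slot start,
        # mirrored on the minus strand): exons [0,200] and [500,1600]
        # downstream of the TSS, CDS [100,1400]
        if (strand == "+") {
            e1 <- c(relTss, relTss + 200L)
            e2 <- c(relTss + 500L, relTss + 1600L)
            cds <- c(relTss + 100L, relTss + 1400L)
        } else {
            e1 <- c(relTss - 200L, relTss)
            e2 <- c(relTss - 1600L, relTss - 500L)
            cds <- c(relTss - 1400L, relTss - 100L)
        }
        list(contig = contig, strand = strand, gene_id = gene_id,
             tx_id = tx_id,
             exons = rbind(off0 + sort(c(e1, e2))[1:2],
                           off0 + sort(c(e1, e2))[3:4]),
             cds = off0 + cds,
             tss = off0 + relTss)
    }
    for (i in seq_len(cfg$nGenes)) {
        s <- gs[i, ]
        t1 <- rel(s$strand, 1200L)
        txRows[[length(txRows) + 1L]] <-
            mkTx(s$contig, s$off0, s$strand, s$gene_id,
                 paste0(s$gene_id, ".t1"), t1)
        if (i %in% multiIdx) {
            t2 <- rel(s$strand, 1800L)
            txRows[[length(txRows) + 1L]] <-
                mkTx(s$contig, s$off0, s$strand, s$gene_id,
                     paste0(s$gene_id, ".t2"), t2)
        }
    }

    ## ---- planted loci ------------------------------------------------
    nAnnot <- length(txRows)
    annotDf <- data.frame(
        contig = vapply(txRows, `[[`, character(1), "contig"),
        position = vapply(txRows, `[[`, numeric(1), "tss"),
        strand = vapply(txRows, `[[`, character(1), "strand"),
        class = "annotated",
        gene_id = vapply(txRows, `[[`, character(1), "gene_id"),
        tx_id = vapply(txRows, `[[`, character(1), "tx_id"))

    nNovel <- round(cfg$fracNovelTss / (1 - cfg$fracNovelTss) * nAnnot)
    nTS <- round(cfg$fracTissueSpecific * (nAnnot + nNovel))
    nFam <- cfg$nTissueFamilies * cfg$familyBlockSize
    nDecoy <- round(cfg$enhancerDecoyFrac * cfg$nGenes)
    # two auxiliary sites per slot, well away from every promoter window
    auxRel <- function(s) {
        if (s$gene) rel(s$strand, c(3000L, 3400L)) else c(1500L, 2500L)
    }
    auxPool <- do.call(rbind, lapply(seq_len(nSlots), function(k) {
        data.frame(contig = slots$contig[k],
                   pos = slots$off0[k] + auxRel(slots[k, ]))
    }))
    auxPool <- auxPool[sample(nrow(auxPool)), ]
    nAux <- nNovel + nTS + nFam + nDecoy
    aux <- auxPool[seq_len(nAux), ]
    auxClass <- rep(c("novel", "tissue_specific", "family", "decoy"),
                    c(nNovel, nTS, nFam, nDecoy))
    auxStrand <- sample(c("+", "-"), nAux, replace = TRUE)

    novelDf <- data.frame(contig = aux$contig[auxClass == "novel"],
                          position = aux$pos[auxClass == "novel"],
                          strand = auxStrand[auxClass == "novel"],
                          class = "novel", gene_id = NA_character_,
                          tx_id = NA_character_)
    tsDf <- data.frame(contig = aux$contig[auxClass == "tissue_specific"],
                       position = aux$pos[auxClass == "tissue_specific"],
                       strand = auxStrand[auxClass == "tissue_specific"],
                       class = "tissue_specific", gene_id = NA_character_,
                       tx_id = NA_character_)
    famLoci <- data.frame(contig = aux$contig[auxClass == "family"],
                          position = aux$pos[auxClass == "family"],
                          strand = auxStrand[auxClass == "family"],
                          class = "family", gene_id = NA_character_,
                          tx_id = NA_character_)
    famOfLocus <- rep(seq_len(cfg$nTissueFamilies),
                      each = cfg$familyBlockSize)

    tssDf <- rbind(annotDf, novelDf, tsDf, famLoci)
    tssDf$locus_id <- sprintf("locus%04d", seq_len(nrow(tssDf)))
    tsTissue <- sample(tissues, nTS, replace = TRUE)
    tssDf$tissues <- NA_character_
    tssDf$nTissues <- cfg$nTissues
    tssDf$tissues[tssDf$class %in% c("annotated", "novel")] <- "all"
    tssDf$nTissues[tssDf$class == "tissue_specific"] <- 1L
    tssDf$tissues[tssDf$class == "tissue_specific"] <- tsTissue
    tssDf$nTissues[tssDf$class == "family"] <-
        as.integer(table(family)[famOfLocus])
    tssDf$tissues[tssDf$class == "family"] <-
        sprintf("family%d", famOfLocus)

    ## ---- enhancers and decoys ---------------------------------------
    nEnh <- round(cfg$fracWithEnhancer * cfg$nGenes)
    enhGenes <- sort(sample(cfg$nGenes, nEnh))
    enhD <- sample(450:950, nEnh, replace = TRUE)
    eg <- gs[enhGenes, ]
    enhMid <- ifelse(eg$strand == "+",
                     eg$off0 + 1200L - enhD,
                     eg$off0 + rel("-", 1200L) + enhD)
    enhDf <- data.frame(contig = eg$contig, midpoint = enhMid,
                        distance = enhD, inRange = TRUE,
                        gene_id = eg$gene_id, nTissues = cfg$nTissues)
    # decoys stay below the two-thirds representation threshold
    nDecoyT <- min(cfg$decoyTissues,
                   max(1L, representationThreshold(cfg$nTissues) - 1L))
    if (nDecoy > 0L) {
        decoyDf <- data.frame(contig = aux$contig[auxClass == "decoy"],
                              midpoint = aux$pos[auxClass == "decoy"],
                              distance = NA_real_, inRange = FALSE,
                              gene_id = NA_character_,
                              nTissues = nDecoyT)
        enhDf <- rbind(enhDf, decoyDf)
    }
    decoyTissueSets <- lapply(seq_len(nDecoy), function(i)
        sample(tissues, nDecoyT))

    ## ---- planted methylation islands --------------------------------
    isAnnot <- tssDf$class == "annotated"
    isNovel <- tssDf$class == "novel"
    hmrAnnot <- sort(sample(which(isAnnot),
                            round(cfg$fracAnnotatedWithHmr *
                                      sum(isAnnot))))
    hmrNovel <- sort(sample(which(isNovel),
                            round(cfg$fracNovelWithHmr * sum(isNovel))))
    tssDf$hmr <- FALSE
    tssDf$hmr[c(hmrAnnot, hmrNovel)] <- TRUE
    hmrDf <- data.frame(
        contig = tssDf$contig[c(hmrAnnot, hmrNovel)],
        start = tssDf$position[c(hmrAnnot, hmrNovel)] - 250L,
        end = tssDf$position[c(hmrAnnot, hmrNovel)] + 250L,
        category = rep(c("annotated_tss", "novel_tss"),
                       c(length(hmrAnnot), length(hmrNovel))))

    ## ---- per-tissue CAGE tag profiles -------------------------------
    size <- 1 / cfg$tssCountDispersion
    mu <- cfg$tssCountMean
    profiles <- vector("list", cfg$nTissues)
    names(profiles) <- tissues
    tpmBase <- matrix(0, nrow = nAnnot, ncol = cfg$nTissues,
                      dimnames = list(annotDf$tx_id, tissues))
    genomeLen <- sum(as.numeric(seqlengths(contigs)))
    # locus table: every TSS plus the two arms of every divergent locus
    nTss <- nrow(tssDf)
    armDf <- data.frame(
        contig = rep(enhDf$contig, each = 2L),
        peak = as.vector(rbind(enhDf$midpoint - 80L,
                               enhDf$midpoint + 80L)),
        strand = rep(c("-", "+"), nrow(enhDf)),
        enhIdx = rep(seq_len(nrow(enhDf)), each = 2L))
    lociContig <- c(tssDf$contig, armDf$contig)
    lociPeak <- as.integer(c(tssDf$position, armDf$peak))
    lociStrand <- c(tssDf$strand, armDf$strand)
    nLoci <- length(lociPeak)
    tsIdx <- which(tssDf$class == "tissue_specific")
    famIdx <- which(tssDf$class == "family")
    decoyArmIdx <- nTss + which(armDf$enhIdx > nEnh)
    for (t in seq_len(cfg$nTissues)) {
        ts <- tissues[t]
        expressed <- rep(TRUE, nLoci)
        expressed[tsIdx] <- tsTissue == ts
        expressed[famIdx] <- family[t] == famOfLocus
        if (length(decoyArmIdx))
            expressed[decoyArmIdx] <- vapply(
                armDf$enhIdx[armDf$enhIdx > nEnh],
                function(k) ts %in% decoyTissueSets[[k - nEnh]],
                logical(1))
        cnt <- stats::rnbinom(nLoci, size = size, mu = mu)
        if (length(tsIdx))
            cnt[tsIdx] <- 11L + stats::rnbinom(length(tsIdx),
                                               size = size, mu = mu)
        cnt[!expressed] <- 0L
        tpmBase[, t] <- cnt[seq_len(nAnnot)]
        js <- .jitterSpread(cnt, lociPeak, cfg$jitterBp)
        df <- data.frame(contig = lociContig[js$idx], pos = js$pos,
                         strand = lociStrand[js$idx], count = js$count)
        nNoise <- stats::rpois(1L, cfg$noiseRate * genomeLen)
        if (nNoise > 0L) {
            ctgIdx <- sample(cfg$nContigs, nNoise, replace = TRUE)
            df <- rbind(df, data.frame(
                contig = seqlevels(contigs)[ctgIdx],
                pos = sample.int(cfg$contigLength, nNoise,
                                 replace = TRUE),
                strand = sample(c("+", "-"), nNoise, replace = TRUE),
                count = 1L))
        }
        key <- paste(df$contig, df$pos, df$strand)
        cnt <- rowsum(df$count, key)[, 1L]
        first <- !duplicated(key)
        gr <- GRanges(df$contig[first], IRanges(df$pos[first], width = 1L),
                      strand = df$strand[first], seqinfo = contigs)
        gr$count <- as.integer(unname(cnt[key[first]]))
        profiles[[t]] <- TagProfile(ts, gr)
    }

    ## ---- WGBS CpG tracks --------------------------------------------
    islandGR <- reduce(GRanges(hmrDf$contig,
                               IRanges(hmrDf$start, hmrDf$end)))
    cpgPos <- list()
    for (ctg in seqlevels(contigs)) {
        steps <- sample(150:250, ceiling(cfg$contigLength / 150),
                        replace = TRUE)
        bg <- cumsum(steps)
        bg <- bg[bg < cfg$contigLength - 1L]
        isl <- islandGR[seqnames(islandGR) == ctg]
        islPos <- unlist(lapply(seq_along(isl), function(k)
            seq(start(isl)[k], end(isl)[k], by = 25L)))
        pos <- sort(unique(c(bg, islPos)))
        inIsland <- overlapsAny(GRanges(ctg, IRanges(pos, width = 1L)),
                                isl)
        cpgPos[[ctg]] <- data.frame(pos = pos, island = inIsland)
    }
    cpgTracks <- list()
    wgbsTissues <- tissues[seq_len(cfg$nWgbsTissues)]
    cgmapRows <- list()
    for (ts in wgbsTissues) {
        recs <- list()
        for (ctg in seqlevels(contigs)) {
            cp <- cpgPos[[ctg]]
            nC <- nrow(cp)
            p <- ifelse(cp$island,
                        stats::rbeta(nC, cfg$islandMeth[1L],
                                     cfg$islandMeth[2L]),
                        stats::rbeta(nC, cfg$backgroundMeth[1L],
                                     cfg$backgroundMeth[2L]))
            nPlus <- stats::rpois(nC, cfg$coverageMean / 2)
            nMinus <- stats::rpois(nC, cfg$coverageMean / 2)
            mPlus <- stats::rbinom(nC, nPlus, p)
            mMinus <- stats::rbinom(nC, nMinus, p)
            recs[[ctg]] <- data.frame(
                contig = ctg,
                strand = rep(c("+", "-"), each = nC),
                position = c(cp$pos, cp$pos + 1L),
                methylated = c(mPlus, mMinus),
                coverage = c(nPlus, nMinus))
        }
        raw <- do.call(rbind, recs)
        raw <- raw[raw$coverage > 0L, , drop = FALSE]
        cpgTracks[[ts]] <- suppressMessages(
            mergeSymmetricCpGs(raw, sampleID = ts))
        cgmapRows[[ts]] <- raw
    }

    ## ---- transcript TPM ---------------------------------------------
    tpm <- tpmBase * exp(matrix(stats::rnorm(length(tpmBase), 0,
                                             cfg$tpmNoiseSd),
                                nrow(tpmBase)))
    tpm <- sweep(tpm, 2L, colSums(tpm), "/") * 1e6

    truth <- new("TruthTable", tss = tssDf, enhancers = enhDf,
                 hmrs = hmrDf, families = famDf, config = unclass(cfg))
    models <- .modelsFromTxRows(txRows, contigs)
    panel <- structure(list(truth = truth, contigs = contigs,
                            models = models, profiles = profiles,
                            cpgTracks = cpgTracks, tpm = tpm,
                            config = cfg, dir = outdir),
                       class = "CagePanel")
    if (!is.null(outdir)) .writePanel(panel, cgmapRows, outdir)
    panel
}

#' @noRd
.modelsFromTxRows <- function(txRows, contigs) {
    # vectorized assembly: the generator's transcripts all have two exons
    # with the CDS starting in the first and ending in the second
    ctg <- vapply(txRows, `[[`, character(1), "contig")
    str <- vapply(txRows, `[[`, character(1), "strand")
    txID <- vapply(txRows, `[[`, character(1), "tx_id")
    gnID <- vapply(txRows, `[[`, character(1), "gene_id")
    tss <- as.integer(vapply(txRows, `[[`, numeric(1), "tss"))
    e11 <- vapply(txRows, function(x) x$exons[1L, 1L], numeric(1))
    e12 <- vapply(txRows, function(x) x$exons[1L, 2L], numeric(1))
    e21 <- vapply(txRows, function(x) x$exons[2L, 1L], numeric(1))
    e22 <- vapply(txRows, function(x) x$exons[2L, 2L], numeric(1))
    cLo <- vapply(txRows, function(x) x$cds[1L], numeric(1))
    cHi <- vapply(txRows, function(x) x$cds[2L], numeric(1))

    txGR <- GRanges(ctg, IRanges(e11, e22), strand = str,
                    seqinfo = contigs)
    txGR$tx_id <- txID
    txGR$gene_id <- gnID
    txGR$tss <- tss

    lv <- factor(txID, levels = txID)
    mkGRL <- function(contig, lo, hi, strand, who) {
        keep <- lo <= hi
        gr <- GRanges(contig[keep], IRanges(lo[keep], hi[keep]),
                      strand = strand[keep], seqinfo = contigs)
        split(gr, lv[who][keep])
    }
    i2 <- rep(seq_along(txID), each = 2L)
    exons <- mkGRL(ctg[i2],
                   as.vector(rbind(e11, e21)),
                   as.vector(rbind(e12, e22)), str[i2], i2)
    cds <- mkGRL(ctg[i2],
                 as.vector(rbind(pmax(cLo, e11), pmax(cLo, e21))),
                 as.vector(rbind(pmin(cHi, e12), pmin(cHi, e22))),
                 str[i2], i2)
    # UTR pieces: exonic sequence flanking the CDS span
    leftLo <- e11; leftHi <- cLo - 1
    rightLo <- cHi + 1; rightHi <- e22
    plus <- str == "+"
    utr5 <- mkGRL(ctg,
                  ifelse(plus, leftLo, rightLo),
                  ifelse(plus, leftHi, rightHi), str,
                  seq_along(txID))
    utr3 <- mkGRL(ctg,
                  ifelse(plus, rightLo, leftLo),
                  ifelse(plus, rightHi, leftHi), str,
                  seq_along(txID))
    new("TranscriptModels", transcripts = txGR, exons = exons,
        cds = cds, utr5 = utr5, utr3 = utr3)
}

#' @noRd
.writePanel <- function(panel, cgmapRows, outdir) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (d in c("cage", "wgbs", "tpm"))
        dir.create(file.path(outdir, d), showWarnings = FALSE)
    .writeContigs(panel$contigs, file.path(outdir, "contigs.tsv"))
    .writeGFF3(panel$models, file.path(outdir, "annotation.gff3"))
    for (p in panel$profiles)
        writeTagBED(p, file.path(outdir, "cage",
                                 paste0(sampleID(p), ".bed")))
    for (ts in names(cgmapRows)) {
        raw <- cgmapRows[[ts]]
        o <- order(raw$contig, raw$position)
        raw <- raw[o, , drop = FALSE]
        out <- data.frame(
            contig = raw$contig,
            nucleotide = ifelse(raw$strand == "+", "C", "G"),
            position = raw$position, context = "CG",
            dinucleotide = "CG",
            level = round(ifelse(raw$coverage > 0,
                                 raw$methylated / raw$coverage, 0), 4L),
            methylated = raw$methylated, coverage = raw$coverage)
        utils::write.table(out, file.path(outdir, "wgbs",
                                          paste0(ts, ".cgmap.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE,
                           col.names = FALSE)
    }
    for (ts in colnames(panel$tpm)) {
        ab <- data.frame(target_id = rownames(panel$tpm),
                         length = 1500L, eff_length = 1400L,
                         est_counts = round(panel$tpm[, ts] / 10, 2L),
                         tpm = round(panel$tpm[, ts], 4L))
        utils::write.table(ab, file.path(outdir, "tpm",
                                         paste0(ts, "_abundance.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    truth <- panel$truth
    jsonlite::write_json(
        list(tss = truth@tss, enhancers = truth@enhancers,
             hmrs = truth@hmrs, families = truth@families,
             config = truth@config[!vapply(truth@config, is.function,
                                           logical(1))]),
        file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA,
        na = "null")
    invisible(outdir)
}

#' @noRd
.writeGFF3 <- function(models, path) {
    tx <- models@transcripts
    recs <- list()
    # gene records: span of their transcripts
    byGene <- split(seq_along(tx), tx$gene_id)
    geneGR <- unlist(GRangesList(lapply(byGene, function(i)
        range(granges(tx[i])))), use.names = FALSE)
    geneGR$type <- "gene"
    geneGR$ID <- names(byGene)
    geneGR$Parent <- CharacterList(vector("list", length(geneGR)))
    geneGR$phase <- NA_integer_
    strand(geneGR) <- strand(tx)[vapply(byGene, `[`, integer(1), 1L)]
    txGR <- granges(tx)
    txGR$type <- "mRNA"
    txGR$ID <- tx$tx_id
    txGR$Parent <- CharacterList(as.list(tx$gene_id))
    txGR$phase <- NA_integer_
    exGR <- unlist(models@exons, use.names = TRUE)
    exParent <- names(exGR); names(exGR) <- NULL
    exGR$type <- "exon"
    exGR$ID <- NA_character_
    exGR$Parent <- CharacterList(as.list(exParent))
    exGR$phase <- NA_integer_
    cdsGR <- unlist(models@cds, use.names = TRUE)
    cdsParent <- names(cdsGR); names(cdsGR) <- NULL
    if (length(cdsGR)) {
        cdsGR$type <- "CDS"
        cdsGR$ID <- NA_character_
        cdsGR$Parent <- CharacterList(as.list(cdsParent))
        # phase: bases to skip to reach the next codon start, 5' to 3'
        cdsGR$phase <- 0L
        for (id in unique(cdsParent)) {
            i <- which(cdsParent == id)
            if (as.character(strand(cdsGR))[i[1L]] == "-")
                i <- i[order(-start(cdsGR)[i])]
            else i <- i[order(start(cdsGR)[i])]
            cum <- cumsum(width(cdsGR)[i])
            cdsGR$phase[i] <- c(0L, (3L - cum[-length(cum)] %% 3L) %% 3L)
        }
    }
    all <- c(geneGR, txGR, exGR, if (length(cdsGR)) cdsGR)
    all <- sort(all, ignore.strand = TRUE)
    rtracklayer::export(all, path, format = "gff3")
    invisible(path)
}

#' Score recovery of planted features
#'
#' Compares called features with the planted truth. In `"points"` mode
#' (TSS/enhancer midpoints) truth and calls are matched one-to-one,
#' closest pair first, with a maximum matching distance of `toleranceBp`;
#' precision is the matched fraction of calls and recall the matched
#' fraction of truth. In `"intervals"` mode (hypomethylated regions) the
#' per-region matching uses any (>= 1 bp) overlap and the base-pair
#' Jaccard index of the two interval sets is reported as well.
#'
#' @param truth `GRanges`, or data.frame with `contig` + `position`
#'   (points) or `contig` + `start` + `end` (intervals).
#' @param called `GRanges` (point mode uses the `peak`/`midpoint` column
#'   when present), [TagClusterSet-class], [BidirClusterSet-class] or
#'   [HMRSet-class].
#' @param toleranceBp maximum peak-to-truth distance for a point match
#'   (default 10).
#' @param mode `"points"` or `"intervals"`.
#' @return list: `precision`, `recall`, `nMatched`, `nTruth`, `nCalled`
#'   and (interval mode) `jaccard`.
#' @export
scoreRecovery <- function(truth, called, toleranceBp = 10,
                          mode = c("points", "intervals")) {
    mode <- match.arg(mode)
    toGR <- function(x, pointCol = FALSE) {
        if (is(x, "HMRSet")) return(hmrRegions(x))
        if (is(x, "SummarizedExperiment")) x <- rowRanges(x)
        if (is(x, "GRanges")) return(x)
        if (!is.null(x$position))
            GRanges(x$contig, IRanges(x$position, width = 1L))
        else GRanges(x$contig, IRanges(x$start, x$end))
    }
    tGR <- toGR(truth); cGR <- toGR(called)
    nT <- length(tGR); nC <- length(cGR)
    if (nC == 0L)
        return(list(precision = NA_real_, recall = 0, nMatched = 0L,
                    nTruth = nT, nCalled = 0L,
                    jaccard = if (mode == "intervals") 0 else NULL))
    if (mode == "points") {
        tPos <- start(tGR)
        cPos <- cGR$peak
        if (is.null(cPos)) cPos <- cGR$midpoint
        if (is.null(cPos)) cPos <- start(cGR)
        pairs <- do.call(rbind, lapply(seq_len(nT), function(i) {
            same <- which(as.character(seqnames(cGR)) ==
                              as.character(seqnames(tGR))[i])
            d <- abs(cPos[same] - tPos[i])
            ok <- d <= toleranceBp
            if (!any(ok)) return(NULL)
            data.frame(t = i, c = same[ok], d = d[ok])
        }))
        tUsed <- logical(nT); cUsed <- logical(nC); nM <- 0L
        if (!is.null(pairs)) {
            pairs <- pairs[order(pairs$d, pairs$t, pairs$c), ,
                           drop = FALSE]
            for (k in seq_len(nrow(pairs))) {
                i <- pairs$t[k]; j <- pairs$c[k]
                if (!tUsed[i] && !cUsed[j]) {
                    tUsed[i] <- TRUE; cUsed[j] <- TRUE
                    nM <- nM + 1L
                }
            }
        }
        list(precision = nM / nC, recall = nM / nT, nMatched = nM,
             nTruth = nT, nCalled = nC)
    } else {
        ovl <- findOverlaps(tGR, cGR, ignore.strand = TRUE)
        inter <- sum(as.numeric(width(intersect(
            reduce(granges(tGR), ignore.strand = TRUE),
            reduce(granges(cGR), ignore.strand = TRUE),
            ignore.strand = TRUE))))
        uni <- sum(as.numeric(width(union(
            reduce(granges(tGR), ignore.strand = TRUE),
            reduce(granges(cGR), ignore.strand = TRUE)))))
        nM <- length(unique(queryHits(ovl)))
        list(precision = length(unique(subjectHits(ovl))) / nC,
             recall = nM / nT, nMatched = nM, nTruth = nT, nCalled = nC,
             jaccard = if (uni > 0) inter / uni else NA_real_)
    }
}
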
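#' Read per-bp strand-specific CAGE 5'-end tag counts
#'
#' Two interchange dialects are supported. `bed5p`: a BED6 file of
#' single-base records whose score column is the tag count at that 5'-end
#' position and whose strand column carries the tag strand.
#' `bedgraph_pair`: a pair of bedGraph files with suffixes
#' `.plus.bedGraph` / `.minus.bedGraph` holding integer counts; intervals
#' wider than one base are expanded to per-bp positions. The format is
#' inferred from the file name when `format = "auto"`.
#'
#' @param path path to the BED file, to either member of a bedGraph pair,
#'   or to the common prefix of a pair.
#' @param format one of `"auto"`, `"bed5p"`, `"bedgraph_pair"`.
#' @param sampleID library identifier; defaults to the file base name.
#' @param contigs optional `Seqinfo` attached to the positions.
#' @return a [TagProfile-class].
#' @export
readTagProfile <- function(path, format = c("auto", "bed5p",
                                            "bedgraph_pair"),
                           sampleID = NULL, contigs = NULL) {
    format <- match.arg(format)
    if (format == "auto") {
        format <- if (grepl("\\.bed$", path, ignore.case = TRUE))
            "bed5p" else "bedgraph_pair"
    }
    if (format == "bed5p") {
        gr <- rtracklayer::import(path, format = "BED")
        if (is.null(sampleID))
            sampleID <- sub("\\.bed$", "", basename(path),
                            ignore.case = TRUE)
        if (length(gr) && any(width(gr) != 1L))
            stop("bed5p records must be single-base 5'-end positions")
        if (length(gr) && any(strand(gr) == "*"))
            stop("bed5p records must be stranded")
        cnt <- gr$score
    } else {
        prefix <- sub("\\.(plus|minus)\\.bedGraph$", "", path)
        plusPath <- paste0(prefix, ".plus.bedGraph")
        minusPath <- paste0(prefix, ".minus.bedGraph")
        if (!file.exists(plusPath) || !file.exists(minusPath))
            stop("bedGraph pair not found for prefix '", prefix, "'")
        if (is.null(sampleID)) sampleID <- basename(prefix)
        rd <- function(p, str) {
            g <- rtracklayer::import(p, format = "bedGraph")
            if (length(g) == 0L) return(GRanges())
            if (any(g$score != round(g$score)))
                stop("non-integer bedGraph value in ", p)
            # expand multi-bp intervals to per-bp records
            perBp <- rep(seq_along(g), width(g))
            pos <- unlist(mapply(function(s, e) s:e, start(g), end(g),
                                 SIMPLIFY = FALSE))
            out <- GRanges(rep(seqnames(g), width(g)),
                           IRanges(pos, width = 1L), strand = str)
            out$score <- g$score[perBp]
            out
        }
        gr <- c(rd(plusPath, "+"), rd(minusPath, "-"))
        cnt <- gr$score
    }
    if (length(gr)) {
        keep <- cnt > 0
        gr <- gr[keep]; cnt <- cnt[keep]
    } else cnt <- integer(0)
    tg <- granges(gr)
    tg$count <- as.integer(round(cnt))
    tg <- sort(tg, ignore.strand = TRUE)
    if (!is.null(contigs)) {
        seqlevels(tg) <- seqlevels(contigs)
        seqinfo(tg) <- contigs
    }
    new("TagProfile", sampleID = sampleID, tags = tg,
        totalMapped = if (length(tg)) sum(as.numeric(tg$count)) else 0)
}

#' Construct a TagProfile from positions in memory
#'
#' @param sampleID library identifier.
#' @param tags width-1 stranded `GRanges` with a `count` column.
#' @return a [TagProfile-class].
#' @export
TagProfile <- function(sampleID, tags) {
    tags <- sort(tags, ignore.strand = TRUE)
    new("TagProfile", sampleID = sampleID, tags = tags,
        totalMapped = if (length(tags)) sum(as.numeric(tags$count)) else 0)
}

#' Normalize a tag profile to CAGE tags per million (CTPM)
#'
#' CTPM at a position is `count / totalMapped * 1e6`: the per-position tag
#' count divided by the total mapped tags of the library, scaled to one
#' million. Values of one sample therefore sum to 1e6 exactly (up to float
#' rounding).
#'
#' @param profile a [TagProfile-class].
#' @return a [CTPMProfile-class].
#' @export
toCTPM <- function(profile) {
    stopifnot(is(profile, "TagProfile"))
    if (profile@totalMapped <= 0) stop("empty library: totalMapped is 0")
    tg <- granges(profile@tags)
    tg$ctpm <- profile@tags$count / profile@totalMapped * 1e6
    new("CTPMProfile", sampleID = profile@sampleID, tags = tg,
        totalMapped = profile@totalMapped)
}

#' Pool per-bp signal across samples
#'
#' Sums the per-position signal of several libraries into one pooled track,
#' either on the raw-count scale or after CTPM normalization of each
#' library (`mode = "ctpm"`, the default, which weights libraries equally
#' regardless of depth).
#'
#' @param profiles list of [TagProfile-class] objects.
#' @param mode `"ctpm"` or `"raw"`.
#' @return width-1 stranded `GRanges`, sorted, with a `score` column
#'   holding the pooled signal.
#' @export
poolProfiles <- function(profiles, mode = c("ctpm", "raw")) {
    mode <- match.arg(mode)
    stopifnot(length(profiles) >= 1L)
    lv <- lapply(profiles, function(p) seqlevels(tagPositions(p)))
    common <- unique(unlist(lv))
    pieces <- lapply(profiles, function(p) {
        if (!is(p, "TagProfile")) stop("profiles must be TagProfile objects")
        tg <- tagPositions(p)
        val <- if (mode == "ctpm") {
            if (p@totalMapped <= 0) stop("empty library: ", sampleID(p))
            tg$count / p@totalMapped * 1e6
        } else as.numeric(tg$count)
        data.frame(seqnames = as.character(seqnames(tg)),
                   pos = start(tg), strand = as.character(strand(tg)),
                   val = val)
    })
    df <- do.call(rbind, pieces)
    if (nrow(df) == 0L)
        return(GRanges(score = numeric(0)))
    key <- paste(df$seqnames, df$pos, df$strand)
    sums <- rowsum(df$val, key)[, 1L]
    first <- !duplicated(key)
    gr <- GRanges(df$seqnames[first], IRanges(df$pos[first], width = 1L),
                  strand = df$strand[first], score = unname(sums[key[first]]))
    sort(gr, ignore.strand = TRUE)
}

#' Write a per-bp signal track as a strand pair of bedGraph files
#'
#' @param x a [TagProfile-class], [CTPMProfile-class] or a stranded
#'   width-1 `GRanges` with `count`/`ctpm`/`score` values.
#' @param prefix output prefix; `<prefix>.plus.bedGraph` and
#'   `<prefix>.minus.bedGraph` are written.
#' @return the two paths, invisibly.
#' @export
writeBedGraphPair <- function(x, prefix) {
    gr <- if (is(x, "GRanges")) x else tagPositions(x)
    val <- gr$score
    if (is.null(val)) val <- gr$count
    if (is.null(val)) val <- gr$ctpm
    if (is.null(val)) stop("no value column found")
    gr <- granges(gr)
    gr$score <- val
    paths <- paste0(prefix, c(".plus.bedGraph", ".minus.bedGraph"))
    for (i in 1:2) {
        sub <- gr[strand(gr) == c("+", "-")[i]]
        strand(sub) <- "*"
        rtracklayer::export(sort(sub), paths[i], format = "bedGraph")
    }
    invisible(paths)
}

#' Write a tag profile as single-base BED6 (score = count)
#'
#' @param profile a [TagProfile-class].
#' @param path output BED path.
#' @return the path, invisibly.
#' @export
writeTagBED <- function(profile, path) {
    tg <- tagPositions(profile)
    gr <- granges(tg)
    gr$name <- "."
    gr$score <- tg$count
    rtracklayer::export(gr, path, format = "BED")
    invisible(path)
}
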
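#' Bin an expression profile into equal-width bins
#'
#' Discretizes a numeric vector into `nBins` equal-width bins spanning
#' its `[min, max]` range (bin indices `0 .. nBins - 1`; the maximum falls
#' in the last bin). A constant vector occupies bin 0 only. With
#' `scheme = "frequency"`, quantile-based equal-frequency bins are used
#' instead.
#'
#' @param values numeric vector.
#' @param nBins number of bins (default 10).
#' @param scheme `"width"` (default) or `"frequency"`.
#' @return integer vector of bin indices.
#' @export
binProfile <- function(values, nBins = 10, scheme = c("width",
                                                      "frequency")) {
    scheme <- match.arg(scheme)
    stopifnot(nBins >= 1, length(values) >= 1)
    rg <- range(values)
    if (rg[1L] == rg[2L]) return(integer(length(values)))
    if (scheme == "width") {
        idx <- floor((values - rg[1L]) / (rg[2L] - rg[1L]) * nBins)
        as.integer(pmin(idx, nBins - 1L))
    } else {
        qs <- unique(stats::quantile(values,
                                     probs = seq(0, 1, length.out =
                                                     nBins + 1L)))
        as.integer(cut(values, breaks = qs, include.lowest = TRUE)) - 1L
    }
}

#' Plug-in mutual information of two binned profiles
#'
#' Mutual information in nats from the joint histogram of the two bin
#' vectors: `sum p(x, y) log(p(x, y) / (p(x) p(y)))`. MI of a vector with
#' itself equals the entropy of its bin distribution; independent profiles
#' give 0.
#'
#' @param xBins,yBins integer bin vectors of equal length.
#' @return MI in nats (>= 0 up to float rounding).
#' @export
mutualInformation <- function(xBins, yBins) {
    if (length(xBins) != length(yBins))
        stop("bin vectors must have equal length")
    j <- table(xBins, yBins) / length(xBins)
    px <- rowSums(j); py <- colSums(j)
    terms <- j * log(j / outer(px, py))
    max(0, sum(terms[j > 0]))
}

#' Mutual-information distance
#'
#' Maps MI to a dissimilarity in \[0, 1\]:
#' `delta = sqrt(1 - exp(-2 MI))`, `d = 1 - delta`. Independent profiles
#' (MI = 0) are at distance 1; the distance decreases strictly in MI and
#' tends to 0 as MI grows. For bivariate normal data `delta = |rho|`, the
#' absolute correlation, which is why MI is measured in nats.
#'
#' @param mi non-negative MI value(s) in nats.
#' @return distance value(s) in \[0, 1\].
#' @export
miDistance <- function(mi) {
    if (any(mi < 0)) stop("MI must be non-negative")
    1 - sqrt(1 - exp(-2 * mi))
}

#' Pairwise MI-distance matrix over tissues
#'
#' Bins every tissue profile (column) and computes the MI distance for
#' each tissue pair. Expression values are `log1p`-transformed before
#' equal-width binning by default, which keeps heavily skewed CTPM/TPM
#' profiles from collapsing into a single bin.
#'
#' @param mat numeric matrix, rows = clusters/transcripts, columns =
#'   tissues.
#' @param nBins bins per profile (default 10).
#' @param logScale `log1p`-transform before binning (default `TRUE`).
#' @param scheme binning scheme, see [binProfile()].
#' @return list with `mi` and `distance` (symmetric tissue x tissue
#'   matrices; the diagonal holds the self-MI transform).
#' @export
miDistanceMatrix <- function(mat, nBins = 10, logScale = TRUE,
                             scheme = "width") {
    stopifnot(is.matrix(mat), ncol(mat) >= 2)
    v <- if (logScale) log1p(mat) else mat
    bins <- apply(v, 2L, binProfile, nBins = nBins, scheme = scheme)
    nt <- ncol(mat)
    MI <- matrix(0, nt, nt, dimnames = list(colnames(mat), colnames(mat)))
    for (i in seq_len(nt)) for (j in i:nt) {
        MI[i, j] <- MI[j, i] <- mutualInformation(bins[, i], bins[, j])
    }
    list(mi = MI, distance = miDistance(MI))
}

#' Cluster tissues by MI distance
#'
#' Average-linkage hierarchical clustering of the pairwise MI-distance
#' matrix, returned with a Newick serialization of the dendrogram
#' (via [ape::write.tree()], branch lengths from the merge heights).
#'
#' @param mat cluster x tissue expression matrix (CTPM or TPM), or a
#'   [TagClusterSet-class] (its `ctpm` assay is used).
#' @param nBins,logScale,scheme see [miDistanceMatrix()].
#' @param linkage linkage method for [stats::hclust()] (default
#'   `"average"`).
#' @return list: `hclust`, `newick` (string), `distance`, `mi`.
#' @export
clusterTissues <- function(mat, nBins = 10, logScale = TRUE,
                           scheme = "width", linkage = "average") {
    if (is(mat, "SummarizedExperiment")) mat <- assay(mat, "ctpm")
    if (ncol(mat) < 3L) stop("need at least 3 tissues")
    dm <- miDistanceMatrix(mat, nBins = nBins, logScale = logScale,
                           scheme = scheme)
    hc <- stats::hclust(stats::as.dist(dm$distance), method = linkage)
    phy <- ape::as.phylo(hc)
    newick <- ape::write.tree(phy)
    list(hclust = hc, newick = newick, distance = dm$distance,
         mi = dm$mi)
}

#' Tissue x tissue cluster-sharing matrix
#'
#' `S[t, u]` counts the clusters present in both tissues `t` and `u`
#' (chord-diagram input); the diagonal holds per-tissue cluster counts.
#'
#' @param tcs a [TagClusterSet-class] (typically after filtering).
#' @param presenceRule,presenceMin see [presenceMatrix()].
#' @return symmetric integer matrix tissues x tissues.
#' @export
sharingMatrix <- function(tcs, presenceRule = NULL, presenceMin = NULL) {
    P <- presenceMatrix(tcs, presenceRule, presenceMin)
    mode(P) <- "numeric"
    S <- t(P) %*% P
    storage.mode(S) <- "integer"
    S
}

#' Correlate CAGE cluster expression with mRNA-Seq transcript expression
#'
#' Pairs each cluster with a transcript, flattens the matched (CTPM, TPM)
#' values over the tissues common to both matrices, and computes the
#' Pearson correlation with [stats::cor.test()].
#'
#' @param ctpm numeric matrix clusters x tissues.
#' @param tpm numeric matrix transcripts x tissues.
#' @param pairs data.frame with `cluster_id` and `tx_id` columns mapping
#'   rows of `ctpm` to rows of `tpm`.
#' @param logScale correlate on `log1p` values (default `TRUE`).
#' @return list: `r`, `p`, `n` (number of flattened pairs).
#' @export
correlateCageMrna <- function(ctpm, tpm, pairs, logScale = TRUE) {
    common <- intersect(colnames(ctpm), colnames(tpm))
    if (length(common) < 2L) stop("need at least 2 shared tissues")
    ci <- match(pairs$cluster_id, rownames(ctpm))
    ti <- match(pairs$tx_id, rownames(tpm))
    ok <- !is.na(ci) & !is.na(ti)
    x <- as.vector(ctpm[ci[ok], common, drop = FALSE])
    y <- as.vector(tpm[ti[ok], common, drop = FALSE])
    if (length(x) < 10L)
        stop("need at least 10 linked (cluster, transcript) observations")
    if (logScale) { x <- log1p(x); y <- log1p(y) }
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("zero-variance input")
    ct <- stats::cor.test(x, y, method = "pearson")
    list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Read a Kallisto abundance table
#'
#' @param path TSV with at least `target_id` and `tpm` columns.
#' @return data.frame with `target_id` and `tpm`.
#' @export
readKallistoAbundance <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("target_id", "tpm")
    if (!all(need %in% names(tab)))
        stop("abundance table needs columns: ",
             paste(need, collapse = ", "))
    tab[, need]
}

#' Write a square distance matrix in PHYLIP format
#'
#' @param d symmetric numeric matrix with dimnames.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePhylipMatrix <- function(d, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(d)), con)
    for (i in seq_len(nrow(d))) {
        writeLines(paste(formatC(rownames(d)[i], width = -10),
                         paste(sprintf("%.6f", d[i, ]), collapse = " ")),
                   con)
    }
    invisible(path)
}
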
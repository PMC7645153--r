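#' Read a contig table into a Seqinfo object
#'
#' The contig set plays the role a `BSgenome`/`Seqinfo` object plays in a
#' genome-backed workflow: it fixes contig names and lengths so every
#' downstream interval can be bounds-checked. Two dialects are accepted:
#' a two-column TSV (`name<TAB>length`, no header) and the samtools
#' `.fai` index (first two columns used).
#'
#' @param path path to the contig TSV or `.fai` file.
#' @return a [GenomeInfoDb::Seqinfo] object.
#' @examples
#' tf <- tempfile(); writeLines(c("chr1\t50000", "chr2\t30000"), tf)
#' readContigs(tf)
#' @export
readContigs <- function(path) {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 2L)
        stop("contig table needs at least two columns (name, length)")
    nm <- as.character(tab[[1L]])
    len <- suppressWarnings(as.numeric(tab[[2L]]))
    if (anyNA(len) || any(len <= 0))
        stop("contig lengths must be positive numbers")
    if (anyDuplicated(nm)) stop("contig names must be unique")
    Seqinfo(seqnames = nm, seqlengths = as.integer(len))
}

#' @noRd
.writeContigs <- function(seqinfo, path) {
    utils::write.table(
        data.frame(name = seqlevels(seqinfo),
                   length = unname(seqlengths(seqinfo))),
        path, sep = "\t", quote = FALSE, row.names = FALSE,
        col.names = FALSE)
    invisible(path)
}
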
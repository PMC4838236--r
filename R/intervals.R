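## Interval arithmetic. Public coordinates are 0-based half-open; GRanges
## (1-based closed) is used internally, converting with start+1.

# data.frame(chrom, start, end) [0-based half-open] -> GRanges
as_granges0 <- function(df, start_col = "start", end_col = "end") {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df[[start_col]] + 1L,
                              end = df[[end_col]]))
}

# insertion points -> width-1 GRanges
points_granges <- function(insertions) {
  GenomicRanges::GRanges(
    seqnames = insertions$chrom,
    ranges = IRanges::IRanges(start = insertions$pos + 1L, width = 1L))
}

#' Total length of an interval set union
#'
#' Measure (in bp) of the union of a set of genomic intervals; overlapping or
#' duplicated intervals are counted once. This is the "mappable genome" size
#' used as the hypergeometric population when applied to the union of all
#' gene windows.
#'
#' @param intervals `data.frame` with columns `chrom`, `start`, `end`
#'   (0-based half-open)
#' @return total union length in bp (numeric)
#' @examples
#' union_length(data.frame(chrom = "chr1", start = c(0, 5), end = c(10, 15)))
#' @export
union_length <- function(intervals) {
  if (nrow(intervals) == 0L) return(0)
  gr <- GenomicRanges::reduce(as_granges0(intervals))
  sum(as.numeric(GenomicRanges::width(gr)))
}

#' Gene windows: gene span extended by a flank
#'
#' Extends each gene body by `flank` bp on both sides, truncating at
#' chromosome position 0 (chromosome right ends are unknown to the gene
#' table, so there is no right truncation). With the default 25 kb flank the
#' windows capture local regulatory elements around each gene.
#'
#' @param genes gene table (see [read_gene_table()])
#' @param flank window extension in bp (default 25000)
#' @return the gene table with added columns `win_start`, `win_end`,
#'   `win_length`
#' @export
gene_windows <- function(genes, flank = 25000) {
  stopifnot(flank >= 0)
  genes$win_start <- pmax(0L, genes$tx_start - as.integer(flank))
  genes$win_end <- genes$tx_end + as.integer(flank)
  genes$win_length <- genes$win_end - genes$win_start
  genes
}
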
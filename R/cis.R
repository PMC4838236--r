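## Common insertion site (CIS) analysis: exclusive nearest-gene assignment
## within flanked windows and per-gene hypergeometric enrichment against the
## union-of-windows mappable genome.

#' Assign insertions to their nearest gene
#'
#' Each insertion is assigned to at most one gene: among the genes whose
#' window (`gene span +/- flank`) contains the insertion point, the one with
#' the smallest distance to the gene body (0 if the point lies inside the
#' body). Ties are broken by smaller distance to the TSS, then by
#' lexicographic `gene_id`. Insertions outside every window are returned
#' unassigned.
#'
#' @param insertions insertion `data.frame` (see [read_insertions_bed()])
#' @param genes gene table (see [read_gene_table()])
#' @param flank window flank in bp (default 25000)
#' @return list with elements `assignments` (data.frame: insertion index,
#'   `id`, `gene_id`, `body_dist`, `tss_dist`), `counts` (named integer
#'   vector of insertions per gene, all genes), and `unassigned` (subset of
#'   `insertions`)
#' @export
assign_insertions_to_genes <- function(insertions, genes, flank = 25000) {
  stopifnot(flank >= 0)
  if (nrow(genes) == 0L) stop("gene table is empty", call. = FALSE)
  insertions <- validate_insertions(insertions)
  counts <- setNames(integer(nrow(genes)), genes$gene_id)
  if (nrow(insertions) == 0L) {
    return(list(assignments = data.frame(insertion = integer(),
                                         id = character(),
                                         gene_id = character(),
                                         body_dist = integer(),
                                         tss_dist = integer()),
                counts = counts, unassigned = insertions))
  }
  win <- gene_windows(genes, flank)
  hits <- GenomicRanges::findOverlaps(
    points_granges(insertions),
    as_granges0(win, "win_start", "win_end"))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  pos <- insertions$pos[qi]
  body_dist <- pmax(0L, win$tx_start[si] - pos, pos - (win$tx_end[si] - 1L))
  tss_dist <- abs(pos - win$tss[si])
  o <- order(qi, body_dist, tss_dist, win$gene_id[si], method = "radix")
  first <- o[!duplicated(qi[o])]
  assignments <- data.frame(
    insertion = qi[first],
    id = insertions$id[qi[first]],
    gene_id = win$gene_id[si[first]],
    body_dist = body_dist[first],
    tss_dist = tss_dist[first],
    stringsAsFactors = FALSE)
  tab <- table(assignments$gene_id)
  counts[names(tab)] <- as.integer(tab)
  unassigned <- insertions[setdiff(seq_len(nrow(insertions)),
                                   assignments$insertion), , drop = FALSE]
  list(assignments = assignments, counts = counts, unassigned = unassigned)
}

#' Upper-tail hypergeometric CIS test
#'
#' Models the `n` insertion positions inside the mappable genome (population
#' of `N` bp, the union of all gene windows) as draws without replacement;
#' `K` of those bp belong to the window of the gene under test. Returns
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. For a one-sided 2x2 table
#' this coincides with the upper tail of Fisher's exact test.
#'
#' @param k insertions observed in the gene window
#' @param K window length (bp)
#' @param n total insertions in the window union
#' @param N union length of all gene windows (bp)
#' @return upper-tail p-value (vectorised over `k`, `K`)
#' @examples
#' hypergeometric_cis_test(k = 2, K = 5, n = 2, N = 10)  # 10/45
#' @export
hypergeometric_cis_test <- function(k, K, n, N) {
  if (any(K > N)) stop("K must not exceed N", call. = FALSE)
  if (any(k > n)) stop("k must not exceed n", call. = FALSE)
  if (any(k < 0 | K <= 0 | n < 0 | N <= 0))
    stop("counts must be non-negative and K, N positive", call. = FALSE)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment. `n_tests` may exceed the number
#' of supplied p-values when only a subset of the tests performed is being
#' reported.
#'
#' @param p vector of raw p-values in (0, 1]
#' @param n_tests number of tests in the family (default `length(p)`)
#' @return adjusted values, each `>=` its raw p, capped at 1
#' @export
bh_fdr <- function(p, n_tests = length(p)) {
  if (length(p) == 0L) return(numeric())
  # p = 0 admitted: extreme hypergeometric tails underflow to exact zero
  stopifnot(all(p >= 0 & p <= 1), n_tests >= length(p))
  p.adjust(p, method = "BH", n = n_tests)
}

#' Rank significant CIS targets
#'
#' The published ranking rule: keep genes with raw p below `alpha`, order by
#' insertion count `k` descending (ties: smaller p, then `gene_id`), truncate
#' to `top_n`. When the insertion count at the boundary is tied and
#' `expand_ties` is on, the list is expanded to include all genes sharing
#' that boundary count.
#'
#' @param results data.frame with at least `gene_id`, `k`, `p_raw`
#' @param alpha significance cut-off on the raw p (default 0.05); larger
#'   datasets may need a stricter value to keep the ranked list comparable
#' @param top_n list length (default 100)
#' @param expand_ties expand across a tied boundary count (default `FALSE`)
#' @return the filtered, ordered subset with a `rank` column
#' @export
rank_targets <- function(results, alpha = 0.05, top_n = 100,
                         expand_ties = FALSE) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)",
                                     call. = FALSE)
  stopifnot(top_n >= 1)
  sig <- results[results$p_raw < alpha, , drop = FALSE]
  if (nrow(sig) == 0L) {
    sig$rank <- integer()
    return(sig)
  }
  sig <- sig[order(-sig$k, sig$p_raw, sig$gene_id, method = "radix"), ,
             drop = FALSE]
  keep <- min(top_n, nrow(sig))
  if (expand_ties && nrow(sig) > keep) {
    boundary_k <- sig$k[keep]
    keep <- max(which(sig$k == boundary_k))
  }
  sig <- sig[seq_len(keep), , drop = FALSE]
  sig$rank <- seq_len(nrow(sig))
  rownames(sig) <- NULL
  sig
}

#' Common insertion site analysis
#'
#' Runs the full CIS stage: builds flanked gene windows, estimates the
#' mappable genome as the union of all windows (`N` bp), counts the
#' insertions falling inside that union (`n`; insertions outside it are
#' excluded from the null), assigns each insertion to its nearest gene, and
#' tests each gene's window (length `K`, count `k`) with the upper-tail
#' hypergeometric test. Raw p-values are BH-adjusted across all genes with at
#' least one assigned insertion.
#'
#' Note that assignment is exclusive (each insertion counts for one gene)
#' while each gene's test uses its full window length even where windows
#' overlap; output headers document this construction.
#'
#' @param insertions insertion data.frame
#' @param genes gene table
#' @param flank window flank in bp (default 25000)
#' @param alpha significance cut-off for the ranked list (default 0.05)
#' @param top_n ranked-list length (default 100)
#' @param expand_ties expand a tied boundary count in the ranked list
#' @return object of class `grip_cis`: list with `results` (per-gene
#'   data.frame `gene_id`, `symbol`, `k`, `K`, `n`, `N`, `p_raw`, `q`),
#'   `top` (ranked subset with `rank`), `unassigned`, `n`, `N`, `params`
#' @export
grip_cis <- function(insertions, genes, flank = 25000, alpha = 0.05,
                     top_n = 100, expand_ties = FALSE) {
  win <- gene_windows(genes, flank)
  N <- union_length(data.frame(chrom = win$chrom, start = win$win_start,
                               end = win$win_end))
  inside <- GenomicRanges::countOverlaps(
    points_granges(insertions),
    as_granges0(win, "win_start", "win_end")) > 0
  n <- sum(inside)
  asg <- assign_insertions_to_genes(insertions, genes, flank)
  res <- data.frame(gene_id = genes$gene_id, symbol = genes$symbol,
                    k = as.integer(asg$counts[genes$gene_id]),
                    K = win$win_length, n = n, N = N,
                    stringsAsFactors = FALSE)
  res$p_raw <- hypergeometric_cis_test(res$k, res$K, res$n, res$N)
  res$q <- NA_real_
  tested <- res$k > 0
  res$q[tested] <- bh_fdr(res$p_raw[tested])
  top <- rank_targets(res[tested, , drop = FALSE], alpha = alpha,
                      top_n = top_n, expand_ties = expand_ties)
  structure(list(results = res, top = top, unassigned = asg$unassigned,
                 assignments = asg$assignments, n = n, N = N,
                 params = list(flank = flank, alpha = alpha, top_n = top_n,
                               expand_ties = expand_ties)),
            class = "grip_cis")
}

#' @export
print.grip_cis <- function(x, ...) {
  cat("Common insertion site analysis (windowed hypergeometric test)\n")
  cat(sprintf("  mappable genome (union of %d gene windows, flank %d bp): %s bp\n",
              nrow(x$results), x$params$flank,
              format(x$N, big.mark = ",")))
  cat(sprintf("  insertions in window union: %d (unassigned outside: %d)\n",
              x$n, nrow(x$unassigned)))
  cat(sprintf("  genes with >= 1 insertion: %d; significant at alpha = %g: %d\n",
              sum(x$results$k > 0), x$params$alpha,
              sum(x$results$p_raw < x$params$alpha & x$results$k > 0)))
  cat(sprintf("  ranked targets returned: %d (top_n = %d)\n",
              nrow(x$top), x$params$top_n))
  invisible(x)
}

#' @export
summary.grip_cis <- function(object, n_show = 10, ...) {
  print(object)
  if (nrow(object$top)) {
    cat("\nTop targets (k = insertions, p_raw = hypergeometric upper tail):\n")
    print(head(object$top[, c("rank", "gene_id", "symbol", "k", "p_raw", "q")],
               n_show), row.names = FALSE)
  }
  invisible(object)
}

#' Write CIS results as TSV
#' @param x `grip_cis` object
#' @param path output path
#' @param what `"results"` (all genes) or `"top"` (ranked list)
#' @export
write_cis_tsv <- function(x, path, what = c("top", "results")) {
  what <- match.arg(what)
  df <- x[[what]]
  write_grip_tsv(df, path, params = c(
    x$params,
    list(stage = "cis", n = x$n, N = x$N,
         note = "exclusive nearest-gene assignment; K is the full window length even where windows overlap")))
}
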
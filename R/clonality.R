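## Clonal-selection diagnostics: proviral orientation bias ("heads-tails")
## per gene cluster and copy-number comparison of top targets vs the dataset.

#' Fisher exact test for proviral orientation bias
#'
#' Compares the forward/reverse orientation split of insertions in a gene
#' cluster against the remainder of the genome. The two-sided p sums the
#' probabilities of all tables with the observed margins whose point
#' probability does not exceed that of the observed table; `sided` selects a
#' one-sided tail instead.
#'
#' @param fwd_in,rev_in forward/reverse insertion counts in the cluster
#' @param fwd_out,rev_out counts in the rest of the genome
#' @param sided `"two.sided"` (default), `"greater"` (forward excess in the
#'   cluster) or `"less"`
#' @return Fisher exact p-value
#' @export
orientation_bias_test <- function(fwd_in, rev_in, fwd_out, rev_out,
                                  sided = "two.sided") {
  fisher_2x2(fwd_in, rev_in, fwd_out, rev_out, sided = sided)
}

#' Multiple-testing correction for orientation p-values
#'
#' Bonferroni and Benjamini-Hochberg corrections with an explicit family
#' size, which may exceed the number of p-values supplied (nominally
#' significant findings are typically corrected within the full screen, e.g.
#' 8 findings within a 100-gene screen).
#'
#' @param p vector of raw Fisher p-values
#' @param n_tests family size (default `length(p)`)
#' @return list with components `bonferroni` and `bh`
#' @export
correct_orientation_pvalues <- function(p, n_tests = length(p)) {
  if (n_tests < 1) stop("n_tests must be >= 1", call. = FALSE)
  if (n_tests < length(p))
    stop("n_tests must be at least length(p)", call. = FALSE)
  list(bonferroni = pmin(1, p * n_tests),
       bh = bh_fdr(p, n_tests = n_tests))
}

#' Per-gene orientation-bias screen
#'
#' For each requested gene, counts forward/reverse insertions assigned to its
#' cluster (nearest-gene assignment within the flanked window) against the
#' rest of the dataset, and applies the Fisher test with Bonferroni and BH
#' corrections across the screen. Unstranded insertions are ignored.
#'
#' @param insertions insertion data.frame
#' @param genes gene table
#' @param gene_ids genes to screen (default: all genes with assigned
#'   insertions); corrections use this screen as the family
#' @param flank window flank in bp (default 25000)
#' @param sided tail for the Fisher test (default two-sided)
#' @param n_tests family size for corrections (default `length(gene_ids)`)
#' @return data.frame `gene_id`, `fwd_in`, `rev_in`, `fwd_out`, `rev_out`,
#'   `p`, `p_bonf`, `p_bh`
#' @export
orientation_bias <- function(insertions, genes, gene_ids = NULL,
                             flank = 25000, sided = "two.sided",
                             n_tests = NULL) {
  insertions <- validate_insertions(insertions)
  stranded <- insertions[!is.na(insertions$strand), , drop = FALSE]
  asg <- assign_insertions_to_genes(stranded, genes, flank)
  fwd_tot <- sum(stranded$strand == "+")
  rev_tot <- sum(stranded$strand == "-")
  by_gene <- split(asg$assignments$insertion, asg$assignments$gene_id)
  if (is.null(gene_ids)) gene_ids <- names(by_gene)
  n_tests <- n_tests %||% length(gene_ids)
  rows <- lapply(gene_ids, function(g) {
    idx <- by_gene[[g]]
    fwd_in <- sum(stranded$strand[idx] == "+")
    rev_in <- sum(stranded$strand[idx] == "-")
    data.frame(gene_id = g, fwd_in = fwd_in, rev_in = rev_in,
               fwd_out = fwd_tot - fwd_in, rev_out = rev_tot - rev_in,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L)
    return(data.frame(gene_id = character(), fwd_in = integer(),
                      rev_in = integer(), fwd_out = integer(),
                      rev_out = integer(), p = numeric(),
                      p_bonf = numeric(), p_bh = numeric()))
  if (any(out$fwd_in + out$rev_in < 1))
    stop("gene(s) with no stranded insertions in cluster: ",
         paste(out$gene_id[out$fwd_in + out$rev_in < 1], collapse = ", "),
         call. = FALSE)
  out$p <- mapply(orientation_bias_test, out$fwd_in, out$rev_in,
                  out$fwd_out, out$rev_out, MoreArgs = list(sided = sided))
  corr <- correct_orientation_pvalues(out$p, n_tests = n_tests)
  out$p_bonf <- corr$bonferroni
  out$p_bh <- corr$bh
  rownames(out) <- NULL
  out
}

#' Mean junction-fragment copies per unique insertion
#'
#' The arithmetic mean of the per-insertion copy (fragment) count; a low mean
#' indicates that little clonal expansion followed integration. Reports round
#' half away from zero to one decimal.
#'
#' @param insertions insertion data.frame
#' @param report if `TRUE`, return the 1-decimal reported value instead of
#'   full precision
#' @return mean copies per insertion
#' @examples
#' # 20634 fragments over 8052 unique insertions -> 2.6 as reported
#' @export
copies_per_insertion <- function(insertions, report = FALSE) {
  insertions <- validate_insertions(insertions)
  if (nrow(insertions) == 0L)
    stop("empty insertion set", call. = FALSE)
  m <- mean(insertions$copies)
  if (report) round_half_away(m, 1) else m
}

#' Welch t-test on copy numbers
#'
#' Unpaired two-tailed Student's t-test with unequal variance
#' (Welch-Satterthwaite degrees of freedom), comparing the copy counts of
#' insertions at the top targets against the dataset as a whole.
#'
#' @param copies_top copy counts at the top target genes
#' @param copies_all copy counts of the comparison set
#' @return two-tailed p-value
#' @export
copy_number_test <- function(copies_top, copies_all) {
  if (length(copies_top) < 2 || length(copies_all) < 2)
    stop("both samples need at least 2 observations", call. = FALSE)
  if (stats::var(copies_top) == 0 && stats::var(copies_all) == 0)
    stop("degenerate samples: both have zero variance", call. = FALSE)
  t.test(copies_top, copies_all, var.equal = FALSE)$p.value
}
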
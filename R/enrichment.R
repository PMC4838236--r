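## Gene-set enrichment among top targets: chi-squared goodness of fit
## against a genome-background proportion, Fisher 2x2 comparisons, and
## expression-rank overlap profiling across sample sizes.

#' Chi-squared enrichment against a background proportion
#'
#' Goodness-of-fit of the annotated count among a top gene list against the
#' genome-wide background proportion `p0`:
#' `chi2 = (k - n p0)^2 / (n p0) + ((n - k) - n (1 - p0))^2 / (n (1 - p0))`,
#' with the upper-tail p from the chi-squared distribution on 1 df. No
#' continuity correction is applied.
#'
#' @param k annotated genes among the top list
#' @param n top-list size
#' @param p0 background proportion in (0, 1) (e.g. 0.022 for the genome-wide
#'   cancer-driver fraction)
#' @return list of class `grip_gof`: `k`, `n`, `p0`, `chi2`, `p`
#' @examples
#' gof_enrichment(11, 100, 0.022)$p  # ~2e-9
#' @export
gof_enrichment <- function(k, n, p0) {
  stopifnot(n >= 1)
  if (k > n) stop("k must not exceed n", call. = FALSE)
  if (k < 0) stop("k must be non-negative", call. = FALSE)
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)", call. = FALSE)
  e1 <- n * p0
  e0 <- n * (1 - p0)
  chi2 <- (k - e1)^2 / e1 + ((n - k) - e0)^2 / e0
  structure(list(k = k, n = n, p0 = p0, chi2 = chi2,
                 p = pchisq(chi2, df = 1, lower.tail = FALSE)),
            class = "grip_gof")
}

#' @export
print.grip_gof <- function(x, ...) {
  cat(sprintf(
    "Enrichment vs background: %d / %d annotated (%.1f%%) vs p0 = %.3g\n",
    x$k, x$n, 100 * x$k / x$n, x$p0))
  cat(sprintf("  chi-squared (1 df, no continuity correction) = %.4f, p = %.3g\n",
              x$chi2, x$p))
  invisible(x)
}

#' Annotate a top gene list against a gene set
#'
#' Symbol matching is case-insensitive; symbols of the top list that match
#' nothing in the set are listed, never silently dropped.
#'
#' @param top_genes character vector of top-list gene symbols
#' @param gene_set character vector of set symbols (see [read_gene_set()])
#' @return list `k` (top genes in the set), `fraction` (`k / |top|`),
#'   `matched`, `unmatched` (top symbols outside the set)
#' @export
annotate_top_list <- function(top_genes, gene_set) {
  if (length(top_genes) == 0L) stop("empty top list", call. = FALSE)
  hit <- toupper(top_genes) %in% toupper(gene_set)
  list(k = sum(hit), fraction = sum(hit) / length(top_genes),
       matched = top_genes[hit], unmatched = top_genes[!hit])
}

#' Fisher exact test on a 2x2 table
#'
#' Exact conditional test with fixed margins for the table
#' `rbind(c(a, b), c(c, d))`. The two-sided p sums point probabilities not
#' exceeding that of the observed table (with a small relative tolerance for
#' floating-point ties); `"greater"` is the upper tail in the `a` cell.
#'
#' @param a,b,c,d cell counts
#' @param sided `"two.sided"` (default), `"greater"`, or `"less"`
#' @return exact p-value
#' @examples
#' fisher_2x2(10, 8, 2, 16, sided = "greater")  # ~0.0058
#' @export
fisher_2x2 <- function(a, b, c, d, sided = c("two.sided", "greater", "less")) {
  sided <- match.arg(sided)
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("counts must be non-negative", call. = FALSE)
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0)
    stop("all margins must be positive", call. = FALSE)
  support <- max(0, c1 - r2):min(r1, c1)
  dens <- dhyper(support, r1, r2, c1)
  obs <- dhyper(a, r1, r2, c1)
  p <- switch(sided,
              two.sided = sum(dens[dens <= obs * (1 + 1e-7)]),
              greater = sum(dens[support >= a]),
              less = sum(dens[support <= a]))
  min(1, p)   # guard against summation epsilon above 1
}

#' Overlap of top targets with most highly expressed genes across sizes
#'
#' For a sweep of sample sizes, takes the top `s` genes of each ranked list,
#' measures their overlap, and estimates a Monte-Carlo p against uniform
#' draws from the gene universe ([mc_overlap_pvalue()]). A flat profile
#' indicates that the top integration targets are not simply the most
#' abundantly expressed genes.
#'
#' @param grip_ranked ranked integration-target list (data.frame `gene`,
#'   `score`)
#' @param expr_ranked ranked expression list
#' @param sizes ascending sample sizes, each within both list lengths
#' @param universe gene universe for the simulations (default: all genes of
#'   `expr_ranked`)
#' @param n_sim simulations per size (default 1e5)
#' @param seed RNG seed
#' @param expand_ties expand boundary score ties when cutting the tops
#' @return data.frame `size`, `observed`, `effective_size`, `p`,
#'   `transformed`, `is_bound`
#' @export
expression_overlap_profile <- function(grip_ranked, expr_ranked, sizes,
                                       universe = NULL, n_sim = 1e5,
                                       seed = NULL, expand_ties = FALSE) {
  if (is.unsorted(sizes, strictly = TRUE))
    stop("sizes must be strictly ascending", call. = FALSE)
  if (any(sizes > nrow(grip_ranked)) || any(sizes > nrow(expr_ranked)))
    stop("each size must be within both list lengths", call. = FALSE)
  universe <- universe %||% expr_ranked$gene
  rows <- lapply(seq_along(sizes), function(i) {
    s <- sizes[i]
    ov <- top_gene_overlap(grip_ranked, expr_ranked, size = s,
                           expand_ties = expand_ties)
    top_b <- top_ranked(expr_ranked, s, expand_ties)
    mc <- mc_overlap_pvalue(universe, top_b,
                            effective_size = ov$size_a,
                            observed = ov$observed, n_sim = n_sim,
                            seed = if (is.null(seed)) NULL else seed + i)
    data.frame(size = s, observed = ov$observed,
               effective_size = ov$size_a, p = mc$p,
               transformed = mc$transformed, is_bound = mc$is_bound)
  })
  do.call(rbind, rows)
}
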
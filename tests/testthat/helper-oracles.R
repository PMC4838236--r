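# Independent oracles and small fixture builders shared across the suite.
# Oracles deliberately avoid the code paths they check.

# Upper-tail hypergeometric by direct combinatorial enumeration:
# P(X >= k) for X ~ Hyper(population N bp, K success bp, n draws).
enum_hyper_tail <- function(k, K, n, N) {
  j <- max(0, k):min(K, n)
  j <- j[j >= n - (N - K)]  # feasible counts only
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Fisher exact p for table rbind(c(a,b),(c,d)) by enumerating all tables
# with the observed margins, probabilities from choose() directly.
enum_fisher <- function(a, b, c, d, sided = "two.sided") {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  j <- max(0, c1 - r2):min(r1, c1)
  pr <- choose(r1, j) * choose(r2, c1 - j) / choose(n, c1)
  obs <- pr[j == a]
  switch(sided,
         two.sided = sum(pr[pr <= obs * (1 + 1e-7)]),
         greater = sum(pr[j >= a]),
         less = sum(pr[j <= a]))
}

# Exact P(overlap >= obs) for a uniform without-replacement sample of size s
# from `universe`, overlapped with `top`, by exhaustive subset enumeration.
enum_overlap_tail <- function(universe, top, s, obs) {
  subsets <- utils::combn(length(universe), s)
  in_top <- universe %in% top
  mean(colSums(matrix(in_top[subsets], nrow = s)) >= obs)
}

# minimal gene table builder (0-based half-open spans)
make_genes <- function(gene_id, chrom, strand, tx_start, tx_end,
                       symbol = gene_id) {
  g <- data.frame(gene_id = gene_id, symbol = symbol, chrom = chrom,
                  strand = strand, tx_start = as.integer(tx_start),
                  tx_end = as.integer(tx_end), stringsAsFactors = FALSE)
  g$tss <- ifelse(g$strand == "+", g$tx_start, g$tx_end - 1L)
  g
}

make_insertions <- function(chrom, pos, strand = "+", copies = 1L,
                            id = NULL) {
  n <- max(length(chrom), length(pos))
  data.frame(chrom = rep_len(chrom, n), pos = as.integer(rep_len(pos, n)),
             strand = rep_len(strand, n),
             copies = as.integer(rep_len(copies, n)),
             id = rep_len(id %||% sprintf("i%03d", seq_len(n)), n),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_lines_tmp <- function(lines, ext = ".bed") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
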
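test_that("insertions go to the gene with the nearest body, ties to the nearer TSS", {
  genes <- make_genes(c("left", "right"), "chr1", c("+", "-"),
                      tx_start = c(10000, 55000), tx_end = c(20000, 90000))
  # inside the body of `left`
  asg <- assign_insertions_to_genes(make_insertions("chr1", 15000), genes)
  expect_equal(asg$assignments$gene_id, "left")
  expect_equal(asg$assignments$body_dist, 0L)
  # 30 kb from the only window edge: unassigned
  far <- assign_insertions_to_genes(
    make_insertions("chr1", 120000),
    make_genes("only", "chr1", "+", 10000, 20000))
  expect_equal(nrow(far$assignments), 0L)
  expect_equal(nrow(far$unassigned), 1L)
  gene_tie <- make_genes(c("aa", "bb"), "chr1", c("+", "+"),
                         tx_start = c(10000, 40000), tx_end = c(20000, 90000))
  # pos 25000: 5 kb from aa body (TSS dist 15 kb) and 15 kb from bb: aa wins
  t1 <- assign_insertions_to_genes(make_insertions("chr1", 25000), gene_tie)
  expect_equal(t1$assignments$gene_id, "aa")
  # pos 30000: 10 kb from both bodies; TSS distances 20 kb (aa) vs 10 kb (bb)
  t2 <- assign_insertions_to_genes(make_insertions("chr1", 30000), gene_tie)
  expect_equal(t2$assignments$gene_id, "bb")
})

test_that("assignment conserves insertions and empty input yields empty counts", {
  set.seed(5)
  genes <- make_genes(paste0("g", 1:6), rep(c("chr1", "chr2"), 3),
                      sample(c("+", "-"), 6, TRUE),
                      tx_start = rep(c(1e5, 4e5, 8e5), 2),
                      tx_end = rep(c(1.5e5, 4.8e5, 9e5), 2))
  ins <- make_insertions(sample(c("chr1", "chr2", "chr9"), 200, TRUE),
                         sample.int(1.2e6, 200))
  asg <- assign_insertions_to_genes(ins, genes)
  expect_equal(nrow(asg$assignments) + nrow(asg$unassigned), nrow(ins))
  expect_equal(sum(asg$counts), nrow(asg$assignments))
  empty <- assign_insertions_to_genes(ins[0, ], genes)
  expect_equal(sum(empty$counts), 0L)
})

test_that("hypergeometric CIS tail matches enumeration and is monotone in k", {
  expect_equal(hypergeometric_cis_test(0, 5, 3, 50), 1)
  expect_equal(hypergeometric_cis_test(2, 10, 4, 10), 1)  # K = N
  expect_equal(hypergeometric_cis_test(2, 5, 2, 10), 10 / 45)
  # spot agreement with the combinatorial oracle
  set.seed(8)
  for (i in 1:50) {
    N <- sample(5:60, 1); K <- sample.int(N, 1); n <- sample.int(N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeometric_cis_test(k, K, n, N),
                 enum_hyper_tail(k, K, n, N), tolerance = 1e-12)
  }
  p <- hypergeometric_cis_test(0:10, 40, 10, 200)
  expect_true(all(diff(p) <= 1e-12))
  expect_error(hypergeometric_cis_test(3, 30, 2, 20), "K")
  expect_error(hypergeometric_cis_test(5, 10, 3, 20), "k")
})

test_that("BH adjustment follows the step-up rule and dominates the raw p", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(13)
  for (i in 1:10) {
    p <- runif(sample(2:30, 1))
    q <- bh_fdr(p)
    expect_true(all(q >= p - 1e-12) && all(q <= 1))
    # independent step-up computation
    m <- length(p); o <- order(p, decreasing = TRUE)
    expected <- pmin(1, cummin(p[o] * m / rev(seq_len(m))))[order(o)]
    expect_equal(q, expected)
  }
  expect_equal(bh_fdr(numeric()), numeric())
})

test_that("target ranking filters by alpha, orders by count, and can expand boundary ties", {
  res <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                    k = c(7L, 3L, 9L, 3L, 3L),
                    p_raw = c(0.001, 0.02, 0.5, 0.01, 0.02))
  expect_equal(nrow(rank_targets(data.frame(gene_id = "a", k = 5L,
                                            p_raw = 0.2))), 0L)
  r <- rank_targets(res)
  # c is filtered (p >= alpha); order: k desc, then p, then gene_id
  expect_equal(r$gene_id, c("a", "d", "b", "e"))
  expect_equal(r$rank, 1:4)
  expect_equal(nrow(rank_targets(res, top_n = 2)), 2L)
  expanded <- rank_targets(res, top_n = 2, expand_ties = TRUE)
  expect_equal(nrow(expanded), 4L)  # boundary k = 3 has a 3-way tie
  expect_error(rank_targets(res, alpha = 1.2), "alpha")
})

test_that("the CIS fit exposes consistent counts and BH-dominated q values", {
  cfg <- grip_sim_config(seed = 3, n_insertions = 800, n_genes = 40)
  sim <- simulate_dataset(cfg)
  fit <- grip_cis(sim$insertions, sim$genes)
  res <- fit$results
  expect_equal(fit$n + nrow(fit$unassigned), nrow(sim$insertions))
  expect_equal(sum(res$k), fit$n)
  expect_true(all(res$K <= res$N))
  tested <- !is.na(res$q)
  expect_true(all(res$q[tested] >= res$p_raw[tested] - 1e-12))
  expect_equal(unique(res$N), union_length(data.frame(
    chrom = sim$genes$chrom,
    start = pmax(0, sim$genes$tx_start - 25000),
    end = sim$genes$tx_end + 25000)))
  expect_output(print(fit), "mappable genome")
  expect_output(summary(fit), "Top targets")
})
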
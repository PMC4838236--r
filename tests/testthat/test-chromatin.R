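test_that("global overlap assigns insertions to mark combinations exactly", {
  ins <- make_insertions("chr1", c(5, 100, 205))
  empty_pk <- data.frame(chrom = character(), start = integer(),
                         end = integer(), score = numeric())
  ov0 <- global_overlap(ins, list(A = empty_pk))
  expect_equal(ov0$combinations$combination, "none")
  expect_equal(ov0$combinations$count, 3L)
  A <- data.frame(chrom = "chr1", start = c(0L, 200L), end = c(10L, 210L),
                  score = NA_real_)
  B <- data.frame(chrom = "chr1", start = 0L, end = 10L, score = NA_real_)
  ov <- global_overlap(ins, list(A = A, B = B))
  cc <- setNames(ov$combinations$count, ov$combinations$combination)
  expect_equal(cc[["A+B"]], 1L)   # pos 5 in both
  expect_equal(cc[["A"]], 1L)     # pos 205 in A's second peak
  expect_equal(cc[["none"]], 1L)  # pos 100
  expect_equal(sum(ov$combinations$count), nrow(ins))
})

test_that("global overlap matches a brute-force point-in-interval oracle", {
  set.seed(55)
  ins <- make_insertions("chr1", sample.int(1000, 10))
  mk <- function() {
    s <- sort(sample.int(900, 4))
    data.frame(chrom = "chr1", start = s, end = s + sample.int(80, 4),
               score = NA_real_)
  }
  pks <- list(m1 = mk(), m2 = mk())
  ov <- global_overlap(ins, pks)
  oracle <- vapply(pks, function(pk) vapply(ins$pos, function(p)
    any(p >= pk$start & p < pk$end), NA), logical(nrow(ins)))
  expect_equal(unname(ov$membership), unname(oracle))
  expect_equal(unname(ov$totals), unname(colSums(oracle)))
  # half-open boundaries: a point at `end` is outside, at `start` inside
  edge <- global_overlap(
    make_insertions("chr1", c(10, 19, 20)),
    list(m = data.frame(chrom = "chr1", start = 10L, end = 20L,
                        score = NA_real_)))
  expect_equal(unname(edge$totals), 2)
})

test_that("pairwise overlap p uses the supplied population", {
  ins <- make_insertions("chr1", c(5, 15, 500))
  pk <- data.frame(chrom = "chr1", start = 0L, end = 20L, score = NA_real_)
  ov <- global_overlap(ins, list(m = pk),
                       population = data.frame(chrom = "chr1", start = 0,
                                               end = 1000))
  expect_equal(ov$pairwise$p,
               enum_hyper_tail(2, 20, 3, 1000), tolerance = 1e-12)
})

test_that("top-list overlap respects the size cut and expands score ties", {
  rk <- function(genes, scores) data.frame(gene = genes, score = scores,
                                           stringsAsFactors = FALSE)
  a <- rk(paste0("g", 1:20), 20:1)
  expect_equal(top_gene_overlap(a, a, size = 10)$observed, 10L)
  b <- rk(paste0("h", 1:20), 20:1)
  expect_equal(top_gene_overlap(a, b, size = 10)$observed, 0L)
  # scores tie across the boundary: ranks 4-6 share score 5
  t1 <- rk(paste0("g", 1:8), c(9, 8, 7, 5, 5, 5, 2, 1))
  ov <- top_gene_overlap(t1, a, size = 4, expand_ties = TRUE)
  expect_equal(ov$size_a, 6L)
  expect_equal(top_gene_overlap(t1, a, size = 4,
                                expand_ties = FALSE)$size_a, 4L)
  expect_error(top_gene_overlap(a, b, size = 0), "size")
})

test_that("Monte-Carlo overlap p matches exact enumeration on small universes", {
  universe <- LETTERS[1:5]
  top <- c("A", "B")
  expect_equal(enum_overlap_tail(universe, top, 2, 2), 1 / 10)
  for (method in c("hypergeometric", "resample")) {
    mc <- mc_overlap_pvalue(universe, top, effective_size = 2, observed = 2,
                            n_sim = 1e5, seed = 101, method = method)
    se <- sqrt(0.1 * 0.9 / 1e5)
    expect_lt(abs(mc$p - 0.1), 3 * se)
  }
  # larger universes, several configurations
  set.seed(33)
  for (i in 1:4) {
    n_u <- sample(8:12, 1)
    universe <- paste0("u", seq_len(n_u))
    top <- sample(universe, sample(3:5, 1))
    s <- sample(3:5, 1)
    obs <- sample(0:min(s, length(top)), 1)
    exact <- enum_overlap_tail(universe, top, s, obs)
    mc <- mc_overlap_pvalue(universe, top, s, obs, n_sim = 1e5, seed = i)
    se <- sqrt(exact * (1 - exact) / 1e5)
    expect_lt(abs(mc$p - exact), 3 * se + 1e-9)
  }
})

test_that("Monte-Carlo results are deterministic given a seed and validate input", {
  u <- paste0("u", 1:50)
  top <- u[1:10]
  a <- mc_overlap_pvalue(u, top, 10, 4, n_sim = 2e4, seed = 9)
  b <- mc_overlap_pvalue(u, top, 10, 4, n_sim = 2e4, seed = 9)
  expect_identical(a$exceed, b$exceed)
  expect_identical(a$p, b$p)
  expect_equal(mc_overlap_pvalue(u, top, 5, 0, n_sim = 1000, seed = 1)$p, 1)
  expect_error(mc_overlap_pvalue(u, top, 100, 1, 10), "universe")
  expect_error(mc_overlap_pvalue(u, top, 5, 6, 10), "observed")
})

test_that("zero exceedances reports the 1/n_sim bound; add-one estimator differs", {
  u <- paste0("u", 1:100)
  # observed overlap of 10 is impossible: only 4 top genes in the universe
  top <- u[1:4]
  mc <- mc_overlap_pvalue(u, top, effective_size = 10, observed = 10,
                          n_sim = 5000, seed = 2)
  expect_equal(mc$exceed, 0)
  expect_true(mc$is_bound)
  expect_equal(mc$p, 1 / 5000)
  expect_equal(mc$transformed, -log10(1 / 5000))
  mc1 <- mc_overlap_pvalue(u, top, 10, 10, n_sim = 5000, seed = 2,
                           estimator = "add_one")
  expect_equal(mc1$p, 1 / 5001)
  expect_false(mc1$is_bound)
})

test_that("the -log10 transform is exact and invertible", {
  expect_equal(transform_p(1), 0)
  expect_equal(transform_p(0.001402), 2.853251986, tolerance = 1e-9)
  t <- c(0, 0.5, 3, 7.778151)
  expect_equal(transform_p(10^(-t)), t)
  expect_error(transform_p(0), "p must")
  expect_error(transform_p(1.2), "p must")
})
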
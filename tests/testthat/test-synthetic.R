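test_that("simulated genomes are deterministic, disjoint, and respect the config", {
  cfg <- grip_sim_config(seed = 19)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)
  expect_equal(nrow(g1), cfg$n_genes)
  expect_true(all(g1$tx_end - g1$tx_start >= cfg$gene_length_min))
  expect_true(all(g1$tx_end - g1$tx_start <= cfg$gene_length_max))
  expect_true(all(g1$tx_end <= cfg$chrom_length))
  # pairwise disjoint by interval scan per chromosome
  for (ch in unique(g1$chrom)) {
    gg <- g1[g1$chrom == ch, ]
    gg <- gg[order(gg$tx_start), ]
    expect_true(all(gg$tx_start[-1] >= gg$tx_end[-nrow(gg)]))
  }
  expect_true(all(g1$tss >= g1$tx_start & g1$tss < g1$tx_end))
  expect_equal(nrow(simulate_genome(grip_sim_config(n_genes = 0))), 0L)
  # a different seed moves the genes
  expect_false(identical(simulate_genome(grip_sim_config(seed = 20)), g1))
  expect_error(simulate_genome(grip_sim_config(
    n_genes = 10, n_chroms = 1, chrom_length = 50000,
    gene_length_min = 20000, gene_length_max = 20000)), "packing")
})

test_that("peak placement follows peak_fraction and sits on the TSS", {
  cfg <- grip_sim_config(seed = 29, n_genes = 200, n_chroms = 8)
  genes <- simulate_genome(cfg)
  expect_equal(nrow(simulate_peaks(genes, grip_sim_config(
    seed = 29, n_genes = 200, n_chroms = 8, peak_fraction = 0))), 0L)
  all_pk <- simulate_peaks(genes, grip_sim_config(
    seed = 29, n_genes = 200, n_chroms = 8, peak_fraction = 1))
  expect_equal(nrow(all_pk), nrow(genes))
  pk <- simulate_peaks(genes, cfg)
  # binomial tolerance around the configured fraction
  expect_lt(abs(nrow(pk) / nrow(genes) - cfg$peak_fraction),
            3 * sqrt(0.3 * 0.7 / 200))
  expect_true(all(pk$end - pk$start == cfg$peak_width))
  expect_setequal(peak_bearing_genes(genes, all_pk), genes$gene_id)
})

test_that("pure background insertions are uniform over the genome", {
  cfg <- grip_sim_config(seed = 37, pi = 0, n_insertions = 2000)
  sim <- simulate_dataset(cfg)
  expect_true(all(sim$truth$channel == "background"))
  # Kolmogorov-Smirnov against uniform within each chromosome
  for (ch in unique(sim$insertions$chrom)) {
    pos <- sim$insertions$pos[sim$insertions$chrom == ch]
    ks <- suppressWarnings(ks.test(pos, "punif", 0, cfg$chrom_length))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("a fully biased draw lands within the flank of peak-bearing TSSs", {
  cfg <- grip_sim_config(seed = 41, pi = 1, n_insertions = 1000)
  sim <- simulate_dataset(cfg)
  expect_true(all(sim$truth$channel == "biased"))
  pg <- peak_bearing_genes(sim$genes, sim$peaks)
  expect_true(all(sim$truth$gene_id %in% pg))
  tss <- sim$genes$tss[match(sim$truth$gene_id, sim$genes$gene_id)]
  expect_true(all(abs(sim$insertions$pos - tss) <= cfg$flank))
  # offsets avoid the exclusion zone and centre near the configured mode
  expect_true(all(abs(sim$truth$offset) >= cfg$offset_exclusion))
  expect_lt(abs(mean(abs(sim$truth$offset)) - cfg$tss_offset_mode), 200)
})

test_that("the biased-channel fraction tracks pi within binomial error", {
  cfg <- grip_sim_config(seed = 43, pi = 0.6, n_insertions = 4000)
  sim <- simulate_dataset(cfg)
  frac <- mean(sim$truth$channel == "biased")
  expect_lt(abs(frac - 0.6), 3 * sqrt(0.6 * 0.4 / 4000))
  # copies follow 1 + Geometric(p): mean 1 + (1-p)/p
  exp_mean <- 1 + (1 - cfg$copies_geometric_p) / cfg$copies_geometric_p
  expect_lt(abs(mean(sim$insertions$copies) - exp_mean), 0.15)
  expect_true(all(sim$insertions$copies >= 1))
})

test_that("biased insertions show the double peak with a trough at the TSS", {
  cfg <- grip_sim_config(seed = 47, n_insertions = 6000, pi = 1)
  sim <- simulate_dataset(cfg)
  d <- distance_to_nearest_tss(sim$insertions, sim$genes)
  h <- tss_histogram(d$distance, bin_width = 500, range = 5000)
  mode_bins <- h$count[h$bin_start %in% c(-2000, -1500, 1000, 1500)]
  centre <- h$count[h$bin_start == -500 | h$bin_start == 0]
  expect_gt(min(mode_bins), 2 * max(centre))
})

test_that("orientation bias follows beta per gene", {
  cfg0 <- grip_sim_config(seed = 53, n_insertions = 3000)
  sim0 <- simulate_dataset(cfg0)
  frac_fwd <- mean(sim0$insertions$strand == "+")
  expect_lt(abs(frac_fwd - 0.5), 3 * sqrt(0.25 / 3000))
  pg <- peak_bearing_genes(sim0$genes, sim0$peaks)
  target <- pg[1]
  cfg1 <- grip_sim_config(seed = 53, n_insertions = 3000, pi = 1,
                          hot_genes = target,
                          beta_genes = setNames(0.95, target))
  sim1 <- simulate_dataset(cfg1)
  at_target <- sim1$truth$gene_id == target
  expect_gt(sum(at_target), 30)
  expect_gt(mean(sim1$insertions$strand[at_target] == "+"), 0.85)
  expect_lt(abs(mean(sim1$insertions$strand[!at_target] == "+") - 0.5), 0.05)
})

test_that("stage substreams regenerate independently from one master seed", {
  cfg <- grip_sim_config(seed = 59)
  genes <- simulate_genome(cfg)
  # changing insertion-stage knobs leaves the genome and peaks untouched
  cfg2 <- grip_sim_config(seed = 59, pi = 0.9, n_insertions = 123,
                          hot_genes = genes$gene_id[1])
  expect_identical(simulate_genome(cfg2), genes)
  expect_identical(simulate_peaks(genes, cfg2), simulate_peaks(genes, cfg))
  s1 <- simulate_insertions(genes, simulate_peaks(genes, cfg), cfg)
  s2 <- simulate_insertions(genes, simulate_peaks(genes, cfg), cfg)
  expect_identical(s1, s2)
})
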
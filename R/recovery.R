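## Built-in simulation studies: parameter recovery for the CIS stage and
## calibration/power of the orientation-bias screen. Used by the package's
## validation suite and reusable for sensitivity analyses.

#' One CIS hot-gene recovery replicate
#'
#' Simulates a genome and peak set, designates `n_hot` peak-bearing genes as
#' hot targets with a multiplicative weight, draws insertions, runs the CIS
#' stage, and reports how many designated genes appear among the top
#' `top_n` ranked targets.
#'
#' @param seed replicate seed
#' @param n_hot number of designated hot genes (default 10)
#' @param hot_weight multiplicative targeting weight (default 20)
#' @param n_insertions insertions to draw (default 5000)
#' @param top_n ranked-list size examined (default `n_hot`)
#' @param pi chromatin-bias mixture weight (default 0.6)
#' @return list `recovered` (hot genes in the top list), `n_hot`,
#'   `hot_genes`, `top`
#' @export
sim_cis_recovery <- function(seed, n_hot = 10, hot_weight = 20,
                             n_insertions = 5000, top_n = n_hot, pi = 0.6) {
  base <- grip_sim_config(seed = seed, pi = pi,
                          n_insertions = n_insertions)
  genes <- simulate_genome(base)
  peaks <- simulate_peaks(genes, base)
  pg <- peak_bearing_genes(genes, peaks)
  if (length(pg) < n_hot)
    stop("fewer than n_hot peak-bearing genes; raise peak_fraction",
         call. = FALSE)
  hot <- pg[seq_len(n_hot)]
  cfg <- grip_sim_config(seed = seed, pi = pi, n_insertions = n_insertions,
                         hot_genes = hot, hot_weight = hot_weight)
  ins <- simulate_insertions(genes, peaks, cfg)$insertions
  fit <- grip_cis(ins, genes, top_n = top_n)
  list(recovered = length(intersect(fit$top$gene_id, hot)),
       n_hot = n_hot, hot_genes = hot, top = fit$top)
}

#' One orientation-bias screen replicate
#'
#' Simulates a dataset in which `n_hot` heavily targeted genes carry a
#' forward-orientation probability `beta_hot` while every other insertion is
#' unbiased (`beta = 0.5`), then runs the per-gene orientation screen. With
#' `beta_hot = 0.5` the replicate probes type-I error; with a strong bias
#' (e.g. 0.95) it probes power at the designated genes, which the hot
#' weight guarantees carry many insertions.
#'
#' @param seed replicate seed
#' @param beta_hot forward probability at the designated genes (default 0.5)
#' @param n_hot designated genes (default 10)
#' @param hot_weight targeting weight (default 20)
#' @param n_insertions insertions to draw (default 4000)
#' @param min_cluster minimum stranded insertions for a gene to enter the
#'   screen (default 1)
#' @return list `screen` (the [orientation_bias()] table), `hot_genes`,
#'   `hot_cluster_sizes` (insertions at each designated gene)
#' @export
sim_orientation_screen <- function(seed, beta_hot = 0.5, n_hot = 10,
                                   hot_weight = 20, n_insertions = 4000,
                                   min_cluster = 1) {
  base <- grip_sim_config(seed = seed, n_insertions = n_insertions)
  genes <- simulate_genome(base)
  peaks <- simulate_peaks(genes, base)
  pg <- peak_bearing_genes(genes, peaks)
  if (length(pg) < n_hot)
    stop("fewer than n_hot peak-bearing genes; raise peak_fraction",
         call. = FALSE)
  hot <- pg[seq_len(n_hot)]
  cfg <- grip_sim_config(seed = seed, n_insertions = n_insertions,
                         hot_genes = hot, hot_weight = hot_weight,
                         beta_genes = setNames(rep(beta_hot, n_hot), hot))
  ins <- simulate_insertions(genes, peaks, cfg)$insertions
  screen <- orientation_bias(ins, genes)
  screen <- screen[screen$fwd_in + screen$rev_in >= min_cluster, ,
                   drop = FALSE]
  sizes <- screen$fwd_in + screen$rev_in
  list(screen = screen, hot_genes = hot,
       hot_cluster_sizes = setNames(
         sizes[match(hot, screen$gene_id)], hot))
}
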
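## Seeded synthetic-data generator: toy multi-chromosome genomes, peak sets
## at a subset of TSSs, and insertion datasets drawn from a mixture of
## uniform background and peak/TSS-biased placement with a double-peak
## offset around the TSS, per-insertion clonal copy counts, and configurable
## per-gene orientation bias.

#' Simulation configuration
#'
#' Collects every generator knob with defaults chosen to emulate the
#' statistical structure of a gamma-retroviral integration dataset at desk
#' scale: a strong preference for peak-marked TSSs (`pi`), a double-peak
#' placement around the TSS with modes near +/-1.5 kb and a trough at the
#' TSS itself (`tss_offset_mode`, `tss_offset_sd`, `offset_exclusion`), a
#' geometric clonal copy distribution with a mean near 2.6
#' copies/insertion, and unbiased orientation (`beta = 0.5`) unless a gene
#' is given a different forward probability.
#'
#' All randomness flows from `seed` through fixed per-stage substreams, so
#' the genome, the peaks and the insertions can each be regenerated
#' independently.
#'
#' @param n_chroms number of chromosomes (default 4)
#' @param chrom_length chromosome length in bp (default 5e6)
#' @param n_genes genes in the genome (default 100)
#' @param gene_length_min,gene_length_max uniform gene-length range in bp
#' @param flank gene-window flank in bp (default 25000)
#' @param pi probability an insertion is chromatin-biased rather than
#'   uniform background (default 0.6)
#' @param peak_fraction fraction of TSSs carrying a peak (default 0.3)
#' @param peak_width peak width in bp (default 2000)
#' @param tss_offset_mode modal |offset| of biased insertions from the TSS
#'   in bp (default 1500)
#' @param tss_offset_sd spread of the offset magnitude in bp (default 500)
#' @param offset_exclusion bp around the TSS excluded from biased placement
#'   (default 200), producing the trough at the TSS
#' @param hot_genes designated hot genes: a character vector of gene ids
#'   (each given weight `hot_weight`) or a named numeric vector of
#'   multiplicative targeting weights `>= 1`
#' @param hot_weight default weight for `hot_genes` given as characters
#'   (default 20)
#' @param beta genome-wide forward-orientation probability (default 0.5)
#' @param beta_genes named vector of per-gene forward probabilities
#'   overriding `beta` for biased insertions at those genes
#' @param copies_geometric_p geometric parameter for the clonal copy count,
#'   `copies ~ 1 + Geometric(p)`; the default 0.385 gives a mean of about
#'   2.6 copies/insertion
#' @param n_insertions insertions to draw (default 5000)
#' @param seed master seed (default 1)
#' @return list of class `grip_sim_config`
#' @export
grip_sim_config <- function(n_chroms = 4, chrom_length = 5e6, n_genes = 100,
                            gene_length_min = 5000, gene_length_max = 20000,
                            flank = 25000, pi = 0.6, peak_fraction = 0.3,
                            peak_width = 2000, tss_offset_mode = 1500,
                            tss_offset_sd = 500, offset_exclusion = 200,
                            hot_genes = character(), hot_weight = 20,
                            beta = 0.5, beta_genes = numeric(),
                            copies_geometric_p = 0.385, n_insertions = 5000,
                            seed = 1) {
  if (is.character(hot_genes))
    hot_genes <- setNames(rep(hot_weight, length(hot_genes)), hot_genes)
  cfg <- list(n_chroms = n_chroms, chrom_length = chrom_length,
              n_genes = n_genes, gene_length_min = gene_length_min,
              gene_length_max = gene_length_max, flank = flank, pi = pi,
              peak_fraction = peak_fraction, peak_width = peak_width,
              tss_offset_mode = tss_offset_mode,
              tss_offset_sd = tss_offset_sd,
              offset_exclusion = offset_exclusion, hot_genes = hot_genes,
              beta = beta, beta_genes = beta_genes,
              copies_geometric_p = copies_geometric_p,
              n_insertions = n_insertions, seed = seed)
  stopifnot(n_chroms >= 1, chrom_length > 0, n_genes >= 0,
            gene_length_min > 0, gene_length_max >= gene_length_min,
            pi >= 0, pi <= 1, peak_fraction >= 0, peak_fraction <= 1,
            peak_width > 0, tss_offset_mode >= 0, tss_offset_sd > 0,
            offset_exclusion >= 0, beta >= 0, beta <= 1,
            all(hot_genes >= 1), all(beta_genes >= 0 & beta_genes <= 1),
            copies_geometric_p > 0, copies_geometric_p <= 1,
            n_insertions >= 0)
  structure(cfg, class = "grip_sim_config")
}

# per-stage substream seeds derived from the master seed
sim_seed <- function(config, stage) {
  offset <- c(genome = 11L, peaks = 23L, insertions = 37L)[[stage]]
  (as.integer(config$seed) + offset) %% .Machine$integer.max
}

#' Simulate a toy genome
#'
#' Places `n_genes` non-overlapping genes across the chromosomes
#' (round-robin), with uniform lengths in the configured range, starts
#' placed by distributing the free space uniformly between genes, and
#' strands Bernoulli(0.5). Deterministic given `config$seed`.
#'
#' @param config a [grip_sim_config()]
#' @return gene table in the [read_gene_table()] layout
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "grip_sim_config"))
  with_seed(sim_seed(config, "genome"), {
    if (config$n_genes == 0L) return(empty_genes())
    chrom_of <- rep_len(seq_len(config$n_chroms), config$n_genes)
    rows <- lapply(seq_len(config$n_chroms), function(ci) {
      k <- sum(chrom_of == ci)
      if (k == 0L) return(NULL)
      len <- sample(config$gene_length_min:config$gene_length_max, k,
                    replace = TRUE)
      free <- config$chrom_length - sum(len)
      if (free < 0)
        stop("infeasible packing: genes do not fit on chromosome ", ci,
             call. = FALSE)
      gaps <- as.vector(rmultinom(1, free, rep(1, k + 1)))
      starts <- cumsum(gaps[seq_len(k)]) + c(0, cumsum(len))[seq_len(k)]
      data.frame(chrom = paste0("chr", ci),
                 strand = sample(c("+", "-"), k, replace = TRUE),
                 tx_start = as.integer(starts),
                 tx_end = as.integer(starts + len),
                 stringsAsFactors = FALSE)
    })
    g <- do.call(rbind, rows)
    g <- g[order(g$chrom, g$tx_start, method = "radix"), , drop = FALSE]
    g$gene_id <- sprintf("G%04d", seq_len(nrow(g)))
    g$symbol <- g$gene_id
    g$tss <- ifelse(g$strand == "+", g$tx_start, g$tx_end - 1L)
    rownames(g) <- NULL
    g[, c("gene_id", "symbol", "chrom", "strand", "tx_start", "tx_end",
          "tss")]
  })
}

#' Simulate a chromatin-mark peak set
#'
#' Each gene's TSS carries a peak with probability `peak_fraction`
#' (Bernoulli, by seed); peaks are centred on the TSS with the configured
#' width. A stand-in for an active-mark ChIP peak set.
#'
#' @param genes gene table
#' @param config a [grip_sim_config()]
#' @return peak data.frame as from [read_peaks()] (mark `"sim_mark"`)
#' @export
simulate_peaks <- function(genes, config) {
  stopifnot(inherits(config, "grip_sim_config"))
  with_seed(sim_seed(config, "peaks"), {
    sel <- runif(nrow(genes)) < config$peak_fraction
    half <- floor(config$peak_width / 2)
    pk <- data.frame(chrom = genes$chrom[sel],
                     start = pmax(0L, genes$tss[sel] - half),
                     score = round(runif(sum(sel), 100, 1000)),
                     stringsAsFactors = FALSE)
    pk$end <- pk$start + as.integer(config$peak_width)
    pk <- pk[order(pk$chrom, pk$start, method = "radix"),
             c("chrom", "start", "end", "score"), drop = FALSE]
    rownames(pk) <- NULL
    attr(pk, "mark_name") <- "sim_mark"
    attr(pk, "dialect") <- "bed"
    pk
  })
}

#' Simulate an insertion dataset
#'
#' Draws `n_insertions` insertions: with probability `pi` an insertion is
#' chromatin-biased — a peak-bearing gene is chosen (hot-gene weights
#' multiply the selection probability) and the point placed at
#' `TSS +/- offset`, where `|offset|` follows a distribution peaked at
#' `tss_offset_mode` and excluded from `offset_exclusion` bp around the TSS
#' — otherwise the position is uniform over the genome. Strand is forward
#' with the gene's probability (`beta_genes`, falling back to `beta`);
#' copies are `1 + Geometric(copies_geometric_p)`.
#'
#' @param genes gene table
#' @param peaks peak data.frame (peak-bearing genes are those whose TSS lies
#'   inside a peak)
#' @param config a [grip_sim_config()]
#' @return list with `insertions` (standard insertion data.frame) and
#'   `truth` (data.frame `id`, `channel` = biased/background, `gene_id`,
#'   `offset`)
#' @export
simulate_insertions <- function(genes, peaks, config) {
  stopifnot(inherits(config, "grip_sim_config"))
  with_seed(sim_seed(config, "insertions"), {
    n <- config$n_insertions
    chroms <- paste0("chr", seq_len(config$n_chroms))
    if (n == 0L) {
      return(list(insertions = empty_insertions(),
                  truth = data.frame(id = character(), channel = character(),
                                     gene_id = character(),
                                     offset = integer())))
    }
    peak_genes <- which(GenomicRanges::countOverlaps(
      GenomicRanges::GRanges(genes$chrom,
                             IRanges::IRanges(genes$tss + 1L, width = 1L)),
      as_granges0(peaks)) > 0)
    biased <- runif(n) < config$pi
    nb <- sum(biased)
    if (nb > 0 && length(peak_genes) == 0L)
      stop("pi > 0 but no gene carries a peak; raise peak_fraction",
           call. = FALSE)
    pos <- integer(n)
    gene_of <- rep(NA_character_, n)
    offset <- rep(NA_integer_, n)
    if (nb > 0) {
      w <- rep(1, length(peak_genes))
      hot <- match(names(config$hot_genes), genes$gene_id[peak_genes])
      w[hot[!is.na(hot)]] <- config$hot_genes[!is.na(hot)]
      gidx <- peak_genes[sample.int(length(peak_genes), nb, replace = TRUE,
                                    prob = w)]
      mag <- config$offset_exclusion +
        abs(rnorm(nb, config$tss_offset_mode - config$offset_exclusion,
                  config$tss_offset_sd))
      off <- as.integer(round(mag) * sample(c(-1L, 1L), nb, replace = TRUE))
      pos[biased] <- pmin(pmax(genes$tss[gidx] + off, 0L),
                          config$chrom_length - 1L)
      gene_of[biased] <- genes$gene_id[gidx]
      offset[biased] <- off
    }
    if (n - nb > 0) {
      bg_chrom <- sample(chroms, n - nb, replace = TRUE)
      pos[!biased] <- as.integer(floor(runif(n - nb) * config$chrom_length))
    }
    chrom <- character(n)
    chrom[biased] <- if (nb > 0) genes$chrom[gidx] else character()
    chrom[!biased] <- if (n - nb > 0) bg_chrom else character()
    beta_i <- rep(config$beta, n)
    if (length(config$beta_genes)) {
      ov <- match(gene_of, names(config$beta_genes))
      beta_i[!is.na(ov)] <- config$beta_genes[ov[!is.na(ov)]]
    }
    strand <- ifelse(runif(n) < beta_i, "+", "-")
    copies <- 1L + rgeom(n, config$copies_geometric_p)
    id <- sprintf("INS%06d", seq_len(n))
    ins <- data.frame(chrom = chrom, pos = pos, strand = strand,
                      copies = copies, id = id, stringsAsFactors = FALSE)
    truth <- data.frame(id = id,
                        channel = ifelse(biased, "biased", "background"),
                        gene_id = gene_of, offset = offset,
                        stringsAsFactors = FALSE)
    list(insertions = ins, truth = truth)
  })
}

#' Simulate a complete dataset
#'
#' Convenience wrapper running [simulate_genome()], [simulate_peaks()] and
#' [simulate_insertions()] from one configuration.
#'
#' @param config a [grip_sim_config()]
#' @return list `genes`, `peaks`, `insertions`, `truth`, `config`
#' @export
simulate_dataset <- function(config) {
  genes <- simulate_genome(config)
  peaks <- simulate_peaks(genes, config)
  ins <- simulate_insertions(genes, peaks, config)
  list(genes = genes, peaks = peaks, insertions = ins$insertions,
       truth = ins$truth, config = config)
}
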
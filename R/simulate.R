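#' Configure a two-population pool-seq simulation
#'
#' Defines the study conditions emulated by the generator: two populations
#' split from a common ancestor with background differentiation `background_f`
#' (Balding-Nichols model), pooled sequencing of two pools at mean depth
#' `mean_depth` with per-base error `base_error`, and scattered indels to
#' exercise the indel-proximity filter.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param snp_density Expected SNPs per bp (default 3e-3, i.e. ~60k SNPs on a
#'   20 Mb genome).
#' @param background_f Balding-Nichols differentiation parameter F in (0, 1)
#'   shared by both daughter populations.
#' @param ancestral_range Bounds of the uniform ancestral allele-frequency
#'   distribution; the default `c(0.05, 0.95)` keeps the MAF filter relevant.
#' @param pools List of two [pool_spec()] objects; defaults to 35 vs 59
#'   diploids as in [default_pools()].
#' @param mean_depth Mean sequencing depth per pool per site (Poisson,
#'   truncated at >= 1 read).
#' @param base_error Per-read base error probability (must be < 0.01).
#' @param indel_density Expected indels per bp.
#' @param ts_prob Probability that a simulated SNP is a transition; the
#'   default 0.65 gives an expected Ts/Tv ratio of ~1.86, typical of dog
#'   variant sets.
#' @param qual_range Range from which per-record Phred-like qualities are
#'   drawn uniformly.
#' @param seed Integer seed; mandatory for reproducible output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(chrom_lengths = c(chr1 = 5e6, chr2 = 5e6,
                                         chr3 = 5e6, chr4 = 5e6),
                       snp_density = 3e-3,
                       background_f = 0.05,
                       ancestral_range = c(0.05, 0.95),
                       pools = default_pools(),
                       mean_depth = 30,
                       base_error = 0.002,
                       indel_density = 1e-3,
                       ts_prob = 0.65,
                       qual_range = c(20, 60),
                       seed = 1L) {
  if (length(chrom_lengths) < 1L || any(chrom_lengths < 25000)) {
    stop_config("each chromosome must be at least one 25-kb window long")
  }
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- sprintf("chr%d", seq_along(chrom_lengths))
  }
  if (!(background_f > 0 && background_f < 1)) {
    stop_config("'background_f' must lie strictly between 0 and 1")
  }
  if (mean_depth <= 0) stop_config("'mean_depth' must be positive")
  if (base_error < 0 || base_error >= 0.01) {
    stop_config("'base_error' must lie in [0, 0.01)")
  }
  if (ancestral_range[1] <= 0 || ancestral_range[2] >= 1 ||
      ancestral_range[1] >= ancestral_range[2]) {
    stop_config("'ancestral_range' must be an increasing interval inside (0, 1)")
  }
  structure(
    list(chrom_lengths = chrom_lengths, snp_density = snp_density,
         background_f = background_f, ancestral_range = ancestral_range,
         pools = check_pools(pools), mean_depth = mean_depth,
         base_error = base_error, indel_density = indel_density,
         ts_prob = ts_prob, qual_range = qual_range,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Describe a planted selective sweep
#'
#' @param chrom Chromosome id carrying the sweep.
#' @param position Focal position of the beneficial allele (bp).
#' @param s Selection coefficient (> 0).
#' @param n_effective Effective population size N.
#' @param rec_rate Recombination rate r per bp per generation.
#' @param pool Target population (1 or 2) experiencing the sweep.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(chrom, position, s = 0.05, n_effective = 1e4,
                       rec_rate = 1e-8, pool = 1L) {
  if (s <= 0) stop_config("selection coefficient 's' must be > 0")
  if (rec_rate <= 0) stop_config("'rec_rate' must be > 0")
  if (!pool %in% c(1L, 2L)) stop_config("'pool' must be 1 or 2")
  structure(
    list(chrom = chrom, position = position, s = s,
         n_effective = n_effective, rec_rate = rec_rate,
         pool = as.integer(pool)),
    class = "sweep_spec"
  )
}

#' Hitchhiking escape probability
#'
#' Under the star-like approximation, a neutral lineage at recombination
#' distance `r * d` from a sweeping allele escapes the hitchhiking event with
#' probability `c = 1 - (2 N s)^(-r d / s)`. `c = 0` at the focal site
#' (complete hitchhiking) and `c -> 1` for unlinked sites.
#'
#' @param d Physical distance from the focal site (bp).
#' @param s Selection coefficient.
#' @param n_effective Effective population size.
#' @param rec_rate Recombination rate per bp per generation.
#' @return Escape probabilities in `[0, 1]`.
#' @export
escape_probability <- function(d, s, n_effective, rec_rate) {
  stopifnot(s > 0, n_effective > 0, rec_rate > 0)
  two_ns <- 2 * n_effective * s
  if (two_ns <= 1) return(rep(1, length(d)))  # too weak to drag anything
  pmin(1, pmax(0, 1 - exp(-(rec_rate * d / s) * log(two_ns))))
}

#' Simulate per-site allele frequencies for two diverged populations
#'
#' Ancestral frequencies are uniform on `ancestral_range`; each population's
#' frequency is an independent Balding-Nichols draw
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` around the ancestral value, so that
#' `Var(p_i) = F p (1 - p)`. Sites are independent.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed; when `NULL` the current RNG stream is used
#'   (so [simulate_poolseq()] can seed once for the whole run).
#' @return `data.frame` with columns `chrom`, `pos`, `p_anc`, `p1`, `p2`.
#' @export
simulate_frequencies <- function(config, seed = config$seed) {
  if (!inherits(config, "sim_config")) stop_config("'config' must be a sim_config")
  if (!is.null(seed)) set.seed(seed)
  ff <- config$background_f
  out <- lapply(names(config$chrom_lengths), function(cn) {
    len <- config$chrom_lengths[[cn]]
    n <- rpois(1L, len * config$snp_density)
    if (n == 0L) return(NULL)
    pos <- sort(sample.int(len, min(n, len)))
    p_anc <- runif(length(pos), config$ancestral_range[1], config$ancestral_range[2])
    a <- p_anc * (1 - ff) / ff
    b <- (1 - p_anc) * (1 - ff) / ff
    data.frame(chrom = cn, pos = pos, p_anc = p_anc,
               p1 = rbeta(length(pos), a, b),
               p2 = rbeta(length(pos), a, b))
  })
  do.call(rbind, out)
}

#' Overlay a selective sweep on simulated frequencies
#'
#' For each site at distance `d` from the focal position, the allele linked
#' to the beneficial background (the current alternate allele with
#' probability equal to its frequency `p0`) is dragged from `p0` to
#' `p' = (1 - c) + c p0`, where `c` is [escape_probability()]. At `d = 0`
#' the linked allele fixes; as `r d / s -> Inf` the frequency is untouched.
#'
#' @param freqs Output of [simulate_frequencies()].
#' @param sweep A [sweep_spec()].
#' @param seed Optional seed for the linked-allele draws.
#' @return `freqs` with the target population's column modified on the sweep
#'   chromosome.
#' @export
apply_sweep <- function(freqs, sweep, seed = NULL) {
  if (!inherits(sweep, "sweep_spec")) stop_config("'sweep' must be a sweep_spec")
  on_chrom <- freqs$chrom == sweep$chrom
  if (!any(on_chrom)) stop_config("sweep chromosome '%s' not in simulated genome", sweep$chrom)
  if (sweep$position < 1 || sweep$position > max(freqs$pos[on_chrom])) {
    # allow focal positions anywhere on the declared chromosome; only reject
    # plainly impossible coordinates
    if (sweep$position < 1) stop_config("sweep position must be >= 1")
  }
  if (!is.null(seed)) set.seed(seed)
  col <- paste0("p", sweep$pool)
  d <- abs(freqs$pos[on_chrom] - sweep$position)
  cc <- escape_probability(d, sweep$s, sweep$n_effective, sweep$rec_rate)
  p0 <- freqs[[col]][on_chrom]
  alt_linked <- runif(length(p0)) < p0
  p_new <- ifelse(alt_linked, (1 - cc) + cc * p0, cc * p0)
  freqs[[col]][on_chrom] <- pmin(1, pmax(0, p_new))
  freqs
}

#' Sample pooled read counts from population frequencies
#'
#' Per pool and site: the pool allele frequency is a binomial draw of
#' `2 * individuals` chromosomes from the population frequency; depth is
#' Poisson(`mean_depth`) truncated at >= 1; alternate reads are binomial in
#' depth at the pool frequency perturbed by the base error
#' (`f' = f (1 - e) + (1 - f) e`). Qualities are uniform on `qual_range`.
#'
#' @param freqs Frequency table from [simulate_frequencies()] (possibly after
#'   [apply_sweep()]).
#' @param config A [sim_config()]; supplies pools, depth, error, bases.
#' @param seed Optional seed.
#' @return A variant table (`data.frame`) with columns `chrom`, `pos`, `ref`,
#'   `alt`, `type`, `qual`, `ref1`, `alt1`, `ref2`, `alt2`.
#' @export
sample_pool_counts <- function(freqs, config, seed = NULL) {
  if (config$mean_depth <= 0) stop_config("'mean_depth' must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(freqs)
  bases <- c("A", "T", "C", "G")
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  transversions <- list(A = c("C", "T"), G = c("C", "T"),
                        C = c("A", "G"), T = c("A", "G"))
  ref <- sample(bases, n, replace = TRUE)
  is_ts <- runif(n) < config$ts_prob
  alt <- ifelse(is_ts, transitions[ref],
                vapply(transversions[ref], function(x) x[sample.int(2L, 1L)],
                       character(1)))
  counts <- lapply(1:2, function(i) {
    hap <- config$pools[[i]]$haploids
    f_pool <- rbinom(n, hap, freqs[[paste0("p", i)]]) / hap
    depth <- rpois(n, config$mean_depth)
    depth[depth == 0L] <- 1L  # truncated Poisson: no zero-depth records
    f_read <- f_pool * (1 - config$base_error) + (1 - f_pool) * config$base_error
    alt_n <- rbinom(n, depth, f_read)
    cbind(depth - alt_n, alt_n)
  })
  data.frame(
    chrom = freqs$chrom, pos = freqs$pos, ref = unname(ref),
    alt = unname(alt), type = "SNP",
    qual = round(runif(n, config$qual_range[1], config$qual_range[2]), 2),
    ref1 = counts[[1]][, 1], alt1 = counts[[1]][, 2],
    ref2 = counts[[2]][, 1], alt2 = counts[[2]][, 2]
  )
}

#' Interleave indel records into a variant table
#'
#' Indel positions are Poisson-scattered along each chromosome at
#' `indel_density`; each gets a record whose ref/alt strings differ in length
#' and pooled counts drawn like a SNP's. They provide anchors for the
#' indel-proximity SNP filter.
#'
#' @param config A [sim_config()].
#' @param records Variant table to augment.
#' @param seed Optional seed.
#' @return List with `records` (sorted, indels interleaved) and
#'   `indel_positions` (`data.frame` of `chrom`, `pos`).
#' @export
plant_indels <- function(config, records, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (config$indel_density <= 0) {
    return(list(records = records,
                indel_positions = data.frame(chrom = character(0),
                                             pos = integer(0))))
  }
  pieces <- lapply(names(config$chrom_lengths), function(cn) {
    len <- config$chrom_lengths[[cn]]
    n <- rpois(1L, len * config$indel_density)
    if (n == 0L) return(NULL)
    data.frame(chrom = cn, pos = sort(sample.int(len, min(n, len))))
  })
  ipos <- do.call(rbind, pieces)
  if (is.null(ipos) || nrow(ipos) == 0L) {
    return(list(records = records,
                indel_positions = data.frame(chrom = character(0),
                                             pos = integer(0))))
  }
  n <- nrow(ipos)
  base <- sample(c("A", "T", "C", "G"), n, replace = TRUE)
  ins <- runif(n) < 0.5
  ref <- ifelse(ins, base, paste0(base, "A"))
  alt <- ifelse(ins, paste0(base, "T"), base)
  af <- runif(n, 0.1, 0.9)
  cnt <- lapply(1:2, function(i) {
    depth <- pmax(1L, rpois(n, config$mean_depth))
    alt_n <- rbinom(n, depth, af)
    cbind(depth - alt_n, alt_n)
  })
  indels <- data.frame(
    chrom = ipos$chrom, pos = ipos$pos, ref = ref, alt = alt, type = "indel",
    qual = round(runif(n, config$qual_range[1], config$qual_range[2]), 2),
    ref1 = cnt[[1]][, 1], alt1 = cnt[[1]][, 2],
    ref2 = cnt[[2]][, 1], alt2 = cnt[[2]][, 2]
  )
  merged <- rbind(records, indels)
  merged <- merged[order(merged$chrom, merged$pos, merged$type), ]
  rownames(merged) <- NULL
  list(records = merged, indel_positions = ipos)
}

#' Windows occupied by planted sweeps
#'
#' The sweep footprint is the interval `position +/- half_width`; by default
#' `half_width` is the distance at which the escape probability reaches 0.5,
#' `s log(2) / (r log(2 N s))`. Footprint windows are aligned to the same
#' 0-based window grid used by the scan.
#'
#' @param config A [sim_config()].
#' @param sweeps List of [sweep_spec()] objects.
#' @param window_size Window size in bp (default 25000).
#' @param half_width Footprint half-width in bp, or `NULL` for the default.
#' @return `data.frame` with columns `sweep`, `chrom`, `win_start`, `win_end`.
#' @export
truth_table <- function(config, sweeps, window_size = 25000, half_width = NULL) {
  rows <- lapply(seq_along(sweeps), function(i) {
    sw <- sweeps[[i]]
    hw <- half_width %||%
      (sw$s * log(2) / (sw$rec_rate * log(2 * sw$n_effective * sw$s)))
    len <- config$chrom_lengths[[sw$chrom]]
    lo <- max(1, sw$position - hw)
    hi <- min(len, sw$position + hw)
    starts <- seq(floor((lo - 1) / window_size) * window_size,
                  floor((hi - 1) / window_size) * window_size,
                  by = window_size)
    data.frame(sweep = i, chrom = sw$chrom, win_start = starts,
               win_end = starts + window_size)
  })
  do.call(rbind, rows)
}

#' Run the full synthetic pool-seq generator
#'
#' Seeds the RNG once, then simulates frequencies, overlays sweeps, samples
#' pooled read counts, plants indels, and records the truth table of sweep
#' footprint windows.
#'
#' @param config A [sim_config()].
#' @param sweeps List of [sweep_spec()] objects (may be empty for a neutral
#'   genome).
#' @param window_size Window grid used for the truth table.
#' @return An object of class `poolseq_sim`: list with `records`, `freqs`,
#'   `indel_positions`, `truth`, `config`, `sweeps`.
#' @examples
#' cfg <- sim_config(chrom_lengths = c(chr1 = 2e5), snp_density = 1e-3, seed = 7)
#' sim <- simulate_poolseq(cfg, list(sweep_spec("chr1", 1e5)))
#' head(sim$records)
#' @export
simulate_poolseq <- function(config, sweeps = list(), window_size = 25000) {
  set.seed(config$seed)
  freqs <- simulate_frequencies(config, seed = NULL)
  for (sw in sweeps) freqs <- apply_sweep(freqs, sw, seed = NULL)
  records <- sample_pool_counts(freqs, config, seed = NULL)
  planted <- plant_indels(config, records, seed = NULL)
  truth <- if (length(sweeps) > 0L) {
    truth_table(config, sweeps, window_size = window_size)
  } else {
    data.frame(sweep = integer(0), chrom = character(0),
               win_start = numeric(0), win_end = numeric(0))
  }
  structure(
    list(records = planted$records, freqs = freqs,
         indel_positions = planted$indel_positions, truth = truth,
         config = config, sweeps = sweeps),
    class = "poolseq_sim"
  )
}

#' @export
print.poolseq_sim <- function(x, ...) {
  cat(sprintf(
    "<poolseq_sim> %d records (%d SNPs, %d indels) on %d chromosome(s), %d sweep(s)\n",
    nrow(x$records), sum(x$records$type == "SNP"),
    sum(x$records$type == "indel"), length(x$config$chrom_lengths),
    length(x$sweeps)))
  invisible(x)
}

#' Build a toy gene annotation covering sweep footprints
#'
#' Places one named gene across the focal window of every planted sweep and
#' scatters additional background genes along each chromosome, so gene
#' overlap of candidate windows can be tested end to end.
#'
#' @param sim A `poolseq_sim`.
#' @param genes_per_chrom Background genes per chromosome.
#' @param seed Seed for background gene placement.
#' @return Gene table as returned by [read_gff3()].
#' @export
toy_gene_annotation <- function(sim, genes_per_chrom = 5L, seed = 1L) {
  set.seed(seed)
  cfg <- sim$config
  sweep_genes <- if (length(sim$sweeps) > 0L) {
    do.call(rbind, lapply(seq_along(sim$sweeps), function(i) {
      sw <- sim$sweeps[[i]]
      data.frame(gene_id = sprintf("SWEEPG%03d", i),
                 symbol = sprintf("SWEEPG%03d", i),
                 chrom = sw$chrom,
                 start = max(1, sw$position - 15000),
                 end = sw$position + 15000, strand = "+")
    }))
  } else NULL
  bg <- do.call(rbind, lapply(names(cfg$chrom_lengths), function(cn) {
    len <- cfg$chrom_lengths[[cn]]
    starts <- sort(sample.int(max(1, len - 30000), genes_per_chrom))
    data.frame(gene_id = sprintf("BGGENE_%s_%02d", cn, seq_len(genes_per_chrom)),
               symbol = sprintf("BGGENE_%s_%02d", cn, seq_len(genes_per_chrom)),
               chrom = cn, start = starts,
               end = starts + sample(5000:25000, genes_per_chrom, replace = TRUE),
               strand = sample(c("+", "-"), genes_per_chrom, replace = TRUE))
  }))
  out <- rbind(sweep_genes, bg)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}
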
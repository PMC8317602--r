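# Builders for small in-code fixtures.

snp_row <- function(chrom = "chr1", pos, ref = "A", alt = "G", type = "SNP",
                    qual = 50, ref1 = 20, alt1 = 10, ref2 = 15, alt2 = 15) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, type = type,
             qual = qual, ref1 = ref1, alt1 = alt1, ref2 = ref2, alt2 = alt2)
}

variant_table <- function(...) {
  out <- do.call(rbind, list(...))
  out[order(out$chrom, out$pos), , drop = FALSE]
}

# Random variant table for property tests (sorted, mixed SNP/indel).
random_variant_table <- function(n = 50, seed = 1) {
  set.seed(seed)
  pos <- sort(sample.int(5e4, n))
  d1 <- rpois(n, 25) + 1L
  d2 <- rpois(n, 25) + 1L
  a1 <- rbinom(n, d1, runif(n))
  a2 <- rbinom(n, d2, runif(n))
  type <- sample(c("SNP", "indel"), n, replace = TRUE, prob = c(0.85, 0.15))
  data.frame(chrom = "chr1", pos = pos,
             ref = ifelse(type == "SNP", "A", "AT"),
             alt = ifelse(type == "SNP", "G", "A"),
             type = type, qual = round(runif(n, 5, 60), 1),
             ref1 = d1 - a1, alt1 = a1, ref2 = d2 - a2, alt2 = a2)
}

# Small simulation shared by several tests: 2 x 300 kb, one sweep.
small_sim <- function(seed = 11, sweeps = list(sweep_spec("chr1", 150000))) {
  cfg <- sim_config(chrom_lengths = c(chr1 = 3e5, chr2 = 3e5),
                    snp_density = 2e-3, seed = seed)
  simulate_poolseq(cfg, sweeps)
}

# Independent ANOVA mean-squares oracle for the per-site F_ST estimator:
# build literal 0/1 allele indicators and take the mean squares from
# anova(lm(...)), never from the closed form under test.
anova_fst_oracle <- function(a1, n1, a2, n2) {
  y <- c(rep(1, a1), rep(0, n1 - a1), rep(1, a2), rep(0, n2 - a2))
  g <- factor(rep(c("p1", "p2"), c(n1, n2)))
  ms <- suppressWarnings(anova(lm(y ~ g))$`Mean Sq`)  # perfect fits are fine here
  nc <- 2 * n1 * n2 / (n1 + n2)
  (ms[1] - ms[2]) / (ms[1] + (nc - 1) * ms[2])
}

# Plain-R fine-grid reference for the XP-CLR site likelihood (midpoint rule
# at high resolution), independent of the compiled implementation.
midpoint_xpclr_loglik <- function(p_ref, alt, depth, dist, s, omega,
                                  n_eff = 1e4, rec_rate = 1e-8,
                                  n_points = 4096, sd_floor = 0.01) {
  clamp <- 1 / (2 * n_points)
  mu <- min(1 - clamp, max(clamp, p_ref))
  sdv <- max(sd_floor, sqrt(omega * mu * (1 - mu)))
  x <- (seq_len(n_points) - 0.5) / n_points
  dens <- dnorm(x, mu, sdv) / n_points
  m0 <- pnorm(0, mu, sdv)
  m1 <- pnorm(1, mu, sdv, lower.tail = FALSE)
  tot <- m0 + m1 + sum(dens)
  cc <- if (s == 0) 1 else {
    tw <- 2 * n_eff * s
    if (tw <= 1) 1 else min(1, max(0, 1 - exp(-(rec_rate * dist / s) * log(tw))))
  }
  emis <- function(y) {
    ifelse(y <= 0, as.numeric(alt == 0),
           ifelse(y >= 1, as.numeric(alt == depth), dbinom(alt, depth, y)))
  }
  lik <- m0 * emis(0) + m1 * emis(1) +
    sum(dens * (x * emis((1 - cc) + cc * x) + (1 - x) * emis(cc * x)))
  log(max(lik / tot, 1e-300))
}
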
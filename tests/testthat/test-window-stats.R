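test_that("window assignment follows the half-open 25-kb grid", {
  cfg <- windowing_config()
  rec <- snp_row(pos = 25000)
  expect_equal(assign_windows(rec, cfg)$win_start, 0)
  rec2 <- snp_row(pos = 25001)
  expect_equal(assign_windows(rec2, cfg)$win_start, 25000)
  expect_equal(assign_windows(rec2, cfg)$win_end, 50000)
})

test_that("windowing partitions records exactly", {
  set.seed(42)
  tab <- data.frame(chrom = sample(c("chr1", "chr2"), 1000, TRUE),
                    pos = sample.int(3e5, 1000, TRUE))
  w <- assign_windows(tab, windowing_config())
  # every record in exactly one window, and per-window counts sum back
  expect_true(all(w$pos > w$win_start & w$pos <= w$win_end))
  counts <- table(paste(w$chrom, w$win_start))
  expect_equal(sum(counts), 1000L)
  # independent oracle: recompute each record's window by scalar division
  oracle <- vapply(seq_len(1000), function(i) (ceiling(tab$pos[i] / 25000) - 1) * 25000,
                   numeric(1))
  expect_equal(w$win_start, oracle)
})

test_that("site F_ST components satisfy the fixed-difference and identical-frequency identities", {
  one <- site_fst_components(1, 0, 70, 118)
  expect_equal(one$msg, 0)
  expect_equal(one$fst, 1)
  same <- site_fst_components(0.3, 0.3, 50, 50)
  expect_equal(same$msp, 0)
  expect_equal(same$fst, -1 / (50 - 1))
  expect_error(site_fst_components(0.5, 0.5, 1, 1), "n1 \\+ n2")
  expect_error(site_fst_components(1.2, 0.5, 10, 10), "frequencies")
})

test_that("both algebraic forms of the estimator agree to machine precision", {
  set.seed(7)
  p1 <- runif(500); p2 <- runif(500)
  n1 <- sample(4:100, 500, TRUE); n2 <- sample(4:100, 500, TRUE)
  comp <- site_fst_components(p1, p2, n1, n2)
  denom <- comp$msp + (comp$nc - 1) * comp$msg
  alt_form <- 1 - comp$nc * comp$msg / denom
  ok <- is.finite(comp$fst)
  expect_lt(max(abs(comp$fst[ok] - alt_form[ok])), 1e-12)
})

test_that("site F_ST matches an independent ANOVA mean-squares oracle", {
  set.seed(11)
  for (i in 1:25) {
    n1 <- sample(4:80, 1); n2 <- sample(4:80, 1)
    a1 <- sample(0:n1, 1); a2 <- sample(0:n2, 1)
    if (a1 %in% c(0, n1) && a2 %in% c(0, n2)) next  # degenerate: both fixed
    ours <- site_fst_components(a1 / n1, a2 / n2, n1, n2)$fst
    expect_equal(ours, anova_fst_oracle(a1, n1, a2, n2), tolerance = 1e-10)
  }
  # the default two-pool design: n1 = 70, n2 = 118 haploid genomes
  expect_equal(site_fst_components(56 / 70, 35 / 118, 70, 118)$fst,
               anova_fst_oracle(56, 70, 35, 118), tolerance = 1e-10)
})

test_that("windowed F_ST reduces to the site identities and matches a brute-force sum", {
  cfg <- windowing_config(min_snps = 5)
  pools <- list(pool_spec(25), pool_spec(25))
  # identical frequencies in equal pools -> -1/(n-1) in ratio-of-sums mode
  same <- do.call(rbind, lapply(1:10, function(i) {
    snp_row(pos = 100 * i, ref1 = 12, alt1 = 8, ref2 = 12, alt2 = 8)
  }))
  w <- window_fst(same, pools, cfg)
  expect_equal(w$fst, -1 / (50 - 1))
  # single-SNP window: both modes agree with the site estimator
  cfg1 <- windowing_config(min_snps = 1)
  single <- snp_row(pos = 10, ref1 = 5, alt1 = 25, ref2 = 20, alt2 = 10)
  ros <- window_fst(single, pools, cfg1, mode = "ratio-of-sums")$fst
  mor <- window_fst(single, pools, cfg1, mode = "mean-of-ratios")$fst
  site <- site_fst_components(25 / 30, 10 / 30, 50, 50)$fst
  expect_equal(ros, site)
  expect_equal(mor, site)
  # 20-SNP window against a from-scratch re-derivation of the summed mean squares
  set.seed(3)
  tab <- do.call(rbind, lapply(1:20, function(i) {
    d1 <- 30; d2 <- 30
    a1 <- rbinom(1, d1, 0.4); a2 <- rbinom(1, d2, 0.6)
    snp_row(pos = 500 + i, ref1 = d1 - a1, alt1 = a1, ref2 = d2 - a2, alt2 = a2)
  }))
  got <- window_fst(tab, pools, cfg)$fst
  p1 <- tab$alt1 / 30; p2 <- tab$alt2 / 30; n1 <- 50; n2 <- 50
  msp <- n1 * n2 / (n1 + n2) * (p1 - p2)^2
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (n1 + n2 - 2)
  nc <- 2 * n1 * n2 / (n1 + n2)
  expect_equal(got, (sum(msp) - sum(msg)) / sum(msp + (nc - 1) * msg))
})

test_that("H_p evaluates its closed form and stays in [0, 0.5]", {
  cfg <- windowing_config(min_snps = 2)
  # sum nMAJ = 30, sum nMIN = 10 across the window -> 600/1600
  tab <- rbind(snp_row(pos = 10, ref1 = 20, alt1 = 6, ref2 = 1, alt2 = 1),
               snp_row(pos = 20, ref1 = 4, alt1 = 10, ref2 = 1, alt2 = 1))
  expect_equal(window_hp(tab, cfg, target_pool = 1)$hp, 0.375)
  # equality of summed counts gives the maximum 0.5
  eq <- rbind(snp_row(pos = 10, ref1 = 10, alt1 = 10),
              snp_row(pos = 20, ref1 = 7, alt1 = 7))
  expect_equal(window_hp(eq, cfg)$hp, 0.5)
  # monomorphic pool gives 0
  mono <- rbind(snp_row(pos = 10, ref1 = 20, alt1 = 0),
                snp_row(pos = 20, ref1 = 30, alt1 = 0))
  expect_equal(window_hp(mono, cfg)$hp, 0)
  # property: random windows stay within [0, 0.5]
  for (seed in 1:5) {
    tab <- random_variant_table(60, seed)
    hp <- window_hp(tab[tab$type == "SNP", ], windowing_config(min_snps = 1))$hp
    expect_true(all(hp >= 0 & hp <= 0.5))
  }
})

test_that("the Z-transform centers, scales, and inverts as an affine map", {
  set.seed(5)
  hp <- runif(200, 0, 0.5)
  zt <- z_transform(hp)
  expect_equal(mean(zt$zhp), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(zt$zhp^2)), 1, tolerance = 1e-12)
  # -ZHp is strictly decreasing in Hp
  o <- order(hp)
  expect_true(all(diff(zt$zhp[o]) < 0))
  # value at the mean maps to 0
  expect_equal(zhp_from_params(zt$params$mu, zt$params), 0)
  # re-application via stored parameters reproduces the transform
  expect_equal(zhp_from_params(hp, zt$params), zt$zhp)
  expect_error(z_transform(rep(0.2, 5)), "degenerate|constant")
})

test_that("solve_z_params recovers the parameters of a known transform", {
  params <- list(mu = 0.31, sigma = 0.07)
  hp <- c(0.05, 0.21)
  got <- solve_z_params(hp, zhp_from_params(hp, params))
  expect_equal(got$mu, 0.31)
  expect_equal(got$sigma, 0.07)
})

test_that("top-quantile selection matches a full sort and breaks ties deterministically", {
  set.seed(9)
  w <- data.frame(chrom = "chr1", win_start = seq(0, by = 25000, length.out = 1000))
  w$win_end <- w$win_start + 25000
  w$stat <- runif(1000)
  top <- top_quantile(w, "stat", q = 0.01)
  expect_equal(top$n_selected, 10L)
  oracle <- w[order(-w$stat), ][1:10, ]
  expect_setequal(top$selected$win_start, oracle$win_start)
  expect_equal(top$threshold, min(oracle$stat))
  # ceiling rule: 86,886 windows at 1% select 869
  expect_equal(ceiling(0.01 * 86886), 869)
  # all-tied values: still exactly ceiling(qN), lowest coordinates first
  w$stat <- 1
  top2 <- top_quantile(w, "stat", q = 0.01)
  expect_equal(top2$n_selected, 10L)
  expect_equal(top2$selected$win_start, w$win_start[1:10])
  expect_error(top_quantile(w, "stat", q = 1.2), "q")
  # low direction mirrors the sort oracle
  set.seed(10); w$stat <- rnorm(1000)
  low <- top_quantile(w, "stat", q = 0.01, direction = "low")
  expect_setequal(low$selected$stat, sort(w$stat)[1:10])
})

test_that("window statistics are invariant to record order", {
  sim <- small_sim(seed = 21)
  flt <- apply_filters(sim$records)
  rec <- flt$records
  set.seed(1)
  shuf <- rec[sample.int(nrow(rec)), ]
  pools <- sim$config$pools
  expect_equal(window_fst(shuf, pools), window_fst(rec, pools))
  expect_equal(window_hp(shuf), window_hp(rec))
  a <- window_xpclr(rec, pools, xpclr = xpclr_config(omega = 0.2, n_points = 64))
  b <- window_xpclr(shuf, pools, xpclr = xpclr_config(omega = 0.2, n_points = 64))
  expect_equal(a, b, ignore_attr = TRUE)
})
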
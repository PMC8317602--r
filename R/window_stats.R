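#' Windowing configuration
#'
#' Non-overlapping windows of `window_size` bp anchored at multiples of the
#' size in 0-based coordinates; windows with fewer than `min_snps` SNPs are
#' discarded from all statistic distributions.
#'
#' @param window_size Window size in bp (default 25000).
#' @param min_snps Minimum SNPs for a window to be retained (default 10).
#' @return An object of class `windowing_config`.
#' @export
windowing_config <- function(window_size = 25000, min_snps = 10) {
  if (window_size <= 0) stop_config("'window_size' must be > 0")
  if (min_snps < 1) stop_config("'min_snps' must be >= 1")
  structure(list(window_size = window_size, min_snps = min_snps),
            class = "windowing_config")
}

#' Assign records to non-overlapping windows
#'
#' A record at 1-based position `p` belongs to the window starting at
#' `floor((p - 1) / size) * size`; occupancy is half-open, so position
#' 25,000 falls in window `[0, 25000)`-printed-as-`0..25000` and position
#' 25,001 starts the next window. Consecutive windows share their printed
#' boundary.
#'
#' @param records Variant table.
#' @param config A [windowing_config()].
#' @return `records` with `win_start` and `win_end` columns added.
#' @export
assign_windows <- function(records, config = windowing_config()) {
  ws <- config$window_size
  records$win_start <- floor((records$pos - 1) / ws) * ws
  records$win_end <- records$win_start + ws
  records
}

#' Per-site Weir-Cockerham F_ST components
#'
#' For two populations with haploid sample sizes `n1`, `n2` and sample
#' allele frequencies `p1`, `p2`:
#' \deqn{MSP = \frac{n_1 n_2}{n_1 + n_2}(p_1 - p_2)^2,\quad
#'       MSG = \frac{n_1 p_1(1-p_1) + n_2 p_2(1-p_2)}{n_1 + n_2 - 2},\quad
#'       n_c = \frac{2 n_1 n_2}{n_1 + n_2}}
#' and the single-site estimate is
#' `fst = (MSP - MSG) / (MSP + (nc - 1) MSG)`, algebraically identical to
#' `1 - nc * MSG / (MSP + (nc - 1) MSG)`.
#'
#' @param p1,p2 Sample allele frequencies (vectors).
#' @param n1,n2 Haploid sample sizes (scalars or vectors).
#' @return `data.frame` with columns `msp`, `msg`, `nc`, `fst` (`fst` is
#'   `NaN` where both mean squares vanish).
#' @export
site_fst_components <- function(p1, p2, n1, n2) {
  if (any(n1 + n2 <= 2)) stop_config("need n1 + n2 > 2 haploid samples")
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1, na.rm = TRUE)) {
    stop_config("allele frequencies must lie in [0, 1]")
  }
  msp <- (n1 * n2 / (n1 + n2)) * (p1 - p2)^2
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (n1 + n2 - 2)
  nc <- 2 * n1 * n2 / (n1 + n2)
  denom <- msp + (nc - 1) * msg
  data.frame(msp = msp, msg = msg, nc = nc, fst = (msp - msg) / denom)
}

site_frequencies <- function(records, pools, n_mode = c("haploid", "min-depth")) {
  n_mode <- match.arg(n_mode)
  d1 <- records$ref1 + records$alt1
  d2 <- records$ref2 + records$alt2
  p1 <- ifelse(d1 > 0, records$alt1 / d1, NA_real_)
  p2 <- ifelse(d2 > 0, records$alt2 / d2, NA_real_)
  n1 <- pools[[1]]$haploids
  n2 <- pools[[2]]$haploids
  if (n_mode == "min-depth") {
    n1 <- pmax(2, pmin(n1, d1))
    n2 <- pmax(2, pmin(n2, d2))
  }
  list(p1 = p1, p2 = p2, n1 = n1, n2 = n2)
}

#' Windowed Weir-Cockerham F_ST
#'
#' Aggregates per-site mean squares over each retained window. The default
#' `"ratio-of-sums"` mode computes
#' `(sum MSP - sum MSG) / sum(MSP + (nc - 1) MSG)`; `"mean-of-ratios"`
#' averages the defined per-site estimates. No clamping is applied: weakly
#' differentiated windows may be (slightly) negative.
#'
#' @param records Filtered SNP table.
#' @param pools List of two [pool_spec()]s giving haploid sizes.
#' @param config A [windowing_config()].
#' @param mode Aggregation mode.
#' @param n_mode `"haploid"` uses `2 * individuals` as the per-site sample
#'   size; `"min-depth"` caps it at the observed depth.
#' @return `data.frame` with `chrom`, `win_start`, `win_end`, `n_snps`,
#'   `fst` for retained windows.
#' @export
window_fst <- function(records, pools = default_pools(),
                       config = windowing_config(),
                       mode = c("ratio-of-sums", "mean-of-ratios"),
                       n_mode = c("haploid", "min-depth")) {
  mode <- match.arg(mode)
  check_pools(pools)
  if (!("win_start" %in% names(records))) records <- assign_windows(records, config)
  sf <- site_frequencies(records, pools, match.arg(n_mode))
  comp <- site_fst_components(sf$p1, sf$p2, sf$n1, sf$n2)
  dt <- data.table::data.table(
    chrom = records$chrom, win_start = records$win_start,
    win_end = records$win_end, msp = comp$msp, msg = comp$msg,
    denom = comp$msp + (comp$nc - 1) * comp$msg, fst_site = comp$fst
  )
  dt <- dt[!is.na(msp) & !is.na(msg)]
  agg <- if (mode == "ratio-of-sums") {
    dt[, .(n_snps = .N,
           fst = (sum(msp) - sum(msg)) / sum(denom)),
       by = .(chrom, win_start, win_end)]
  } else {
    dt[, .(n_snps = .N, fst = mean(fst_site, na.rm = TRUE)),
       by = .(chrom, win_start, win_end)]
  }
  agg <- agg[n_snps >= config$min_snps]
  data.table::setorder(agg, chrom, win_start)
  as.data.frame(agg)
}

#' Windowed pooled heterozygosity H_p
#'
#' For each retained window, with `nMAJ`/`nMIN` the target pool's read
#' counts of its within-pool major/minor allele at each SNP:
#' \deqn{H_p = \frac{2 \sum n_{MAJ} \sum n_{MIN}}{(\sum n_{MAJ} + \sum n_{MIN})^2}}
#' `H_p` lies in `[0, 0.5]`, reaching 0.5 only when the summed counts are
#' equal; sweeps depress it.
#'
#' @param records Filtered SNP table.
#' @param config A [windowing_config()].
#' @param target_pool Pool (1 or 2) whose heterozygosity is scanned.
#' @return `data.frame` with `chrom`, `win_start`, `win_end`, `n_snps`, `hp`.
#' @export
window_hp <- function(records, config = windowing_config(), target_pool = 1L) {
  stopifnot(target_pool %in% 1:2)
  if (!("win_start" %in% names(records))) records <- assign_windows(records, config)
  refc <- records[[paste0("ref", target_pool)]]
  altc <- records[[paste0("alt", target_pool)]]
  dt <- data.table::data.table(
    chrom = records$chrom, win_start = records$win_start,
    win_end = records$win_end,
    n_maj = pmax(refc, altc), n_min = pmin(refc, altc)
  )
  agg <- dt[, .(n_snps = .N,
                hp = 2 * sum(n_maj) * sum(n_min) /
                  (sum(n_maj) + sum(n_min))^2),
            by = .(chrom, win_start, win_end)]
  agg <- agg[n_snps >= config$min_snps]
  zero <- agg$n_snps > 0 & !is.finite(agg$hp)
  if (any(zero)) {
    warning(sprintf("%d window(s) with zero total counts skipped", sum(zero)))
    agg <- agg[!zero]
  }
  data.table::setorder(agg, chrom, win_start)
  as.data.frame(agg)
}

#' Negative Z-transform of window H_p
#'
#' `-ZH_p = (mu - H_p) / sigma`, with `mu` and `sigma` the mean and standard
#' deviation of `H_p` over all retained windows (population convention,
#' divide by N). Large positive values mark heterozygosity deficits. The
#' returned parameters allow re-applying the same transform to other values
#' via [zhp_from_params()].
#'
#' @param hp Vector of window H_p values.
#' @param params Optional list with `mu` and `sigma` to reuse a previous
#'   transform instead of estimating from `hp`.
#' @return List with `zhp` and `params` (`mu`, `sigma`).
#' @export
z_transform <- function(hp, params = NULL) {
  if (is.null(params)) {
    if (length(hp) < 2L) stop_config("need >= 2 windows to estimate Z parameters")
    mu <- mean(hp)
    sigma <- sqrt(mean((hp - mu)^2))
    if (sigma == 0) stop_config("H_p values are constant; Z-transform degenerate")
    params <- list(mu = mu, sigma = sigma)
  }
  if (params$sigma <= 0) stop_config("'sigma' must be > 0")
  list(zhp = (params$mu - hp) / params$sigma, params = params)
}

#' Apply stored Z-transform parameters
#'
#' @param hp H_p values.
#' @param params List with `mu` and `sigma` (e.g. from [z_transform()] or
#'   [solve_z_params()]).
#' @return `-ZH_p` values.
#' @export
zhp_from_params <- function(hp, params) {
  (params$mu - hp) / params$sigma
}

#' Recover Z-transform parameters from two (H_p, -ZH_p) pairs
#'
#' Since `-ZH_p` is affine in `H_p`, two distinct pairs determine `mu` and
#' `sigma` exactly: `sigma = (hp1 - hp2) / (zhp2 - zhp1)`,
#' `mu = hp1 + zhp1 * sigma`. Useful for internal-consistency checks on
#' published window tables.
#'
#' @param hp Two H_p values.
#' @param zhp The corresponding `-ZH_p` values.
#' @return List with `mu` and `sigma`.
#' @export
solve_z_params <- function(hp, zhp) {
  stopifnot(length(hp) == 2L, length(zhp) == 2L)
  if (zhp[2] == zhp[1]) stop_config("the two pairs must have distinct -ZH_p")
  sigma <- (hp[1] - hp[2]) / (zhp[2] - zhp[1])
  if (sigma <= 0) stop_config("pairs are inconsistent with a decreasing affine relation")
  list(mu = hp[1] + zhp[1] * sigma, sigma = sigma)
}

#' Select the top quantile of a window statistic
#'
#' Selects the `ceiling(q * N)` most extreme windows (`direction = "high"`
#' keeps the largest values). Ties at the cutoff are broken deterministically
#' by (chromosome, window start). The reported threshold is the least extreme
#' selected value.
#'
#' @param windows Window table containing `chrom` and `win_start`.
#' @param column Name of the statistic column.
#' @param q Quantile in (0, 1), default 0.01.
#' @param direction `"high"` or `"low"`.
#' @return List with `threshold`, `selected` (the selected rows, sorted by
#'   chromosome and start), and `n_selected`.
#' @export
top_quantile <- function(windows, column, q = 0.01,
                         direction = c("high", "low")) {
  direction <- match.arg(direction)
  if (q <= 0 || q >= 1) stop_config("'q' must lie strictly between 0 and 1")
  v <- windows[[column]]
  if (length(v) == 0L) stop_config("no windows to select from")
  k <- ceiling(q * length(v))
  key <- if (direction == "high") -v else v
  o <- order(key, windows$chrom, windows$win_start)
  idx <- o[seq_len(k)]
  sel <- windows[idx, , drop = FALSE]
  thr <- if (direction == "high") min(sel[[column]]) else max(sel[[column]])
  sel <- sel[order(sel$chrom, sel$win_start), , drop = FALSE]
  rownames(sel) <- NULL
  list(threshold = thr, selected = sel, n_selected = k)
}

#' Compute all window statistics in one pass
#'
#' Convenience wrapper joining [window_fst()], [window_hp()] (with
#' [z_transform()]) and [window_xpclr()] on the shared window grid.
#'
#' @param records Filtered SNP table.
#' @param pools List of two [pool_spec()]s.
#' @param config A [windowing_config()].
#' @param target_pool Pool scanned for sweeps (H_p and XP-CLR object
#'   population); the other pool is the XP-CLR reference.
#' @param xpclr A [xpclr_config()] or `NULL` to skip XP-CLR.
#' @param fst_mode Aggregation mode for [window_fst()].
#' @return `data.frame` with `chrom`, `win_start`, `win_end`, `n_snps`,
#'   `fst`, `hp`, `zhp` and (unless skipped) `xpclr_raw`, `xpclr`, `s_hat`.
#' @export
scan_windows <- function(records, pools = default_pools(),
                         config = windowing_config(), target_pool = 1L,
                         xpclr = xpclr_config(),
                         fst_mode = c("ratio-of-sums", "mean-of-ratios")) {
  records <- assign_windows(records, config)
  fst <- window_fst(records, pools, config, mode = match.arg(fst_mode))
  hp <- window_hp(records, config, target_pool = target_pool)
  zt <- z_transform(hp$hp)
  hp$zhp <- zt$zhp
  out <- merge(fst, hp[, c("chrom", "win_start", "hp", "zhp")],
               by = c("chrom", "win_start"), all = FALSE)
  if (!is.null(xpclr)) {
    xp <- window_xpclr(records, pools, config = config,
                       target_pool = target_pool, xpclr = xpclr)
    out <- merge(out, xp[, c("chrom", "win_start", "xpclr_raw", "xpclr", "s_hat")],
                 by = c("chrom", "win_start"), all = FALSE)
  }
  out <- out[order(out$chrom, out$win_start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "z_params") <- zt$params
  out
}
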
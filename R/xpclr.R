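#' XP-CLR configuration
#'
#' The cross-population composite likelihood ratio contrasts a neutral model
#' (the object population's allele frequency drifts around the reference
#' frequency as a truncated Gaussian with variance `omega * p (1 - p)`)
#' against a sweep model in which linked alleles are dragged toward fixation
#' with escape probability `c = 1 - (2 N s)^(-r d / s)`. Scores are
#' maximized over a grid of selection coefficients containing the null
#' `s = 0`, so raw scores are non-negative.
#'
#' @param s_grid Selection-coefficient grid; must contain 0. Default: 0 plus
#'   10 log-spaced values from 1e-4 to 0.1.
#' @param n_effective Effective population size used in the escape
#'   probability.
#' @param rec_rate Constant recombination rate per bp per generation
#'   (default 1e-8) used to convert physical distances.
#' @param omega Drift variance parameter; `NULL` (default) estimates it from
#'   the data via [estimate_omega()].
#' @param n_points Gauss-Legendre quadrature resolution (>= 64).
#' @param sd_floor Numerical floor on the drift standard deviation, keeping
#'   the integrand resolvable by the quadrature.
#' @param omega_floor Floor applied by [estimate_omega()] when the estimate
#'   degenerates.
#' @return An object of class `xpclr_config`.
#' @export
xpclr_config <- function(s_grid = c(0, 10^seq(-4, -1, length.out = 10)),
                         n_effective = 1e4, rec_rate = 1e-8, omega = NULL,
                         n_points = 256, sd_floor = 0.01,
                         omega_floor = 1e-3) {
  if (!any(s_grid == 0)) stop_config("'s_grid' must contain the null s = 0")
  if (any(s_grid < 0)) stop_config("'s_grid' must be non-negative")
  if (n_points < 64) stop_config("'n_points' must be >= 64 quadrature points")
  if (!is.null(omega) && omega <= 0) stop_config("'omega' must be > 0")
  structure(
    list(s_grid = sort(unique(s_grid)), n_effective = n_effective,
         rec_rate = rec_rate, omega = omega, n_points = as.integer(n_points),
         sd_floor = sd_floor, omega_floor = omega_floor),
    class = "xpclr_config"
  )
}

#' Moment estimate of the drift variance parameter
#'
#' `omega = mean((p_obj - p_ref)^2 / (p_ref (1 - p_ref)))` over putatively
#' neutral sites, with the reference frequency clamped away from 0/1 by half
#' a quadrature step. Sites monomorphic in the reference sample (`p_ref` of
#' exactly 0 or 1) carry no information about drift and would dominate the
#' ratio through the clamped denominator, so they are excluded from the
#' moment sum. The estimate captures the full variance of the frequency
#' contrast (both populations' drift since the split plus pool/read
#' sampling), which is the spread the null model must reproduce.
#'
#' @param p_ref Reference-population allele frequencies.
#' @param p_obj Object-population allele frequencies.
#' @param n_points Quadrature resolution defining the clamp.
#' @param floor Lower bound; estimates below it are floored and flagged via
#'   the `degenerate` attribute.
#' @param min_sites Minimum number of usable sites.
#' @return Scalar omega with attribute `degenerate` (logical).
#' @export
estimate_omega <- function(p_ref, p_obj, n_points = 256, floor = 1e-3,
                           min_sites = 1000L) {
  ok <- is.finite(p_ref) & is.finite(p_obj) & p_ref > 0 & p_ref < 1
  p_ref <- p_ref[ok]; p_obj <- p_obj[ok]
  if (length(p_ref) < min_sites) {
    stop_config("need >= %d sites to estimate omega (got %d)",
                min_sites, length(p_ref))
  }
  clamp <- 1 / (2 * n_points)
  p <- pmin(1 - clamp, pmax(clamp, p_ref))
  om <- mean((p_obj - p)^2 / (p * (1 - p)))
  degenerate <- om < floor
  if (degenerate) {
    warning(sprintf("omega estimate %.3g below floor %.3g; floored (degenerate)",
                    om, floor))
    om <- floor
  }
  structure(om, degenerate = degenerate)
}

#' Per-site XP-CLR log composite likelihood
#'
#' Integrates the binomial emission of the object pool's read counts over
#' the modeled frequency density (truncated Gaussian drift around the
#' reference frequency under `s = 0`; its hitchhiking-transformed mixture
#' under `s > 0`) by Gauss-Legendre quadrature.
#'
#' @param p_ref Reference-population sample frequencies (vector).
#' @param alt,depth Object pool alternate read counts and depths.
#' @param dist Physical distance of each site from the scored focal point
#'   (bp).
#' @param s Selection coefficient(s); the result has one column per value.
#' @param omega Drift variance parameter.
#' @param config An [xpclr_config()] supplying `n_effective`, `rec_rate`,
#'   `n_points`, `sd_floor`.
#' @param n_points Optional quadrature-resolution override (used e.g. to
#'   cross-check a score against a finer integration).
#' @return Matrix of log likelihoods, `length(p_ref)` rows x `length(s)`
#'   columns.
#' @export
site_xpclr_loglik <- function(p_ref, alt, depth, dist, s, omega,
                              config = xpclr_config(), n_points = NULL) {
  np <- as.integer(n_points %||% config$n_points)
  if (any(dist < 0)) stop_config("distances must be >= 0")
  if (any(s < 0)) stop_config("'s' must be non-negative")
  gl <- pracma::gaussLegendre(np, 0, 1)
  ll <- cpp_xpclr_loglik(as.numeric(p_ref), as.integer(alt),
                         as.integer(depth), as.numeric(dist),
                         as.numeric(s), as.numeric(omega),
                         config$n_effective, config$rec_rate,
                         gl$x, gl$w, config$sd_floor)
  if (any(!is.finite(ll))) {
    bad <- which(!is.finite(ll), arr.ind = TRUE)[1L, ]
    stop_config("non-finite XP-CLR likelihood at site %d (s = %g)",
                bad[1L], s[bad[2L]])
  }
  ll
}

#' Windowed XP-CLR scores
#'
#' For each retained window, distances are measured from the window center
#' and the raw score is `2 * max_s (sum_i ll_i(s) - sum_i ll_i(0))` over the
#' configured grid; the composite sum runs over the window's SNPs. Raw
#' scores are Z-normalized over retained windows.
#'
#' @param records Filtered SNP table.
#' @param pools List of two [pool_spec()]s.
#' @param config A [windowing_config()].
#' @param target_pool The object population scanned for sweeps (1 or 2); the
#'   other pool provides the reference frequencies.
#' @param xpclr An [xpclr_config()].
#' @return `data.frame` with `chrom`, `win_start`, `win_end`, `n_snps`,
#'   `xpclr_raw`, `xpclr` (normalized), `s_hat` (argmax of the grid), plus
#'   an `omega` attribute.
#' @export
window_xpclr <- function(records, pools = default_pools(),
                         config = windowing_config(), target_pool = 1L,
                         xpclr = xpclr_config()) {
  stopifnot(target_pool %in% 1:2)
  ref_pool <- if (target_pool == 1L) 2L else 1L
  if (!("win_start" %in% names(records))) records <- assign_windows(records, config)
  d_obj <- records[[paste0("ref", target_pool)]] + records[[paste0("alt", target_pool)]]
  d_ref <- records[[paste0("ref", ref_pool)]] + records[[paste0("alt", ref_pool)]]
  usable <- d_obj > 0L & d_ref > 0L & records$type == "SNP"
  rec <- records[usable, , drop = FALSE]
  p_ref <- rec[[paste0("alt", ref_pool)]] / (d_ref[usable])
  alt_o <- rec[[paste0("alt", target_pool)]]
  dep_o <- d_obj[usable]
  p_obj <- alt_o / dep_o
  omega <- xpclr$omega %||%
    as.numeric(estimate_omega(p_ref, p_obj, n_points = xpclr$n_points,
                              floor = xpclr$omega_floor))
  gl <- pracma::gaussLegendre(xpclr$n_points, 0, 1)
  sgrid <- xpclr$s_grid
  null_col <- which(sgrid == 0)

  key <- paste(rec$chrom, rec$win_start, sep = "\r")
  groups <- split(seq_len(nrow(rec)), key)
  counts <- lengths(groups)
  groups <- groups[counts >= config$min_snps]
  rows <- lapply(groups, function(idx) {
    ws <- rec$win_start[idx[1L]]
    focal <- ws + config$window_size / 2
    ll <- cpp_xpclr_loglik(p_ref[idx], as.integer(alt_o[idx]),
                           as.integer(dep_o[idx]),
                           abs(rec$pos[idx] - focal),
                           sgrid, omega, xpclr$n_effective, xpclr$rec_rate,
                           gl$x, gl$w, xpclr$sd_floor)
    scores <- 2 * (colSums(ll) - sum(ll[, null_col]))
    best <- which.max(scores)
    data.frame(chrom = rec$chrom[idx[1L]], win_start = ws,
               win_end = rec$win_end[idx[1L]], n_snps = length(idx),
               xpclr_raw = max(scores[best], 0), s_hat = sgrid[best])
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) {
    stop_config("no windows with >= %d usable SNPs", config$min_snps)
  }
  out <- out[order(out$chrom, out$win_start), , drop = FALSE]
  rownames(out) <- NULL
  if (length(unique(out$xpclr_raw)) == 1L) {
    # every window prefers the null: no sweep signal anywhere; normalized
    # scores are all zero and the top quantile falls back to position order
    warning("raw XP-CLR scores are constant; normalized scores set to 0")
    out$xpclr <- rep(0, nrow(out))
    attr(out, "norm_params") <- list(mu = out$xpclr_raw[1L], sigma = 0)
  } else {
    nz <- normalize_scores(out$xpclr_raw)
    out$xpclr <- nz$z
    attr(out, "norm_params") <- nz$params
  }
  attr(out, "omega") <- omega
  out
}

#' Z-normalize raw scores over retained windows
#'
#' `(x - mean) / sd` with the population (divide-by-N) standard deviation,
#' so the outputs have mean 0 and sd 1 exactly.
#'
#' @param x Raw scores.
#' @return List with `z` and `params` (`mu`, `sigma`).
#' @export
normalize_scores <- function(x) {
  if (length(x) < 2L) stop_config("need >= 2 windows to normalize")
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (sigma == 0) stop_config("scores have zero variance; normalization degenerate")
  list(z = (x - mu) / sigma, params = list(mu = mu, sigma = sigma))
}
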
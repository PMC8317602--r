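#' Describe a sequenced pool
#'
#' A pool is a DNA mix of `individuals` diploid animals sequenced as one
#' library; its haploid sample size (`2 * individuals`) is the `n_i` entering
#' the Weir-Cockerham F_ST estimator.
#'
#' @param individuals Number of diploid individuals in the pool.
#' @param name Optional pool label used in file headers and VCF sample names.
#' @return An object of class `pool_spec`.
#' @examples
#' pool_spec(35, "small_breed")
#' @export
pool_spec <- function(individuals, name = NULL) {
  if (!is.numeric(individuals) || length(individuals) != 1L ||
      individuals < 1 || individuals != round(individuals)) {
    stop_config("'individuals' must be a single positive integer")
  }
  structure(
    list(individuals = as.integer(individuals),
         haploids = 2L * as.integer(individuals),
         name = name %||% sprintf("pool_%d", as.integer(individuals))),
    class = "pool_spec"
  )
}

#' @export
print.pool_spec <- function(x, ...) {
  cat(sprintf("<pool_spec> %s: %d diploids (n = %d haploid genomes)\n",
              x$name, x$individuals, x$haploids))
  invisible(x)
}

#' Default two-pool design
#'
#' The default design mirrors a two-breed dog comparison: a pool of 35
#' diploids scanned for sweeps against a reference pool of 59 diploids.
#'
#' @return List of two [pool_spec()] objects.
#' @export
default_pools <- function() {
  list(pool_spec(35L, "target_breed"), pool_spec(59L, "reference_breed"))
}

check_pools <- function(pools) {
  if (!is.list(pools) || length(pools) != 2L ||
      !all(vapply(pools, inherits, logical(1), "pool_spec"))) {
    stop_config("'pools' must be a list of exactly two pool_spec objects")
  }
  pools
}
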
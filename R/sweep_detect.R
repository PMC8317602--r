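#' Intersect three top-percentile window sets
#'
#' A window is a candidate sweep region when it appears in all three
#' top-percentile sets (F_ST, -ZH_p, normalized XP-CLR). All sets must come
#' from the same window grid.
#'
#' @param set_fst,set_zhp,set_xpclr Window tables with `chrom`, `win_start`,
#'   `win_end` (e.g. the `selected` element of [top_quantile()]).
#' @return `data.frame` of the intersection, sorted by (chromosome, start).
#' @export
intersect_top_windows <- function(set_fst, set_zhp, set_xpclr) {
  sets <- list(set_fst, set_zhp, set_xpclr)
  sizes <- unique(unlist(lapply(sets, function(s) {
    if (nrow(s) == 0L) return(NULL)
    unique(s$win_end - s$win_start)
  })))
  if (length(sizes) > 1L) {
    stop_config("window sets use different grids (window sizes: %s)",
                paste(sizes, collapse = ", "))
  }
  key <- function(s) paste(s$chrom, s$win_start, sep = "\r")
  common <- Reduce(intersect, lapply(sets, key))
  out <- set_fst[key(set_fst) %in% common,
                 c("chrom", "win_start", "win_end"), drop = FALSE]
  out <- out[order(out$chrom, out$win_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate candidate windows with overlapping genes
#'
#' A gene overlaps a window when `gene_start <= win_end` and
#' `gene_end > win_start` (at least 1 bp of overlap under the window's
#' half-open occupancy; a gene ending exactly at the window start does not
#' overlap). Gene lists are deduplicated and ordered by genomic start; a
#' gene spanning two candidate windows appears in both rows.
#'
#' @param candidates Window table (`chrom`, `win_start`, `win_end`).
#' @param genes Gene table from [read_gff3()].
#' @return `candidates` with a `genes` list-column of symbols and a
#'   `gene_symbol` column (comma-separated, `"-"` when empty).
#' @export
overlap_genes <- function(candidates, genes) {
  glist <- lapply(seq_len(nrow(candidates)), function(i) {
    w <- candidates[i, ]
    hit <- genes$chrom == w$chrom &
      genes$start <= w$win_end & genes$end > w$win_start
    g <- genes[hit, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    unique(g$symbol)
  })
  candidates$genes <- I(glist)
  candidates$gene_symbol <- vapply(glist, function(g) {
    if (length(g) == 0L) "-" else paste(g, collapse = ", ")
  }, character(1))
  candidates
}

#' Summarize candidate sweep regions
#'
#' @param regions Output of [overlap_genes()].
#' @return List with `n_regions`, `distinct_genes` (each symbol counted once
#'   across all regions), `n_distinct_genes`, and `n_without_genes`.
#' @export
summarize_candidates <- function(regions) {
  if (nrow(regions) == 0L) {
    return(list(n_regions = 0L, distinct_genes = character(0),
                n_distinct_genes = 0L, n_without_genes = 0L))
  }
  all_genes <- unique(unlist(regions$genes))
  list(n_regions = nrow(regions),
       distinct_genes = all_genes,
       n_distinct_genes = length(all_genes),
       n_without_genes = sum(lengths(regions$genes) == 0L))
}

#' Full candidate detection from a window-statistic table
#'
#' Selects the top `q` of each statistic with [top_quantile()], intersects
#' the three sets, and (optionally) annotates genes.
#'
#' @param windows Output of [scan_windows()] (columns `fst`, `zhp`,
#'   `xpclr`).
#' @param genes Optional gene table; `NULL` skips annotation.
#' @param q Top quantile (default 0.01).
#' @return List with `candidates` (annotated when `genes` given),
#'   `thresholds` (named vector), and the three `selected` tables.
#' @export
detect_candidates <- function(windows, genes = NULL, q = 0.01) {
  top_fst <- top_quantile(windows, "fst", q = q, direction = "high")
  top_zhp <- top_quantile(windows, "zhp", q = q, direction = "high")
  top_xp <- top_quantile(windows, "xpclr", q = q, direction = "high")
  cand <- intersect_top_windows(top_fst$selected, top_zhp$selected,
                                top_xp$selected)
  cand <- merge(cand, windows[, c("chrom", "win_start", "n_snps", "fst",
                                  "hp", "zhp", "xpclr")],
                by = c("chrom", "win_start"), all.x = TRUE, sort = FALSE)
  cand <- cand[order(cand$chrom, cand$win_start), , drop = FALSE]
  rownames(cand) <- NULL
  if (!is.null(genes)) cand <- overlap_genes(cand, genes)
  list(candidates = cand,
       thresholds = c(fst = top_fst$threshold, zhp = top_zhp$threshold,
                      xpclr = top_xp$threshold),
       top_fst = top_fst$selected, top_zhp = top_zhp$selected,
       top_xpclr = top_xp$selected)
}

#' Published candidate sweep windows from a two-breed dog scan
#'
#' The 12 25-kb windows reported to exceed the top-1% thresholds of all
#' three statistics (F_ST > 0.146, -ZH_p > 2.860, normalized XP-CLR > 3.07)
#' in a published comparison of a miniature dog breed against its parent
#' breed, with the genes overlapping each window. Used as an
#' internal-consistency fixture: the printed (H_p, -ZH_p) pairs determine a
#' single affine Z-transform, and the gene column deduplicates to nine
#' distinct symbols with three gene-less regions.
#'
#' @return `data.frame` with `chrom`, `win_start`, `win_end`, `fst`, `hp`,
#'   `zhp`, `xpclr`, `gene_symbol`, plus a `thresholds` attribute.
#' @export
published_candidate_regions <- function() {
  out <- data.frame(
    chrom = c("1", "1", "3", "5", "5", "5", "5", "8", "8", "27", "33", "36"),
    win_start = c(109625000, 116300000, 52950000, 40575000, 42875000,
                  57800000, 57825000, 34250000, 62250000, 18625000,
                  23675000, 7975000),
    win_end = c(109650000, 116325000, 52975000, 40600000, 42900000,
                57825000, 57850000, 34275000, 62275000, 18650000,
                23700000, 8000000),
    fst = c(0.149, 0.149, 0.196, 0.199, 0.184, 0.170, 0.211, 0.147, 0.149,
            0.217, 0.169, 0.162),
    hp = c(0.076, 0.040, 0.008, 0.045, 0.060, 0.031, 0.040, 0.044, 0.064,
           0.041, 0.055, 0.040),
    zhp = c(2.873, 3.292, 3.677, 3.232, 3.060, 3.406, 3.297, 3.244, 3.015,
            3.278, 3.121, 3.294),
    xpclr = c(3.305, 6.477, 15.727, 3.143, 9.002, 8.475, 20.152, 24.152,
              4.824, 19.421, 31.624, 25.154),
    gene_symbol = c("CCDC61", "ZNF382, ZNF461", "-", "ALDH3A2",
                    "ENSCAFG00000018533", "PRDM16", "PRDM16",
                    "ENSCAFG00000033351", "-", "ERGIC2",
                    "ENSCAFG00000011141", "-")
  )
  out$genes <- I(lapply(strsplit(out$gene_symbol, ",\\s*"), function(g) {
    setdiff(g, "-")
  }))
  attr(out, "thresholds") <- c(fst = 0.146, zhp = 2.860, xpclr = 3.07)
  out
}
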
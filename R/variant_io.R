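SYNC_BASES <- c("A", "T", "C", "G")  # sync sextet order is A:T:C:G:N:del

#' Write a variant table as a Popoolation2 sync file
#'
#' One line per site: chromosome, position, reference base, then one
#' colon-separated count sextet `A:T:C:G:N:del` per pool. SNP alternate
#' counts go to the alternate base's slot; indel alternate counts go to the
#' `del` slot (the sync dialect carries no indel allele strings).
#'
#' @param records Variant table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sync <- function(records, path) {
  check_variant_table(records)
  if (nrow(records) == 0L) stop_config("refusing to write an empty sync file")
  refb <- substr(records$ref, 1L, 1L)
  sextet <- function(refn, altn) {
    m <- matrix(0L, nrow = nrow(records), ncol = 6L)
    ri <- match(refb, SYNC_BASES)
    m[cbind(seq_len(nrow(records)), ri)] <- refn
    is_snp <- records$type == "SNP"
    ai <- match(records$alt, SYNC_BASES)
    snp_rows <- which(is_snp & !is.na(ai))
    m[cbind(snp_rows, ai[snp_rows])] <- m[cbind(snp_rows, ai[snp_rows])] + altn[snp_rows]
    ind_rows <- which(!is_snp)
    m[cbind(ind_rows, rep(6L, length(ind_rows)))] <- altn[ind_rows]
    apply(m, 1L, paste, collapse = ":")
  }
  lines <- paste(records$chrom, records$pos, refb,
                 sextet(records$ref1, records$alt1),
                 sextet(records$ref2, records$alt2),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

parse_sextets <- function(col, lineno) {
  parts <- data.table::tstrsplit(col, ":", fixed = TRUE)
  if (length(parts) != 6L) {
    bad <- lineno[1L]
    stop_config("malformed count sextet at line %d (expected 6 ':'-separated counts)", bad)
  }
  m <- suppressWarnings(vapply(parts, as.integer, integer(length(col))))
  if (!is.matrix(m)) m <- matrix(m, nrow = length(col))
  bad <- which(rowSums(is.na(m)) > 0L | grepl("[^0-9:]", col))
  if (length(bad) > 0L) {
    stop_config("malformed count sextet at line %d: '%s'", lineno[bad[1L]], col[bad[1L]])
  }
  m
}

#' Read a Popoolation2 sync file for two pools
#'
#' Per-pool base counts are mapped to reference/alternate counts against the
#' stated reference base; the most frequent non-reference base across both
#' pools becomes the alternate allele (ties broken in A,T,C,G order). Sites
#' whose non-reference signal is dominated by the `del` slot are typed as
#' indels. Sync files carry no site quality, so `qual` is `NA` (records then
#' pass the quality filter by default).
#'
#' @param path Sync file path.
#' @param pools List of two [pool_spec()]s (kept for interface symmetry;
#'   counts are taken from the file).
#' @return Variant table.
#' @export
read_sync <- function(path, pools = default_pools()) {
  if (!file.exists(path)) stop_config("sync file '%s' does not exist", path)
  check_pools(pools)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = "character", fill = TRUE)
  if (ncol(dt) != 5L) {
    stop_config("expected %d tab-separated columns (chrom, pos, ref + 2 pools), found %d",
                5L, ncol(dt))
  }
  n <- nrow(dt)
  lineno <- seq_len(n)
  if (any(is.na(dt[[4L]])) || any(is.na(dt[[5L]]))) {
    stop_config("malformed count sextet at line %d",
                lineno[which(is.na(dt[[4L]]) | is.na(dt[[5L]]))[1L]])
  }
  m1 <- parse_sextets(dt[[4L]], lineno)
  m2 <- parse_sextets(dt[[5L]], lineno)
  refb <- toupper(dt[[3L]])
  ri <- match(refb, SYNC_BASES)
  if (anyNA(ri)) {
    stop_config("unknown reference base at line %d", lineno[which(is.na(ri))[1L]])
  }
  tot <- m1[, 1:4, drop = FALSE] + m2[, 1:4, drop = FALSE]
  tot[cbind(seq_len(n), ri)] <- -1L  # exclude ref base from alt choice
  ai <- max.col(tot, ties.method = "first")
  alt_base_count <- tot[cbind(seq_len(n), ai)]
  del_tot <- m1[, 6L] + m2[, 6L]
  is_indel <- del_tot > 0L & del_tot >= alt_base_count
  alt <- ifelse(is_indel, refb, SYNC_BASES[ai])
  ref <- ifelse(is_indel, paste0(refb, "N"), refb)  # placeholder deletion allele
  alt1 <- ifelse(is_indel, m1[, 6L], m1[cbind(seq_len(n), ai)])
  alt2 <- ifelse(is_indel, m2[, 6L], m2[cbind(seq_len(n), ai)])
  data.frame(
    chrom = dt[[1L]], pos = as.integer(dt[[2L]]),
    ref = ref, alt = alt,
    type = ifelse(is_indel, "indel", "SNP"),
    qual = NA_real_,
    ref1 = m1[cbind(seq_len(n), ri)], alt1 = as.integer(alt1),
    ref2 = m2[cbind(seq_len(n), ri)], alt2 = as.integer(alt2)
  )
}

#' Write a variant table as a two-sample VCF with allelic depths
#'
#' Minimal VCF 4.2 with `QUAL` from the record quality and a `AD:DP` FORMAT
#' per pool sample, which is what [read_vcf_counts()] consumes.
#'
#' @param records Variant table.
#' @param path Output path.
#' @param pools List of two [pool_spec()]s providing the sample names.
#' @param contigs Optional named vector of contig lengths for the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, pools = default_pools(), contigs = NULL) {
  check_variant_table(records)
  if (nrow(records) == 0L) stop_config("refusing to write an empty VCF")
  check_pools(pools)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=poolsweep",
    if (!is.null(contigs)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs))
    },
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", pools[[1]]$name, pools[[2]]$name), collapse = "\t")
  )
  body <- paste(
    records$chrom, records$pos, ".", records$ref, records$alt,
    ifelse(is.na(records$qual), ".", format(records$qual, trim = TRUE)),
    ".", ".", "AD:DP",
    sprintf("%d,%d:%d", records$ref1, records$alt1, records$ref1 + records$alt1),
    sprintf("%d,%d:%d", records$ref2, records$alt2, records$ref2 + records$alt2),
    sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read per-pool allelic depths from a VCF
#'
#' Extracts biallelic records from a VCF whose two samples carry an `AD`
#' FORMAT field. At multiallelic sites the alternate allele with the largest
#' summed depth across both samples is kept and the others dropped; the
#' number of such collapsed sites is recorded in the `multiallelic` attribute
#' of the result.
#'
#' @param path VCF path (plain or bgzipped).
#' @return Variant table with a `multiallelic` attribute.
#' @export
read_vcf_counts <- function(path) {
  if (!file.exists(path)) stop_config("VCF '%s' does not exist", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(v@gt) < 3L) stop_config("VCF must contain two pool samples")
  fmt <- v@gt[, 1L]
  if (!all(grepl("(^|:)AD(:|$)", fmt))) {
    stop_config("VCF lacks the AD (allelic depth) FORMAT field")
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  fix <- vcfR::getFIX(v)
  n <- nrow(fix)
  ref <- fix[, "REF"]
  alt_full <- fix[, "ALT"]
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  split_counts <- function(x) {
    parts <- strsplit(x, ",", fixed = TRUE)
    lapply(parts, function(p) suppressWarnings(as.integer(p)))
  }
  ad1 <- split_counts(ad[, 1L])
  ad2 <- split_counts(ad[, 2L])
  alts <- strsplit(alt_full, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  multi <- sum(n_alt > 1L)
  pick <- vapply(seq_len(n), function(i) {
    if (n_alt[i] == 1L) return(1L)
    tot <- (ad1[[i]][-1L] %||% 0L) + (ad2[[i]][-1L] %||% 0L)
    which.max(tot)
  }, integer(1))
  alt <- vapply(seq_len(n), function(i) alts[[i]][pick[i]], character(1))
  take <- function(adl, i) {
    x <- adl[[i]]
    if (length(x) < pick[i] + 1L || anyNA(x[c(1L, pick[i] + 1L)])) {
      stop_config("missing AD values at record %d", i)
    }
    c(x[1L], x[pick[i] + 1L])
  }
  c1 <- vapply(seq_len(n), function(i) take(ad1, i), integer(2))
  c2 <- vapply(seq_len(n), function(i) take(ad2, i), integer(2))
  data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = ref, alt = alt,
    type = ifelse(nchar(ref) != nchar(alt), "indel", "SNP"),
    qual = qual,
    ref1 = c1[1L, ], alt1 = c1[2L, ],
    ref2 = c2[1L, ], alt2 = c2[2L, ]
  ) -> out
  attr(out, "multiallelic") <- multi
  out
}

#' Read gene models from a GFF3 file
#'
#' Keeps `gene`-type features only, 1-based inclusive coordinates as in the
#' file. The gene symbol is the `Name` attribute, falling back to `ID` (bare
#' ENSEMBL-style ids keep their stable id as symbol).
#'
#' @param path GFF3 path.
#' @return `data.frame` with columns `gene_id`, `symbol`, `chrom`, `start`,
#'   `end`, `strand`.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop_config("GFF3 '%s' does not exist", path)
  g <- ape::read.gff(path, na.strings = c(".", "?"), GFF3 = TRUE)
  g <- g[g$type == "gene", , drop = FALSE]
  if (nrow(g) == 0L) {
    warning("no gene-type features found in GFF3; returning empty table")
    return(data.frame(gene_id = character(0), symbol = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  }
  attr_field <- function(attrs, key) {
    pat <- sprintf("(^|;)\\s*%s=[^;]+", key)
    m <- regexpr(pat, attrs)
    out <- rep(NA_character_, length(attrs))
    hit <- m > 0L
    out[hit] <- sub(sprintf(".*%s=", key), "", regmatches(attrs, m))
    out
  }
  ids <- attr_field(g$attributes, "ID")
  nm <- attr_field(g$attributes, "Name")
  ids[is.na(ids)] <- sprintf("gene_%d", which(is.na(ids)))
  data.frame(
    gene_id = ids, symbol = ifelse(is.na(nm), ids, nm),
    chrom = as.character(g$seqid), start = g$start, end = g$end,
    strand = as.character(g$strand), row.names = NULL
  )
}

#' Write gene models as GFF3
#'
#' @param genes Gene table as from [read_gff3()] or [toy_gene_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tpoolsweep\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                     genes$chrom, as.integer(genes$start), as.integer(genes$end),
                     genes$strand, genes$gene_id, genes$symbol))
  writeLines(lines, path)
  invisible(path)
}

#' SNP filtering configuration
#'
#' Defaults mirror the standard pool-seq quality rules: discard SNPs with
#' minor allele frequency below 0.05 (computed on counts summed over both
#' pools), depth below 10, quality below 20, or lying within 15 bp of an
#' indel. The boundary is strict for MAF/depth/quality (`< threshold` is
#' discarded) and inclusive for indel distance (`<= indel_dist` is
#' discarded).
#'
#' @param min_maf Minimum minor allele frequency.
#' @param min_depth Minimum read depth.
#' @param min_qual Minimum site quality.
#' @param indel_dist Exclusion distance around indels (bp).
#' @param depth_mode `"per-pool"` (default; both pools must reach
#'   `min_depth`) or `"combined"` (summed depth must).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_maf = 0.05, min_depth = 10, min_qual = 20,
                          indel_dist = 15, depth_mode = c("per-pool", "combined")) {
  if (min_maf < 0 || min_maf >= 0.5) stop_config("'min_maf' must lie in [0, 0.5)")
  if (min_depth < 0 || min_qual < 0 || indel_dist < 0) {
    stop_config("filter thresholds must be >= 0")
  }
  structure(
    list(min_maf = min_maf, min_depth = min_depth, min_qual = min_qual,
         indel_dist = indel_dist, depth_mode = match.arg(depth_mode)),
    class = "filter_config"
  )
}

nearest_indel_distance <- function(records) {
  dist <- rep(Inf, nrow(records))
  for (cn in unique(records$chrom)) {
    on <- records$chrom == cn
    anchors <- sort(records$pos[on & records$type == "indel"])
    if (length(anchors) == 0L) next
    p <- records$pos[on]
    idx <- findInterval(p, anchors)
    left <- ifelse(idx >= 1L, p - anchors[pmax(idx, 1L)], Inf)
    right <- ifelse(idx < length(anchors), anchors[pmin(idx + 1L, length(anchors))] - p, Inf)
    dist[on] <- pmin(abs(left), abs(right))
  }
  dist
}

#' Apply SNP quality filters
#'
#' A SNP is discarded when its combined minor allele frequency is below
#' `min_maf`, its depth is below `min_depth` (per pool by default), its
#' quality is below `min_qual` (records with missing quality pass), or it
#' lies within `indel_dist` bp of an indel on the same chromosome. Indel
#' records are excluded from the SNP output but serve as exclusion anchors.
#'
#' @param records Variant table sorted by (chromosome, position).
#' @param config A [filter_config()].
#' @return List with `records` (retained SNPs) and `report` (a
#'   `filter_report`: input/retained counts and per-rule discard tallies; a
#'   record failing several rules is tallied once per rule and once overall).
#' @export
apply_filters <- function(records, config = filter_config()) {
  check_variant_table(records, require_sorted = TRUE)
  is_indel <- records$type == "indel"
  idist <- nearest_indel_distance(records)

  d1 <- records$ref1 + records$alt1
  d2 <- records$ref2 + records$alt2
  tot_alt <- records$alt1 + records$alt2
  tot <- d1 + d2
  f <- ifelse(tot > 0, tot_alt / tot, NA_real_)
  maf <- pmin(f, 1 - f)

  fail_maf <- !is_indel & !is.na(maf) & maf < config$min_maf
  fail_depth <- !is_indel & if (config$depth_mode == "per-pool") {
    d1 < config$min_depth | d2 < config$min_depth
  } else {
    tot < config$min_depth
  }
  fail_qual <- !is_indel & !is.na(records$qual) & records$qual < config$min_qual
  fail_indel <- !is_indel & idist <= config$indel_dist

  fail_any <- fail_maf | fail_depth | fail_qual | fail_indel
  keep <- !is_indel & !fail_any
  report <- structure(
    list(input = nrow(records),
         retained = sum(keep),
         discarded = list(maf = sum(fail_maf), depth = sum(fail_depth),
                          qual = sum(fail_qual),
                          indel_proximity = sum(fail_indel),
                          indel_records = sum(is_indel)),
         discarded_unique = sum(fail_any) + sum(is_indel),
         config = config),
    class = "filter_report"
  )
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %d records in, %d SNPs retained (%.1f%%)\n",
              x$input, x$retained, 100 * x$retained / max(1, x$input)))
  d <- x$discarded
  cat(sprintf("  discarded: MAF %d | depth %d | quality %d | near-indel %d | indel records %d\n",
              d$maf, d$depth, d$qual, d$indel_proximity, d$indel_records))
  invisible(x)
}

#' Write a filter report as TSV
#'
#' @param report A `filter_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  df <- data.frame(
    metric = c("input", "retained", "discarded_maf", "discarded_depth",
               "discarded_qual", "discarded_indel_proximity", "indel_records",
               "discarded_unique"),
    value = c(report$input, report$retained, report$discarded$maf,
              report$discarded$depth, report$discarded$qual,
              report$discarded$indel_proximity, report$discarded$indel_records,
              report$discarded_unique)
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Transition/transversion ratio
#'
#' Ratio of transition (A<->G, C<->T) to transversion substitution counts, a
#' standard quality indicator for a SNP set. Optionally restricted to sites
#' where a given pool carries alternate reads, giving a per-population ratio.
#'
#' @param records Variant table (non-SNP records are ignored).
#' @param pool `NULL` for all SNPs, or 1/2 to count only SNPs with alternate
#'   reads in that pool.
#' @return List with `ratio` (`NA` and a warning when no transversions),
#'   `transitions`, `transversions`.
#' @export
compute_tstv <- function(records, pool = NULL) {
  snps <- records[records$type == "SNP", , drop = FALSE]
  if (!is.null(pool)) {
    stopifnot(pool %in% 1:2)
    snps <- snps[snps[[paste0("alt", pool)]] > 0L, , drop = FALSE]
  }
  if (nrow(snps) == 0L) {
    warning("no SNP records; Ts/Tv undefined")
    return(list(ratio = NA_real_, transitions = 0L, transversions = 0L))
  }
  pair <- paste0(snps$ref, snps$alt)
  ts <- sum(pair %in% c("AG", "GA", "CT", "TC"))
  tv <- nrow(snps) - ts
  if (tv == 0L) {
    warning("no transversions; Ts/Tv undefined")
    return(list(ratio = NA_real_, transitions = ts, transversions = 0L))
  }
  list(ratio = ts / tv, transitions = ts, transversions = tv)
}
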
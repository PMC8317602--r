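#' Pipeline configuration
#'
#' Bundles every stage's parameters for a simulate -> filter -> scan ->
#' detect run. May also be read from a YAML file via
#' [read_pipeline_config()].
#'
#' @param out_dir Output directory (created if missing).
#' @param sim A [sim_config()]; `NULL` when reading existing input files.
#' @param sweeps List of [sweep_spec()]s planted by the simulation stage.
#' @param filter A [filter_config()].
#' @param windowing A [windowing_config()].
#' @param xpclr An [xpclr_config()].
#' @param target_pool Population scanned for sweeps (H_p / XP-CLR object).
#' @param q Top quantile for candidate selection.
#' @param gff Optional path to an existing GFF3; `NULL` writes a toy
#'   annotation from the simulation.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, sim = sim_config(), sweeps = list(),
                            filter = filter_config(),
                            windowing = windowing_config(),
                            xpclr = xpclr_config(), target_pool = 1L,
                            q = 0.01, gff = NULL) {
  if (q <= 0 || q >= 1) stop_config("'q' must lie strictly between 0 and 1")
  structure(
    list(out_dir = out_dir, sim = sim, sweeps = sweeps, filter = filter,
         windowing = windowing, xpclr = xpclr,
         target_pool = as.integer(target_pool), q = q, gff = gff),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' The file mirrors the arguments of [pipeline_config()], [sim_config()],
#' [sweep_spec()], [filter_config()], [windowing_config()] and
#' [xpclr_config()] as nested keys; `sim: seed:` is mandatory.
#'
#' @param path YAML file.
#' @param out_dir Output directory override (defaults to the file's
#'   `out_dir` key).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  simy <- y$sim %||% list()
  if (!is.null(simy$chrom_lengths)) {
    simy$chrom_lengths <- unlist(simy$chrom_lengths)
  }
  if (!is.null(simy$pools)) {
    simy$pools <- lapply(simy$pools, function(p) {
      pool_spec(p$individuals, p$name %||% NULL)
    })
  }
  if (is.null(simy$seed)) stop_config("config must set sim: seed")
  sweeps <- lapply(y$sweeps %||% list(), function(s) do.call(sweep_spec, s))
  pipeline_config(
    out_dir = out_dir %||% y$out_dir %||% stop_config("config must set out_dir"),
    sim = do.call(sim_config, simy),
    sweeps = sweeps,
    filter = do.call(filter_config, y$filter %||% list()),
    windowing = do.call(windowing_config, y$windowing %||% list()),
    xpclr = do.call(xpclr_config, y$xpclr %||% list()),
    target_pool = y$target_pool %||% 1L,
    q = y$q %||% 0.01,
    gff = y$gff
  )
}

write_stat_tsv <- function(df, path, params = character(0)) {
  hdr <- c(sprintf("# poolsweep %s", as.character(utils::packageVersion("poolsweep"))),
           sprintf("# %s", params))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  keep <- !vapply(df, is.list, logical(1))
  suppressWarnings(write.table(df[, keep, drop = FALSE], con, sep = "\t",
                               quote = FALSE, row.names = FALSE))
  invisible(path)
}

#' Read a statistic TSV written by [run_pipeline()]
#'
#' @param path TSV path ('#'-prefixed metadata lines are skipped).
#' @return `data.frame`.
#' @export
read_stat_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE, colClasses = NA)
}

#' Run the full synthetic sweep-scan pipeline
#'
#' Stages run in dependency order: simulate (sync/VCF/GFF3/truth files),
#' filter, window statistics (F_ST, H_p/-ZH_p, XP-CLR), candidate detection
#' and gene annotation, and recovery evaluation against the planted truth.
#' Every output TSV carries '#'-prefixed metadata (package version, seed,
#' parameters); rerunning with an identical config reproduces identical
#' statistic files.
#'
#' @param config A [pipeline_config()].
#' @return List with `manifest` (`data.frame` of file, md5), `windows`,
#'   `candidates`, `thresholds`, `summary`, `recovery`, `filter_report`,
#'   `sim`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop_config("'config' must be a pipeline_config")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  meta <- sprintf("seed=%d q=%g target_pool=%d window=%d min_snps=%d",
                  config$sim$seed, config$q, config$target_pool,
                  config$windowing$window_size, config$windowing$min_snps)

  # --- simulate -------------------------------------------------------
  sim <- simulate_poolseq(config$sim, config$sweeps,
                          window_size = config$windowing$window_size)
  write_sync(sim$records, p("variants.sync"))
  write_vcf(sim$records, p("variants.vcf"), pools = config$sim$pools,
            contigs = config$sim$chrom_lengths)
  if (is.null(config$gff)) {
    genes <- toy_gene_annotation(sim, seed = config$sim$seed)
    write_gff3(genes, p("genes.gff3"))
    gff_path <- p("genes.gff3")
  } else {
    if (!file.exists(config$gff)) {
      stop_config("detect stage: GFF3 '%s' not found", config$gff)
    }
    genes <- read_gff3(config$gff)
    gff_path <- config$gff
  }
  write_stat_tsv(sim$truth, p("truth_windows.tsv"), meta)

  # --- filter ---------------------------------------------------------
  flt <- apply_filters(sim$records, config$filter)
  write_filter_report(flt$report, p("filter_report.tsv"))
  write_sync(flt$records, p("variants.filtered.sync"))

  # --- scan -----------------------------------------------------------
  windows <- scan_windows(flt$records, pools = config$sim$pools,
                          config = config$windowing,
                          target_pool = config$target_pool,
                          xpclr = config$xpclr)
  write_stat_tsv(windows[, c("chrom", "win_start", "win_end", "n_snps", "fst")],
                 p("fst_windows.tsv"), meta)
  write_stat_tsv(windows[, c("chrom", "win_start", "win_end", "n_snps", "hp", "zhp")],
                 p("zhp_windows.tsv"), meta)
  write_stat_tsv(windows[, c("chrom", "win_start", "win_end", "n_snps",
                             "xpclr_raw", "xpclr", "s_hat")],
                 p("xpclr_windows.tsv"), meta)

  # --- detect ---------------------------------------------------------
  det <- detect_candidates(windows, genes = genes, q = config$q)
  write_stat_tsv(det$candidates, p("candidates.tsv"),
                 c(meta, sprintf("thresholds fst=%.4g zhp=%.4g xpclr=%.4g",
                                 det$thresholds["fst"], det$thresholds["zhp"],
                                 det$thresholds["xpclr"])))
  summary <- summarize_candidates(det$candidates)
  recovery <- evaluate_recovery(det$candidates, sim$truth)

  files <- c("variants.sync", "variants.vcf", basename(gff_path),
             "truth_windows.tsv", "filter_report.tsv",
             "variants.filtered.sync", "fst_windows.tsv", "zhp_windows.tsv",
             "xpclr_windows.tsv", "candidates.tsv")
  files <- unique(files)
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(config$out_dir, files)))
  )
  list(manifest = manifest, windows = windows, candidates = det$candidates,
       thresholds = det$thresholds, summary = summary, recovery = recovery,
       filter_report = flt$report, sim = sim)
}

#' Evaluate sweep recovery against the planted truth
#'
#' Window-level sensitivity is the fraction of truth windows that are
#' candidates; footprint-level sensitivity is the fraction of planted sweeps
#' with at least one candidate window inside their footprint; the false
#' discovery proportion (FDP) is the fraction of candidate windows outside
#' every footprint.
#'
#' @param candidates Candidate window table (`chrom`, `win_start`).
#' @param truth Truth table from [truth_table()] (columns `sweep`, `chrom`,
#'   `win_start`).
#' @return List with `window_sensitivity`, `footprint_sensitivity`, `fdp`,
#'   `n_candidates`, `n_truth_windows`, `n_sweeps`. With an empty truth
#'   table the sensitivities are `NA` (flagged by a warning).
#' @export
evaluate_recovery <- function(candidates, truth) {
  key <- function(df) paste(df$chrom, df$win_start, sep = "\r")
  n_cand <- nrow(candidates)
  if (nrow(truth) == 0L) {
    warning("empty truth table; sensitivity undefined")
    return(list(window_sensitivity = NA_real_,
                footprint_sensitivity = NA_real_,
                fdp = if (n_cand > 0L) 1 else NA_real_,
                n_candidates = n_cand, n_truth_windows = 0L, n_sweeps = 0L))
  }
  in_truth <- key(candidates) %in% key(truth)
  hit_windows <- key(truth) %in% key(candidates)
  sweeps_hit <- tapply(hit_windows, truth$sweep, any)
  list(
    window_sensitivity = mean(hit_windows),
    footprint_sensitivity = mean(sweeps_hit),
    fdp = if (n_cand > 0L) mean(!in_truth) else 0,
    n_candidates = n_cand,
    n_truth_windows = nrow(truth),
    n_sweeps = length(sweeps_hit)
  )
}
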
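`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' @noRd
check_variant_table <- function(records, require_sorted = FALSE) {
  needed <- c("chrom", "pos", "ref", "alt", "type", "qual",
              "ref1", "alt1", "ref2", "alt2")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0L) {
    stop_config("variant table is missing column(s): %s",
                paste(missing, collapse = ", "))
  }
  if (any(records$pos < 1L)) stop_config("positions must be 1-based (>= 1)")
  if (require_sorted && nrow(records) > 1L) {
    o <- order(records$chrom, records$pos)
    if (!identical(o, seq_len(nrow(records)))) {
      stop_config("records must be sorted by (chromosome, position)")
    }
  }
  invisible(records)
}

pool_depths <- function(records) {
  cbind(records$ref1 + records$alt1, records$ref2 + records$alt2)
}
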
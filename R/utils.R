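# Internal helpers shared across modules. All genomic coordinates inside the
# package are 0-based half-open (BED convention); conversions happen at the
# file boundary only.

# Coerce a tibble of intervals (chrom/start/end [+ strand]) to GRanges.
# GRanges is 1-based closed, so start+1 on the way in.
tbl_to_gr <- function(x) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  strand <- if ("strand" %in% names(x)) {
    s <- as.character(x$strand)
    s[!s %in% c("+", "-")] <- "*"
    s
  } else rep("*", nrow(x))
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

check_interval_tbl <- function(x, what = "intervals") {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame of intervals.", what))
  }
  missing <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(missing) > 0) {
    abort(sprintf("`%s` lacks column(s): %s.", what,
                  paste(missing, collapse = ", ")))
  }
  if (nrow(x) > 0) {
    if (any(x$end <= x$start)) {
      abort(sprintf("`%s` contains intervals with end <= start.", what))
    }
    if (any(x$start < 0)) {
      abort(sprintf("`%s` contains negative start coordinates.", what))
    }
  }
  invisible(x)
}

# A seed derived from a master seed and a stage label, kept inside .Machine
# integer range so set.seed() accepts it.
derive_seed <- function(seed, stage) {
  stage_num <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + stage_num) %% 2147483647)
}

fmt_num <- function(x, digits = 6) {
  formatC(x, digits = digits, format = "f")
}
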
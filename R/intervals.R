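#' Build a fast overlap index over a set of genomic intervals
#'
#' Wraps the interval collection in a [GenomicRanges::GRanges] so repeated
#' overlap queries run through the interval-tree machinery of
#' `findOverlaps()` instead of a linear scan. The original rows travel with
#' the index and are returned verbatim by [query_overlaps()].
#'
#' @param x A data frame of intervals with columns `chrom`, `start`, `end`
#'   (0-based half-open) and optionally `strand` plus any payload columns
#'   (scores, names, ...).
#' @return An object of class `interval_index`.
#' @examples
#' peaks <- tibble::tibble(chrom = "chr1", start = c(100, 500), end = c(200, 800))
#' idx <- build_index(peaks)
#' query_overlaps(idx, tibble::tibble(chrom = "chr1", start = 150, end = 160))
#' @export
build_index <- function(x) {
  check_interval_tbl(x)
  x <- as_tibble(x)
  structure(
    list(gr = tbl_to_gr(x), table = x),
    class = "interval_index"
  )
}

#' @export
print.interval_index <- function(x, ...) {
  cat(sprintf("<interval_index: %d intervals on %d chromosome(s)>\n",
              nrow(x$table),
              length(unique(x$table$chrom))))
  invisible(x)
}

#' Query an interval index for overlapping intervals
#'
#' Overlap means at least one shared base pair under half-open semantics:
#' `[100, 200)` overlaps `[199, 300)` but not `[200, 300)`.
#'
#' @param index An `interval_index` from [build_index()].
#' @param query A data frame of query intervals (`chrom`, `start`, `end`).
#' @return A tibble of the stored intervals that overlap any query interval,
#'   with a `query_row` column identifying which query row each hit answers
#'   (one output row per (query, hit) pair).
#' @export
query_overlaps <- function(index, query) {
  stopifnot(inherits(index, "interval_index"))
  check_interval_tbl(query, "query")
  if (nrow(query) == 0 || nrow(index$table) == 0) {
    out <- index$table[0, , drop = FALSE]
    out$query_row <- integer(0)
    return(relocate(as_tibble(out), "query_row"))
  }
  qgr <- align_seqlevels(tbl_to_gr(query), index$gr)
  hits <- GenomicRanges::findOverlaps(qgr, index$gr, ignore.strand = TRUE)
  out <- index$table[S4Vectors::subjectHits(hits), , drop = FALSE]
  out$query_row <- S4Vectors::queryHits(hits)
  relocate(as_tibble(out), "query_row")
}

# Vectorised: for each query interval, does >= 1 stored interval overlap it?
idx_any_overlap <- function(index, query) {
  stopifnot(inherits(index, "interval_index"))
  if (nrow(query) == 0) return(logical(0))
  if (nrow(index$table) == 0) return(rep(FALSE, nrow(query)))
  qgr <- align_seqlevels(tbl_to_gr(query), index$gr)
  GenomicRanges::countOverlaps(qgr, index$gr, ignore.strand = TRUE) > 0
}

# Vectorised: total overlap width in bp between each query interval and a
# single best-hit stored interval is not meaningful here; this returns, per
# (query, hit) pair, the intersection width. Used by gene annotation.
idx_overlap_widths <- function(index, query) {
  stopifnot(inherits(index, "interval_index"))
  if (nrow(query) == 0 || nrow(index$table) == 0) {
    return(tibble(query_row = integer(0), subject_row = integer(0),
                  overlap_bp = integer(0)))
  }
  qgr <- align_seqlevels(tbl_to_gr(query), index$gr)
  hits <- GenomicRanges::findOverlaps(qgr, index$gr, ignore.strand = TRUE)
  inter <- IRanges::pintersect(qgr[S4Vectors::queryHits(hits)],
                               index$gr[S4Vectors::subjectHits(hits)],
                               ignore.strand = TRUE)
  tibble(
    query_row = S4Vectors::queryHits(hits),
    subject_row = S4Vectors::subjectHits(hits),
    overlap_bp = GenomicRanges::width(inter)
  )
}

# put the query on the union of both seqlevel sets so overlap operations on
# disjoint chromosome sets stay silent (they correctly return no hits)
align_seqlevels <- function(qgr, sgr) {
  lv <- union(GenomeInfoDb::seqlevels(qgr), GenomeInfoDb::seqlevels(sgr))
  GenomeInfoDb::seqlevels(qgr) <- lv
  qgr
}
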
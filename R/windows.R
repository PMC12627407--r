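#' Filter raw loop calls on PET support and FDR
#'
#' Mirrors the standard ChIA-PET quality filter: loops with fewer than
#' `min_pet` paired-end tags or an FDR above `max_fdr` are removed. Both
#' boundaries are kept (a loop with exactly `min_pet` PETs and exactly
#' `max_fdr` FDR survives).
#'
#' @param loops Loop tibble from [read_bedpe_loops()].
#' @param min_pet Minimum PET count (default 2).
#' @param max_fdr Maximum FDR (default 0.05).
#' @return The surviving loops, original order preserved.
#' @export
filter_loops <- function(loops, min_pet = 2, max_fdr = 0.05) {
  stopifnot(min_pet >= 0, max_fdr >= 0, max_fdr <= 1)
  filter(loops, .data$pet_count >= min_pet, .data$fdr <= max_fdr)
}

#' Build anchor and interloop windows for each loop
#'
#' For every loop, three evaluation windows are derived: a window of
#' `2 * half_width` bp centred on each anchor midpoint (clamped at
#' coordinate 0) and the interloop region between them. The loop `span` is
#' the midpoint-to-midpoint distance. When the two anchor windows touch or
#' overlap (a very short loop), the interloop window is empty and
#' `interloop_empty` is set.
#'
#' @param loops Loop tibble (`chrom`, `start1`, `end1`, `start2`, `end2`, ...).
#' @param half_width Window half-width in bp; the full window width the
#'   pipeline is configured with is `2 * half_width` (1000-bp windows for the
#'   cell-line preset, 500-bp for the brain preset).
#' @return The input with added columns `span`, `sw_start`, `sw_end`
#'   (start-anchor window), `ew_start`, `ew_end` (end-anchor window),
#'   `il_start`, `il_end` (interloop) and `interloop_empty`.
#' @export
add_loop_windows <- function(loops, half_width = 500) {
  stopifnot(half_width >= 1)
  mid1 <- floor((loops$start1 + loops$end1) / 2)
  mid2 <- floor((loops$start2 + loops$end2) / 2)
  out <- mutate(
    loops,
    span = as.integer(mid2 - mid1),
    sw_start = pmax(0L, as.integer(mid1 - half_width)),
    sw_end = as.integer(mid1 + half_width),
    ew_start = pmax(0L, as.integer(mid2 - half_width)),
    ew_end = as.integer(mid2 + half_width)
  )
  out <- mutate(
    out,
    interloop_empty = .data$ew_start <= .data$sw_end,
    il_start = ifelse(.data$interloop_empty, .data$sw_end, .data$sw_end),
    il_end = ifelse(.data$interloop_empty, .data$sw_end, .data$ew_start)
  )
  out$il_start <- as.integer(out$il_start)
  out$il_end <- as.integer(out$il_end)
  if (any(out$span <= 0)) {
    abort("Loops with non-positive span; anchors must be normalised first.")
  }
  out
}

#' Retain loops whose span lies in a plausible loop-size range
#'
#' Chromatin loops in human data overwhelmingly fall between 2 kb and 2 Mb;
#' spans outside `[min_span, max_span]` (both bounds inclusive) are removed.
#'
#' @param windowed Output of [add_loop_windows()] (needs a `span` column).
#' @param min_span,max_span Inclusive span bounds in bp.
#' @return The surviving rows, order preserved.
#' @export
filter_span <- function(windowed, min_span = 2000, max_span = 2000000) {
  stopifnot(min_span < max_span)
  filter(windowed, .data$span >= min_span, .data$span <= max_span)
}
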
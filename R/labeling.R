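#' Assign the representative CTCF motif to each anchor window
#'
#' Each anchor window may contain several FIMO hits; the hit with the
#' highest FIMO score represents the anchor (ties broken by leftmost start).
#' Loops whose start or end window holds no motif get `NA` motif fields and
#' cannot become positives.
#'
#' @param windowed Output of [add_loop_windows()].
#' @param motifs Motif tibble from [read_fimo_tsv()] or an `interval_index`
#'   built over one.
#' @return The input with added columns `start_motif_start`,
#'   `start_motif_end`, `start_motif_strand`, `start_motif_score` and the
#'   `end_motif_*` counterparts.
#' @export
assign_anchor_motifs <- function(windowed, motifs) {
  idx <- as_index(motifs)
  pick <- function(win_start, win_end) {
    q <- tibble(chrom = windowed$chrom, start = win_start, end = win_end)
    hits <- query_overlaps(idx, q)
    best <- hits |>
      group_by(.data$query_row) |>
      arrange(desc(.data$score), .data$start, .by_group = TRUE) |>
      slice(1) |>
      ungroup()
    out <- tibble(start = rep(NA_integer_, nrow(windowed)),
                  end = NA_integer_, strand = NA_character_,
                  score = NA_real_)
    out$start[best$query_row] <- best$start
    out$end[best$query_row] <- best$end
    out$strand[best$query_row] <- best$strand
    out$score[best$query_row] <- best$score
    out
  }
  s <- pick(windowed$sw_start, windowed$sw_end)
  e <- pick(windowed$ew_start, windowed$ew_end)
  mutate(
    windowed,
    start_motif_start = s$start, start_motif_end = s$end,
    start_motif_strand = s$strand, start_motif_score = s$score,
    end_motif_start = e$start, end_motif_end = e$end,
    end_motif_strand = e$strand, end_motif_score = e$score
  )
}

#' Test convergent CTCF motif orientation
#'
#' Under the loop-extrusion model a loop forms between a forward-strand
#' CTCF motif at the upstream anchor and a reverse-strand motif at the
#' downstream anchor. Vectorised.
#'
#' @param start_strand,end_strand Strand of the upstream / downstream anchor
#'   motif (`"+"` or `"-"`).
#' @return Logical vector: `TRUE` for convergent pairs only.
#' @export
is_convergent <- function(start_strand, end_strand) {
  !is.na(start_strand) & !is.na(end_strand) &
    start_strand == "+" & end_strand == "-"
}

#' Label candidate loops as high-confidence positives or negatives
#'
#' A loop is positive when (a) its anchor motifs are convergently oriented,
#' (b) both anchor motifs are occupied by CTCF (overlap a CTCF ChIP-seq
#' peak by >= 1 bp), and (c) RAD21 colocalises with the loop — in at least
#' one anchor window, or in any of the three loop windows when
#' `rad21_windows = "all3"`. RAD21 is consumed here only; it must never
#' appear in a feature matrix. Loops lacking an anchor motif stay
#' `unlabeled` with a reason.
#'
#' @param cands Output of [assign_anchor_motifs()].
#' @param ctcf_peaks,rad21_peaks Peak tibbles ([read_narrowpeak()]) or
#'   `interval_index` objects over them.
#' @param rad21_windows `"all3"` (default) tests RAD21 in the two anchor
#'   windows and the interloop region; `"anchors"` tests the anchors only.
#' @param require_convergent Drop criterion (a) when `FALSE`.
#' @return The input with columns `label`
#'   (`positive`/`negative`/`unlabeled`) and `label_reason`.
#' @export
label_loops <- function(cands, ctcf_peaks, rad21_peaks,
                        rad21_windows = c("all3", "anchors"),
                        require_convergent = TRUE) {
  rad21_windows <- match.arg(rad21_windows)
  ctcf_idx <- as_index(ctcf_peaks)
  rad21_idx <- as_index(rad21_peaks)

  has_both <- !is.na(cands$start_motif_score) & !is.na(cands$end_motif_score)
  conv <- is_convergent(cands$start_motif_strand, cands$end_motif_strand)

  q_start_motif <- tibble(chrom = cands$chrom,
                          start = coalesce0(cands$start_motif_start),
                          end = coalesce0(cands$start_motif_end, 1L))
  q_end_motif <- tibble(chrom = cands$chrom,
                        start = coalesce0(cands$end_motif_start),
                        end = coalesce0(cands$end_motif_end, 1L))
  bound_start <- idx_any_overlap(ctcf_idx, q_start_motif) & has_both
  bound_end <- idx_any_overlap(ctcf_idx, q_end_motif) & has_both

  rad_start <- window_overlap(rad21_idx, cands, "sw")
  rad_end <- window_overlap(rad21_idx, cands, "ew")
  rad_any <- rad_start | rad_end
  if (rad21_windows == "all3") {
    rad_any <- rad_any | window_overlap(rad21_idx, cands, "il")
  }

  positive <- has_both & bound_start & bound_end & rad_any
  if (require_convergent) positive <- positive & conv

  label <- ifelse(has_both, ifelse(positive, "positive", "negative"),
                  "unlabeled")
  reason <- ifelse(has_both, NA_character_, "missing_anchor_motif")
  mutate(cands, label = label, label_reason = reason)
}

#' Sample negative loop examples from unbound motif pairs
#'
#' Negative training loops are pairs of CTCF motifs on the same chromosome
#' that are not occupied by CTCF, with no RAD21 peak in any of the three
#' loop windows the pair defines, and a span inside `span_range`. When the
#' positive spans are supplied, negatives are drawn to match their span
#' histogram (deciles of log-span), so span carries no label signal.
#'
#' @param motifs Motif tibble from [read_fimo_tsv()].
#' @param ctcf_peaks,rad21_peaks Peak tibbles or `interval_index` objects.
#' @param n Number of negatives requested.
#' @param span_range Length-2 numeric, allowed midpoint-to-midpoint span.
#' @param seed Integer seed; the same seed reproduces the same sample.
#' @param half_width Window half-width used for the RAD21 exclusion test and
#'   for the returned windows.
#' @param positive_spans Optional numeric vector of positive-loop spans to
#'   match.
#' @return A candidate tibble shaped like [label_loops()] output with
#'   `label = "negative"`; anchors are the motif intervals themselves.
#' @export
sample_negatives <- function(motifs, ctcf_peaks, rad21_peaks, n,
                             span_range = c(2000, 2000000), seed = 1,
                             half_width = 500, positive_spans = NULL) {
  ctcf_idx <- as_index(ctcf_peaks)
  rad21_idx <- as_index(rad21_peaks)
  motifs <- as_tibble(motifs)
  unbound <- motifs[!idx_any_overlap(ctcf_idx, motifs), , drop = FALSE]
  pairs <- enumerate_span_pairs(unbound, span_range)
  if (nrow(pairs) == 0) {
    warn("No eligible unbound motif pairs; returning an empty set.")
    return(mutate(pairs_to_candidates(unbound, pairs, half_width),
                  label = character(0), label_reason = character(0)))
  }

  # RAD21 exclusion over the three windows of each putative pair
  cand <- pairs_to_candidates(unbound, pairs, half_width)
  rad <- window_overlap(rad21_idx, cand, "sw") |
    window_overlap(rad21_idx, cand, "ew") |
    window_overlap(rad21_idx, cand, "il")
  cand <- cand[!rad, , drop = FALSE]

  if (nrow(cand) <= n) {
    if (nrow(cand) < n) {
      warn(sprintf("Only %d eligible negative pairs (requested %d).",
                   nrow(cand), n))
    }
    chosen <- cand
  } else {
    chosen <- withr::with_seed(seed, {
      if (is.null(positive_spans)) {
        cand[sample.int(nrow(cand), n), , drop = FALSE]
      } else {
        sample_span_matched(cand, positive_spans, n)
      }
    })
  }
  chosen <- arrange(chosen, .data$chrom, .data$sw_start)
  mutate(chosen,
         loop_id = sprintf("neg_%05d", seq_len(nrow(chosen))),
         label = "negative", label_reason = NA_character_)
}

# all same-chromosome motif pairs with midpoint span inside span_range
enumerate_span_pairs <- function(motifs, span_range) {
  if (nrow(motifs) == 0) {
    return(tibble(i = integer(0), j = integer(0), span = integer(0)))
  }
  motifs$.mid <- floor((motifs$start + motifs$end) / 2)
  motifs$.row <- seq_len(nrow(motifs))
  out <- lapply(split(motifs, motifs$chrom), function(m) {
    m <- m[order(m$.mid), , drop = FALSE]
    mids <- m$.mid
    lo <- findInterval(mids + span_range[1] - 0.5, mids) + 1L
    hi <- findInterval(mids + span_range[2] + 0.5, mids)
    len <- pmax(0L, hi - lo + 1L)
    i <- rep.int(seq_along(mids), len)
    j <- sequence(len, from = lo)
    tibble(i = m$.row[i], j = m$.row[j],
           span = as.integer(mids[j] - mids[i]))
  })
  bind_rows(out)
}

pairs_to_candidates <- function(motifs, pairs, half_width) {
  a <- motifs[pairs$i, , drop = FALSE]
  b <- motifs[pairs$j, , drop = FALSE]
  loops <- tibble(
    loop_id = NA_character_,
    chrom = a$chrom,
    start1 = a$start, end1 = a$end,
    start2 = b$start, end2 = b$end,
    pet_count = NA_integer_, fdr = NA_real_
  )
  w <- add_loop_windows(loops, half_width = half_width)
  mutate(w,
         start_motif_start = a$start, start_motif_end = a$end,
         start_motif_strand = a$strand, start_motif_score = a$score,
         end_motif_start = b$start, end_motif_end = b$end,
         end_motif_strand = b$strand, end_motif_score = b$score)
}

# quantile-bin matching of a candidate pool to a reference span distribution
sample_span_matched <- function(cand, ref_spans, n, bins = 10) {
  edges <- unique(quantile(log10(ref_spans), probs = seq(0, 1, length.out = bins + 1)))
  cut_ref <- cut(log10(ref_spans), edges, include.lowest = TRUE)
  want <- round(n * as.numeric(table(cut_ref)) / length(ref_spans))
  cut_cand <- cut(log10(cand$span), edges, include.lowest = TRUE)
  picked <- integer(0)
  for (b in seq_along(levels(cut_ref))) {
    pool <- which(!is.na(cut_cand) & as.integer(cut_cand) == b)
    k <- min(length(pool), want[b])
    if (k > 0) picked <- c(picked, sample(pool, k))
  }
  short <- n - length(picked)
  if (short > 0) {
    rest <- setdiff(seq_len(nrow(cand)), picked)
    picked <- c(picked, sample(rest, min(short, length(rest))))
  }
  cand[sort(picked), , drop = FALSE]
}

# -- small shared helpers ----------------------------------------------------

as_index <- function(x) {
  if (inherits(x, "interval_index")) x else build_index(x)
}

coalesce0 <- function(x, default = 0L) {
  x[is.na(x)] <- default
  x
}

# does any indexed interval overlap the named window of each candidate row?
window_overlap <- function(idx, cands, which = c("sw", "ew", "il")) {
  which <- match.arg(which)
  s <- cands[[paste0(which, "_start")]]
  e <- cands[[paste0(which, "_end")]]
  empty <- e <= s
  q <- tibble(chrom = cands$chrom,
              start = ifelse(empty, 0L, s),
              end = ifelse(empty, 1L, e))
  hit <- idx_any_overlap(idx, q)
  hit & !empty
}
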
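# Independent brute-force oracles. These deliberately share no code with
# the package internals: plain loops and scans over data frames.

bf_overlap_rows <- function(intervals, chrom, start, end) {
  hits <- integer(0)
  for (i in seq_len(nrow(intervals))) {
    if (intervals$chrom[i] == chrom &&
        intervals$start[i] < end && intervals$end[i] > start) {
      hits <- c(hits, i)
    }
  }
  hits
}

bf_any_overlap <- function(intervals, chrom, start, end) {
  length(bf_overlap_rows(intervals, chrom, start, end)) > 0
}

bf_filter_loops <- function(loops, min_pet, max_fdr) {
  keep <- logical(nrow(loops))
  for (i in seq_len(nrow(loops))) {
    keep[i] <- loops$pet_count[i] >= min_pet && loops$fdr[i] <= max_fdr
  }
  loops[keep, , drop = FALSE]
}

# direct restatement of the positive-loop definition
bf_label_one <- function(cand, ctcf, rad21, rad21_all3 = TRUE) {
  if (is.na(cand$start_motif_score) || is.na(cand$end_motif_score)) {
    return("unlabeled")
  }
  conv <- cand$start_motif_strand == "+" && cand$end_motif_strand == "-"
  b1 <- bf_any_overlap(ctcf, cand$chrom, cand$start_motif_start,
                       cand$start_motif_end)
  b2 <- bf_any_overlap(ctcf, cand$chrom, cand$end_motif_start,
                       cand$end_motif_end)
  r <- bf_any_overlap(rad21, cand$chrom, cand$sw_start, cand$sw_end) ||
    bf_any_overlap(rad21, cand$chrom, cand$ew_start, cand$ew_end)
  if (rad21_all3 && cand$il_end > cand$il_start) {
    r <- r || bf_any_overlap(rad21, cand$chrom, cand$il_start, cand$il_end)
  }
  if (conv && b1 && b2 && r) "positive" else "negative"
}

bf_site_matrix_row <- function(chrom, mid, tracks, span, bin) {
  n_bins <- span / bin
  out <- c()
  for (tr in names(tracks)) {
    for (b in seq_len(n_bins)) {
      b_start <- mid - span / 2 + (b - 1) * bin
      b_end <- b_start + bin
      flag <- if (b_end <= 0) FALSE else {
        bf_any_overlap(tracks[[tr]], chrom, max(0, b_start), b_end)
      }
      out <- c(out, as.numeric(flag))
    }
  }
  out
}

bf_best_gene <- function(chrom, mid1, mid2, genes) {
  best <- NULL
  best_ov <- 0
  for (i in seq_len(nrow(genes))) {
    if (genes$chrom[i] != chrom) next
    ov <- min(mid2, genes$end[i]) - max(mid1, genes$start[i])
    if (ov > best_ov ||
        (ov == best_ov && ov > 0 && !is.null(best) &&
         genes$start[i] < genes$start[best])) {
      best <- i
      best_ov <- ov
    }
  }
  if (is.null(best) || best_ov <= 0) NA_character_ else genes$gene_name[best]
}

# ROC AUC as the probability a random positive outscores a random negative
# (ties count one half)
bf_concordance_auc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

random_intervals <- function(n, chroms = c("chrA", "chrB"), max_pos = 10000,
                             max_len = 500) {
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = sample.int(max_pos, n, replace = TRUE) - 1L
  ) |>
    dplyr::mutate(end = start + sample.int(max_len, n, replace = TRUE))
}
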
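#' Discordant loop score
#'
#' The squared difference between the loop score in the control condition
#' and in the case condition: `D = (s_control - s_case)^2`. Symmetric,
#' zero iff the scores agree, and bounded by 1 for probability inputs.
#'
#' @param s_control,s_case Numeric vectors of loop scores in `[0, 1]`.
#' @return `(s_control - s_case)^2`, vectorised.
#' @examples
#' discordant_score(1.0, 8.93e-5)   # ~0.999821, a lost loop
#' discordant_score(0.0, 0.999782)  # ~0.999564, a gained loop
#' @export
discordant_score <- function(s_control, s_case) {
  check_unit_interval(s_control, "s_control")
  check_unit_interval(s_case, "s_case")
  (s_control - s_case)^2
}

#' Classify loops as lost, gained or concordant between conditions
#'
#' A loop is *lost* when it scores high in the controls
#' (`s_control >= tau_high`) and essentially zero in the case
#' (`s_case < tau_lost`); *gained* when the control score is essentially
#' zero (`s_control <= tau_low`) and the case score high
#' (`s_case > tau_gained`); otherwise *concordant*. The defaults
#' operationalise "control score 1 / case score < 0.0005" and
#' "control score 0 / case score > 0.999" with a 0.0005-wide tolerance at
#' the extremes, since a probabilistic classifier almost never emits an
#' exact 0 or 1.
#'
#' @param records A data frame with columns `s_control` and `s_case`.
#' @param tau_lost Case-score ceiling for a lost loop (default 0.0005).
#' @param tau_gained Case-score floor for a gained loop (default 0.999).
#' @param tau_high,tau_low Control-score floor/ceiling standing in for
#'   "score 1" / "score 0" (defaults 0.9995 and 0.0005).
#' @return The input with columns `d_score` (the discordant loop score)
#'   and `klass` (`"lost"`, `"gained"` or `"concordant"`).
#' @export
classify_loops <- function(records, tau_lost = 0.0005, tau_gained = 0.999,
                           tau_high = 0.9995, tau_low = 0.0005) {
  stopifnot(all(c("s_control", "s_case") %in% names(records)))
  for (tau in c(tau_lost, tau_gained, tau_high, tau_low)) {
    stopifnot(tau >= 0, tau <= 1)
  }
  mutate(
    records,
    d_score = discordant_score(.data$s_control, .data$s_case),
    klass = dplyr::case_when(
      .data$s_control >= tau_high & .data$s_case < tau_lost ~ "lost",
      .data$s_control <= tau_low & .data$s_case > tau_gained ~ "gained",
      .default = "concordant"
    )
  )
}

#' Aggregate per-sample control scores into one control score per loop
#'
#' Control samples are assumed to share a common loop landscape; the
#' per-loop control score is the mean of the per-sample predicted scores.
#' Every loop must be scored in every control sample.
#'
#' @param scores Long tibble with columns `loop_id`, `sample`, `score`.
#' @return A tibble `loop_id`, `s_control`, loops in first-appearance
#'   order; per-sample scores are retained in `attr(x, "per_sample")`.
#' @export
aggregate_control_scores <- function(scores) {
  stopifnot(all(c("loop_id", "sample", "score") %in% names(scores)))
  n_samples <- length(unique(scores$sample))
  counts <- table(scores$loop_id)
  incomplete <- names(counts)[counts != n_samples]
  if (length(incomplete) > 0) {
    abort(sprintf("Loop(s) not scored in every control sample: %s.",
                  paste(head(incomplete, 5), collapse = ", ")))
  }
  out <- scores |>
    group_by(.data$loop_id) |>
    summarise(s_control = mean(.data$score)) |>
    ungroup()
  out <- out[match(unique(scores$loop_id), out$loop_id), , drop = FALSE]
  attr(out, "per_sample") <- as_tibble(scores)
  out
}

#' Annotate each loop with the gene(s) it most overlaps
#'
#' The loop body is taken as the inter-anchor span (anchor midpoint to
#' anchor midpoint); each loop is assigned the `k` genes with the longest
#' overlap against that span (ties broken by leftmost gene start). Loops
#' overlapping no gene keep `NA` gene fields.
#'
#' @param records A data frame of loops with `chrom`, `start1`, `end1`,
#'   `start2`, `end2` (and any payload).
#' @param genes Gene tibble from [read_gtf_genes()] or an
#'   `interval_index` over one.
#' @param k Number of genes kept per loop (default 1, the single
#'   longest-overlap gene; `k = 2` mirrors two-genes-per-loop reporting).
#' @return One row per kept (loop, gene) pair — with `k = 1`, exactly one
#'   row per loop — adding `gene_id`, `gene_name`, `overlap_bp`,
#'   `gene_rank`.
#' @export
annotate_loop_genes <- function(records, genes, k = 1) {
  idx <- as_index(genes)
  mid1 <- floor((records$start1 + records$end1) / 2)
  mid2 <- floor((records$start2 + records$end2) / 2)
  q <- tibble(chrom = records$chrom, start = mid1, end = pmax(mid2, mid1 + 1L))
  ov <- idx_overlap_widths(idx, q)
  gene_tbl <- idx$table
  ov <- ov |>
    mutate(gene_start = gene_tbl$start[.data$subject_row]) |>
    group_by(.data$query_row) |>
    arrange(desc(.data$overlap_bp), .data$gene_start, .by_group = TRUE) |>
    slice(seq_len(k)) |>
    mutate(gene_rank = row_number()) |>
    ungroup()
  base <- mutate(as_tibble(records), .row = row_number())
  hits <- left_join(base, select(ov, ".row" = "query_row", "subject_row",
                                 "overlap_bp", "gene_rank"),
                    by = ".row")
  hits |>
    mutate(
      gene_id = ifelse(is.na(.data$subject_row), NA_character_,
                       gene_tbl$gene_id[coalesce0(.data$subject_row, 1L)]),
      gene_name = ifelse(is.na(.data$subject_row), NA_character_,
                         gene_tbl$gene_name[coalesce0(.data$subject_row, 1L)]),
      overlap_bp = as.integer(ifelse(is.na(.data$subject_row), NA,
                                     .data$overlap_bp)),
      gene_rank = ifelse(is.na(.data$subject_row), NA_integer_,
                         .data$gene_rank)
    ) |>
    select(-".row", -"subject_row")
}

#' Rank genes by summed discordant loop score
#'
#' For each gene annotated to at least one discordant loop, sums the
#' discordant loop scores of its loops; lost and gained loops are ranked
#' separately and the top `top_n` of each reported.
#'
#' @param records Classified, gene-annotated loop records
#'   ([classify_loops()] then [annotate_loop_genes()]).
#' @param top_n Genes reported per class (default 5).
#' @return A tibble `gene_name`, `klass`, `total_d_score`, `n_loops`,
#'   sorted within class by descending total score.
#' @export
rank_genes <- function(records, top_n = 5) {
  stopifnot(all(c("klass", "gene_name", "d_score") %in% names(records)))
  records |>
    filter(.data$klass %in% c("lost", "gained"), !is.na(.data$gene_name)) |>
    group_by(.data$klass, .data$gene_name) |>
    summarise(total_d_score = sum(.data$d_score), n_loops = n(),
              .groups = "drop") |>
    group_by(.data$klass) |>
    arrange(desc(.data$total_d_score), .data$gene_name, .by_group = TRUE) |>
    slice(seq_len(top_n)) |>
    ungroup() |>
    select("gene_name", "klass", "total_d_score", "n_loops")
}

#' Plot the control-versus-case score plane of a discordance table
#'
#' @param records Output of [classify_loops()].
#' @return A ggplot: each loop at (`s_control`, `s_case`), coloured by
#'   class; lost loops sit bottom-right, gained top-left.
#' @export
plot_discordance <- function(records) {
  ggplot2::ggplot(records, ggplot2::aes(.data$s_control, .data$s_case,
                                        colour = .data$klass)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(
      concordant = "grey60", lost = "#d1495b", gained = "#00798c")) +
    ggplot2::labs(x = "Control loop score", y = "Case loop score",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

check_unit_interval <- function(x, what) {
  if (anyNA(x) || any(x < 0 | x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1].", what))
  }
  invisible(x)
}
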
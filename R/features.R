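#' Named feature presets
#'
#' Two mark sets are used in practice: `"cellline"` pairs CTCF occupancy
#' with the four histone marks profiled in lymphoblastoid/leukemia lines
#' (1000-bp windows), `"ad"` pairs CTCF with accessibility and the marks
#' available for dorsolateral prefrontal cortex (500-bp windows).
#'
#' @param preset `"cellline"` or `"ad"`.
#' @return Character vector of mark names.
#' @export
feature_preset_marks <- function(preset = c("cellline", "ad")) {
  switch(match.arg(preset),
    cellline = c("ctcf", "h3k4me1", "h3k9me3", "h3k27me3", "h3k27ac"),
    ad = c("ctcf", "dnase", "h3k4me3", "h3k27me3", "h3k27ac")
  )
}

#' Turn candidate loops into the model's feature matrix
#'
#' One row per candidate: the FIMO scores of the two anchor motifs, the
#' loop span, and a binary presence flag per configured mark per window
#' (start anchor, end anchor, interloop). Presence means >= 1 track
#' interval overlaps the window by >= 1 bp; flags of an empty interloop are
#' 0. RAD21 is a labeling input only and is refused here.
#'
#' @param cands Candidate tibble from [label_loops()] /
#'   [sample_negatives()] (windows + anchor motifs assigned).
#' @param tracks Named list mapping each mark to a peak tibble or
#'   `interval_index`.
#' @param marks Marks to use; defaults to all of `tracks`. Every mark must
#'   be present in `tracks`.
#' @return A tibble: `loop_id`, then feature columns. The feature schema
#'   (column names in order) is stored as `attr(x, "schema")`.
#' @export
extract_features <- function(cands, tracks, marks = names(tracks)) {
  if (any(tolower(marks) == "rad21")) {
    abort("RAD21 is reserved for labeling and cannot be a feature mark.")
  }
  missing <- setdiff(marks, names(tracks))
  if (length(missing) > 0) {
    abort(sprintf("Track(s) missing for configured mark(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  out <- tibble(
    loop_id = cands$loop_id,
    start_motif_score = cands$start_motif_score,
    end_motif_score = cands$end_motif_score,
    loop_span = as.numeric(cands$span)
  )
  for (m in marks) {
    idx <- as_index(tracks[[m]])
    out[[paste0("presence_", m, "_start")]] <-
      as.numeric(window_overlap(idx, cands, "sw"))
    out[[paste0("presence_", m, "_end")]] <-
      as.numeric(window_overlap(idx, cands, "ew"))
    out[[paste0("presence_", m, "_interloop")]] <-
      as.numeric(window_overlap(idx, cands, "il"))
  }
  attr(out, "schema") <- setdiff(names(out), "loop_id")
  out
}

#' Swap in (or add) predicted CTCF-binding probabilities
#'
#' When CTCF ChIP-seq is unavailable, the anchor CTCF evidence can come
#' from the binding predictor instead. `mode = "replace"` substitutes the
#' binary `presence_ctcf_start`/`presence_ctcf_end` flags with the anchor
#' motif's predicted binding probability (a real in `[0, 1]`);
#' `mode = "augment"` keeps the ChIP flags and adds two probability
#' columns `pred_ctcf_start`/`pred_ctcf_end`.
#'
#' @param features Feature tibble from [extract_features()].
#' @param cands The candidate tibble the features were extracted from
#'   (supplies each anchor's motif coordinates).
#' @param site_scores Tibble with `chrom`, `start`, `end` (motif interval)
#'   and `probability` from [predict_binding()].
#' @param mode `"replace"` (default) or `"augment"`.
#' @return The feature tibble with an updated schema attribute.
#' @export
substitute_binding_predictions <- function(features, cands, site_scores,
                                           mode = c("replace", "augment")) {
  mode <- match.arg(mode)
  stopifnot(nrow(features) == nrow(cands))
  key <- function(chrom, start, end) paste(chrom, start, end, sep = ":")
  lookup <- setNames(site_scores$probability,
                     key(site_scores$chrom, site_scores$start, site_scores$end))
  p_start <- unname(lookup[key(cands$chrom, cands$start_motif_start,
                               cands$start_motif_end)])
  p_end <- unname(lookup[key(cands$chrom, cands$end_motif_start,
                             cands$end_motif_end)])
  miss <- is.na(p_start) & !is.na(cands$start_motif_start)
  miss_e <- is.na(p_end) & !is.na(cands$end_motif_start)
  if (any(miss) || any(miss_e)) {
    bad <- unique(c(
      key(cands$chrom, cands$start_motif_start, cands$start_motif_end)[miss],
      key(cands$chrom, cands$end_motif_start, cands$end_motif_end)[miss_e]))
    abort(sprintf("No predicted binding probability for motif(s): %s.",
                  paste(head(bad, 5), collapse = ", ")))
  }
  if (mode == "replace") {
    if (!all(c("presence_ctcf_start", "presence_ctcf_end") %in% names(features))) {
      abort("Features lack presence_ctcf_start/end to replace.")
    }
    features$presence_ctcf_start <- p_start
    features$presence_ctcf_end <- p_end
  } else {
    features$pred_ctcf_start <- p_start
    features$pred_ctcf_end <- p_end
  }
  attr(features, "schema") <- setdiff(names(features), "loop_id")
  features
}
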
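# End-to-end workflows over a study directory (the layout written by
# simulate_loop_study()/simulate_binding_study(), which mirrors how the real
# inputs are organised: shared loop calls, motif scan and gene models, one
# subdirectory of peak tracks per sample).

#' Read one sample's peak tracks
#'
#' @param study_dir Study directory.
#' @param sample Sample subdirectory name (e.g. `"control1"`).
#' @param tracks Track names to load (files `<track>.narrowPeak`).
#' @return Named list of peak tibbles.
#' @export
load_sample_tracks <- function(study_dir, sample, tracks) {
  paths <- file.path(study_dir, sample, paste0(tracks, ".narrowPeak"))
  missing <- !file.exists(paths)
  if (any(missing)) {
    abort(sprintf("Missing track file(s): %s.",
                  paste(paths[missing], collapse = ", ")))
  }
  setNames(lapply(paths, read_narrowpeak), tracks)
}

#' Build labeled training candidates for one sample
#'
#' Runs the candidate pipeline: read and quality-filter the loop calls,
#' build windows, keep spans in range, assign anchor motifs, label against
#' the sample's CTCF and RAD21 peaks, and draw span-matched unbound-pair
#' negatives at `negative_ratio` negatives per positive.
#'
#' @param study_dir Study directory (expects `loops.bedpe`, `motifs.tsv`
#'   and per-sample track subdirectories).
#' @param sample Sample name.
#' @param half_width Window half-width in bp (500 for 1000-bp windows).
#' @param min_pet,max_fdr Loop-call quality thresholds.
#' @param span_range Allowed loop span (bp).
#' @param rad21_windows Passed to [label_loops()].
#' @param negative_ratio Negatives sampled per labeled positive.
#' @param seed Integer seed for negative sampling.
#' @return A list: `training` (positives plus sampled negatives),
#'   `universe` (every filtered loop with both anchor motifs, labels
#'   attached), `motifs`, and the sample's `ctcf`/`rad21` indexes.
#' @export
prepare_candidates <- function(study_dir, sample, half_width = 500,
                               min_pet = 2, max_fdr = 0.05,
                               span_range = c(2000, 2e6),
                               rad21_windows = "all3",
                               negative_ratio = 1, seed = 1) {
  loops <- read_bedpe_loops(file.path(study_dir, "loops.bedpe"))
  motifs <- read_fimo_tsv(file.path(study_dir, "motifs.tsv"))
  peaks <- load_sample_tracks(study_dir, sample, c("ctcf", "rad21"))
  cands <- loops |>
    filter_loops(min_pet = min_pet, max_fdr = max_fdr) |>
    add_loop_windows(half_width = half_width) |>
    filter_span(min_span = span_range[1], max_span = span_range[2]) |>
    assign_anchor_motifs(motifs) |>
    label_loops(peaks$ctcf, peaks$rad21, rad21_windows = rad21_windows)
  universe <- filter(cands, .data$label != "unlabeled")
  positives <- filter(universe, .data$label == "positive")
  n_neg <- round(negative_ratio * nrow(positives))
  negatives <- sample_negatives(
    motifs, peaks$ctcf, peaks$rad21, n = n_neg,
    span_range = span_range, seed = seed, half_width = half_width,
    positive_spans = positives$span
  )
  list(training = bind_rows(positives, negatives), universe = universe,
       motifs = motifs, ctcf = peaks$ctcf, rad21 = peaks$rad21)
}

#' Extract loop features against one sample's tracks
#'
#' @param cands Candidate tibble (windows and motifs assigned).
#' @param study_dir,sample Study directory and sample name.
#' @param marks Feature marks; each needs `<mark>.narrowPeak` in the
#'   sample directory.
#' @return Feature tibble from [extract_features()].
#' @export
sample_features <- function(cands, study_dir, sample,
                            marks = c("ctcf", "h3k4me1", "h3k9me3",
                                      "h3k27me3", "h3k27ac")) {
  tracks <- load_sample_tracks(study_dir, sample, marks)
  extract_features(cands, tracks, marks = marks)
}

#' Train and evaluate the loop classifier on a study
#'
#' Pools labeled candidates from the training samples, fits the
#' gradient-boosted classifier, and (when a test sample is given) labels
#' and scores that sample's candidates.
#'
#' @param study_dir Study directory.
#' @param train_samples Character vector of training sample names.
#' @param test_sample Optional test sample name.
#' @param marks Feature marks.
#' @param seed Integer seed.
#' @param ... Passed to [prepare_candidates()] (window width, filters) and
#'   split between it and [train_loop_model()] by name.
#' @return A list: `model`, and when a test sample was given `eval`
#'   (an `eval_report`) plus `test_scores`.
#' @export
run_loop_workflow <- function(study_dir, train_samples, test_sample = NULL,
                              marks = c("ctcf", "h3k4me1", "h3k9me3",
                                        "h3k27me3", "h3k27ac"),
                              seed = 1, ...) {
  prep_args <- intersect(names(list(...)),
                         names(formals(prepare_candidates)))
  train_parts <- lapply(train_samples, function(s) {
    prep <- do.call(prepare_candidates,
                    c(list(study_dir, s, seed = derive_seed(seed, s)),
                      list(...)[prep_args]))
    feats <- sample_features(prep$training, study_dir, s, marks = marks)
    list(features = feats, labels = prep$training$label)
  })
  features <- bind_rows(lapply(train_parts, `[[`, "features"))
  labels <- unlist(lapply(train_parts, `[[`, "labels"))
  model <- train_loop_model(features, labels, seed = seed)
  out <- list(model = model)
  if (!is.null(test_sample)) {
    prep <- do.call(prepare_candidates,
                    c(list(study_dir, test_sample,
                           seed = derive_seed(seed, test_sample)),
                      list(...)[prep_args]))
    feats <- sample_features(prep$training, study_dir, test_sample,
                             marks = marks)
    scores <- predict_scores(model, feats)
    out$eval <- evaluate_predictions(scores, prep$training$label)
    out$test_scores <- tibble(loop_id = prep$training$loop_id,
                              label = prep$training$label, score = scores)
  }
  out
}

#' Control-versus-case discordant-loop workflow
#'
#' Trains the loop classifier on the pooled control samples, scores every
#' candidate loop in each control sample (control score = mean across
#' controls) and in the case sample, classifies lost/gained/concordant
#' loops, annotates each discordant loop with the gene it most overlaps,
#' and ranks genes by summed discordant score.
#'
#' @param study_dir Study directory.
#' @param control_samples,case_sample Sample names.
#' @param marks Feature marks.
#' @param seed Integer seed.
#' @param tau_lost,tau_gained,tau_high,tau_low Passed to
#'   [classify_loops()].
#' @param top_n Genes reported per class.
#' @param ... Passed to [prepare_candidates()].
#' @return A list: `records` (per-loop discordance table), `ranking`
#'   (gene ranking), `model`, `control_scores` (long per-sample scores).
#' @export
run_discordance_workflow <- function(study_dir, control_samples, case_sample,
                                     marks = c("ctcf", "h3k4me1", "h3k9me3",
                                               "h3k27me3", "h3k27ac"),
                                     seed = 1, tau_lost = 0.0005,
                                     tau_gained = 0.999, tau_high = 0.9995,
                                     tau_low = 0.0005, top_n = 5, ...) {
  preps <- lapply(control_samples, function(s) {
    do.call(prepare_candidates,
            c(list(study_dir, s, seed = derive_seed(seed, s)), list(...)))
  })
  names(preps) <- control_samples
  features <- bind_rows(lapply(control_samples, function(s) {
    sample_features(preps[[s]]$training, study_dir, s, marks = marks)
  }))
  labels <- unlist(lapply(preps, function(p) p$training$label))
  model <- train_loop_model(features, labels, seed = seed)

  universe <- preps[[1]]$universe
  long <- bind_rows(lapply(control_samples, function(s) {
    feats <- sample_features(universe, study_dir, s, marks = marks)
    tibble(loop_id = universe$loop_id, sample = s,
           score = predict_scores(model, feats))
  }))
  control <- aggregate_control_scores(long)
  case_feats <- sample_features(universe, study_dir, case_sample,
                                marks = marks)
  case_scores <- tibble(loop_id = universe$loop_id,
                        s_case = predict_scores(model, case_feats))

  genes <- read_gtf_genes(file.path(study_dir, "genes.gtf"))
  records <- universe |>
    left_join(control, by = "loop_id") |>
    left_join(case_scores, by = "loop_id") |>
    classify_loops(tau_lost = tau_lost, tau_gained = tau_gained,
                   tau_high = tau_high, tau_low = tau_low) |>
    annotate_loop_genes(genes, k = 1)
  list(records = records, ranking = rank_genes(records, top_n = top_n),
       model = model, control_scores = long)
}

#' Binding-predictor workflow over a binding study
#'
#' Supports the three evaluation regimes: `"self"` (one sample, 2/3-1/3
#' split), `"loo"` (train on all but the last listed sample, test on it),
#' and `"cross"` (train on all `train_samples`, test on `test_sample`).
#'
#' @param study_dir Binding-study directory (expects `sites.tsv` and
#'   per-sample track subdirectories).
#' @param regime `"self"`, `"loo"` or `"cross"`.
#' @param train_samples Sample name(s) used for training (for `"self"`,
#'   the single sample to split).
#' @param test_sample Test sample for `"cross"`; for `"loo"` the last
#'   element of `train_samples` is held out.
#' @param tracks Track names (default: the brain study set).
#' @param span,bin Site-matrix geometry.
#' @param num_trees,seed Forest size and seed.
#' @return A list: `model`, `eval` (an `eval_report`), and `site_scores`
#'   (tibble `chrom`, `start`, `end`, `probability` for the test sites,
#'   consumable by [substitute_binding_predictions()]).
#' @export
run_binding_workflow <- function(study_dir, regime = c("self", "loo", "cross"),
                                 train_samples, test_sample = NULL,
                                 tracks = c("dnase", "h3k4me3", "h3k27me3",
                                            "h3k27ac"),
                                 span = 500, bin = 25, num_trees = 500,
                                 seed = 1) {
  regime <- match.arg(regime)
  sites <- read_fimo_tsv(file.path(study_dir, "sites.tsv"))
  sample_data <- function(s) {
    trk <- load_sample_tracks(study_dir, s, tracks)
    ctcf <- load_sample_tracks(study_dir, s, "ctcf")$ctcf
    mats <- build_site_matrices(sites, trk, span = span, bin = bin)
    list(matrices = mats, labels = label_sites(sites, ctcf))
  }
  if (regime == "self") {
    stopifnot(length(train_samples) == 1)
    d <- sample_data(train_samples)
    d$matrices$label <- d$labels
    parts <- split_train_test(d$matrices, fraction = 2 / 3, seed = seed)
    model <- train_binding_model(select(parts$train, -"label"),
                                 parts$train$label,
                                 num_trees = num_trees, seed = seed)
    test_m <- select(parts$test, -"label")
    p <- predict_binding(model, test_m)
    ev <- evaluate_predictions(p, parts$test$label)
    test_sites <- sites[match(test_m$site_id, site_key(sites)), ]
  } else {
    if (regime == "loo") {
      test_sample <- train_samples[length(train_samples)]
      train_samples <- train_samples[-length(train_samples)]
    }
    if (is.null(test_sample)) abort("`test_sample` is required.")
    train_d <- lapply(train_samples, sample_data)
    model <- train_binding_model(
      bind_rows(lapply(train_d, `[[`, "matrices")),
      unlist(lapply(train_d, `[[`, "labels")),
      num_trees = num_trees, seed = seed)
    d <- sample_data(test_sample)
    p <- predict_binding(model, d$matrices)
    ev <- evaluate_predictions(p, d$labels)
    test_sites <- sites
  }
  list(model = model, eval = ev,
       site_scores = tibble(chrom = test_sites$chrom,
                            start = test_sites$start, end = test_sites$end,
                            probability = p))
}

#' Ground-truth-labeled dataset from a synthetic loop study
#'
#' Builds the planted classification problem of a simulated study: every
#' true loop (windowed, span-filtered, anchor motifs assigned) is a
#' positive; an equal number of span-matched unbound motif pairs are drawn
#' as negatives; features come from one sample's tracks. Labels are the
#' generator's planted status, so classifier performance measures feature
#' recovery, not labeling noise.
#'
#' @param study_dir Directory written by [simulate_loop_study()].
#' @param sample Sample whose tracks provide the features.
#' @param marks Feature marks (tracks present in the sample directory).
#' @param half_width Window half-width in bp.
#' @param seed Seed for negative sampling.
#' @return A list: `features` (tibble) and `labels`
#'   (`"positive"`/`"negative"`).
#' @export
planted_loop_dataset <- function(study_dir, sample,
                                 marks = c("ctcf", "h3k4me1", "h3k9me3",
                                           "h3k27me3", "h3k27ac"),
                                 half_width = 500, seed = 1) {
  truth <- readr::read_tsv(file.path(study_dir, "ground_truth.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  loops <- read_bedpe_loops(file.path(study_dir, "loops.bedpe")) |>
    filter_loops() |>
    add_loop_windows(half_width = half_width) |>
    filter_span()
  motifs <- read_fimo_tsv(file.path(study_dir, "motifs.tsv"))
  peaks <- load_sample_tracks(study_dir, sample, c("ctcf", "rad21"))
  cands <- assign_anchor_motifs(loops, motifs)
  pos <- cands |>
    dplyr::semi_join(filter(truth, .data$status == "true"), by = "loop_id") |>
    filter(!is.na(.data$start_motif_score), !is.na(.data$end_motif_score))
  neg <- sample_negatives(motifs, peaks$ctcf, peaks$rad21, n = nrow(pos),
                          seed = seed, half_width = half_width,
                          positive_spans = pos$span)
  all_cands <- bind_rows(pos, neg)
  features <- sample_features(all_cands, study_dir, sample, marks = marks)
  list(features = features,
       labels = c(rep("positive", nrow(pos)), rep("negative", nrow(neg))))
}
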
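site_tbl <- function(chrom, mid, score = 12) {
  tibble::tibble(chrom = chrom, start = as.integer(mid - 9),
                 end = as.integer(mid + 10), strand = "+",
                 score = score, p_value = 1e-5)
}

test_that("site matrices tile 500 bp into twenty 25-bp flags", {
  sites <- site_tbl("chr1", 5000)
  # a peak covering bins 8-11 only: bins count from mid - 250
  tracks <- list(dnase = tibble::tibble(
    chrom = "chr1", start = 4925L, end = 5025L))
  m <- build_site_matrices(sites, tracks)
  flags <- as.numeric(m[1, sprintf("dnase_bin%02d", 1:20)])
  expect_equal(which(flags == 1), 8:11)
  expect_equal(ncol(m), 2 + 20)  # site_id + fimo_score + 20 bins
  expect_equal(m$fimo_score, 12)
  expect_error(build_site_matrices(sites, tracks, span = 510), "divisible")
  expect_error(build_site_matrices(sites, tracks,
                                   track_names = c("dnase", "h3k4me3")),
               "h3k4me3")
})

test_that("bins beyond the chromosome start are clamped to zero", {
  sites <- site_tbl("chr1", 100)
  blanket <- list(dnase = tibble::tibble(chrom = "chr1", start = 0L,
                                         end = 10000L))
  m <- build_site_matrices(sites, blanket)
  flags <- as.numeric(m[1, sprintf("dnase_bin%02d", 1:20)])
  # bins 1-6 end at or before position 0 (mid 100 - 250 + b*25 <= 0)
  expect_equal(flags[1:6], rep(0, 6))
  expect_equal(flags[7:20], rep(1, 14))
})

test_that("site matrices and labels match brute force on random tracks", {
  withr::with_seed(29, {
    sites <- site_tbl("chrA", sample(500:9000, 30))
    tracks <- list(
      dnase = random_intervals(50, "chrA", max_pos = 10000, max_len = 60),
      h3k27ac = random_intervals(50, "chrA", max_pos = 10000, max_len = 60)
    )
    ctcf <- random_intervals(25, "chrA", max_pos = 10000, max_len = 60)
  })
  m <- build_site_matrices(sites, tracks)
  for (i in seq_len(nrow(sites))) {
    mid <- floor((sites$start[i] + sites$end[i]) / 2)
    want <- bf_site_matrix_row("chrA", mid, tracks, 500, 25)
    got <- as.numeric(m[i, -(1:2)])
    expect_equal(got, want)
  }
  labs <- label_sites(sites, ctcf)
  for (i in seq_len(nrow(sites))) {
    expect_equal(labs[i] == "bound",
                 bf_any_overlap(ctcf, "chrA", sites$start[i], sites$end[i]))
  }
})

test_that("occupancy labels follow 1-bp overlap semantics", {
  peaks <- tibble::tibble(chrom = "chr1", start = 1000L, end = 1100L)
  inside <- site_tbl("chr1", 1050)
  outside <- tibble::tibble(chrom = "chr1", start = 1100L, end = 1119L,
                            strand = "+", score = 10, p_value = 1e-5)
  expect_equal(label_sites(inside, peaks), "bound")
  expect_equal(label_sites(outside, peaks), "unbound")
})

test_that("the forest recovers a planted occupancy rule and is seeded", {
  study <- small_binding_study()
  sites <- read_fimo_tsv(file.path(study$dir, "sites.tsv"))
  tracks <- load_sample_tracks(study$dir, "control1",
                               study$config$tracks)
  ctcf <- load_sample_tracks(study$dir, "control1", "ctcf")$ctcf
  mats <- build_site_matrices(sites, tracks)
  labels <- label_sites(sites, ctcf)
  mats$label <- labels
  parts <- split_train_test(mats, seed = 3)
  model <- train_binding_model(dplyr::select(parts$train, -label),
                               parts$train$label, num_trees = 200, seed = 3)
  p <- predict_binding(model, dplyr::select(parts$test, -label))
  ev <- evaluate_predictions(p, parts$test$label)
  expect_gte(ev$roc_auc, 0.95)

  # same seed, same probabilities
  model2 <- train_binding_model(dplyr::select(parts$train, -label),
                                parts$train$label, num_trees = 200, seed = 3)
  expect_identical(predict_binding(model2, dplyr::select(parts$test, -label)),
                   p)

  # shuffled labels: chance level
  withr::with_seed(5, shuffled <- sample(parts$train$label))
  null_model <- train_binding_model(dplyr::select(parts$train, -label),
                                    shuffled, num_trees = 200, seed = 3)
  ev_null <- evaluate_predictions(
    predict_binding(null_model, dplyr::select(parts$test, -label)),
    parts$test$label)
  expect_gt(ev_null$roc_auc, 0.35)
  expect_lt(ev_null$roc_auc, 0.65)

  expect_error(predict_binding(model, mats[, -3]), "mismatch")
})

test_that("all three evaluation regimes run on the multi-sample fixture", {
  study <- small_binding_study()
  controls <- c("control1", "control2", "control3")
  r_self <- run_binding_workflow(study$dir, "self", "control1",
                                 num_trees = 150, seed = 2)
  r_loo <- run_binding_workflow(study$dir, "loo", controls,
                                num_trees = 150, seed = 2)
  r_cross <- run_binding_workflow(study$dir, "cross", controls,
                                  test_sample = "case1",
                                  num_trees = 150, seed = 2)
  for (r in list(r_self, r_loo, r_cross)) {
    expect_s3_class(r$eval, "eval_report")
    expect_gte(r$eval$roc_auc, 0.9)
    expect_true(all(r$site_scores$probability >= 0 &
                      r$site_scores$probability <= 1))
  }
})
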
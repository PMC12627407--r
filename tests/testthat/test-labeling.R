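windowed_loop <- function(chrom = "chr1", m1 = 10000L, m2 = 50000L,
                          half_width = 500) {
  add_loop_windows(tibble::tibble(
    loop_id = "l1", chrom = chrom,
    start1 = m1 - 50L, end1 = m1 + 50L,
    start2 = m2 - 50L, end2 = m2 + 50L,
    pet_count = 3L, fdr = 0.01
  ), half_width = half_width)
}

motif_tbl <- function(chrom, start, strand, score, width = 19L) {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(start + width), strand = strand,
                 score = score, p_value = 1e-5)
}

test_that("anchor motif assignment keeps the best-scoring hit", {
  w <- windowed_loop()
  motifs <- motif_tbl("chr1", c(9800, 10100, 49900), c("+", "+", "-"),
                      c(12.1, 18.4, 15))
  out <- assign_anchor_motifs(w, motifs)
  expect_equal(out$start_motif_score, 18.4)
  expect_equal(out$start_motif_start, 10100L)
  expect_equal(out$end_motif_score, 15)

  # tie on score: leftmost start wins
  tie <- assign_anchor_motifs(w, motif_tbl("chr1", c(10100, 9800),
                                           c("+", "+"), c(10, 10)))
  expect_equal(tie$start_motif_start, 9800L)

  # no hit in a window -> absent
  none <- assign_anchor_motifs(w, motif_tbl("chr1", 9800, "+", 10))
  expect_true(is.na(none$end_motif_score))
})

test_that("convergence requires forward upstream and reverse downstream", {
  expect_true(is_convergent("+", "-"))
  expect_false(is_convergent("-", "+"))   # divergent
  expect_false(is_convergent("+", "+"))   # tandem
  expect_false(is_convergent("-", "-"))
  expect_false(is_convergent(NA, "-"))
})

test_that("loop labeling enforces convergence, occupancy and RAD21", {
  w <- windowed_loop()
  motifs <- motif_tbl("chr1", c(10000, 50000), c("+", "-"), c(15, 14))
  cand <- assign_anchor_motifs(w, motifs)
  ctcf <- tibble::tibble(chrom = "chr1", start = c(9990L, 49990L),
                         end = c(10040L, 50040L))
  rad_start <- tibble::tibble(chrom = "chr1", start = 9900L, end = 10100L)
  no_peaks <- tibble::tibble(chrom = character(), start = integer(),
                             end = integer())

  expect_equal(label_loops(cand, ctcf, rad_start)$label, "positive")
  expect_equal(label_loops(cand, ctcf, no_peaks)$label, "negative")
  expect_equal(label_loops(cand, no_peaks, rad_start)$label, "negative")

  # divergent motifs fail unless convergence is waived
  div <- assign_anchor_motifs(
    w, motif_tbl("chr1", c(10000, 50000), c("-", "+"), c(15, 14)))
  expect_equal(label_loops(div, ctcf, rad_start)$label, "negative")
  expect_equal(label_loops(div, ctcf, rad_start,
                           require_convergent = FALSE)$label, "positive")

  # missing anchor motif -> unlabeled with a reason
  miss <- assign_anchor_motifs(w, motif_tbl("chr1", 10000, "+", 15))
  lab <- label_loops(miss, ctcf, rad_start)
  expect_equal(lab$label, "unlabeled")
  expect_equal(lab$label_reason, "missing_anchor_motif")
})

test_that("labeling matches direct predicate evaluation on random candidates", {
  withr::with_seed(21, {
    n <- 60
    m1 <- sample.int(5e5, n) + 2000L
    m2 <- m1 + sample(2000:80000, n, replace = TRUE)
    loops <- tibble::tibble(
      loop_id = sprintf("l%d", 1:n), chrom = "chr1",
      start1 = m1 - 50L, end1 = m1 + 50L,
      start2 = m2 - 50L, end2 = m2 + 50L,
      pet_count = 3L, fdr = 0.01
    )
    w <- add_loop_windows(loops, half_width = 500)
    motifs <- motif_tbl("chr1",
                        c(m1 + sample(-400:400, n, replace = TRUE),
                          m2 + sample(-400:400, n, replace = TRUE)),
                        sample(c("+", "-"), 2 * n, replace = TRUE),
                        round(runif(2 * n, 8, 20), 2))
    ctcf <- random_intervals(80, chroms = "chr1", max_pos = 6e5,
                             max_len = 400)
    rad21 <- random_intervals(40, chroms = "chr1", max_pos = 6e5,
                              max_len = 400)
  })
  cands <- assign_anchor_motifs(w, motifs)
  got <- label_loops(cands, ctcf, rad21)$label
  want <- vapply(seq_len(nrow(cands)), function(i) {
    bf_label_one(as.list(cands[i, ]), ctcf, rad21)
  }, character(1))
  expect_equal(got, want)
})

test_that("negative sampling honours every exclusion predicate and the seed", {
  withr::with_seed(31, {
    motifs <- motif_tbl("chr1", sample.int(2e6, 300),
                        sample(c("+", "-"), 300, replace = TRUE),
                        round(runif(300, 8, 20), 2))
    ctcf <- random_intervals(40, chroms = "chr1", max_pos = 2e6,
                             max_len = 300)
    rad21 <- random_intervals(30, chroms = "chr1", max_pos = 2e6,
                              max_len = 300)
  })
  neg <- sample_negatives(motifs, ctcf, rad21, n = 25,
                          span_range = c(2000, 500000), seed = 5)
  expect_lte(nrow(neg), 25)
  expect_true(all(neg$label == "negative"))
  expect_true(all(neg$span >= 2000 & neg$span <= 500000))
  for (i in seq_len(nrow(neg))) {
    r <- as.list(neg[i, ])
    expect_false(bf_any_overlap(ctcf, r$chrom, r$start_motif_start,
                                r$start_motif_end))
    expect_false(bf_any_overlap(ctcf, r$chrom, r$end_motif_start,
                                r$end_motif_end))
    expect_false(bf_any_overlap(rad21, r$chrom, r$sw_start, r$sw_end))
    expect_false(bf_any_overlap(rad21, r$chrom, r$ew_start, r$ew_end))
    expect_false(bf_any_overlap(rad21, r$chrom, r$il_start, r$il_end))
  }
  # determinism
  neg2 <- sample_negatives(motifs, ctcf, rad21, n = 25,
                           span_range = c(2000, 500000), seed = 5)
  expect_identical(neg, neg2)
  # different seed gives a different draw
  neg3 <- sample_negatives(motifs, ctcf, rad21, n = 25,
                           span_range = c(2000, 500000), seed = 6)
  expect_false(identical(neg$start1, neg3$start1))

  # no eligible motifs -> empty with a warning
  all_bound <- motifs
  blanket <- tibble::tibble(chrom = "chr1", start = 0L, end = 3e6)
  expect_warning(
    none <- sample_negatives(all_bound, blanket, rad21, n = 5, seed = 1),
    "eligible|empty")
  expect_equal(nrow(none), 0)
})

test_that("sampled negative spans track the positive span distribution", {
  withr::with_seed(41, {
    motifs <- motif_tbl("chr1", sample.int(5e6, 2000),
                        sample(c("+", "-"), 2000, replace = TRUE),
                        round(runif(2000, 8, 20), 2))
    no_peaks <- tibble::tibble(chrom = character(), start = integer(),
                               end = integer())
    pos_spans <- round(10^runif(400, log10(4000), log10(300000)))
  })
  neg <- sample_negatives(motifs, no_peaks, no_peaks, n = 400,
                          span_range = c(2000, 2e6), seed = 9,
                          positive_spans = pos_spans)
  expect_equal(nrow(neg), 400)
  # medians of log-span agree within a quarter decade
  expect_lt(abs(median(log10(neg$span)) - median(log10(pos_spans))), 0.25)
})
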
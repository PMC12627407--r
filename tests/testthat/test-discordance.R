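test_that("the discordant score reproduces the reported worked examples", {
  # top lost loop: control 1.0 vs case 8.93e-5
  expect_equal(round(discordant_score(1.0, 8.93e-5), 6), 0.999821)
  # top gained loop: control 0.0 vs case 0.999782
  expect_equal(round(discordant_score(0.0, 0.999782), 6), 0.999564)
})

test_that("the discordant score is a symmetric, bounded squared difference", {
  withr::with_seed(3, {
    a <- runif(100); b <- runif(100)
  })
  expect_equal(discordant_score(a, b), discordant_score(b, a))
  expect_equal(discordant_score(a, a), rep(0, 100))
  expect_true(all(discordant_score(a, b) >= 0 & discordant_score(a, b) <= 1))
  expect_error(discordant_score(1.2, 0.5), "\\[0, 1\\]")
  expect_error(discordant_score(0.5, -0.1), "\\[0, 1\\]")
})

test_that("loop classification implements the lost/gained conditions", {
  rec <- tibble::tibble(
    s_control = c(1.0, 0.0, 0.7, 0.9995, 0.999, 0.0004),
    s_case = c(1e-4, 0.9995, 0.7, 0.0004, 1e-4, 0.99995)
  )
  out <- classify_loops(rec)
  expect_equal(out$klass,
               c("lost", "gained", "concordant", "lost", "concordant",
                 "gained"))
  expect_equal(out$d_score, (rec$s_control - rec$s_case)^2)

  # the classes partition the unit square: exactly one class everywhere
  withr::with_seed(5, {
    grid <- tibble::tibble(s_control = runif(500), s_case = runif(500))
  })
  klass <- classify_loops(grid)$klass
  expect_true(all(klass %in% c("lost", "gained", "concordant")))
  expect_length(klass, 500)
})

test_that("control scores aggregate by mean over complete samples", {
  long <- tibble::tibble(
    loop_id = rep(c("a", "b"), each = 3),
    sample = rep(c("s1", "s2", "s3"), 2),
    score = c(1, 1, 1, 0.9, 1.0, 0.8)
  )
  agg <- aggregate_control_scores(long)
  expect_equal(agg$s_control, c(1, 0.9))
  # single sample is the identity
  single <- aggregate_control_scores(
    tibble::tibble(loop_id = "a", sample = "s1", score = 0.42))
  expect_equal(single$s_control, 0.42)
  expect_error(aggregate_control_scores(long[-1, ]), "every control sample")
})

test_that("gene annotation picks the longest-overlap gene", {
  rec <- tibble::tibble(
    loop_id = "l1", chrom = "chr1",
    start1 = 99950L, end1 = 100050L, start2 = 199950L, end2 = 200050L
  )
  genes <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    gene_name = c("SHORT", "LONG", "ELSEWHERE"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(110000L, 120000L, 110000L),
    end = c(115000L, 150000L, 190000L),
    strand = "+"
  )
  ann <- annotate_loop_genes(rec, genes)
  expect_equal(ann$gene_name, "LONG")
  expect_equal(ann$overlap_bp, 30000L)

  none <- annotate_loop_genes(
    dplyr::mutate(rec, chrom = "chr9"), genes)
  expect_true(is.na(none$gene_name))

  # top-2 reporting duplicates the loop row
  two <- annotate_loop_genes(rec, genes, k = 2)
  expect_equal(nrow(two), 2)
  expect_equal(two$gene_name, c("LONG", "SHORT"))
  expect_equal(two$gene_rank, 1:2)
})

test_that("gene annotation matches brute-force intersection lengths", {
  withr::with_seed(37, {
    n <- 40
    m1 <- sample.int(5e5, n)
    recs <- tibble::tibble(
      loop_id = sprintf("l%d", 1:n), chrom = "chr1",
      start1 = m1 - 50L, end1 = m1 + 50L,
      start2 = m1 + sample(5000:100000, n) - 50L,
      end2 = m1 + sample(5000:100000, n) + 50L
    )
    recs$end2 <- pmax(recs$end2, recs$start2 + 100L)
    genes <- tibble::tibble(
      gene_id = sprintf("g%d", 1:60),
      gene_name = sprintf("G%02d", 1:60),
      chrom = "chr1",
      start = sample.int(6e5, 60)
    ) |>
      dplyr::mutate(end = start + sample(1000:50000, 60), strand = "+")
  })
  ann <- annotate_loop_genes(recs, genes)
  for (i in seq_len(nrow(recs))) {
    mid1 <- floor((recs$start1[i] + recs$end1[i]) / 2)
    mid2 <- floor((recs$start2[i] + recs$end2[i]) / 2)
    expect_equal(ann$gene_name[i], bf_best_gene("chr1", mid1, mid2, genes),
                 info = sprintf("loop %d", i))
  }
})

test_that("gene ranking sums discordant scores within class", {
  rec <- tibble::tibble(
    klass = c("lost", "lost", "lost", "gained", "concordant", "lost"),
    gene_name = c("A", "A", "B", "C", "D", NA),
    d_score = c(0.4, 0.5, 0.3, 0.99, 0.9, 0.7)
  )
  rk <- rank_genes(rec)
  lost <- rk[rk$klass == "lost", ]
  expect_equal(lost$gene_name, c("A", "B"))
  expect_equal(lost$total_d_score, c(0.9, 0.3))
  expect_equal(lost$n_loops, c(2L, 1L))
  # concordant-only and unannotated loops never appear
  expect_false("D" %in% rk$gene_name)
  expect_equal(rk$gene_name[rk$klass == "gained"], "C")

  # brute-force group sums on random records
  withr::with_seed(41, {
    rnd <- tibble::tibble(
      klass = sample(c("lost", "gained", "concordant"), 200, replace = TRUE),
      gene_name = sample(LETTERS[1:8], 200, replace = TRUE),
      d_score = runif(200)
    )
  })
  rk2 <- rank_genes(rnd, top_n = 100)
  for (i in seq_len(nrow(rk2))) {
    rows <- rnd$klass == rk2$klass[i] & rnd$gene_name == rk2$gene_name[i]
    expect_equal(rk2$total_d_score[i], sum(rnd$d_score[rows]))
  }
  # descending within class
  for (kl in c("lost", "gained")) {
    v <- rk2$total_d_score[rk2$klass == kl]
    expect_true(all(diff(v) <= 0))
  }
})
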
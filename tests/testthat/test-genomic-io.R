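test_that("narrowPeak reader maps fields and applies the skip rule", {
  path <- write_lines_file(c(
    narrowpeak_line("chr1", 100, 600, signal = 5.2, name = "pk1"),
    narrowpeak_line("chr1", 900, 700, name = "inverted")
  ))
  expect_warning(x <- read_narrowpeak(path), "end <= start")
  expect_equal(nrow(x), 1)
  expect_equal(x$chrom, "chr1")
  expect_equal(x$start, 100L)
  expect_equal(x$end, 600L)
  expect_equal(x$score, 5.2)
  expect_equal(attr(x, "n_skipped"), 1L)

  empty <- write_lines_file(character(0))
  expect_no_warning(y <- read_narrowpeak(empty))
  expect_equal(nrow(y), 0)
  expect_equal(attr(y, "n_skipped"), 0L)

  expect_error(read_narrowpeak(tempfile()), "not found")
  short <- write_lines_file("chr1\t1\t10")
  expect_error(read_narrowpeak(short), ">= 10")
})

test_that("bedpe reader normalises anchors and drops inter-chromosomal rows", {
  path <- write_lines_file(c(
    paste("chr2", 5000, 6000, "chr2", 1000, 2000, 5, 0.001, 0.01, sep = "\t"),
    paste("chr2", 100, 200, "chr3", 1000, 2000, 5, 0.001, 0.01, sep = "\t"),
    paste("chr1", 100, 200, "chr1", 5000, 6000, 3, 0.002, 0.02, sep = "\t")
  ))
  expect_warning(x <- read_bedpe_loops(path), "inter-chromosomal")
  expect_equal(nrow(x), 2)
  expect_equal(attr(x, "n_interchrom"), 1L)
  # flipped row stored with the left anchor first
  expect_equal(x$start1[1], 1000L)
  expect_equal(x$start2[1], 5000L)
  expect_equal(x$pet_count, c(5L, 3L))
  expect_equal(x$fdr, c(0.01, 0.02))

  bad <- write_lines_file("chr1\t1\t2\tchr1\t3")
  expect_error(read_bedpe_loops(bad), "line 1")

  ok3 <- write_lines_file(vapply(1:3, function(i) {
    paste("chr1", i * 100, i * 100 + 50, "chr1", i * 1000, i * 1000 + 50,
          2, 0.1, 0.01, sep = "\t")
  }, character(1)))
  expect_equal(nrow(read_bedpe_loops(ok3)), 3)
})

test_that("FIMO reader converts coordinates and rejects unstranded hits", {
  path <- write_lines_file(c(
    fimo_header,
    fimo_line("chr5", 101, 119, "+", score = 14.5, p = 2e-6),
    fimo_line("chr5", 300, 318, ".", score = 9, p = 1e-4)
  ), ext = ".tsv")
  expect_warning(x <- read_fimo_tsv(path), "strand")
  expect_equal(nrow(x), 1)
  expect_equal(x$start, 100L)   # 1-based inclusive 101 -> 0-based 100
  expect_equal(x$end, 119L)
  expect_equal(x$score, 14.5)
  expect_equal(x$p_value, 2e-6)

  header_only <- write_lines_file(fimo_header, ext = ".tsv")
  expect_equal(nrow(read_fimo_tsv(header_only)), 0)

  bad <- write_lines_file(
    paste("motif_id", "sequence_name", "start", sep = "\t"), ext = ".tsv")
  expect_error(read_fimo_tsv(bad), "stop")
})

test_that("GTF reader keeps gene features only and converts coordinates", {
  gene <- function(id, name, start1, end1) {
    sprintf("chr1\tsrc\tgene\t%d\t%d\t.\t+\t.\tgene_id \"%s\"; gene_name \"%s\";",
            start1, end1, id, name)
  }
  exon <- "chr1\tsrc\texon\t1100\t1200\t.\t+\t.\tgene_id \"g1\";"
  path <- write_lines_file(c(gene("g1", "ALPHA", 1001, 2000),
                             rep(exon, 5),
                             gene("g2", "BETA", 5001, 6000)), ext = ".gtf")
  x <- read_gtf_genes(path)
  expect_equal(nrow(x), 2)
  expect_equal(x$start[x$gene_id == "g1"], 1000L)
  expect_equal(x$end[x$gene_id == "g1"], 2000L)
  expect_equal(sort(x$gene_name), c("ALPHA", "BETA"))

  dup <- write_lines_file(c(gene("g1", "A", 1, 10), gene("g1", "A", 50, 90)),
                          ext = ".gtf")
  expect_error(read_gtf_genes(dup), "duplicated")
})

test_that("pipeline tables round-trip through write/read at 6-decimal precision", {
  withr::with_seed(42, {
    x <- tibble::tibble(
      loop_id = sprintf("loop_%03d", 1:20),
      chrom = sample(c("chr1", "chr2"), 20, replace = TRUE),
      start1 = sample.int(1e6, 20), end1 = sample.int(1e6, 20),
      start2 = sample.int(1e6, 20), end2 = sample.int(1e6, 20),
      score = round(runif(20), 6)
    )
  })
  path <- tempfile(fileext = ".tsv")
  write_genomic_table(x, path, "scores")
  y <- read_genomic_table(path, "scores")
  expect_equal(as.data.frame(y), as.data.frame(x), tolerance = 1e-6)

  # empty collection -> header-only file
  write_genomic_table(x[0, ], path, "scores")
  expect_equal(length(readLines(path)), 1)
  expect_equal(nrow(read_genomic_table(path, "scores")), 0)

  expect_error(write_genomic_table(x[, -1], path, "scores"), "loop_id")
})

test_that("discordance tables carry the reported-layout columns", {
  rec <- tibble::tibble(
    loop_id = "loop_1", chrom = "chr10", startloop = 124025000L,
    endloop = 124095000L, s_control = 1, s_case = 8.93e-5,
    d_score = 0.999821, klass = "lost", gene_name = "CHST15",
    overlap_bp = 35000L
  )
  path <- tempfile(fileext = ".tsv")
  write_genomic_table(rec, path, "discordance")
  line <- readLines(path)[2]
  expect_match(line, "chr10\t124025000\t124095000\t")
  expect_match(line, "0\\.999821")
  expect_match(line, "CHST15")
})
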
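# Shared small fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

# a small loop study used by several module tests
small_loop_study <- function() {
  if (is.null(.fixture_cache$loop_study)) {
    dir <- file.path(tempdir(), "ctcfloops-small-study")
    unlink(dir, recursive = TRUE)
    cfg <- loop_study_config(
      n_true_loops = 80, n_decoy_loops = 24, n_background_motifs = 1200,
      chrom_length = 8e6, n_extra_genes = 15, seed = 101
    )
    res <- suppressWarnings(simulate_loop_study(dir, cfg))
    .fixture_cache$loop_study <- res
  }
  .fixture_cache$loop_study
}

small_binding_study <- function() {
  if (is.null(.fixture_cache$binding_study)) {
    dir <- file.path(tempdir(), "ctcfloops-small-binding")
    unlink(dir, recursive = TRUE)
    cfg <- binding_study_config(n_sites = 900, chrom_length = 8e6, seed = 202)
    .fixture_cache$binding_study <- simulate_binding_study(dir, cfg)
  }
  .fixture_cache$binding_study
}

write_lines_file <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

fimo_header <- paste("motif_id", "motif_alt_id", "sequence_name", "start",
                     "stop", "strand", "score", "p-value", "q-value",
                     "matched_sequence", sep = "\t")

fimo_line <- function(chrom, start1, stop1, strand, score = 10, p = 1e-5) {
  paste("MA0139.1", "CTCF", chrom, start1, stop1, strand, score, p, "", "",
        sep = "\t")
}

narrowpeak_line <- function(chrom, start, end, signal = 5.2, name = "pk") {
  paste(chrom, start, end, name, 0, ".", signal, -1, -1,
        floor((end - start) / 2), sep = "\t")
}
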